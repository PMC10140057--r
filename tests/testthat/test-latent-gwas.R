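test_that("Pillai MANOVA matches the reference implementation and ANOVA reduction", {
  ## identical group means (generic scatter): V = 0, p = 1
  set.seed(1)
  Z0 <- do.call(rbind, lapply(1:3, function(i) {
    S <- matrix(rnorm(15), 5, 3)
    sweep(S, 2, colMeans(S))       # every group mean is exactly zero
  }))
  g0 <- rep(0:2, each = 5)
  r0 <- manova_pillai(Z0, g0, min_class_size = 1)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  ## p = 1 reduces to the one-way ANOVA F
  z1 <- c(1, 2, 3, 2, 3, 4, 7, 8, 9)
  g1 <- rep(0:2, each = 3)
  r1 <- manova_pillai(matrix(z1, ncol = 1), g1, min_class_size = 1)
  a <- anova(lm(z1 ~ factor(g1)))
  expect_equal(r1$F, a$`F value`[1], tolerance = 1e-10)
  expect_equal(r1$p, a$`Pr(>F)`[1], tolerance = 1e-10)

  ## random data against stats::manova with the Pillai test
  set.seed(2)
  Z <- matrix(rnorm(200 * 5), 200, 5)
  g <- sample(0:2, 200, replace = TRUE)
  r <- manova_pillai(Z, g)
  ref <- summary(manova(Z ~ factor(g)), test = "Pillai")$stats
  expect_equal(r$statistic, unname(ref[1, "Pillai"]), tolerance = 1e-8)
  expect_equal(r$F, unname(ref[1, "approx F"]), tolerance = 1e-8)
  expect_equal(r$df1, unname(ref[1, "num Df"]))
  expect_equal(r$df2, unname(ref[1, "den Df"]))
  expect_equal(r$p, unname(ref[1, "Pr(>F)"]), tolerance = 1e-8)

  ## invariance under orthogonal transforms and positive scaling of Z
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  r_rot <- manova_pillai(Z %*% Q * 3.7, g)
  expect_equal(r_rot$statistic, r$statistic, tolerance = 1e-8)

  ## missing dosages excluded; undersized classes merged
  gm <- g; gm[1:5] <- NA
  rm_ <- manova_pillai(Z, gm)
  expect_equal(rm_$n, 195)
  g_small <- c(rep(0, 50), rep(1, 50), rep(2, 3))
  rs <- manova_pillai(Z[1:103, ], g_small, min_class_size = 10)
  expect_length(rs$group_sizes, 2)
  expect_equal(sort(rs$group_sizes), c(50, 53))

  ## single remaining group is skipped with a reason
  r_one <- manova_pillai(Z[1:20, ], rep(0, 20))
  expect_true(is.na(r_one$p))
  expect_match(r_one$skip_reason, "fewer than 2")
})

test_that("genomic-control lambda follows the chi-square definition", {
  expect_equal(genomic_control_lambda(rep(0.5, 11)), 1)
  expect_equal(genomic_control_lambda(rep(0.25, 11)),
               qchisq(0.75, 1) / qchisq(0.5, 1), tolerance = 1e-12)
  set.seed(4)
  expect_lt(abs(genomic_control_lambda(runif(10001)) - 1), 0.07)
  expect_error(genomic_control_lambda(numeric(0)), "no p-values")
  expect_error(genomic_control_lambda(c(0.5, 0)), "p-values must")
})

test_that("unsupervised GWAS guards, filters and records skips", {
  ch <- small_cohort(n = 80, n_snps = 6, seed = 4,
                     maf_range = c(0.3, 0.5), confounder_strength = 0)
  expect_error(run_unsupervised_gwas(ch$z_true, ch$genotypes),
               "projection state")
  gs <- run_unsupervised_gwas(ch$z_true, ch$genotypes, allow_unprojected = TRUE,
                              min_mac = 20)
  expect_equal(nrow(gs$records), 6)

  ## monomorphic SNP lands in the records with a skip reason and no p
  G2 <- cbind(ch$genotypes, mono = 0L)
  gs2 <- run_unsupervised_gwas(ch$z_true, G2, allow_unprojected = TRUE)
  rec <- gs2$records[gs2$records$snp == "mono", ]
  expect_true(is.na(rec$p))
  expect_match(rec$skip_reason, "minor allele count")

  expect_error(run_unsupervised_gwas(ch$z_true[1:10, ], ch$genotypes,
                                     allow_unprojected = TRUE), "misalignment")
})

test_that("cohort-wide phenotype inference follows the 80/20 protocol", {
  set.seed(5)
  n <- 1000
  emb <- matrix(rnorm(n * 6), n, 6)
  beta <- rnorm(6)
  y_full <- drop(emb %*% beta)
  labels <- rep(NA_real_, n)
  lab_idx <- sample(n, 100)
  labels[lab_idx] <- y_full[lab_idx]

  out <- predict_phenotype_cohortwide(emb, labels, ridge_lambda = 1e-8, seed = 2)
  expect_length(out$predictions, n)
  expect_equal(out$n_train, 80)
  expect_equal(out$n_heldout, 20)
  expect_gt(out$heldout_r2, 0.99)
  expect_equal(out$predictions, y_full, tolerance = 1e-3)

  ## constant labels
  labc <- rep(NA_real_, n); labc[lab_idx] <- 3
  expect_warning(outc <- predict_phenotype_cohortwide(emb, labc), "constant")
  expect_true(all(outc$predictions == 3))

  expect_error(predict_phenotype_cohortwide(emb, rep(NA_real_, n)), "at least 10")
})

test_that("supervised GWAS matches an OLS oracle and stays calibrated under the null", {
  ## small worked matrix against lm()
  set.seed(6)
  n <- 40
  g <- rbinom(n, 2, 0.4)
  C <- cbind(age = rnorm(n), pc1 = rnorm(n))
  y <- 0.3 * g + 0.5 * C[, 1] + rnorm(n)
  gs <- supervised_gwas(y, matrix(g, ncol = 1), C, min_mac = 1)
  fit <- summary(lm(y ~ g + C))$coefficients
  expect_equal(gs$records$stat, fit["g", "t value"], tolerance = 1e-10)
  expect_equal(gs$records$p, fit["g", "Pr(>|t|)"], tolerance = 1e-10)

  ## planted linear effect is overwhelmingly significant
  set.seed(7)
  n <- 500
  gpl <- rbinom(n, 2, 0.3)
  ypl <- 0.5 * gpl + rnorm(n, sd = 0.1)
  gsp <- supervised_gwas(ypl, matrix(gpl, ncol = 1), NULL)
  expect_lt(gsp$records$p, 1e-10)

  ## null phenotype: p-values uniform (KS) over 1000 SNPs
  set.seed(8)
  G <- matrix(rbinom(n * 1000, 2, 0.3), n, 1000)
  yn <- rnorm(n)
  gsn <- supervised_gwas(yn, G, NULL)
  expect_gt(ks.test(gsn$records$p, "punif")$p.value, 0.01)

  ## dosage collinear with a covariate is skipped
  gcol <- supervised_gwas(yn, matrix(G[, 1], ncol = 1), cbind(G[, 1]), min_mac = 1)
  expect_match(gcol$records$skip_reason, "collinear")
})
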
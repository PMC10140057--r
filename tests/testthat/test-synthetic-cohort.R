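test_that("genotype simulation respects allele-frequency structure", {
  G <- simulate_genotypes(4, 1, c(0.5, 0.5), seed = 3)
  expect_true(all(G %in% 0:2))

  ## monomorphic limit
  G0 <- simulate_genotypes(50, 3, c(1e-9, 1e-9), seed = 3)
  expect_true(all(G0 == 0))

  ## empirical frequency within 3 binomial SDs of the target
  n <- 2000
  G3 <- simulate_genotypes(n, 1, c(0.3, 0.3), seed = 9)
  phat <- mean(G3) / 2
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(phat - 0.3), 3 * se)

  ## reproducibility and error paths
  expect_identical(simulate_genotypes(20, 5, c(0.1, 0.4), seed = 1),
                   simulate_genotypes(20, 5, c(0.1, 0.4), seed = 1))
  expect_error(simulate_genotypes(10, 2, c(0, 0.6)), "maf_range")
})

test_that("waveform renderer is a deterministic template with designed invariances", {
  roles <- crossmodal:::latent_roles(8)
  ## structural coordinates leave the waveform untouched
  z1 <- numeric(8); z2 <- numeric(8); z2[roles$structural] <- c(1.5, -2, 0.7)
  expect_identical(render_waveform(z1, noise_sd = 0, wander_sd = 0),
                   render_waveform(z2, noise_sd = 0, wander_sd = 0))

  ## golden baseline template at z = 0
  W <- render_waveform(numeric(8), noise_sd = 0, wander_sd = 0)
  gold <- read_fixture_matrix("waveform_template_z0.tsv")
  expect_equal(dim(W), c(2, 128))
  expect_equal(W, gold, tolerance = 1e-8, ignore_attr = TRUE)

  ## amplitude coordinate scales its bump by the documented affine factor:
  ## main bump amplitude is 1.4 + 0.5 * z_elec1, so z = 2 adds exactly 1.0
  ## at the bump centre relative to z = 0
  za <- numeric(8); za[roles$electrical[1]] <- 2
  Wa <- render_waveform(za, noise_sd = 0, wander_sd = 0)
  delta <- Wa[1, ] - W[1, ]
  t <- seq(0, 1, length.out = 128)
  expect_equal(max(delta), 1.0 * max(exp(-(t - 0.42)^2 / (2 * 0.022^2))),
               tolerance = 1e-6)
})

test_that("image renderer geometry follows the structural and shared coordinates", {
  ## golden fixture at z = 0
  img <- render_image(numeric(8), noise_sd = 0)
  gold <- array(read_fixture_matrix("image_template_z0.tsv"), dim = c(16, 16, 4))
  expect_equal(img, gold, tolerance = 1e-8, ignore_attr = TRUE)

  ## z-scoring post-condition
  zr <- c(0.3, -1, 2, 0.5, -0.2, 1, -1, 0.4)
  im <- render_image(zr, noise_sd = 0.05, seed = 4)
  expect_equal(mean(im), 0, tolerance = 1e-12)
  expect_equal(sd(im), 1, tolerance = 1e-12)

  ## wall-pixel count increases monotonically in the wall-thickness coordinate
  roles <- crossmodal:::latent_roles(8)
  counts <- sapply(c(-1.5, 0, 1.5), function(v) {
    z <- numeric(8); z[roles$shared[1]] <- v
    measure_wall_area(render_image(z, noise_sd = 0))
  })
  expect_true(all(diff(counts) > 0))
})

test_that("cohort generation is deterministic and plants effects additively", {
  cfg <- cohort_config(n_subjects = 64, n_snps = 3, seed = 2)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$z_true, c2$z_true)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$waveforms, c2$waveforms)

  ## no planted signal: genotype explains ~none of the latent variance
  null_cfg <- cohort_config(n_subjects = 300, n_snps = 2, seed = 8,
                            confounder_strength = 0)
  ch <- generate_cohort(null_cfg)
  r2 <- summary(lm(ch$z_true[, 1] ~ ch$genotypes))$r.squared
  expect_lt(r2, 0.05)

  ## one strong causal SNP orders latent group means by dosage
  beta <- numeric(8); beta[4] <- 1
  eff_cfg <- cohort_config(n_subjects = 300, n_snps = 2, seed = 8,
                           maf_range = c(0.4, 0.5), confounder_strength = 0,
                           causal_snps = list(list(snp = 1, beta = beta, scale = 3)))
  che <- generate_cohort(eff_cfg)
  mg <- tapply(che$z_true[, 4], che$genotypes[, 1], mean)
  expect_true(all(diff(mg[as.character(0:2)]) > 0))

  ## split sizes follow the documented floor rule
  cfg7 <- cohort_config(n_subjects = 512, seed = 7)
  ch7 <- generate_cohort(cfg7)
  expect_equal(as.vector(table(ch7$split)), c(512 - 64 - 64, 64, 64))

  ## confounder leakage is present by default (INLP has work to do)
  chc <- generate_cohort(cohort_config(n_subjects = 400, seed = 3))
  fit <- fit_confounder_map(chc$z_true, chc$confounders)
  expect_gt(fit$r2, 0.1)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(10, maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(cohort_config(10, split_fractions = c(0.5, 0.2, 0.2)), "split_fractions")
  expect_error(cohort_config(10, n_snps = 2,
                             causal_snps = list(list(snp = 5, beta = numeric(8), scale = 1))),
               "out of range")
  expect_error(cohort_config(10, n_snps = 2,
                             causal_snps = list(list(snp = 1, beta = numeric(3), scale = 1))),
               "latent_dim_true")
})
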
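#' MANOVA with Pillai's trace for one SNP
#'
#' Groups subjects by dosage class (0/1/2; classes smaller than
#' `min_class_size` are merged into the adjacent dosage class), forms the
#' between-group (H) and within-group (E) SSCP matrices, and computes
#' Pillai's trace `V = tr(H (H + E)^-1)` with the standard F approximation:
#' with `s = min(p, g - 1)`, `m* = (|p - g + 1| - 1)/2`,
#' `n* = (n - g - p - 1)/2`,
#' `F = ((2 n* + s + 1)/(2 m* + s + 1)) * V/(s - V)` on
#' `df1 = s (2 m* + s + 1)` and `df2 = s (2 n* + s + 1)` degrees of freedom.
#'
#' @param Z n x p embedding matrix.
#' @param genotype length-n dosage vector in \{0, 1, 2, NA\}; missing
#'   dosages are excluded (complete-case).
#' @param snp_id identifier carried into the record.
#' @param min_class_size dosage classes below this size are merged into the
#'   adjacent class (class 1 merges into the smaller neighbour).
#' @return an `association_record` list: `snp`, `mode`, `statistic`
#'   (Pillai V), `F`, `df1`, `df2`, `p`, `n`, `group_sizes`, `skip_reason`
#'   (`NA` when tested).
#' @export
manova_pillai <- function(Z, genotype, snp_id = "snp", min_class_size = 10L) {
  Z <- as.matrix(Z)
  keep <- !is.na(genotype)
  rec <- function(stat = NA_real_, Fv = NA_real_, df1 = NA_real_,
                  df2 = NA_real_, p = NA_real_, n = sum(keep),
                  sizes = NULL, skip = NA_character_) {
    structure(list(snp = snp_id, mode = "unsupervised", statistic = stat,
                   F = Fv, df1 = df1, df2 = df2, p = p, n = n,
                   group_sizes = sizes, skip_reason = skip),
              class = "association_record")
  }
  if (!any(keep)) return(rec(n = 0L, skip = "all dosages missing"))
  Zk <- Z[keep, , drop = FALSE]
  g_raw <- genotype[keep]
  grp <- merge_dosage_classes(g_raw, min_class_size)
  sizes <- table(grp)
  g <- length(sizes)
  if (g < 2) return(rec(sizes = as.vector(sizes), skip = "fewer than 2 genotype groups"))
  n <- length(grp); p <- ncol(Zk)
  if (n - g - p + 1 <= 0) {
    return(rec(sizes = as.vector(sizes), skip = "insufficient residual df"))
  }
  gm <- colMeans(Zk)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lev in names(sizes)) {
    Zi <- Zk[grp == lev, , drop = FALSE]
    mi <- colMeans(Zi)
    dmi <- mi - gm
    H <- H + nrow(Zi) * tcrossprod(dmi)
    Ri <- sweep(Zi, 2, mi)
    E <- E + crossprod(Ri)
  }
  HE <- H + E
  sol <- tryCatch(solve(HE, H), error = function(e) NULL)
  if (is.null(sol)) return(rec(sizes = as.vector(sizes), skip = "singular H + E"))
  V <- sum(diag(sol))
  s <- min(p, g - 1)
  m_star <- (abs(p - g + 1) - 1) / 2
  n_star <- (n - g - p - 1) / 2
  Fv <- ((2 * n_star + s + 1) / (2 * m_star + s + 1)) * (V / (s - V))
  df1 <- s * (2 * m_star + s + 1)
  df2 <- s * (2 * n_star + s + 1)
  pval <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  rec(stat = V, Fv = Fv, df1 = df1, df2 = df2, p = pval, n = n,
      sizes = as.vector(sizes))
}

# Merge undersized dosage classes into adjacent classes: 0 -> 1, 2 -> 1;
# an undersized heterozygote class joins the smaller homozygote class.
merge_dosage_classes <- function(g, min_class_size) {
  grp <- as.integer(g)
  repeat {
    tab <- table(factor(grp, levels = sort(unique(grp))))
    small <- names(tab)[tab < min_class_size & tab > 0]
    if (!length(small)) break
    lv <- as.integer(small[1])
    present <- sort(unique(grp))
    if (length(present) <= 1) break
    if (lv == min(present)) {
      target <- present[match(lv, present) + 1]
    } else if (lv == max(present)) {
      target <- present[match(lv, present) - 1]
    } else {
      lo <- present[match(lv, present) - 1]; hi <- present[match(lv, present) + 1]
      target <- if (sum(grp == lo) <= sum(grp == hi)) lo else hi
    }
    grp[grp == lv] <- target
  }
  grp
}

#' Genomic-control inflation factor
#'
#' Converts each p-value to a 1-df chi-square quantile at `1 - p` and
#' divides the median by the 1-df chi-square median (`qchisq(0.5, 1)`,
#' about 0.4549).
#'
#' @param pvals p-values in (0, 1].
#' @return lambda_GC.
#' @export
genomic_control_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

# Expected-vs-observed -log10 p table for a QQ plot.
qq_points <- function(pvals) {
  pvals <- sort(pvals[!is.na(pvals)])
  n <- length(pvals)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(pvals))
}

#' Unsupervised latent-space GWAS
#'
#' Runs [manova_pillai()] per SNP on confounder-scrubbed embeddings,
#' applying a minor-allele-count filter first, and assembles lambda_GC and
#' QQ diagnostics. Because confounded embeddings inflate the test badly,
#' the function requires evidence that INLP ran: pass the
#' `projection_state` from [inlp()], or set `allow_unprojected = TRUE`
#' explicitly (used e.g. to demonstrate the inflation).
#'
#' @param Z_clean n x p embedding matrix (post-INLP).
#' @param G n x S dosage matrix.
#' @param state the `projection_state` from [inlp()].
#' @param allow_unprojected explicit override when no state is supplied.
#' @param min_mac minimum minor-allele count (default 20).
#' @param min_class_size passed to [manova_pillai()].
#' @return object of class `gwas_summary`: `records` (data frame with snp,
#'   mode, stat, F, df1, df2, p, n, skip_reason), `lambda_gc`, `qq`,
#'   `filter_log`.
#' @export
run_unsupervised_gwas <- function(Z_clean, G, state = NULL,
                                  allow_unprojected = FALSE,
                                  min_mac = 20L, min_class_size = 10L) {
  if (is.null(state) && !allow_unprojected) {
    stop("supply the inlp() projection state, or set allow_unprojected = TRUE; ",
         "without confounder removal the MANOVA is not calibrated")
  }
  if (!is.null(state) && !inherits(state, "projection_state")) {
    stop("state must be a projection_state")
  }
  Z_clean <- as.matrix(Z_clean); G <- as.matrix(G)
  if (nrow(Z_clean) != nrow(G)) stop("row misalignment between embeddings and genotypes")
  if (!is.null(rownames(Z_clean)) && !is.null(rownames(G)) &&
      !identical(rownames(Z_clean), rownames(G))) {
    stop("subject id mismatch between embeddings and genotypes")
  }
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  filter_log <- character(0)
  rows <- vector("list", ncol(G))
  for (s in seq_len(ncol(G))) {
    dose <- G[, s]
    mac <- min(sum(dose, na.rm = TRUE), sum(2 - dose, na.rm = TRUE))
    if (is.na(mac) || mac < min_mac) {
      rows[[s]] <- data.frame(snp = snps[s], mode = "unsupervised",
                              stat = NA_real_, F = NA_real_, df1 = NA_real_,
                              df2 = NA_real_, p = NA_real_,
                              n = sum(!is.na(dose)),
                              skip_reason = sprintf("minor allele count %d < %d", mac, min_mac))
      filter_log <- c(filter_log, sprintf("%s: MAC filter (%d)", snps[s], mac))
      next
    }
    r <- manova_pillai(Z_clean, dose, snps[s], min_class_size)
    rows[[s]] <- data.frame(snp = r$snp, mode = r$mode, stat = r$statistic,
                            F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
                            n = r$n, skip_reason = r$skip_reason)
  }
  records <- do.call(rbind, rows)
  tested <- records$p[!is.na(records$p)]
  structure(list(records = records,
                 lambda_gc = if (length(tested)) genomic_control_lambda(tested) else NA_real_,
                 qq = if (length(tested)) qq_points(tested) else NULL,
                 filter_log = filter_log),
            class = "gwas_summary")
}

#' Cohort-wide phenotype inference from embeddings
#'
#' Ridge regression fitted on a seeded random 80% of the labelled rows,
#' evaluated on the held-out 20%, then applied to every cohort row --
#' turning a partially labelled phenotype into a cohort-wide predicted
#' trait for supervised GWAS.
#'
#' @param emb n x d embedding matrix for the whole cohort.
#' @param labels length-n phenotype with `NA` for unlabelled rows; at least
#'   10 labelled rows required.
#' @param ridge_lambda ridge penalty (default 1e-3 * d).
#' @param seed seed for the 80/20 split.
#' @return list with `predictions` (length n), `heldout_r2`, `n_train`,
#'   `n_heldout`, `coef`.
#' @export
predict_phenotype_cohortwide <- function(emb, labels, ridge_lambda = NULL,
                                         seed = 1L) {
  emb <- as.matrix(emb)
  lab_idx <- which(!is.na(labels))
  if (length(lab_idx) < 10) stop("need at least 10 labelled rows")
  if (is.null(ridge_lambda)) ridge_lambda <- 1e-3 * ncol(emb)
  if (stats::sd(labels[lab_idx]) == 0) {
    warning("constant labels; returning constant predictions")
    return(list(predictions = rep(labels[lab_idx][1], nrow(emb)),
                heldout_r2 = NA_real_,
                n_train = length(lab_idx), n_heldout = 0L, coef = NULL))
  }
  rs <- local_rng(seed); on.exit(rs(), add = TRUE)
  n_lab <- length(lab_idx)
  n_tr <- floor(0.8 * n_lab)
  perm <- sample(lab_idx)
  tr <- perm[seq_len(n_tr)]; ho <- perm[(n_tr + 1):n_lab]
  ctr <- colMeans(emb[tr, , drop = FALSE]); ybar <- mean(labels[tr])
  Xtr <- sweep(emb[tr, , drop = FALSE], 2, ctr)
  beta <- solve(crossprod(Xtr) + ridge_lambda * diag(ncol(Xtr)),
                crossprod(Xtr, labels[tr] - ybar))
  pred_all <- drop(sweep(emb, 2, ctr) %*% beta) + ybar
  r2 <- 1 - sum((labels[ho] - pred_all[ho])^2) /
    sum((labels[ho] - mean(labels[ho]))^2)
  list(predictions = pred_all, heldout_r2 = r2,
       n_train = n_tr, n_heldout = length(ho), coef = drop(beta))
}

#' Supervised (covariate-adjusted) GWAS on a quantitative trait
#'
#' Per SNP, ordinary least squares of the phenotype on dosage plus
#' covariates plus intercept, with a two-sided t-test on the dosage
#' coefficient. Shares the MAC filter and lambda_GC machinery with the
#' unsupervised path.
#'
#' @param phenotype length-n numeric trait (e.g. cohort-wide predictions).
#' @param G n x S dosage matrix.
#' @param C n x q covariate matrix (may have zero columns); must be full
#'   rank together with the intercept.
#' @param min_mac minimum minor-allele count.
#' @return a `gwas_summary` (records carry the dosage t statistic in
#'   `stat`).
#' @export
supervised_gwas <- function(phenotype, G, C = NULL, min_mac = 20L) {
  G <- as.matrix(G); n <- nrow(G)
  stopifnot(length(phenotype) == n)
  if (is.null(C)) C <- matrix(0, n, 0) else C <- as.matrix(C)
  X0 <- cbind(`(Intercept)` = 1, C)
  if (qr(X0)$rank < ncol(X0)) stop("covariates are rank deficient")
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  rows <- vector("list", ncol(G))
  filter_log <- character(0)
  for (s in seq_len(ncol(G))) {
    dose <- G[, s]
    keep <- !is.na(dose) & !is.na(phenotype)
    mac <- min(sum(dose[keep]), sum(2 - dose[keep]))
    skip <- NULL
    if (mac < min_mac) {
      skip <- sprintf("minor allele count %d < %d", mac, min_mac)
    } else {
      X <- cbind(X0[keep, , drop = FALSE], dose = dose[keep])
      qx <- qr(X)
      if (qx$rank < ncol(X)) {
        skip <- "dosage collinear with covariates"
      } else {
        y <- phenotype[keep]
        cf <- qr.coef(qx, y)
        res <- y - X %*% cf
        df <- sum(keep) - ncol(X)
        sigma2 <- sum(res^2) / df
        XtXinv_dd <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
        se <- sqrt(sigma2 * XtXinv_dd)
        tval <- cf[["dose"]] / se
        pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
        rows[[s]] <- data.frame(snp = snps[s], mode = "supervised",
                                stat = tval, F = tval^2, df1 = 1, df2 = df,
                                p = pval, n = sum(keep),
                                skip_reason = NA_character_)
        next
      }
    }
    filter_log <- c(filter_log, sprintf("%s: %s", snps[s], skip))
    rows[[s]] <- data.frame(snp = snps[s], mode = "supervised",
                            stat = NA_real_, F = NA_real_, df1 = NA_real_,
                            df2 = NA_real_, p = NA_real_, n = sum(keep),
                            skip_reason = skip)
  }
  records <- do.call(rbind, rows)
  tested <- records$p[!is.na(records$p)]
  structure(list(records = records,
                 lambda_gc = if (length(tested)) genomic_control_lambda(tested) else NA_real_,
                 qq = if (length(tested)) qq_points(tested) else NULL,
                 filter_log = filter_log),
            class = "gwas_summary")
}
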
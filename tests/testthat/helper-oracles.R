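# Independent oracles used across tests. Each is a direct, readable
# enumeration or closed form, deliberately separate from the package's
# implementation path.

# Brute-force paired-sample contrastive loss for two modalities.
brute_contrastive <- function(A, B, temp) {
  tau <- exp(temp)
  b <- nrow(A)
  mods <- list(A, B)
  tot <- 0
  for (pair in list(c(1, 2), c(2, 1))) {
    Z1 <- mods[[pair[1]]]; Z2 <- mods[[pair[2]]]
    for (i in seq_len(b)) {
      num <- exp(tau * sum(Z1[i, ] * Z2[i, ]))
      den1 <- sum(vapply(seq_len(b), function(ip) exp(tau * sum(Z1[ip, ] * Z2[i, ])), 1))
      den2 <- sum(vapply(seq_len(b), function(ip) exp(tau * sum(Z1[i, ] * Z2[ip, ])), 1))
      tot <- tot + log(num / den1) + log(num / den2)
    }
  }
  -tot / 2
}

# Small deterministic cohort for module tests (no training involved).
small_cohort <- function(n = 60, n_snps = 4, seed = 5, ...) {
  generate_cohort(cohort_config(n_subjects = n, n_snps = n_snps, seed = seed, ...))
}

read_fixture_matrix <- function(name) {
  M <- as.matrix(utils::read.table(test_path("fixtures", name), sep = "\t"))
  dimnames(M) <- NULL
  M
}
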
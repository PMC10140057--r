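#' Latent effect signature of one SNP
#'
#' The vector in latent space from the mean embedding of the homozygous
#' reference group (dosage 0) to the mean embedding of the combined
#' heterozygous / homozygous alternate group (dosage 1 or 2). Missing
#' dosages are excluded.
#'
#' @param Z n x d embedding matrix.
#' @param genotype length-n dosage vector.
#' @param snp_id used in error messages.
#' @return numeric d-vector.
#' @export
snp_signature <- function(Z, genotype, snp_id = "snp") {
  Z <- as.matrix(Z)
  keep <- !is.na(genotype)
  ref <- keep & genotype == 0
  alt <- keep & genotype >= 1
  if (!any(ref) || !any(alt)) {
    stop("empty genotype group for SNP ", snp_id,
         " (need both dosage-0 and dosage>=1 subjects)")
  }
  colMeans(Z[alt, , drop = FALSE]) - colMeans(Z[ref, , drop = FALSE])
}

#' Signature matrix over a set of SNPs
#'
#' @param Z n x d embedding matrix (typically cross-modal embeddings of one
#'   designated modality).
#' @param G n x S dosage matrix.
#' @param normalize unit-normalize each signature (cluster by direction
#'   only); default off, raw difference vectors.
#' @return object of class `signature_matrix`: S x d matrix `signatures`
#'   (rownames = SNP ids), `n_ref`/`n_alt` per SNP, `normalized` flag.
#'   SNPs with an empty group are dropped with a warning.
#' @export
snp_signature_matrix <- function(Z, G, normalize = FALSE) {
  G <- as.matrix(G)
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  sig <- list(); n_ref <- integer(0); n_alt <- integer(0); kept <- character(0)
  for (s in seq_len(ncol(G))) {
    v <- tryCatch(snp_signature(Z, G[, s], snps[s]), error = function(e) NULL)
    if (is.null(v)) next
    if (normalize) {
      nr <- sqrt(sum(v^2))
      if (nr > 0) v <- v / nr
    }
    sig[[length(sig) + 1]] <- v
    kept <- c(kept, snps[s])
    n_ref <- c(n_ref, sum(G[, s] == 0, na.rm = TRUE))
    n_alt <- c(n_alt, sum(G[, s] >= 1, na.rm = TRUE))
  }
  if (length(kept) < ncol(G)) {
    warning(ncol(G) - length(kept), " SNP(s) dropped for empty genotype groups")
  }
  S <- do.call(rbind, sig)
  rownames(S) <- kept
  structure(list(signatures = S, n_ref = n_ref, n_alt = n_alt,
                 normalized = normalize), class = "signature_matrix")
}

#' Ward clustering of SNP signatures
#'
#' Agglomerative clustering with Ward's linkage (`hclust` method
#' `"ward.D2"`) on Euclidean distances between signature vectors. Merge
#' heights equal `sqrt(2 * delta_ESS)` where `delta_ESS` is the increase in
#' total within-cluster sum of squares caused by the merge, so they are
#' non-decreasing. Ties are resolved by `hclust`'s deterministic order, so
#' results are reproducible given the input row order.
#'
#' @param signatures a `signature_matrix` or plain S x d matrix.
#' @param k number of flat clusters to cut (optional).
#' @param h cut height (alternative to `k`).
#' @return object of class `cluster_result`: `merge`, `height`, `order`
#'   (the dendrogram record), `labels` (flat assignment, `NULL` when no cut
#'   requested), `hclust` (the underlying object).
#' @export
cluster_signatures <- function(signatures, k = NULL, h = NULL) {
  S <- if (inherits(signatures, "signature_matrix")) signatures$signatures else as.matrix(signatures)
  if (nrow(S) < 1) stop("need at least one signature")
  if (nrow(S) == 1) {
    return(structure(list(merge = matrix(numeric(0), 0, 2), height = numeric(0),
                          order = 1L, labels = stats::setNames(1L, rownames(S)),
                          hclust = NULL), class = "cluster_result"))
  }
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  labels <- NULL
  if (!is.null(k) || !is.null(h)) {
    labels <- stats::cutree(hc, k = k, h = h)
    names(labels) <- rownames(S)
  }
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = labels, hclust = hc), class = "cluster_result")
}
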
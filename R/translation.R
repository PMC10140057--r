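#' Translate observations from one modality to another
#'
#' Encodes with the source modality's encoder and decodes with the target
#' modality's decoder: `g_to(f_from(x))`. `from == to` is permitted and is
#' plain reconstruction.
#'
#' @param model a `crossmodal_model`.
#' @param x matrix of flattened observations (rows = subjects) in the
#'   source modality.
#' @param from,to modality names.
#' @return matrix of flattened observations in the target modality.
#' @export
translate <- function(model, x, from, to) {
  for (nm in c(from, to)) {
    if (!nm %in% model$modalities) stop("unknown modality: ", nm)
  }
  Z <- mlp_forward(model$encoders[[from]], x)
  out <- mlp_forward(model$decoders[[to]], Z)
  rownames(out) <- rownames(x)
  out
}

#' Reshape a flattened translated observation back to its array form
#'
#' @param x_row numeric vector (one row of a translated matrix).
#' @param spec the target modality's shape: list with either
#'   `n_leads`/`n_timepoints` or `height`/`width`/`n_frames`.
#' @return matrix or 3-d array.
#' @export
unflatten_observation <- function(x_row, spec) {
  if (!is.null(spec$n_leads)) {
    matrix(x_row, spec$n_leads, spec$n_timepoints)
  } else {
    array(x_row, c(spec$height, spec$width, spec$n_frames))
  }
}

#' Shift an embedding along a latent direction
#'
#' `embedding + magnitude * direction/||direction||`. Decoding shifted
#' embeddings (e.g. along a SNP signature) is the caller's composition with
#' the decoders.
#'
#' @param embedding d-vector (or matrix of rows).
#' @param direction d-vector, nonzero.
#' @param magnitude scalar step along the unit direction.
#' @return shifted embedding, same shape as input.
#' @export
latent_shift <- function(embedding, direction, magnitude) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  u <- direction / nrm
  if (is.matrix(embedding)) {
    sweep(embedding, 2, magnitude * u, "+")
  } else {
    embedding + magnitude * u
  }
}

#' Top-k cross-modal retrieval accuracy
#'
#' For each query row, all target rows are ranked by cosine similarity
#' (descending, ties broken by stable index order); accuracy at k is the
#' fraction of queries whose own row index ranks within the top k. Rows of
#' the two matrices are aligned by position (row i of each belongs to
#' subject i).
#'
#' @param query_emb,target_emb n x d embedding matrices.
#' @param ks integer vector of cutoffs, `max(ks) <= n`.
#' @return object of class `retrieval_result`: data frame `accuracy` with
#'   columns `k`, `accuracy`, plus `n_queries`, `metric`, and the per-query
#'   `ranks`.
#' @export
retrieval_topk <- function(query_emb, target_emb, ks = c(1L, 5L, 10L)) {
  stopifnot(nrow(query_emb) == nrow(target_emb))
  n <- nrow(query_emb)
  if (max(ks) > n) stop("max(ks) exceeds the number of targets")
  qn <- sqrt(rowSums(query_emb^2)); tn <- sqrt(rowSums(target_emb^2))
  bad <- which(qn == 0 | tn == 0)
  if (length(bad)) {
    nm <- rownames(query_emb)
    stop("zero-norm embedding row for subject ",
         if (is.null(nm)) bad[1] else nm[bad[1]])
  }
  S <- tcrossprod(query_emb / qn, target_emb / tn)
  ranks <- vapply(seq_len(n), function(i) {
    s <- S[i, ]
    # stable tie-break: earlier index wins among equal similarities
    1L + sum(s > s[i]) + sum(s[seq_len(i - 1)] == s[i])
  }, 1L)
  acc <- vapply(ks, function(k) mean(ranks <= k), 1.0)
  structure(list(accuracy = data.frame(k = ks, accuracy = acc),
                 n_queries = n, metric = "cosine", ranks = ranks),
            class = "retrieval_result")
}
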
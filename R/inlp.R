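#' Fit the linear embedding-to-confounder map
#'
#' Least-squares `w` (m_c x d) minimizing `sum_i ||w x_i - F_i||^2` on
#' centred embeddings and standardized confounders. The pooled multivariate
#' R^2 is `1 - SS_res/SS_tot` summed over the standardized confounder
#' columns; the reported `r2` is its degrees-of-freedom-adjusted version,
#' `1 - (SS_res/(n - d - 1)) / (SS_tot/(n - 1))`, which is centred at zero
#' for confounders unrelated to the embeddings. (The raw training R^2 is
#' upward-biased by about d/n, which at moderate n would sit above any
#' small termination threshold and make the iterated projection impossible
#' to terminate; the raw value is returned as `r2_raw`.)
#'
#' @param Z n x d embedding matrix.
#' @param F_conf n x m_c numeric confounder matrix (encode factors first,
#'   e.g. with [encode_confounders()]).
#' @param standardize z-score confounder columns (default TRUE; columns
#'   with zero variance are left centred only).
#' @return list with `w` (m_c x d), `r2` (pooled, adjusted), `r2_raw`,
#'   `r2_per_column` (raw), `center_z`, `center_f`, `scale_f`.
#' @export
fit_confounder_map <- function(Z, F_conf, standardize = TRUE) {
  Z <- as.matrix(Z); F_conf <- as.matrix(F_conf)
  n <- nrow(Z); d <- ncol(Z); m_c <- ncol(F_conf)
  stopifnot(nrow(F_conf) == n, m_c >= 1)
  if (d < m_c) stop("embedding dimension below confounder count: nullspace construction impossible")
  if (n <= d) stop("need more samples than embedding dimensions")
  cz <- colMeans(Z); Zc <- sweep(Z, 2, cz)
  cf <- colMeans(F_conf); Fc <- sweep(F_conf, 2, cf)
  sf <- rep(1, m_c)
  if (standardize) {
    sf <- apply(Fc, 2, stats::sd)
    sf[sf == 0] <- 1
    Fc <- sweep(Fc, 2, sf, "/")
  }
  qz <- qr(Zc)
  if (qz$rank < d) {
    warning("rank-deficient embeddings; using minimum-norm solution")
    sv <- svd(Zc)
    pos <- sv$d > 1e-10 * sv$d[1]
    B <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], Fc) / sv$d[pos])
  } else {
    B <- qr.coef(qz, Fc)            # d x m_c
  }
  resid <- Fc - Zc %*% B
  ss_res_col <- colSums(resid^2)
  ss_tot_col <- colSums(Fc^2)
  r2_raw <- 1 - sum(ss_res_col) / sum(ss_tot_col)
  adj <- (n - 1) / max(n - d - 1, 1)
  list(w = t(B), r2 = 1 - adj * sum(ss_res_col) / sum(ss_tot_col),
       r2_raw = r2_raw, r2_per_column = 1 - ss_res_col / ss_tot_col,
       center_z = cz, center_f = cf, scale_f = sf)
}

#' Nullspace basis of a confounder predictor
#'
#' SVD `w = U S V'`; returns the bottom `d - m_c` rows of `V'` (right
#' singular vectors of the smallest singular values). Rows are orthonormal
#' and `w %*% t(Vt)` has operator norm at most the (m_c+1)-th singular
#' value (exactly 0 when `rank(w) <= m_c`). The number of removed
#' dimensions follows `m_c`, not `rank(w)`.
#'
#' @param w m_c x d matrix.
#' @return `(d - m_c) x d` matrix with orthonormal rows.
#' @export
nullspace_project <- function(w) {
  w <- as.matrix(w)
  m_c <- nrow(w); d <- ncol(w)
  if (all(w == 0)) stop("w must be nonzero")
  if (d <= m_c) stop("no nullspace rows: d <= m_c")
  # right singular vectors via the spectral decomposition of w'w (full basis)
  ev <- eigen(crossprod(w), symmetric = TRUE)
  t(ev$vectors[, (m_c + 1):d, drop = FALSE])
}

#' Iterated nullspace projection of confounders out of embeddings
#'
#' Repeats (1) fit the linear confounder map, (2) build the nullspace basis
#' of the fitted `w`, (3) replace `Z <- Z %*% t(Vt)` until the pooled
#' adjusted confounder R^2 (see [fit_confounder_map()]) falls below
#' `r2_threshold` (default 0.001) or `max_iter` is hit. Each iteration
#' removes exactly `m_c` dimensions. Note that near the null the adjusted
#' R^2 fluctuates around zero with SD of order `sqrt(2 d) / n`, so at small
#' n a threshold this tight is occasionally crossed by chance and one extra
#' iteration runs; `max_iter` caps this.
#'
#' @param Z n x d embedding matrix.
#' @param F_conf n x m_c numeric confounder matrix.
#' @param r2_threshold termination threshold on the pooled R^2.
#' @param max_iter iteration cap.
#' @return list with `Z_clean` (n x final_d, centred) and `state`, an object
#'   of class `projection_state`: `bases` (per-iteration Vt), `r2_trajectory`
#'   (R^2 before each projection), `final_r2`, `final_dim`, `iterations`,
#'   `center_z`, `center_f`, `scale_f`, `threshold`.
#' @export
inlp <- function(Z, F_conf, r2_threshold = 0.001, max_iter = 10L) {
  Z <- as.matrix(Z); F_conf <- as.matrix(F_conf)
  m_c <- ncol(F_conf); d0 <- ncol(Z)
  fit0 <- fit_confounder_map(Z, F_conf)
  center_z <- fit0$center_z
  Zc <- sweep(Z, 2, center_z)
  bases <- list(); r2s <- numeric(0)
  fit <- fit0
  it <- 0L
  while (fit$r2 >= r2_threshold && it < max_iter) {
    d <- ncol(Zc)
    if (d - m_c < m_c) {
      stop("dimension would drop below the confounder count before convergence; ",
           "R^2 trajectory: ", paste(signif(c(r2s, fit$r2), 4), collapse = ", "))
    }
    r2s <- c(r2s, fit$r2)
    Vt <- nullspace_project(fit$w)
    bases[[length(bases) + 1]] <- Vt
    Zc <- Zc %*% t(Vt)
    it <- it + 1L
    fit <- fit_confounder_map(Zc, F_conf)
  }
  state <- structure(list(
    bases = bases, r2_trajectory = r2s, final_r2 = fit$r2,
    final_dim = ncol(Zc), iterations = it, initial_dim = d0, m_c = m_c,
    center_z = center_z, center_f = fit0$center_f, scale_f = fit0$scale_f,
    threshold = r2_threshold
  ), class = "projection_state")
  rownames(Zc) <- rownames(Z)
  list(Z_clean = Zc, state = state)
}

#' Apply a stored projection state to new embeddings
#'
#' Reproduces the cleaned embeddings from raw ones: centre with the stored
#' vector, then apply each iteration's retained basis in order.
#'
#' @param state a `projection_state`.
#' @param Z n x d raw embedding matrix (d = `state$initial_dim`).
#' @return n x final_dim matrix.
#' @export
apply_projection <- function(state, Z) {
  stopifnot(inherits(state, "projection_state"), ncol(Z) == state$initial_dim)
  Zc <- sweep(as.matrix(Z), 2, state$center_z)
  for (Vt in state$bases) Zc <- Zc %*% t(Vt)
  Zc
}

#' Serialize / restore a projection state as JSON
#'
#' @param state a `projection_state`.
#' @param path file path.
#' @return `read_projection_state` returns the restored state.
#' @export
write_projection_state <- function(state, path) {
  obj <- unclass(state)
  obj$bases <- lapply(obj$bases, function(M) list(v = as.vector(M), dim = dim(M)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection_state
#' @export
read_projection_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  bases <- lapply(obj$bases, function(b) {
    dm <- as.integer(unlist(b$dim)); matrix(num(b$v), dm[1], dm[2])
  })
  structure(list(
    bases = bases, r2_trajectory = num(obj$r2_trajectory),
    final_r2 = as.numeric(obj$final_r2), final_dim = as.integer(obj$final_dim),
    iterations = as.integer(obj$iterations),
    initial_dim = as.integer(obj$initial_dim), m_c = as.integer(obj$m_c),
    center_z = num(obj$center_z), center_f = num(obj$center_f),
    scale_f = num(obj$scale_f), threshold = as.numeric(obj$threshold)
  ), class = "projection_state")
}
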
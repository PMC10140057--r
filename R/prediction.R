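#' Neural tangent kernel of a fully-connected ReLU network
#'
#' Closed-form NTK recursion on the unit sphere. Inputs are L2-normalized
#' internally (zero rows rejected). With `Sigma^0 = x . x'`, the recursion is
#' `Sigma^h = kappa1(Sigma^{h-1})`, `Sigmadot^h = kappa0(Sigma^{h-1})` where
#' `kappa0(t) = (pi - acos(t))/pi` and
#' `kappa1(t) = (sqrt(1 - t^2) + t (pi - acos(t)))/pi`, and
#' `NTK^0 = Sigma^0`, `NTK^h = Sigma^h + NTK^{h-1} * Sigmadot^h`. For unit
#' inputs `K(x, x) = depth + 1`.
#'
#' @param X1 n1 x d matrix.
#' @param X2 n2 x d matrix (defaults to `X1`).
#' @param depth number of recursion layers, `>= 1`.
#' @return n1 x n2 kernel matrix.
#' @export
ntk_kernel <- function(X1, X2 = X1, depth = 3L) {
  if (depth < 1) stop("depth must be >= 1")
  unitize <- function(X) {
    nr <- sqrt(rowSums(X^2))
    if (any(nr == 0)) stop("zero rows cannot be normalized to the unit sphere")
    X / nr
  }
  S <- tcrossprod(unitize(X1), unitize(X2))
  # numerical excursions beyond [-1,1] (tolerance ~1e-12) are clamped
  S[S > 1] <- 1; S[S < -1] <- -1
  K <- S
  for (h in seq_len(depth)) {
    th <- acos(S)
    Sdot <- (pi - th) / pi
    S <- (sqrt(pmax(0, 1 - S^2)) + S * (pi - th)) / pi
    S[S > 1] <- 1; S[S < -1] <- -1
    K <- S + K * Sdot
  }
  K
}

#' Ridgeless kernel regression with validation-based early stopping
#'
#' Solves `K alpha = y` by plain gradient iteration in the dual
#' (`alpha <- alpha + eta (y - K alpha)`, `eta = 1/lambda_max(K)`), which has
#' monotone non-increasing training loss and converges to the minimum-norm
#' interpolant `K^+ y`. The stopping iteration minimizes validation loss
#' (`K_val %*% alpha` against `y_val`).
#'
#' @param K_train n x n PSD kernel matrix.
#' @param y length-n numeric response.
#' @param K_val n_val x n kernel between validation and training inputs
#'   (use `K_train`/`y` to disable early stopping).
#' @param y_val validation response.
#' @param max_iter iteration cap.
#' @return object of class `kernel_predictor` with `alpha`, `iter`
#'   (early-stop iteration) and `val_loss`.
#' @export
fit_kernel_regression <- function(K_train, y, K_val = K_train, y_val = y,
                                  max_iter = 500L) {
  if (nrow(K_train) != ncol(K_train)) stop("K_train must be square")
  n <- nrow(K_train)
  stopifnot(length(y) == n, nrow(K_val) == length(y_val), ncol(K_val) == n)
  lam_max <- max(abs(eigen(K_train, symmetric = TRUE, only.values = TRUE)$values))
  eta <- 1 / (lam_max + 1e-12)
  alpha <- numeric(n)
  best <- list(alpha = alpha, iter = 0L,
               loss = mean((drop(K_val %*% alpha) - y_val)^2))
  for (it in seq_len(max_iter)) {
    alpha <- alpha + eta * (y - drop(K_train %*% alpha))
    vl <- mean((drop(K_val %*% alpha) - y_val)^2)
    if (vl < best$loss) best <- list(alpha = alpha, iter = it, loss = vl)
  }
  structure(list(alpha = best$alpha, iter = best$iter, val_loss = best$loss),
            class = "kernel_predictor")
}

#' @rdname fit_kernel_regression
#' @param object fitted `kernel_predictor`.
#' @param K_new n_new x n_train kernel matrix against the training inputs.
#' @param ... unused.
#' @export
predict.kernel_predictor <- function(object, K_new, ...) {
  drop(K_new %*% object$alpha)
}

#' NTK regression on embeddings (convenience wrapper)
#'
#' @param X_train,y_train training embeddings and labels.
#' @param X_val,y_val validation data for early stopping.
#' @param depth NTK depth.
#' @param max_iter passed to [fit_kernel_regression()].
#' @param center,scale centre / unit-variance-scale feature columns by the
#'   training statistics before the kernel (defaults on; without this,
#'   embeddings with a large common offset give near-constant cosines and a
#'   degenerate kernel).
#' @return list with the fitted `kernel_predictor`, the preprocessing
#'   record, and a `predict(X_new)` closure.
#' @export
fit_ntk_regression <- function(X_train, y_train, X_val, y_val, depth = 3L,
                               max_iter = 500L, center = TRUE, scale = TRUE) {
  ctr <- if (center) colMeans(X_train) else rep(0, ncol(X_train))
  scl <- rep(1, ncol(X_train))
  if (scale) {
    scl <- apply(sweep(X_train, 2, ctr), 2, stats::sd)
    scl[scl == 0] <- 1
  }
  pp <- function(X) sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xt <- pp(X_train)
  K <- ntk_kernel(Xt, Xt, depth)
  Kv <- ntk_kernel(pp(X_val), Xt, depth)
  fit <- fit_kernel_regression(K, y_train, Kv, y_val, max_iter)
  list(fit = fit, preprocess = list(center = ctr, scale = scl),
       predict = function(X_new) {
         drop(ntk_kernel(pp(X_new), Xt, depth) %*% fit$alpha)
       })
}

#' Class-weighted L2-regularized logistic regression
#'
#' Positive-class samples are weighted `n/r` and negative-class samples
#' `n/(n - r)` (n total, r positives), equalizing the classes' total loss
#' contributions. Fit by ridge-penalized logistic regression (glmnet,
#' `alpha = 0`).
#'
#' @param X feature matrix.
#' @param y binary 0/1 labels, both classes present.
#' @param lambda ridge penalty (default 1e-3).
#' @return object of class `logistic_predictor`.
#' @export
fit_weighted_logistic <- function(X, y, lambda = 1e-3) {
  y <- as.integer(y)
  n <- length(y); r <- sum(y == 1)
  if (r == 0 || r == n) stop("both classes must be present")
  w <- ifelse(y == 1, n / r, n / (n - r))
  X <- as.matrix(X)
  pad <- ncol(X) == 1   # glmnet requires >= 2 columns; pad an inert zero
  if (pad) X <- cbind(X, 0)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, weights = w, standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, pad = pad,
                 weights = c(pos = n / r, neg = n / (n - r))),
            class = "logistic_predictor")
}

#' @rdname fit_weighted_logistic
#' @param object fitted `logistic_predictor`.
#' @param X_new new feature matrix.
#' @param ... unused.
#' @export
predict.logistic_predictor <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (isTRUE(object$pad)) X_new <- cbind(X_new, 0)
  drop(stats::predict(object$fit, newx = X_new, type = "response"))
}

#' Evaluate predictions against held-out labels
#'
#' Continuous tasks: `R^2 = 1 - SS_res/SS_tot` on the test set. Binary
#' tasks: AUROC from the rank statistic with midrank tie correction.
#'
#' @param predictions numeric predictions (scores for binary tasks).
#' @param y_test observed labels.
#' @param task `"continuous"` or `"binary"`.
#' @return scalar metric.
#' @export
evaluate_predictions <- function(predictions, y_test, task = c("continuous", "binary")) {
  task <- match.arg(task)
  if (task == "continuous") {
    1 - sum((y_test - predictions)^2) / sum((y_test - mean(y_test))^2)
  } else {
    auroc(predictions, y_test)
  }
}

# Rank-based AUROC with midranks for ties.
auroc <- function(scores, y) {
  y <- as.integer(y)
  r <- sum(y == 1); n <- length(y)
  if (r == 0 || r == n) stop("AUROC needs both classes")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[y == 1]) - r * (r + 1) / 2) / (r * (n - r))
}

#' Derive ventricular hypertrophy / systolic dysfunction labels
#'
#' Body surface area by the Mosteller formula,
#' `BSA = sqrt(height_cm * weight_kg / 3600)` (m^2). Hypertrophy (LVH) is
#' positive iff mass indexed to BSA strictly exceeds 72 g/m^2 for males or
#' 55 g/m^2 for females; systolic dysfunction (LVSD) is positive iff the
#' ejection fraction is strictly below 45%.
#'
#' @param lvm left ventricular mass (g).
#' @param lvef ejection fraction (percent).
#' @param height cm; `> 0`.
#' @param weight kg; `> 0`.
#' @param sex `"male"`/`"female"` (vectorized).
#' @return data frame with `bsa`, `lvm_indexed`, `lvh`, `lvsd` (0/1).
#' @export
derive_lvh_lvsd <- function(lvm, lvef, height, weight, sex) {
  stopifnot(all(height > 0), all(weight > 0))
  if (!all(sex %in% c("male", "female"))) stop("unknown sex code")
  bsa <- sqrt(height * weight / 3600)
  idx <- lvm / bsa
  thr <- ifelse(sex == "male", 72, 55)
  data.frame(bsa = bsa, lvm_indexed = idx,
             lvh = as.integer(idx > thr),
             lvsd = as.integer(lvef < 45))
}

#' Fit the unlabelled/labelled scaling law
#'
#' Least-squares fit of mean performance r on `(log2(u), log2(v))` where u is
#' the unlabelled-pair count used for autoencoder pre-training and v the
#' labelled count used for supervised fitting. No intercept by default,
#' matching the two-coefficient form of the law.
#'
#' @param points data frame (or list of lists) with columns `u`, `v`, `r`.
#' @param intercept include an intercept term (default `FALSE`).
#' @return object of class `scaling_law_fit`: `coef_unlabelled`,
#'   `coef_labelled`, optional `intercept`, and `r_squared`
#'   (against the no-intercept null when `intercept = FALSE`).
#' @export
fit_scaling_law <- function(points, intercept = FALSE) {
  pts <- as.data.frame(do.call(rbind, lapply(
    if (is.data.frame(points)) split(points, seq_len(nrow(points))) else points,
    function(p) c(u = p$u, v = p$v, r = p$r))))
  if (nrow(pts) < 2) stop("need at least 2 points")
  if (any(pts$u < 1) || any(pts$v < 1)) stop("u and v must be >= 1")
  lu <- log2(pts$u); lv <- log2(pts$v)
  if (stats::var(lu) + stats::var(lv) == 0) stop("degenerate design: all u, v equal")
  fit <- if (intercept) stats::lm(pts$r ~ lu + lv) else stats::lm(pts$r ~ 0 + lu + lv)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- if (intercept) sum((pts$r - mean(pts$r))^2) else sum(pts$r^2)
  res <- list(coef_unlabelled = unname(co[["lu"]]),
              coef_labelled = unname(co[["lv"]]),
              intercept = if (intercept) unname(co[["(Intercept)"]]) else 0,
              r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
              fitted = stats::fitted(fit))
  structure(res, class = "scaling_law_fit")
}
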
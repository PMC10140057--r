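test_that("NTK closed forms, symmetry and positive semidefiniteness", {
  x <- matrix(c(0.6, 0.8), 1)
  for (L in 1:4) {
    expect_equal(ntk_kernel(x, x, depth = L)[1, 1], L + 1, tolerance = 1e-12)
  }
  ## orthogonal unit inputs at depth 1: kappa1(0) = 1/pi, cross term vanishes
  e1 <- matrix(c(1, 0), 1); e2 <- matrix(c(0, 1), 1)
  expect_equal(ntk_kernel(e1, e2, depth = 1)[1, 1], 1 / pi, tolerance = 1e-12)

  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  K <- ntk_kernel(X, depth = 3)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(K)))

  expect_error(ntk_kernel(X, X, depth = 0), "depth")
  expect_error(ntk_kernel(rbind(X, 0), depth = 2), "zero rows")
})

test_that("ridgeless kernel regression interpolates and matches the pseudoinverse", {
  set.seed(8)
  X <- matrix(rnorm(20 * 4), 20, 4)
  K <- ntk_kernel(X, depth = 2)
  y <- drop(K %*% rnorm(20, sd = 0.3))   # y in the span of K

  fit <- fit_kernel_regression(K, y, K, y, max_iter = 5000)
  pred <- predict(fit, K)
  expect_gt(1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.999)

  ## early-stopped solution close to the pseudoinverse solution
  alpha_pinv <- drop(MASS::ginv(K) %*% y)
  expect_lt(sqrt(mean((drop(K %*% fit$alpha) - drop(K %*% alpha_pinv))^2)), 1e-3)

  ## constant targets give constant predictions
  yc <- rep(2.5, 20)
  fitc <- fit_kernel_regression(K, yc, K, yc, max_iter = 2000)
  expect_equal(predict(fitc, K), yc, tolerance = 1e-6)

  expect_error(fit_kernel_regression(K[1:10, ], y), "square")
})

test_that("weighted logistic regression uses the n/r class weights", {
  set.seed(2)
  ## the weight formulas themselves
  fit1 <- fit_weighted_logistic(matrix(rnorm(200), 100, 2),
                                rep(c(1, 0), c(50, 50)))
  expect_equal(unname(fit1$weights), c(2, 2))
  fit2 <- fit_weighted_logistic(matrix(rnorm(200), 100, 2),
                                rep(c(1, 0), c(10, 90)))
  expect_equal(unname(fit2$weights), c(10, 100 / 90), tolerance = 1e-12)

  ## linearly separable toy reaches AUROC 1 in-sample
  X <- matrix(c(rnorm(40, -3), rnorm(40, 3)), ncol = 1)
  y <- rep(c(0, 1), each = 40)
  fit <- fit_weighted_logistic(X, y)
  expect_equal(evaluate_predictions(predict(fit, X), y, "binary"), 1)

  expect_error(fit_weighted_logistic(X, rep(1, 80)), "both classes")
})

test_that("evaluation metrics: R2 and tie-corrected AUROC", {
  y <- c(1.2, -0.5, 3, 0.7, 2)
  expect_equal(evaluate_predictions(y, y, "continuous"), 1)
  expect_equal(evaluate_predictions(rep(mean(y), 5), y, "continuous"), 0)

  yb <- c(1, 0, 1, 0); sc <- c(0.9, 0.1, 0.8, 0.2)
  expect_equal(evaluate_predictions(sc, yb, "binary"), 1)

  ## agreement with an established AUROC implementation, including ties
  set.seed(6)
  scores <- round(rnorm(200), 1)   # ties on purpose
  lab <- rbinom(200, 1, 0.4)
  expect_equal(evaluate_predictions(scores, lab, "binary"),
               as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))),
               tolerance = 1e-12)

  ## random scores sit near chance level
  set.seed(7)
  sc2 <- rnorm(2000); lab2 <- rbinom(2000, 1, 0.5)
  se <- sqrt(1 / (12 * sum(lab2 == 1)) + 1 / (12 * sum(lab2 == 0)))
  expect_lt(abs(evaluate_predictions(sc2, lab2, "binary") - 0.5), 3 * se)
})

test_that("hypertrophy / dysfunction labels follow the threshold semantics", {
  ## Mosteller BSA perfect square
  d <- derive_lvh_lvsd(lvm = 144, lvef = 60, height = 180, weight = 80, sex = "male")
  expect_equal(d$bsa, 2)

  ## strictly-greater boundary at 72 (male) and 55 (female)
  at <- derive_lvh_lvsd(lvm = 72 * 2, lvef = 60, 180, 80, "male")
  above <- derive_lvh_lvsd(lvm = 72 * 2 + 1e-9, lvef = 60, 180, 80, "male")
  expect_equal(at$lvh, 0)
  expect_equal(above$lvh, 1)
  f_at <- derive_lvh_lvsd(lvm = 55 * 2, lvef = 60, 180, 80, "female")
  expect_equal(f_at$lvh, 0)

  ## strictly-less boundary at LVEF 45
  expect_equal(derive_lvh_lvsd(100, 44.9, 180, 80, "male")$lvsd, 1)
  expect_equal(derive_lvh_lvsd(100, 45.0, 180, 80, "male")$lvsd, 0)
  expect_error(derive_lvh_lvsd(100, 50, 180, 80, "m"), "sex")
})

test_that("scaling-law fit recovers coefficients and is monotone", {
  grid <- expand.grid(u = 2^(5:10), v = 2^(3:8))
  grid$r <- 0.02 * log2(grid$u) + 0.01 * log2(grid$v)
  fit <- fit_scaling_law(grid)
  expect_equal(fit$coef_unlabelled, 0.02, tolerance = 1e-10)
  expect_equal(fit$coef_labelled, 0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  ## zero response
  g0 <- grid; g0$r <- 0
  f0 <- fit_scaling_law(g0)
  expect_equal(f0$coef_unlabelled, 0)
  expect_equal(f0$coef_labelled, 0)

  ## noisy recovery on a 6 x 9 grid
  set.seed(13)
  gn <- expand.grid(u = 2^(4:9), v = 2^seq(2, 10))
  gn$r <- 0.0158 * log2(gn$u) + 0.007 * log2(gn$v) + rnorm(nrow(gn), sd = 1e-3)
  fn <- fit_scaling_law(gn)
  expect_lt(abs(fn$coef_unlabelled - 0.0158), 1e-2)
  expect_lt(abs(fn$coef_labelled - 0.007), 1e-2)

  expect_error(fit_scaling_law(data.frame(u = c(4, 4), v = c(2, 2), r = c(1, 1))),
               "degenerate")
})
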
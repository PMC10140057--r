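# Compact fully-connected network engine: Glorot init, ReLU hidden layers,
# linear output, exact reverse-mode gradients, Adam updates. Internal; the
# public training surface lives in autoencoder.R. Everything operates on
# batches as rows (n x d matrices).

mlp_new <- function(sizes, seed = 1L) {
  rs <- local_rng(seed); on.exit(rs(), add = TRUE)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = numeric(fan_out)
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

# Forward pass; cache = TRUE additionally returns per-layer inputs for backprop.
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$layers)
  acts <- if (cache) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    if (cache) acts[[l]] <- H
    H <- H %*% net$layers[[l]]$W
    H <- sweep(H, 2, net$layers[[l]]$b, "+")
    if (l < L) H[H < 0] <- 0   # ReLU on hidden layers
  }
  if (cache) list(out = H, acts = acts) else H
}

# dOut: gradient of the scalar loss w.r.t. the network output (n x d_out).
# Returns grads (same shape as layers) and dX.
mlp_backward <- function(net, X, fwd, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dOut
  # recompute post-activation outputs layer by layer from cached inputs
  for (l in rev(seq_len(L))) {
    H_in <- fwd$acts[[l]]
    if (l < L) {
      # ReLU mask: output of layer l was max(0, pre); pre = acts[[l+1]] is
      # already post-ReLU, so the mask is acts[[l+1]] > 0
      delta <- delta * (fwd$acts[[l + 1]] > 0)
    }
    grads[[l]] <- list(W = crossprod(H_in, delta), b = colSums(delta))
    delta <- delta %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

adam_new <- function(net) {
  st <- lapply(net$layers, function(lyr) {
    list(mW = lyr$W * 0, vW = lyr$W * 0, mb = lyr$b * 0, vb = lyr$b * 0)
  })
  list(state = st, t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$layers)) {
    s <- opt$state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$state[[l]] <- s
  }
  list(net = net, opt = opt)
}

# Scalar Adam (used for the trainable temperature).
adam_scalar_step <- function(x, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  x <- x - lr * (st$m / (1 - beta1^st$t)) / (sqrt(st$v / (1 - beta2^st$t)) + eps)
  list(x = x, st = st)
}
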
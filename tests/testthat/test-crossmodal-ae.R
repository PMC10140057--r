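test_that("contrastive loss matches brute-force enumeration and closed forms", {
  ## all-equal embeddings: every softmax entry is 1/b
  E <- matrix(rep(c(1, -2, 0.5, 3), each = 4), 4, 4)
  expect_equal(contrastive_loss(list(E, E), temp = 0.7), 2 * 4 * log(4),
               tolerance = 1e-10)

  ## singleton batch
  one <- matrix(c(1, 2), 1, 2)
  expect_equal(contrastive_loss(list(one, 3 * one), temp = 0.2), 0)

  ## worked 2 x 2 identity-rows case
  A <- rbind(c(1, 0), c(0, 1))
  expect_equal(contrastive_loss(list(A, A), temp = 0),
               brute_contrastive(A, A, 0), tolerance = 1e-10)

  ## random batches up to b = 4, d = 4 against the enumeration oracle
  set.seed(11)
  for (b in 2:4) for (d in 2:4) {
    A <- matrix(rnorm(b * d), b, d)
    B <- matrix(rnorm(b * d), b, d)
    tmp <- rnorm(1, sd = 0.5)
    expect_equal(contrastive_loss(list(A, B), tmp),
                 brute_contrastive(A, B, tmp), tolerance = 1e-8)
  }

  ## permutation equivariance: permuting samples jointly leaves loss unchanged
  set.seed(12)
  A <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(16), 4, 4)
  p <- sample(4)
  expect_equal(contrastive_loss(list(A, B), 0.3),
               contrastive_loss(list(A[p, ], B[p, ]), 0.3), tolerance = 1e-10)

  expect_error(contrastive_loss(list(A, B[1:3, ]), 0), "shape")
})

test_that("contrastive gradients agree with finite differences", {
  set.seed(4)
  A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(12), 3, 4)
  g <- contrastive_loss(list(A, B), temp = 0.3, grad = TRUE)
  eps <- 1e-6
  ## one embedding coordinate
  Au <- A; Au[2, 3] <- Au[2, 3] + eps
  Ad <- A; Ad[2, 3] <- Ad[2, 3] - eps
  fd <- (contrastive_loss(list(Au, B), 0.3) - contrastive_loss(list(Ad, B), 0.3)) / (2 * eps)
  expect_equal(g$grad_emb[[1]][2, 3], fd, tolerance = 1e-5)
  ## temperature
  fdt <- (contrastive_loss(list(A, B), 0.3 + eps) -
            contrastive_loss(list(A, B), 0.3 - eps)) / (2 * eps)
  expect_equal(g$grad_temp, fdt, tolerance = 1e-5)
})

test_that("reconstruction and total losses obey their definitions", {
  ch <- small_cohort(n = 24, n_snps = 0)
  specs <- list(modality_spec("waveform", 256, 16L, 8L),
                modality_spec("image", 1024, 16L, 8L))
  m0 <- train_crossmodal(ch, specs, training_config(max_epochs = 0, seed = 2))
  batch <- list(waveform = modality_matrix(ch, "waveform")[1:4, ],
                image = modality_matrix(ch, "image")[1:4, ])

  ## zero-decoder limit: loss equals the total squared norm of the inputs
  mz <- m0
  for (nm in mz$modalities) {
    for (l in seq_along(mz$decoders[[nm]]$layers)) {
      mz$decoders[[nm]]$layers[[l]]$W[] <- 0
      mz$decoders[[nm]]$layers[[l]]$b[] <- 0
    }
  }
  expect_equal(reconstruction_loss(batch, mz),
               sum(batch$waveform^2) + sum(batch$image^2), tolerance = 1e-10)

  ## linearity of the combined objective
  tl0 <- total_loss(batch, m0, lambda = 0)
  tl <- total_loss(batch, m0, lambda = 0.1)
  expect_equal(tl0$total, tl0$contrastive)
  expect_equal(tl$total, tl$contrastive + 0.1 * tl$reconstruction)

  ## finite-difference gradient of the full objective through one encoder weight
  grad_analytic <- local({
    fe <- crossmodal:::mlp_forward(m0$encoders$waveform, batch$waveform, cache = TRUE)
    fei <- crossmodal:::mlp_forward(m0$encoders$image, batch$image, cache = TRUE)
    cl <- contrastive_loss(list(fe$out, fei$out), m0$temp, grad = TRUE)
    fd1 <- crossmodal:::mlp_forward(m0$decoders$waveform, fe$out, cache = TRUE)
    err <- fd1$out - batch$waveform
    bd <- crossmodal:::mlp_backward(m0$decoders$waveform, fe$out, fd1, 0.1 * 2 * err)
    be <- crossmodal:::mlp_backward(m0$encoders$waveform, batch$waveform, fe,
                                    cl$grad_emb[[1]] + bd$dX)
    be$grads[[1]]$W[5, 3]
  })
  eps <- 1e-5
  up <- m0; up$encoders$waveform$layers[[1]]$W[5, 3] <- up$encoders$waveform$layers[[1]]$W[5, 3] + eps
  dn <- m0; dn$encoders$waveform$layers[[1]]$W[5, 3] <- dn$encoders$waveform$layers[[1]]$W[5, 3] - eps
  fd <- (total_loss(batch, up, 0.1)$total - total_loss(batch, dn, 0.1)$total) / (2 * eps)
  expect_equal(grad_analytic, fd, tolerance = 1e-4 * max(1, abs(fd)))
})

test_that("dropout fusion selects coordinates exactly", {
  a <- c(1, 2, 3, 4, 5, 6); b <- -a
  expect_identical(fuse_embeddings(a, b, rep(1, 6)), a)
  expect_identical(fuse_embeddings(a, b, rep(0, 6)), b)
  mask <- c(1, 0, 0, 1, 1, 0)
  expect_identical(fuse_embeddings(a, b, mask),
                   ifelse(mask == 1, a, b))
  ## matrix form
  A <- rbind(a, a); B <- rbind(b, b)
  expect_equal(fuse_embeddings(A, B, mask), cbind(1, -2, -3, 4, 5, -6)[c(1, 1), ],
               ignore_attr = TRUE)
  expect_error(fuse_embeddings(a, b, c(1, 0, 0.5, 1, 1, 0)), "binary")
})

test_that("training bookkeeping: zero-epoch init, determinism of embeddings", {
  ch <- small_cohort(n = 24, n_snps = 0)
  specs <- list(modality_spec("waveform", 256, 16L, 8L),
                modality_spec("image", 1024, 16L, 8L))
  m0 <- train_crossmodal(ch, specs, training_config(max_epochs = 0, seed = 2))
  expect_length(m0$history, 0)
  m0b <- train_crossmodal(ch, specs, training_config(max_epochs = 0, seed = 2))
  expect_identical(m0$encoders, m0b$encoders)

  X <- modality_matrix(ch, "waveform")
  expect_identical(embed_modality(m0, X, "waveform"),
                   embed_modality(m0, X, "waveform"))
  ## loop oracle: embedding matrix equals per-sample encoder application
  Z <- embed_modality(m0, X, "waveform")
  for (i in c(1, 7)) {
    expect_equal(Z[i, ], drop(crossmodal:::mlp_forward(m0$encoders$waveform,
                                                       X[i, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  expect_error(embed_modality(m0, X, "ecg"), "unknown modality")

  ## a short seeded run reduces validation reconstruction loss
  m1 <- train_crossmodal(ch, specs, training_config(max_epochs = 4, seed = 2))
  h <- m1$history$phase1
  w1 <- h[h$modality == "waveform", ]
  expect_lt(w1$val[nrow(w1)], w1$val[1])
})

test_that("model checkpoints round-trip through JSON", {
  ch <- small_cohort(n = 16, n_snps = 0)
  specs <- list(modality_spec("waveform", 256, 8L, 6L),
                modality_spec("image", 1024, 8L, 6L))
  m <- train_crossmodal(ch, specs, training_config(max_epochs = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  X <- modality_matrix(ch, "image")
  expect_equal(embed_modality(m, X, "image"), embed_modality(m2, X, "image"),
               tolerance = 1e-12)
  expect_equal(m$temp, m2$temp)
})
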
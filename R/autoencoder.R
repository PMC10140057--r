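#' Describe one modality's encoder/decoder architecture
#'
#' @param name modality name (e.g. `"waveform"`, `"image"`).
#' @param input_dim flattened observation dimension.
#' @param hidden integer vector of hidden-layer widths (mirrored in the
#'   decoder).
#' @param latent_dim shared latent dimension d; must agree across modalities.
#' @return object of class `modality_spec`.
#' @export
modality_spec <- function(name, input_dim, hidden = c(64L), latent_dim = 16L) {
  stopifnot(input_dim >= 1, latent_dim >= 1)
  structure(list(name = name, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 latent_dim = as.integer(latent_dim)),
            class = "modality_spec")
}

#' Training configuration for the two-phase schedule
#'
#' Phase 1 trains each modality's autoencoder on reconstruction alone
#' (`lr_unimodal`); phase 2 fine-tunes all parameters plus the temperature on
#' the combined objective with dropout fusion (`lr_crossmodal`). After each
#' epoch without validation-loss improvement the learning rate is halved;
#' after `max_decays` decays the phase stops.
#'
#' @param lambda balance weight on the reconstruction term (default 0.1).
#' @param batch_size contrastive batch size b (default 4); the final
#'   incomplete batch of an epoch is dropped.
#' @param lr_unimodal,lr_crossmodal Adam learning rates for the two phases.
#' @param decay_factor learning-rate division factor (default 2).
#' @param patience epochs without improvement before each decay (default 1).
#' @param max_decays decays before the phase terminates (default 3).
#' @param max_epochs hard cap per phase.
#' @param temp_init initial value of the trainable temperature (the loss
#'   scales dot products by `exp(temp)`; 0 is a neutral start).
#' @param fusion_rate Bernoulli rate of the per-coordinate fusion mask.
#' @param normalize_embeddings L2-normalize embeddings inside the
#'   contrastive loss (default off: raw dot products).
#' @param seed integer seed controlling init, shuffling and fusion masks.
#' @return object of class `training_config`.
#' @export
training_config <- function(lambda = 0.1, batch_size = 4L,
                            lr_unimodal = 1e-3, lr_crossmodal = 2e-5,
                            decay_factor = 2, patience = 1L, max_decays = 3L,
                            max_epochs = 50L, temp_init = 0,
                            fusion_rate = 0.5, normalize_embeddings = FALSE,
                            seed = 1L) {
  stopifnot(lambda >= 0, batch_size >= 1)
  structure(list(lambda = lambda, batch_size = as.integer(batch_size),
                 lr_unimodal = lr_unimodal, lr_crossmodal = lr_crossmodal,
                 decay_factor = decay_factor, patience = as.integer(patience),
                 max_decays = as.integer(max_decays),
                 max_epochs = as.integer(max_epochs), temp_init = temp_init,
                 fusion_rate = fusion_rate,
                 normalize_embeddings = isTRUE(normalize_embeddings),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Batch contrastive loss over paired modality embeddings
#'
#' For every ordered pair of distinct modalities and every sample in the
#' batch, adds the two log-softmax terms of the paired-sample (InfoNCE-style)
#' objective -- the softmax runs once over the batch along each axis of the
#' scaled dot-product matrix `exp(temp) * Z1 %*% t(Z2)` -- and multiplies the
#' total by -1/2. With all embeddings identical in a batch of size b and two
#' modalities the loss is `2 * b * log(b)`; a singleton batch gives 0.
#'
#' @param emb_by_modality list of m matrices, each batch_size x d.
#' @param temp temperature scalar (dot products are scaled by `exp(temp)`).
#' @param grad also return gradients w.r.t. each embedding matrix and temp.
#' @return scalar loss, or (with `grad = TRUE`) a list with `value`,
#'   `grad_emb` (list of matrices) and `grad_temp`.
#' @export
contrastive_loss <- function(emb_by_modality, temp = 0, grad = FALSE) {
  m <- length(emb_by_modality)
  stopifnot(m >= 2)
  b <- nrow(emb_by_modality[[1]])
  d <- ncol(emb_by_modality[[1]])
  for (E in emb_by_modality) {
    if (nrow(E) != b || ncol(E) != d) stop("embedding shape mismatch across modalities")
  }
  tau <- exp(temp)
  loss <- 0
  if (grad) {
    gE <- lapply(emb_by_modality, function(E) E * 0)
    gT <- 0
  }
  for (j1 in seq_len(m)) for (j2 in seq_len(m)) {
    if (j1 == j2) next
    S <- tau * tcrossprod(emb_by_modality[[j1]], emb_by_modality[[j2]])
    # term 1: softmax over i' in f_{j1} (rows of S vary i'), evaluated at
    # column i; term 2: softmax over i' in f_{j2} (columns), at row i.
    lse_col <- apply(S, 2, logsumexp)   # denominator over rows, per column
    lse_row <- apply(S, 1, logsumexp)   # denominator over cols, per row
    diagS <- diag(S)
    loss <- loss - 0.5 * (sum(diagS - lse_col) + sum(diagS - lse_row))
    if (grad) {
      P_col <- sweep(exp(S), 2, exp(lse_col), "/")  # softmax down each column
      P_row <- sweep(exp(S), 1, exp(lse_row), "/")  # softmax along each row
      dS <- -0.5 * (2 * diag(b) - P_col - P_row)
      gE[[j1]] <- gE[[j1]] + tau * dS %*% emb_by_modality[[j2]]
      gE[[j2]] <- gE[[j2]] + tau * t(dS) %*% emb_by_modality[[j1]]
      gT <- gT + sum(dS * S)   # dS/dtemp = S since S = e^temp * raw
    }
  }
  if (grad) list(value = loss, grad_emb = gE, grad_temp = gT) else loss
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Reconstruction loss of a trained model on a batch
#'
#' Sum over samples and modalities of the squared Euclidean distance between
#' each flattened observation and its encode-decode round trip.
#'
#' @param batch named list of observation matrices (rows = samples), names
#'   matching the model's modalities.
#' @param model a `crossmodal_model`.
#' @return scalar.
#' @export
reconstruction_loss <- function(batch, model) {
  tot <- 0
  for (nm in names(batch)) {
    X <- batch[[nm]]
    Z <- mlp_forward(model$encoders[[nm]], X)
    Xh <- mlp_forward(model$decoders[[nm]], Z)
    tot <- tot + sum((X - Xh)^2)
  }
  tot
}

#' Combined training objective
#'
#' `L = L_contrast + lambda * L_reconstruct`, returned with both components.
#'
#' @param batch named list of observation matrices.
#' @param model a `crossmodal_model`.
#' @param lambda balance weight.
#' @return list with `total`, `contrastive`, `reconstruction`.
#' @export
total_loss <- function(batch, model, lambda = 0.1) {
  embs <- lapply(names(batch), function(nm)
    mlp_forward(model$encoders[[nm]], batch[[nm]]))
  lc <- contrastive_loss(embs, model$temp)
  lr <- reconstruction_loss(batch, model)
  list(total = lc + lambda * lr, contrastive = lc, reconstruction = lr)
}

#' Dropout fusion of two modality embeddings
#'
#' Coordinate-wise selection: output i is `emb_a[i]` where `mask[i] == 1`,
#' else `emb_b[i]`. During training the mask is Bernoulli(fusion rate) per
#' coordinate, resampled each batch; the fused embedding is decoded by both
#' decoders.
#'
#' @param emb_a,emb_b numeric vectors (or matrices with d columns).
#' @param mask binary vector of length d.
#' @return fused embedding, same shape as `emb_a`.
#' @export
fuse_embeddings <- function(emb_a, emb_b, mask) {
  if (!all(mask %in% c(0, 1))) stop("fusion mask must be binary")
  if (is.matrix(emb_a)) {
    stopifnot(identical(dim(emb_a), dim(emb_b)), length(mask) == ncol(emb_a))
    sweep(emb_a, 2, mask, "*") + sweep(emb_b, 2, 1 - mask, "*")
  } else {
    stopifnot(length(emb_a) == length(emb_b), length(mask) == length(emb_a))
    emb_a * mask + emb_b * (1 - mask)
  }
}

#' Train a cross-modal autoencoder on a cohort
#'
#' Phase 1 trains each modality's autoencoder on the reconstruction loss
#' alone; phase 2 fine-tunes all encoders/decoders and the temperature on
#' the combined objective, with the reconstruction term decoding the fused
#' (dropout-merged) embedding through both decoders. Each phase halves its
#' learning rate after `patience` epochs without total validation-loss
#' improvement and stops after `max_decays` decays (or `max_epochs`). The
#' returned model keeps a snapshot of the phase-1 (unimodal) encoders for
#' comparison studies.
#'
#' @param cohort a `cohort` with train and val splits.
#' @param specs list of two [modality_spec()]s named by modality.
#' @param cfg a [training_config()].
#' @return object of class `crossmodal_model`: encoders/decoders per
#'   modality, `temp`, `phase1` snapshot, `history` (per-epoch losses),
#'   `latent_dim`, `modalities`.
#' @export
train_crossmodal <- function(cohort, specs, cfg = training_config()) {
  stopifnot(length(specs) == 2)
  mods <- vapply(specs, function(s) s$name, "")
  names(specs) <- mods
  d <- unique(vapply(specs, function(s) s$latent_dim, 1L))
  if (length(d) != 1) stop("all modalities must share one latent dimension")
  tr <- cohort$split == "train"; va <- cohort$split == "val"
  if (!any(tr)) stop("cohort has an empty training split")
  X <- lapply(mods, function(nm) modality_matrix(cohort, nm, tr))
  Xv <- lapply(mods, function(nm) modality_matrix(cohort, nm, va))
  names(X) <- names(Xv) <- mods

  rs <- local_rng(cfg$seed); on.exit(rs(), add = TRUE)
  enc <- dec <- list()
  for (nm in mods) {
    s <- specs[[nm]]
    enc[[nm]] <- mlp_new(c(s$input_dim, s$hidden, s$latent_dim),
                         seed = cfg$seed + match(nm, mods))
    dec[[nm]] <- mlp_new(c(s$latent_dim, rev(s$hidden), s$input_dim),
                         seed = cfg$seed + 10L + match(nm, mods))
  }
  model <- structure(list(encoders = enc, decoders = dec,
                          temp = cfg$temp_init, phase1 = NULL,
                          history = list(), latent_dim = d,
                          modalities = mods, specs = specs, config = cfg),
                     class = "crossmodal_model")
  if (cfg$max_epochs < 1) return(model)

  n_tr <- nrow(X[[1]]); b <- cfg$batch_size

  ## ---- phase 1: unimodal reconstruction ----------------------------
  hist1 <- list()
  for (nm in mods) {
    opt_e <- adam_new(model$encoders[[nm]]); opt_d <- adam_new(model$decoders[[nm]])
    lr <- cfg$lr_unimodal; best <- Inf; decays <- 0L; bad <- 0L
    ep_log <- NULL
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      n_batch <- floor(n_tr / b)
      tr_loss <- 0
      for (k in seq_len(n_batch)) {
        idx <- ord[((k - 1) * b + 1):(k * b)]
        Xb <- X[[nm]][idx, , drop = FALSE]
        fe <- mlp_forward(model$encoders[[nm]], Xb, cache = TRUE)
        fd <- mlp_forward(model$decoders[[nm]], fe$out, cache = TRUE)
        err <- fd$out - Xb
        tr_loss <- tr_loss + sum(err^2)
        bd <- mlp_backward(model$decoders[[nm]], fe$out, fd, 2 * err)
        be <- mlp_backward(model$encoders[[nm]], Xb, fe, bd$dX)
        su <- adam_step(model$decoders[[nm]], bd$grads, opt_d, lr)
        model$decoders[[nm]] <- su$net; opt_d <- su$opt
        su <- adam_step(model$encoders[[nm]], be$grads, opt_e, lr)
        model$encoders[[nm]] <- su$net; opt_e <- su$opt
      }
      Zv <- mlp_forward(model$encoders[[nm]], Xv[[nm]])
      val_loss <- sum((mlp_forward(model$decoders[[nm]], Zv) - Xv[[nm]])^2)
      ep_log <- rbind(ep_log, data.frame(phase = 1, modality = nm, epoch = ep,
                                         train = tr_loss, val = val_loss, lr = lr))
      if (val_loss < best - 1e-12) { best <- val_loss; bad <- 0L } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) {
          lr <- lr / cfg$decay_factor; decays <- decays + 1L; bad <- 0L
          if (decays > cfg$max_decays) break
        }
      }
      if (decays > cfg$max_decays) break
    }
    hist1[[nm]] <- ep_log
  }
  model$phase1 <- list(encoders = lapply(model$encoders, identity),
                       decoders = lapply(model$decoders, identity))

  ## ---- phase 2: contrastive + fused reconstruction -----------------
  opt_e <- lapply(model$encoders, adam_new)
  opt_d <- lapply(model$decoders, adam_new)
  opt_t <- list(m = 0, v = 0, t = 0L)
  lr <- cfg$lr_crossmodal; best <- Inf; decays <- 0L; bad <- 0L
  val_mask <- as.numeric(stats::runif(d) < cfg$fusion_rate)  # fixed for comparability
  ep_log <- NULL
  m1 <- mods[1]; m2 <- mods[2]
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_tr)
    n_batch <- floor(n_tr / b)
    tr_tot <- 0
    for (k in seq_len(n_batch)) {
      idx <- ord[((k - 1) * b + 1):(k * b)]
      Xb <- lapply(X, function(M) M[idx, , drop = FALSE])
      fe <- lapply(mods, function(nm) mlp_forward(model$encoders[[nm]], Xb[[nm]], cache = TRUE))
      names(fe) <- mods
      Z <- lapply(fe, `[[`, "out")
      norms <- NULL
      if (cfg$normalize_embeddings) {
        norms <- lapply(Z, function(M) sqrt(rowSums(M^2)) + 1e-12)
        Zc <- Map(function(M, nv) M / nv, Z, norms)
      } else Zc <- Z
      cl <- contrastive_loss(Zc, model$temp, grad = TRUE)
      if (cfg$normalize_embeddings) {
        # back through row normalization: dz = (g - (g.n) n) / ||z||
        cl$grad_emb <- Map(function(g, M, nv) {
          Zn <- M / nv
          (g - Zn * rowSums(g * Zn)) / nv
        }, cl$grad_emb, Z, norms)
      }
      mask <- as.numeric(stats::runif(d) < cfg$fusion_rate)
      Zf <- fuse_embeddings(Z[[m1]], Z[[m2]], mask)
      fd <- lapply(mods, function(nm) mlp_forward(model$decoders[[nm]], Zf, cache = TRUE))
      names(fd) <- mods
      rec <- 0; dZf <- Zf * 0
      for (nm in mods) {
        err <- fd[[nm]]$out - Xb[[nm]]
        rec <- rec + sum(err^2)
        bd <- mlp_backward(model$decoders[[nm]], Zf, fd[[nm]], cfg$lambda * 2 * err)
        su <- adam_step(model$decoders[[nm]], bd$grads, opt_d[[nm]], lr)
        model$decoders[[nm]] <- su$net; opt_d[[nm]] <- su$opt
        dZf <- dZf + bd$dX
      }
      dZ <- list(cl$grad_emb[[1]] + sweep(dZf, 2, mask, "*"),
                 cl$grad_emb[[2]] + sweep(dZf, 2, 1 - mask, "*"))
      names(dZ) <- mods
      for (nm in mods) {
        be <- mlp_backward(model$encoders[[nm]], Xb[[nm]], fe[[nm]], dZ[[nm]])
        su <- adam_step(model$encoders[[nm]], be$grads, opt_e[[nm]], lr)
        model$encoders[[nm]] <- su$net; opt_e[[nm]] <- su$opt
      }
      st <- adam_scalar_step(model$temp, cl$grad_temp, opt_t, lr)
      model$temp <- st$x; opt_t <- st$st
      tr_tot <- tr_tot + cl$value + cfg$lambda * rec
    }
    val_loss <- phase2_val_loss(model, Xv, cfg, val_mask)
    ep_log <- rbind(ep_log, data.frame(phase = 2, modality = "both", epoch = ep,
                                       train = tr_tot, val = val_loss, lr = lr))
    if (val_loss < best - 1e-12) { best <- val_loss; bad <- 0L } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) {
        lr <- lr / cfg$decay_factor; decays <- decays + 1L; bad <- 0L
        if (decays > cfg$max_decays) break
      }
    }
  }
  model$history <- list(phase1 = do.call(rbind, hist1), phase2 = ep_log)
  model
}

# Validation loss for the phase-2 decay schedule: the contrastive term over
# full-batch-size chunks (the component phase 2 exists to improve; the raw
# reconstruction sum is orders of magnitude larger and would mask pairing
# progress). The fused reconstruction still trains through the gradient.
phase2_val_loss <- function(model, Xv, cfg, mask) {
  mods <- model$modalities
  Z <- lapply(mods, function(nm) mlp_forward(model$encoders[[nm]], Xv[[nm]]))
  names(Z) <- mods
  if (cfg$normalize_embeddings) {
    Z <- lapply(Z, function(M) M / (sqrt(rowSums(M^2)) + 1e-12))
  }
  n <- nrow(Z[[1]]); b <- cfg$batch_size
  lc <- 0
  for (k in seq_len(floor(n / b))) {
    idx <- ((k - 1) * b + 1):(k * b)
    lc <- lc + contrastive_loss(lapply(Z, function(M) M[idx, , drop = FALSE]),
                                model$temp)
  }
  lc
}

#' Embed observations of one modality
#'
#' @param model a `crossmodal_model`.
#' @param observations matrix of flattened observations (rows = subjects) or
#'   a `cohort` (flattened internally).
#' @param modality modality name.
#' @param phase1 use the phase-1 (unimodal) encoder snapshot instead of the
#'   cross-modally fine-tuned encoder.
#' @param subset optional row selector when `observations` is a cohort.
#' @return embedding matrix n x d, rownames preserved.
#' @export
embed_modality <- function(model, observations, modality, phase1 = FALSE,
                           subset = NULL) {
  if (!modality %in% model$modalities) {
    stop("unknown modality: ", modality)
  }
  if (inherits(observations, "cohort")) {
    observations <- modality_matrix(observations, modality, subset)
  }
  enc <- if (phase1) model$phase1$encoders[[modality]] else model$encoders[[modality]]
  if (phase1 && is.null(enc)) stop("model has no phase-1 snapshot")
  Z <- mlp_forward(enc, observations)
  rownames(Z) <- rownames(observations)
  Z
}

#' Save / load a model checkpoint as portable JSON
#'
#' Parameter arrays, architecture, temperature and training config are
#' stored with full precision; round trip is exact up to double formatting
#' at 17 significant digits.
#'
#' @param model a `crossmodal_model`.
#' @param path file path.
#' @return `load_model` returns the restored model.
#' @export
save_model <- function(model, path) {
  ser_net <- function(net) list(
    sizes = net$sizes,
    layers = lapply(net$layers, function(l) list(W = as.vector(l$W),
                                                 dim = dim(l$W), b = l$b)))
  obj <- list(
    modalities = model$modalities, latent_dim = model$latent_dim,
    temp = model$temp,
    encoders = lapply(model$encoders, ser_net),
    decoders = lapply(model$decoders, ser_net),
    specs = lapply(model$specs, unclass),
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  de_net <- function(sn) {
    layers <- lapply(sn$layers, function(l) {
      dm <- as.integer(unlist(l$dim))
      list(W = matrix(num(l$W), dm[1], dm[2]), b = num(l$b))
    })
    structure(list(layers = layers, sizes = as.integer(unlist(sn$sizes))),
              class = "mlp")
  }
  structure(list(
    encoders = lapply(obj$encoders, de_net),
    decoders = lapply(obj$decoders, de_net),
    temp = as.numeric(obj$temp), phase1 = NULL, history = list(),
    latent_dim = as.integer(obj$latent_dim),
    modalities = as.character(unlist(obj$modalities)),
    specs = obj$specs, config = obj$config
  ), class = "crossmodal_model")
}
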
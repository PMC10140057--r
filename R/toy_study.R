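#' Reference desk-scale study configurations
#'
#' The package ships one fixed desk-scale experimental design used by its
#' validation suite and by `scripts/acceptance.R`: a 512-subject paired
#' cohort (2 x 128 waveform, 16 x 16 x 4 image sequence, true latent
#' dimension 8), a 16-dimensional model latent space with single-hidden-layer
#' MLP encoders (128 units for the waveform, 192 for the image), and the
#' two-phase schedule with normalized-embedding contrastive fine-tuning.
#' See the methods vignette for the rationale behind each setting.
#'
#' @param seed root seed; cohort and training streams are derived from it.
#' @return `toy_cohort_config`: a [cohort_config()]; `toy_specs`: list of two
#'   [modality_spec()]; `toy_training_config`: a [training_config()].
#' @export
toy_cohort_config <- function(seed = 1L) {
  cohort_config(n_subjects = 512, n_snps = 0, seed = seed + 10L)
}

#' @rdname toy_cohort_config
#' @param latent_dim model latent dimension d.
#' @export
toy_specs <- function(latent_dim = 16L) {
  list(modality_spec("waveform", 2L * 128L, hidden = 128L, latent_dim = latent_dim),
       modality_spec("image", 16L * 16L * 4L, hidden = 192L, latent_dim = latent_dim))
}

#' @rdname toy_cohort_config
#' @export
toy_training_config <- function(seed = 1L) {
  training_config(lr_crossmodal = 1e-3, patience = 2L, max_epochs = 120L,
                  normalize_embeddings = TRUE, seed = seed)
}

#' Run the reference cross-modal study end to end
#'
#' Generates the reference cohort, trains the cross-modal autoencoder, and
#' computes the headline evaluation quantities on the held-out test split:
#' top-1/top-5 cross-modal retrieval for the fine-tuned and the phase-1
#' (unimodal) embeddings, NTK-regression R^2 for the structural remodeling
#' score from waveform embeddings (fine-tuned vs phase-1), and the
#' correlation between the planted wall score and the wall-pixel-count
#' oracle measured on images translated from waveforms.
#'
#' @param seed root seed.
#' @param cohort optionally reuse an existing reference cohort.
#' @param model optionally reuse an already trained model.
#' @return list with `cohort`, `model`, and `metrics` (named list).
#' @export
toy_study <- function(seed = 1L, cohort = NULL, model = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(toy_cohort_config(seed))
  if (is.null(model)) {
    model <- train_crossmodal(cohort, toy_specs(), toy_training_config(seed))
  }
  te <- cohort$split == "test"
  tr <- cohort$split == "train"
  va <- cohort$split == "val"
  Zw <- embed_modality(model, cohort, "waveform", subset = te)
  Zi <- embed_modality(model, cohort, "image", subset = te)
  Zw1 <- embed_modality(model, cohort, "waveform", phase1 = TRUE, subset = te)
  Zi1 <- embed_modality(model, cohort, "image", phase1 = TRUE, subset = te)
  ret <- retrieval_topk(Zw, Zi, ks = c(1L, 5L))
  ret1 <- retrieval_topk(Zw1, Zi1, ks = c(1L, 5L))

  r2_wave <- function(phase1, y) {
    fit <- fit_ntk_regression(
      embed_modality(model, cohort, "waveform", phase1 = phase1, subset = tr), y[tr],
      embed_modality(model, cohort, "waveform", phase1 = phase1, subset = va), y[va])
    preds <- fit$predict(embed_modality(model, cohort, "waveform",
                                        phase1 = phase1, subset = te))
    evaluate_predictions(preds, y[te], "continuous")
  }
  y_rem <- cohort$phenotypes$remodel_score
  r2_cm <- r2_wave(FALSE, y_rem)
  r2_p1 <- r2_wave(TRUE, y_rem)

  translated <- translate(model, modality_matrix(cohort, "waveform", te),
                          "waveform", "image")
  oracle <- apply(translated, 1, function(r)
    measure_wall_area(unflatten_observation(r, cohort$config$image_spec)))
  trans_cor <- stats::cor(cohort$phenotypes$wall_score[te], oracle)

  list(cohort = cohort, model = model, metrics = list(
    n_test = sum(te),
    top1_crossmodal = ret$accuracy$accuracy[1],
    top5_crossmodal = ret$accuracy$accuracy[2],
    top1_phase1 = ret1$accuracy$accuracy[1],
    r2_remodel_crossmodal = r2_cm,
    r2_remodel_phase1 = r2_p1,
    r2_gain = r2_cm - r2_p1,
    translation_cor = trans_cor
  ))
}
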
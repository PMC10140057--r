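#' Configuration for a synthetic paired-modality cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator emulates a cohort in which every subject carries a true latent
#' physiological state `z` of dimension `latent_dim_true`; the waveform and
#' image modalities are deterministic renderings of disjoint-plus-shared
#' subsets of the latent coordinates, genotypes can shift the latent state
#' additively, and confounders (age-like, sex-like, ancestry axes, batch)
#' leak into the latent state through a fixed random loading matrix.
#'
#' Latent coordinates are partitioned by role: coordinates 1..2 are
#' "electrical" (drive the waveform only), 3..5 are "structural" (drive the
#' image only) and 6..8 are "shared" (drive both). Cross-modal matching is
#' therefore possible only through the shared coordinates, which is the
#' premise that makes retrieval and cross-modal phenotype transfer
#' non-trivial. With `latent_dim_true != 8` the partition scales
#' proportionally (first quarter electrical, next ~3/8 structural, rest
#' shared, each at least one coordinate).
#'
#' @param n_subjects number of subjects.
#' @param latent_dim_true dimension k of the true latent state.
#' @param n_snps number of simulated SNPs.
#' @param maf_range length-2 numeric, minor-allele-frequency range in (0, 0.5].
#' @param causal_snps list of lists with elements `snp` (1-based SNP index),
#'   `beta` (length-k direction, need not be unit norm) and `scale` (effect
#'   size per alt allele, in units of latent SD along `beta`).
#' @param confounder_spec list with `n_ancestry_axes`, `n_batches`, and
#'   logical `age`, `sex`.
#' @param confounder_strength SD of the random confounder-to-latent loadings;
#'   0 disables confounder leakage.
#' @param geno_confounding strength of ancestry stratification of allele
#'   frequencies: subject-level allele frequency is
#'   `plogis(qlogis(p_snp) + geno_confounding * PC1)`. 0 disables it.
#' @param waveform_spec list with `n_leads`, `n_timepoints`.
#' @param image_spec list with `height`, `width`, `n_frames`.
#' @param noise_sd named list, additive Gaussian noise SD per modality
#'   (`waveform`, `image`) and for phenotypes (`phenotype`).
#' @param phenotype_loadings named list mapping phenotype name to a length-k
#'   weight vector; `NULL` uses the package defaults (`wall_score`,
#'   `qt_score`, `amp_score`).
#' @param binary_quantile quantile of the continuous score at which the
#'   thresholded binary phenotype (`wall_disease`) turns positive.
#' @param missing_rate fraction of genotype calls set missing.
#' @param split_fractions length-3 numeric (train/val/test), summing to 1.
#' @param seed integer root seed; the same config reproduces the cohort
#'   exactly.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          latent_dim_true = 8L,
                          n_snps = 0L,
                          maf_range = c(0.05, 0.5),
                          causal_snps = list(),
                          confounder_spec = list(n_ancestry_axes = 2L,
                                                 n_batches = 2L,
                                                 age = TRUE, sex = TRUE),
                          confounder_strength = 0.35,
                          geno_confounding = 0,
                          waveform_spec = list(n_leads = 2L, n_timepoints = 128L),
                          image_spec = list(height = 16L, width = 16L, n_frames = 4L),
                          noise_sd = list(waveform = 0.04, image = 0.05,
                                          phenotype = 0.1, wander = 0.15),
                          phenotype_loadings = NULL,
                          binary_quantile = 0.8,
                          missing_rate = 0,
                          split_fractions = c(0.75, 0.125, 0.125),
                          seed = 1L) {
  stopifnot(n_subjects >= 2, latent_dim_true >= 4, n_snps >= 0)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (abs(sum(split_fractions) - 1) > 1e-8 || length(split_fractions) != 3) {
    stop("split_fractions must be three fractions summing to 1")
  }
  for (cs in causal_snps) {
    if (cs$snp < 1 || cs$snp > n_snps) stop("causal SNP index out of range")
    if (length(cs$beta) != latent_dim_true) {
      stop("causal effect vector length must equal latent_dim_true")
    }
  }
  k <- as.integer(latent_dim_true)
  roles <- latent_roles(k)
  if (is.null(phenotype_loadings)) {
    phenotype_loadings <- default_phenotype_loadings(k, roles)
  }
  for (w in phenotype_loadings) {
    if (length(w) != k) stop("phenotype loading length must equal latent_dim_true")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), latent_dim_true = k,
    n_snps = as.integer(n_snps), maf_range = maf_range,
    causal_snps = causal_snps, confounder_spec = confounder_spec,
    confounder_strength = confounder_strength,
    geno_confounding = geno_confounding,
    waveform_spec = waveform_spec, image_spec = image_spec,
    noise_sd = noise_sd, phenotype_loadings = phenotype_loadings,
    binary_quantile = binary_quantile, missing_rate = missing_rate,
    split_fractions = split_fractions, roles = roles,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Partition of latent coordinates into electrical / structural / shared roles.
latent_roles <- function(k) {
  n_elec <- max(1L, floor(k / 4))
  n_struct <- max(1L, floor(3 * k / 8))
  n_shared <- k - n_elec - n_struct
  if (n_shared < 1L) { n_struct <- n_struct - 1L; n_shared <- 1L }
  list(electrical = seq_len(n_elec),
       structural = n_elec + seq_len(n_struct),
       shared = (n_elec + n_struct) + seq_len(n_shared))
}

# Default phenotype loadings. wall_score mirrors the determinants of the
# rendered wall area (wall-thickness coord shared[1], aspect shared[2],
# cavity coord structural[1]), so it is measurable from the image with the
# pixel-count oracle and partially transferable from the waveform.
# remodel_score is a composite structural-remodeling score loading on the
# shared geometry drivers whose waveform footprints are subtle
# (shared[1] latency, shared[3] early-bump amplitude) plus the image-only
# pulsation coordinate -- the natural target for showing cross-modal
# transfer. qt_score / amp_score are waveform-centric analogues.
default_phenotype_loadings <- function(k, roles) {
  w_wall <- numeric(k); w_rem <- numeric(k); w_qt <- numeric(k); w_amp <- numeric(k)
  sh <- roles$shared; st <- roles$structural; el <- roles$electrical
  w_wall[sh[1]] <- 0.6
  if (length(sh) >= 2) w_wall[sh[2]] <- 0.3
  w_wall[st[1]] <- 0.2
  w_rem[sh[1]] <- 0.45
  if (length(sh) >= 3) w_rem[sh[3]] <- 0.4
  w_rem[st[min(3, length(st))]] <- 0.2
  w_qt[el[min(2, length(el))]] <- 0.8
  w_qt[sh[1]] <- 0.4
  w_amp[el[1]] <- 0.8
  if (length(sh) >= 3) w_amp[sh[3]] <- 0.3
  list(wall_score = w_wall, remodel_score = w_rem,
       qt_score = w_qt, amp_score = w_amp)
}

#' Simulate a genotype dosage matrix
#'
#' Each SNP s gets an allele frequency p_s drawn uniformly from `maf_range`;
#' dosages are binomial(2, p_s) per subject (Hardy-Weinberg). With
#' `geno_confounding` nonzero and a supplied `pc1` vector, the subject-level
#' frequency becomes `plogis(qlogis(p_s) + geno_confounding * pc1)`, planting
#' population stratification.
#'
#' @param n subjects, `n >= 2`.
#' @param n_snps SNP count, `>= 1`.
#' @param maf_range frequency range in (0, 0.5].
#' @param seed integer seed.
#' @param geno_confounding stratification strength on the logit scale.
#' @param pc1 optional length-n ancestry axis used for stratification.
#' @param missing_rate fraction of entries set to `NA`.
#' @return integer matrix n x n_snps with values 0/1/2 (`NA` = missing),
#'   columns named `snp1..snpS`, with attribute `maf` (the drawn frequencies).
#' @export
simulate_genotypes <- function(n, n_snps, maf_range, seed = 1L,
                               geno_confounding = 0, pc1 = NULL,
                               missing_rate = 0) {
  stopifnot(n >= 2, n_snps >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("maf_range bounds must lie in (0, 0.5]")
  }
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- matrix(0L, n, n_snps, dimnames = list(NULL, paste0("snp", seq_len(n_snps))))
  for (s in seq_len(n_snps)) {
    p <- if (geno_confounding != 0 && !is.null(pc1)) {
      stats::plogis(stats::qlogis(maf[s]) + geno_confounding * pc1)
    } else rep(maf[s], n)
    G[, s] <- stats::rbinom(n, 2L, p)
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_snps) < missing_rate, n, n_snps)
    G[miss] <- NA_integer_
  }
  attr(G, "maf") <- maf
  G
}

# Save/restore the global RNG so generator calls are reproducible without
# clobbering the caller's stream. Returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

gauss_bump <- function(t, center, width) exp(-(t - center)^2 / (2 * width^2))

#' Render a synthetic multi-lead waveform from a latent state
#'
#' Deterministic smooth template: each lead is a sum of Gaussian bumps whose
#' amplitudes and latencies are affine in designated latent coordinates.
#' Electrical coordinates set bump amplitudes; shared coordinates set the
#' late-bump latency (coordinate `shared[1]`), the second-lead main-bump
#' amplitude (`shared[2]`) and the second-lead early-bump amplitude
#' (`shared[3]`). Structural coordinates do not enter, by construction.
#'
#' On top of the template, per-subject baseline wander -- a random smooth
#' low-frequency oscillation with `wander_sd`-scaled amplitudes -- emulates
#' the structured nuisance variation of real recordings: it is
#' reconstructable (so a unimodal autoencoder spends latent capacity on it)
#' but carries no information shared with the image modality. Set
#' `wander_sd = 0` for the pure template.
#'
#' @param z latent vector of length k.
#' @param spec list with `n_leads`, `n_timepoints`.
#' @param noise_sd additive iid Gaussian noise SD.
#' @param seed seed for the wander and noise draws.
#' @param roles latent-role partition as produced by the cohort config;
#'   defaults to the partition for `length(z)`.
#' @param wander_sd SD of the per-subject baseline-wander amplitudes.
#' @return numeric matrix n_leads x n_timepoints ("millivolt-like" units).
#' @export
render_waveform <- function(z, spec = list(n_leads = 2L, n_timepoints = 128L),
                            noise_sd = 0, seed = 1L, roles = latent_roles(length(z)),
                            wander_sd = 0) {
  stopifnot(length(z) >= max(unlist(roles)))
  el <- roles$electrical; sh <- roles$shared
  z_e1 <- z[el[1]]
  z_e2 <- z[el[min(2, length(el))]]
  z_s1 <- z[sh[1]]
  z_s2 <- z[sh[min(2, length(sh))]]
  z_s3 <- z[sh[min(3, length(sh))]]
  t <- seq(0, 1, length.out = spec$n_timepoints)
  W <- matrix(0, spec$n_leads, spec$n_timepoints)
  # shared latency coordinate: deliberately subtle (small reconstruction
  # footprint) so only pairing pressure extracts it well
  t_late <- 0.68 + 0.045 * z_s1
  lead1 <- 0.45 * gauss_bump(t, 0.18, 0.045) +
    (1.4 + 0.5 * z_e1) * gauss_bump(t, 0.42, 0.022) +
    (0.55 + 0.30 * z_e2) * gauss_bump(t, t_late, 0.055)
  lead2 <- (0.35 + 0.20 * z_s3) * gauss_bump(t, 0.18, 0.05) +
    (0.9 + 0.45 * z_s2) * gauss_bump(t, 0.43, 0.025) +
    (0.40 + 0.20 * z_e2 + 0.10 * z_s1) * gauss_bump(t, t_late + 0.02, 0.06)
  leads <- list(lead1, lead2)
  for (l in seq_len(spec$n_leads)) W[l, ] <- leads[[((l - 1) %% 2) + 1]]
  if (noise_sd > 0 || wander_sd > 0) {
    rs <- local_rng(seed); on.exit(rs(), add = TRUE)
    if (wander_sd > 0) {
      for (l in seq_len(spec$n_leads)) {
        for (f in 1:3) {
          W[l, ] <- W[l, ] + stats::rnorm(1, sd = wander_sd) *
            sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
        }
      }
    }
    if (noise_sd > 0) {
      W <- W + matrix(stats::rnorm(length(W), sd = noise_sd), nrow(W), ncol(W))
    }
  }
  W
}

#' Render a synthetic pulsating annulus image sequence from a latent state
#'
#' A soft-edged elliptical annulus ("wall" around a cavity) whose geometry is
#' affine (or log-affine) in designated latent coordinates: structural
#' coordinates set the cavity radius, wall brightness and pulsation
#' amplitude; shared coordinates set the wall thickness (`shared[1]`), an
#' area-preserving elliptical aspect (`shared[2]`) and a horizontal centre
#' offset (`shared[3]`). Each shared coordinate maps to its own image
#' feature so all of them are identifiable from the image alone. The cavity
#' radius pulsates across frames, mimicking a cardiac cycle. After adding
#' noise the whole sequence is z-scored per subject (mean 0, SD 1).
#'
#' @param z latent vector.
#' @param spec list with `height`, `width`, `n_frames`.
#' @param noise_sd additive Gaussian pixel noise SD before normalization.
#' @param seed seed for the noise draw.
#' @param roles latent-role partition.
#' @param normalize z-score the sequence (the generative default); set
#'   `FALSE` to inspect the raw template.
#' @return numeric array height x width x n_frames.
#' @export
render_image <- function(z, spec = list(height = 16L, width = 16L, n_frames = 4L),
                         noise_sd = 0, seed = 1L, roles = latent_roles(length(z)),
                         normalize = TRUE) {
  st <- roles$structural; sh <- roles$shared
  z_t1 <- z[st[1]]
  z_t2 <- z[st[min(2, length(st))]]
  z_t3 <- z[st[min(3, length(st))]]
  z_s1 <- z[sh[1]]
  z_s2 <- z[sh[min(2, length(sh))]]
  z_s3 <- z[sh[min(3, length(sh))]]
  H <- spec$height; Wd <- spec$width; Tn <- spec$n_frames
  cx <- (Wd + 1) / 2 + 0.7 * z_s3
  cy <- (H + 1) / 2
  wall <- max(0.5, 2.2 + 0.9 * z_s1)
  aspect <- exp(0.12 * z_s2)      # area-preserving elongation
  amp <- 1 + 0.35 * z_t2
  pulse <- 0.12 + 0.04 * z_t3
  img <- array(0, c(H, Wd, Tn))
  xg <- matrix(rep(seq_len(Wd), each = H), H, Wd)
  yg <- matrix(rep(seq_len(H), Wd), H, Wd)
  for (f in seq_len(Tn)) {
    r0 <- (3.2 + 0.45 * z_t1) * (1 + pulse * cos(2 * pi * (f - 1) / Tn))
    r0 <- max(r0, 1)
    r <- sqrt(((xg - cx) / aspect)^2 + ((yg - cy) * aspect)^2)
    img[, , f] <- amp * (stats::plogis((r - r0) / 0.5) -
                           stats::plogis((r - r0 - wall) / 0.5))
  }
  if (noise_sd > 0) {
    rs <- local_rng(seed); on.exit(rs(), add = TRUE)
    img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
  }
  if (normalize) {
    img <- (img - mean(img)) / stats::sd(img)
  }
  img
}

#' Measure the bright-wall pixel area of an image sequence
#'
#' Geometry oracle used to score rendered or model-generated image sequences:
#' counts, in the first frame, pixels brighter than the midpoint of the
#' frame's intensity range. On noiseless rendered sequences this count is
#' monotone in the wall thickness (and cavity radius), so it recovers the
#' structural drivers independently of any learned model.
#'
#' @param img array height x width x n_frames (any affine intensity scale).
#' @return integer pixel count.
#' @export
measure_wall_area <- function(img) {
  f1 <- img[, , 1]
  thr <- min(f1) + 0.5 * (max(f1) - min(f1))
  sum(f1 > thr)
}

#' Generate a complete synthetic paired-modality cohort
#'
#' Draws confounders, genotypes, latent states
#' `z = F %*% Gamma + sum_s dosage_s * scale_s * beta_s + residual`,
#' phenotypes `Y = z %*% loadings + noise` (binary phenotype by quantile
#' thresholding of `wall_score`), and renders both modalities per subject.
#' Identical config (including seed) reproduces the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: list with `subject_ids`, `z_true`
#'   (n x k), `confounders` (n x m_c numeric design, continuous columns
#'   z-scored, factors one-hot with first level dropped),
#'   `confounder_labels` (raw data frame), `genotypes` (n x S),
#'   `phenotypes` (data frame), `waveforms` (n x leads x time),
#'   `images` (n x H x W x frames), `split` (factor train/val/test),
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects; k <- config$latent_dim_true
  roles <- config$roles
  rs <- local_rng(config$seed)
  on.exit(rs(), add = TRUE)

  ids <- sprintf("S%04d", seq_len(n))

  ## confounders -------------------------------------------------------
  cs <- config$confounder_spec
  lab <- data.frame(row.names = seq_len(n))
  if (isTRUE(cs$age)) lab$age <- stats::runif(n, 40, 70)
  if (isTRUE(cs$sex)) lab$sex <- stats::rbinom(n, 1, 0.5)
  n_pc <- if (is.null(cs$n_ancestry_axes)) 0L else cs$n_ancestry_axes
  for (a in seq_len(n_pc)) lab[[paste0("pc", a)]] <- stats::rnorm(n)
  n_batch <- if (is.null(cs$n_batches)) 1L else cs$n_batches
  if (n_batch > 1) lab$batch <- factor(sample.int(n_batch, n, replace = TRUE))
  Fmat <- encode_confounders(lab)
  m_c <- ncol(Fmat)

  ## genotypes ---------------------------------------------------------
  pc1 <- if ("pc1" %in% names(lab)) lab$pc1 else NULL
  G <- NULL
  if (config$n_snps > 0) {
    G <- simulate_genotypes(n, config$n_snps, config$maf_range,
                            seed = config$seed + 101L,
                            geno_confounding = config$geno_confounding,
                            pc1 = pc1, missing_rate = config$missing_rate)
    rownames(G) <- ids
  }

  ## latent states -----------------------------------------------------
  z <- matrix(stats::rnorm(n * k), n, k)
  if (m_c > 0 && config$confounder_strength > 0) {
    Gamma <- matrix(stats::rnorm(m_c * k, sd = config$confounder_strength), m_c, k)
    z <- z + Fmat %*% Gamma
  }
  for (cs_i in config$causal_snps) {
    dose <- G[, cs_i$snp]
    dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    beta_u <- cs_i$beta / sqrt(sum(cs_i$beta^2))
    z <- z + outer(dose * cs_i$scale, beta_u)
  }
  rownames(z) <- ids

  ## phenotypes --------------------------------------------------------
  L <- config$phenotype_loadings
  Y <- data.frame(row.names = ids)
  for (nm in names(L)) {
    Y[[nm]] <- drop(z %*% L[[nm]]) +
      stats::rnorm(n, sd = config$noise_sd$phenotype)
  }
  if ("wall_score" %in% names(Y)) {
    thr <- stats::quantile(Y$wall_score, config$binary_quantile)
    Y$wall_disease <- as.integer(Y$wall_score > thr)
  }

  ## modalities --------------------------------------------------------
  ws <- config$waveform_spec; is_ <- config$image_spec
  waves <- array(0, c(n, ws$n_leads, ws$n_timepoints))
  imgs <- array(0, c(n, is_$height, is_$width, is_$n_frames))
  for (i in seq_len(n)) {
    waves[i, , ] <- render_waveform(z[i, ], ws, config$noise_sd$waveform,
                                    seed = config$seed + 1000L + i, roles = roles,
                                    wander_sd = if (is.null(config$noise_sd$wander)) 0 else config$noise_sd$wander)
    imgs[i, , , ] <- render_image(z[i, ], is_, config$noise_sd$image,
                                  seed = config$seed + 5000L + i, roles = roles)
  }

  ## splits: floor for val/test, remainder to train (documented rule) --
  fr <- config$split_fractions
  n_val <- floor(n * fr[2]); n_test <- floor(n * fr[3])
  n_train <- n - n_val - n_test
  split <- factor(rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
                  levels = c("train", "val", "test"))
  split <- split[sample.int(n)]

  structure(list(
    subject_ids = ids, z_true = z, confounders = Fmat,
    confounder_labels = lab, genotypes = G, phenotypes = Y,
    waveforms = waves, images = imgs, split = split, config = config
  ), class = "cohort")
}

#' Encode a confounder table as a numeric design matrix
#'
#' Continuous columns are z-scored; factor/character columns are one-hot
#' encoded with the first level dropped (avoids perfect collinearity);
#' binary 0/1 numeric columns are centred but not scaled to preserve
#' interpretation.
#'
#' @param df data frame of raw confounders.
#' @return numeric matrix with one row per subject.
#' @export
encode_confounders <- function(df) {
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(v) < 2) next
      M <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      colnames(M) <- paste0(nm, levels(v)[-1])
      cols[[nm]] <- M
    } else {
      u <- unique(v[!is.na(v)])
      if (all(u %in% c(0, 1))) {
        cols[[nm]] <- matrix(v - mean(v), ncol = 1, dimnames = list(NULL, nm))
      } else {
        cols[[nm]] <- matrix(as.numeric(scale(v)), ncol = 1,
                             dimnames = list(NULL, nm))
      }
    }
  }
  if (!length(cols)) return(matrix(0, nrow(df), 0))
  do.call(cbind, cols)
}

#' Flatten a cohort's modality arrays into observation matrices
#'
#' @param cohort a `cohort`.
#' @param modality `"waveform"` or `"image"`.
#' @param subset optional logical/integer row selector (e.g. a split mask).
#' @return numeric matrix, one row per subject (row-major flattening of the
#'   per-subject array), rownames = subject ids.
#' @export
modality_matrix <- function(cohort, modality = c("waveform", "image"),
                            subset = NULL) {
  modality <- match.arg(modality)
  arr <- if (modality == "waveform") cohort$waveforms else cohort$images
  n <- dim(arr)[1]
  X <- matrix(arr, nrow = n)   # column-major flatten; consistent both ways
  rownames(X) <- cohort$subject_ids
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  X
}
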
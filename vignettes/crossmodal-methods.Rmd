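---
title: "Cross-modal latent spaces for paired physiological data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal latent spaces for paired physiological data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Many cohorts record several measurement modalities per subject — here a
multi-lead one-dimensional waveform (an ECG-like trace) and a short image
sequence (a cine cardiac-imaging-like stack) — but most downstream uses have
only one modality available. `crossmodal` trains modality-specific
encoder/decoder pairs into one shared latent space so that (i) a subject's
two observations embed nearby, (ii) either modality alone yields a
representation informative about both, and (iii) the latent space supports
phenotype prediction, cross-modal translation, unsupervised genetic
association, and SNP effect clustering.

# The model

Each modality $j$ has an encoder $f_j:\mathbb{R}^{d_j}\to\mathbb{R}^d$ and a
decoder $g_j:\mathbb{R}^d\to\mathbb{R}^{d_j}$, here compact fully-connected
ReLU networks (one hidden layer; 128 units for the 256-sample waveform, 192
for the 1024-pixel image stack; $d = 16$). The training objective is

$$\mathcal{L} = L_\text{contrast} + \lambda\, L_\text{reconstruct},
\qquad \lambda = 0.1 .$$

$L_\text{reconstruct}$ is the plain squared reconstruction error summed over
samples and modalities. $L_\text{contrast}$ is the symmetric paired-sample
(InfoNCE-style) loss: within a batch of size $b = 4$, for every ordered pair
of distinct modalities and every sample, two log-softmax terms over the
scaled similarity matrix $e^{\text{temp}} Z_{j_1} Z_{j_2}^\top$ — one softmax
along each axis — summed and multiplied by $-1/2$. The temperature is a
trainable scalar initialized at $0$ (so the initial scale is $e^0 = 1$; the
start is neutral and the optimizer is free to sharpen or soften the
softmax). With all embeddings in a batch identical the loss is
$2b\ln b$; a singleton batch contributes $0$ — both are unit-tested against
a brute-force enumeration.

Two details matter in practice:

* **Normalized similarities.** By default at desk scale the contrastive term
  uses L2-normalized embeddings (`normalize_embeddings = TRUE` in
  `training_config()`). With raw dot products the optimizer can trade
  pairing accuracy against embedding norm growth; on the unit sphere the
  objective matches the cosine criterion used for retrieval. The raw-dot
  variant remains available (`FALSE`, the formal default) because the loss
  is written in terms of raw inner products.
* **Dropout fusion.** During fine-tuning a Bernoulli(0.5) mask mixes the two
  embeddings coordinate-wise and the merged vector is decoded by *both*
  decoders, forcing every coordinate of either embedding to carry
  information both decoders can use. With mask rate 0 or 1 this degenerates
  to decoding from a single modality's embedding.

## Two-phase schedule

Phase 1 trains each autoencoder separately on reconstruction (Adam,
learning rate `1e-3`). Phase 2 fine-tunes everything, including the
temperature, on the combined objective. After `patience` epochs without
validation improvement the learning rate halves; after 3 decays the phase
stops. Two desk-scale adaptations, exposed in `training_config()`:

* the phase-2 learning rate is `1e-3` (the biobank-scale value `2e-5` is the
  formal default; with ~500 subjects and small MLPs it moves the
  parameters too little before the decay schedule terminates);
* `patience = 2` instead of 1, because the validation split here has only
  64 subjects and its loss is noisy enough to trigger premature decays;
* the phase-2 schedule watches the **contrastive component** of the
  validation loss. The reconstruction sum is two orders of magnitude larger
  than the contrastive term, so a combined validation total cannot register
  pairing progress; the fused reconstruction still trains through the
  gradient. This was a genuinely open design point; the choice is recorded
  here deliberately.

# The synthetic cohort

No external data are required: `generate_cohort()` emulates the study
design. Every subject carries a true latent state $z \in \mathbb{R}^8$ with
coordinates partitioned by role — *electrical* (1–2, waveform only),
*structural* (3–5, image only), *shared* (6–8, both). The premise of the
whole framework — that modalities are complementary but overlapping — is
thus literal in the generator: cross-modal matching is possible only
through the shared coordinates.

The waveform (2 leads × 128 samples) is a sum of Gaussian bumps whose
amplitudes are affine in the electrical coordinates; shared coordinates
enter as a late-bump latency (z6, deliberately subtle), the second-lead
main-bump amplitude (z7), and the second-lead early-bump amplitude (z8).
On top, each subject receives random low-frequency *baseline wander*
(3 sinusoids per lead, amplitude SD 0.15). This is the one feature
deliberately emulating the *nuisance structure* of real recordings: it is
reconstructable — so a purely unimodal autoencoder spends latent capacity
on it — but carries no cross-subject pairing information, so contrastive
fine-tuning suppresses it. Without such nuisance a desk-scale unimodal
autoencoder encodes essentially everything and no representation can beat
another.

The image (16 × 16 × 4 frames) is a soft-edged pulsating annulus: cavity
radius, brightness and pulsation amplitude are structural; wall thickness
(z6), an area-preserving elliptical aspect (z7) and a centre offset (z8)
are shared. Each shared coordinate has its *own* image feature — an earlier
design in which z7 entered only inside the wall-thickness sum made it
unidentifiable from images and silently broke the latent partition.
Images are z-scored per subject after noise, mirroring standard
preprocessing. `measure_wall_area()` is an analysis-independent geometry
oracle: it thresholds the first frame at mid-intensity and counts bright
pixels, a quantity monotone in wall thickness by construction.

Genotypes are Hardy–Weinberg binomial dosages; causal SNPs shift $z$
additively along configurable directions. Confounders (age-like, sex-like,
ancestry axes, batch) leak into $z$ through a fixed random loading matrix
(SD 0.35 by default — enough that confounder removal genuinely has work to
do, with a linear confounder $R^2$ on $z$ above 0.1). Setting
`geno_confounding` > 0 additionally shifts each SNP's allele frequency
along the first ancestry axis, planting population stratification.
Phenotypes are linear scores of $z$ plus noise (SD 0.1); `wall_score`
mirrors the rendered wall-area determinants (0.6 z6 + 0.3 z7 + 0.2 z3) and
is the translation readout; `remodel_score` (0.45 z6 + 0.4 z8 + 0.2 z5)
loads on shared coordinates whose waveform footprints are subtle, making
it the natural target for demonstrating cross-modal transfer. A binary
`wall_disease` label thresholds `wall_score` at its 0.8 quantile,
mirroring how clinical labels are derived by thresholding continuous
measurements.

What passing tests on this cohort do **not** show: physiological realism
of the waveforms or images, robustness to acquisition artefacts beyond
iid noise and smooth wander, linkage disequilibrium between SNPs, or
non-linear genotype–phenotype architecture. The generator is a testbed for
the *machinery*, not a simulator of cardiology.

# Downstream methods

## Phenotype prediction

`ntk_kernel()` implements the closed-form fully-connected ReLU neural
tangent kernel recursion (depth 3 by default; the depth is a free
parameter because no canonical value exists) on unit-normalized inputs;
`fit_kernel_regression()` solves ridgeless kernel regression by plain
gradient iteration in the dual with validation-based early stopping — the
contract is the ridgeless limit plus early stopping, not any particular
preconditioner. The regression wrapper centres and unit-scales embedding
columns first: embeddings with a large common offset otherwise give
near-constant cosines and a degenerate kernel. Binary phenotypes use
L2-regularized logistic regression with class weights $n/r$ and $n/(n-r)$.
`derive_lvh_lvsd()` encodes the clinical thresholding conventions exactly:
Mosteller body-surface area $\sqrt{hw/3600}$, hypertrophy strictly above
72 (male) / 55 (female) g/m², systolic dysfunction strictly below 45%
ejection fraction. `fit_scaling_law()` fits mean performance on
$(\log_2 u, \log_2 v)$ without an intercept (a flag adds one), matching the
two-coefficient form of the unlabelled/labelled scaling relationship.

## Retrieval and translation

Retrieval ranks target embeddings by cosine similarity; ties break by
stable index order (first-come wins), which makes results reproducible and
is unit-tested. Translation is the cross-composition $g_{to}(f_{from}(x))$;
latent shifts move an embedding along a unit-normalized direction.

## Confounder removal (INLP)

Iterated nullspace projection: regress confounders on embeddings, take the
SVD of the fitted $w$, keep the bottom $d - m_c$ right singular vectors,
project, repeat. Dimensionality is reduced directly (no accumulated
projector matrices), so after $t$ iterations the dimension is exactly
$d - t\,m_c$ — including when $w$ is rank-deficient, where the dimension
count follows the confounder count by contract. Embeddings are centred
once; continuous confounders are z-scored and categorical ones one-hot
encoded with a dropped level (the standardization and pooling rules are
this package's choices; the pooled $R^2$ is
$1 - \sum SS_{res} / \sum SS_{tot}$ across standardized columns, with a
stricter per-column maximum available).

**Small-sample correction.** The stopping rule compares a
degrees-of-freedom-adjusted $R^2$ against the threshold (default 0.001).
The raw in-sample $R^2$ is upward-biased by roughly $d/n$ under the null —
0.016 at $n = 500$, $d = 8$ — which exceeds any tight threshold and would
make termination impossible on already-clean embeddings. The adjusted
statistic is centred at zero under the null; it still fluctuates with SD of
order $\sqrt{2d}/n$, so for $n = 500$ studies the package's validation
suite uses a threshold of 0.01 (≈ 2–3 null SDs at that scale, the analogue
of 0.001 at biobank scale) and caps iterations. `max_iter` always bounds
the loop, and the projection errors out rather than letting the dimension
fall below the confounder count.

## Latent-space GWAS

The unsupervised test groups subjects by dosage class (0/1/2; classes
under 10 subjects merge into the adjacent class, the heterozygote class
into the smaller homozygote class) and computes Pillai's trace
$V = \mathrm{tr}\,(H(H+E)^{-1})$ with the standard F approximation
($s = \min(p, g-1)$, $m^* = (|p-g+1|-1)/2$, $n^* = (n-g-p-1)/2$). The
implementation is authored here and verified to $10^{-8}$ against
`stats::manova`'s Pillai summary, and reduces exactly to one-way ANOVA at
$p = 1$. SNPs are filtered by minor-allele count (default ≥ 20, standard
practice; the choice is an artifact default, configurable), missing
dosages are handled per-SNP complete-case, and skipped SNPs stay in the
output with a reason. $\lambda_{GC}$ divides the median association
chi-square by `qchisq(0.5, 1)` ≈ 0.4549. Because an unprojected scan over
confounded embeddings is badly inflated, `run_unsupervised_gwas()` demands
the projection state from `inlp()` (or an explicit override, used in the
package's own inflation demonstration, where planted stratification drives
$\lambda_{GC}$ above 10 and INLP returns it to ≈ 1).

The supervised path first spreads a partially observed phenotype across
the whole cohort by ridge regression fitted on a seeded 80% of the labels
and evaluated on the remaining 20%, then regresses the predicted trait on
each dosage with covariates and an intercept, t-testing the dosage
coefficient.

## SNP signatures

A SNP's signature is the latent vector from the homozygous-reference group
mean to the combined carrier group mean, computed on cross-modal
embeddings of a single designated modality. Signatures are clustered with
Ward's method on Euclidean distances (`hclust`, `ward.D2`; merge heights
equal $\sqrt{2\,\Delta ESS}$ and are verified against a hand computation).
Raw difference vectors are clustered by default; a flag unit-normalizes
them to cluster by direction only — the orientation-only reading is
equally defensible and deliberately exposed rather than decided silently.

# The reference study and its numbers

`toy_study(seed)` runs the fixed desk-scale experiment used by the test
suite and by `scripts/acceptance.R`: 512 subjects (384/64/64
train/val/test), the architectures above, the two-phase schedule. Typical
results (the suite pins seed 1; other seeds vary): held-out top-1
cross-modal retrieval 0.3–0.45 against a 1/64 chance rate, phase-1
unimodal retrieval at chance; NTK-regression $R^2$ for `remodel_score`
from waveform embeddings ≈ 0.7 cross-modal vs ≈ 0.4 phase-1; correlation
≈ 0.6–0.8 between `wall_score` and the wall-area oracle measured on images
translated from waveforms. Problem sizes for the statistical studies
(500 × 1000 SNP scans, $n = 10^4$ INLP checks) were chosen so the whole
validation runs in a few minutes on one core while leaving the tested
contrasts far from their decision boundaries.

# Numerical choices and degenerate inputs

* NTK correlations are clamped to $[-1, 1]$ (documented tolerance
  $10^{-12}$) before `acos`; zero vectors are rejected rather than
  silently normalized.
* The kernel solver's step size is $1/\lambda_{max}(K)$, guaranteeing a
  monotone non-increasing training loss; constant targets and in-span
  targets are exact special cases covered by tests.
* SVD-based nullspace uses the spectral decomposition of $w^\top w$;
  the rank tolerance for the minimum-norm fallback in the confounder
  regression is $10^{-10}\sigma_{max}$.
* Genotype edge cases: monomorphic SNPs, all-missing SNPs, and
  single-group SNPs produce skip records, never errors; `./.` and `.`
  parse as missing; phased separators are accepted; multi-allelic VCF
  records are skipped with a message.
* Matrix text I/O writes 17 significant digits so round trips are exact;
  duplicate subject ids are an error.

# Known limitations

* Encoders/decoders are MLPs; convolutional architectures would be the
  natural upgrade for larger inputs and are pluggable through
  `modality_spec()`, but the training engine is plain R and not built for
  biobank-scale data.
* The contrastive loss supports $m \ge 2$ modalities as written, but
  training and fusion are implemented for exactly two.
* Retrieval and transfer results at desk scale vary noticeably with the
  random seed (single-digit test sets of 64 subjects); the reported
  quantities are properties of a seeded run, not population estimates.
* No kinship/mixed-model adjustment, imputation, LD-aware clumping, or
  annotation: association records stop at per-SNP statistics.
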
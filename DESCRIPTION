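Package: crossmodal
Title: Cross-Modal Autoencoders for Paired Physiological Modalities with
    Latent-Space Genetic Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates two paired physiological measurement modalities
    (a multi-lead one-dimensional waveform and a short image sequence per
    subject) into a shared latent space using modality-specific autoencoders
    trained with a combined contrastive and reconstruction objective.
    Downstream machinery operates on the learned embeddings: cross-modal
    translation and top-k retrieval, phenotype prediction with neural tangent
    kernel regression and weighted logistic regression, confounder removal by
    iterated nullspace projection, unsupervised genome-wide association
    testing with Pillai's trace MANOVA plus genomic-control diagnostics, and
    Ward clustering of per-SNP latent effect signatures. A synthetic-cohort
    generator with planted genetic effects and confounders makes the full
    pipeline testable without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    MASS,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
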
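#' Read a genotype dosage matrix from VCF or delimited text
#'
#' VCF: GT fields are mapped to alt-allele dosage (`0/0` -> 0, `0/1` or
#' `1/0` -> 1, `1/1` -> 2; phased separators accepted; `./.` or `.` ->
#' missing). Multi-allelic records are skipped with a message. TSV: subjects
#' x SNPs with a header row and a leading `subject_id` column.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return integer matrix subjects x SNPs (`NA` = missing) with subject ids
#'   as rownames and attributes `chrom`/`pos` for VCF input.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(v@gt)[0], colnames(v@gt)[-1]))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dose <- apply(gt, c(1, 2), gt_to_dosage)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  G <- t(dose)
  colnames(G) <- ids
  attr(G, "chrom") <- fix[, "CHROM"]
  attr(G, "pos") <- as.integer(fix[, "POS"])
  storage.mode(G) <- "integer"
  G
}

gt_to_dosage <- function(x) {
  if (is.na(x)) return(NA_integer_)
  g <- strsplit(x, ":", fixed = TRUE)[[1]][1]
  if (g %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == "1")
}

read_genotypes_tsv <- function(path) {
  M <- read_matrix(path)
  storage.mode(M) <- "integer"
  M
}

#' Write a cohort's genotypes as a minimal VCF
#'
#' One contig, unphased GT fields, positions 1-based in file order.
#'
#' @param G subjects x SNPs dosage matrix (rownames = subject ids).
#' @param path output path.
#' @export
write_genotypes_vcf <- function(G, path) {
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(G)))
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (s in seq_len(ncol(G))) {
    calls <- ifelse(is.na(G[, s]), "./.", gt_str[as.character(G[, s])])
    writeLines(paste(c("1", s, snps[s], "A", "G", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read a subject-aligned numeric matrix as delimited text
#'
#' Tab-separated, header row, first column `subject_id`; numeric values at
#' 17 significant digits so a write-read round trip is exact for doubles.
#' An optional `#`-prefixed provenance comment (producing stage and seed)
#' is written above the header and skipped on read.
#'
#' @param M numeric matrix with rownames.
#' @param path file path.
#' @param comment optional provenance string.
#' @return `read_matrix` returns the matrix with subject ids as rownames.
#' @export
write_matrix <- function(M, path, comment = NULL) {
  ids <- rownames(M)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(M)))
  cn <- colnames(M)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(M)))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("subject_id", cn), collapse = "\t"), con)
  body <- apply(M, 1, function(r) paste(format(r, digits = 17, scientific = TRUE,
                                               trim = TRUE), collapse = "\t"))
  writeLines(paste(ids, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "subject_id") stop("missing 'subject_id' header in ", path)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(cells, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate subject ids in ", path)
  M <- do.call(rbind, lapply(cells, function(x) as.numeric(x[-1])))
  rownames(M) <- ids
  colnames(M) <- header[-1]
  M
}

#' Write the text artifacts of a synthetic cohort
#'
#' Phenotypes, encoded confounders and true latent states as delimited
#' matrices, genotypes as a minimal VCF, waveforms/images as flattened
#' delimited matrices plus a JSON manifest with array shapes, splits and
#' the config seed.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$config$seed
  tag <- function(stage) sprintf("stage=%s seed=%d", stage, seed)
  P <- as.matrix(cohort$phenotypes)
  rownames(P) <- cohort$subject_ids
  write_matrix(P, file.path(dir, "phenotypes.tsv"), tag("simulate:phenotypes"))
  write_matrix(cohort$confounders, file.path(dir, "confounders.tsv"),
               tag("simulate:confounders"))
  write_matrix(cohort$z_true, file.path(dir, "z_true.tsv"), tag("simulate:latent"))
  if (!is.null(cohort$genotypes)) {
    write_genotypes_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  }
  write_matrix(modality_matrix(cohort, "waveform"),
               file.path(dir, "waveforms.tsv"), tag("simulate:waveforms"))
  write_matrix(modality_matrix(cohort, "image"),
               file.path(dir, "images.tsv"), tag("simulate:images"))
  manifest <- list(
    seed = seed, n_subjects = cohort$config$n_subjects,
    waveform_spec = cohort$config$waveform_spec,
    image_spec = cohort$config$image_spec,
    split = as.character(cohort$split), subject_ids = cohort$subject_ids
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> train -> embed -> inlp -> gwas -> signatures, writing each
#' stage's artifacts plus a manifest (seeds, per-stage wall time) under
#' `out_dir`. A stage failure stops with the stage name in the error.
#'
#' @param config list with elements `cohort` (a [cohort_config()]),
#'   `specs` (list of two [modality_spec()]), `training` (a
#'   [training_config()]), and optional `inlp_threshold`, `gwas_modality`,
#'   `n_clusters`.
#' @param out_dir output directory.
#' @return list with the manifest and the in-memory stage results,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$cohort$seed, stages = list())
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  results$cohort <- stage("simulate", function() {
    ch <- generate_cohort(config$cohort)
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })
  results$model <- stage("train", function() {
    m <- train_crossmodal(results$cohort, config$specs, config$training)
    save_model(m, file.path(out_dir, "model.json"))
    m
  })
  results$embeddings <- stage("embed", function() {
    emb <- lapply(results$model$modalities, function(nm)
      embed_modality(results$model, results$cohort, nm))
    names(emb) <- results$model$modalities
    for (nm in names(emb)) {
      write_matrix(emb[[nm]], file.path(out_dir, paste0("emb_", nm, ".tsv")),
                   sprintf("stage=embed:%s seed=%d", nm, config$cohort$seed))
    }
    emb
  })
  gw_mod <- if (is.null(config$gwas_modality)) results$model$modalities[1] else config$gwas_modality
  results$inlp <- stage("inlp", function() {
    thr <- if (is.null(config$inlp_threshold)) 0.001 else config$inlp_threshold
    out <- inlp(results$embeddings[[gw_mod]], results$cohort$confounders,
                r2_threshold = thr)
    write_matrix(out$Z_clean, file.path(out_dir, "emb_clean.tsv"),
                 sprintf("stage=inlp seed=%d", config$cohort$seed))
    write_projection_state(out$state, file.path(out_dir, "inlp_state.json"))
    out
  })
  results$gwas <- stage("gwas", function() {
    G <- tryCatch(read_genotypes(file.path(out_dir, "cohort", "genotypes.vcf")),
                  error = function(e) stop("read_genotypes: ", conditionMessage(e)))
    G <- G[results$cohort$subject_ids, , drop = FALSE]
    gs <- run_unsupervised_gwas(results$inlp$Z_clean, G, results$inlp$state)
    utils::write.table(gs$records, file.path(out_dir, "gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs
  })
  results$signatures <- stage("signatures", function() {
    G <- results$cohort$genotypes
    sm <- snp_signature_matrix(results$embeddings[[gw_mod]], G)
    write_matrix(sm$signatures, file.path(out_dir, "signatures.tsv"),
                 sprintf("stage=signatures seed=%d", config$cohort$seed))
    k <- if (is.null(config$n_clusters)) 2L else config$n_clusters
    cl <- cluster_signatures(sm, k = k)
    if (!is.null(cl$labels)) {
      utils::write.table(data.frame(snp = names(cl$labels), cluster = cl$labels),
                         file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(signatures = sm, clusters = cl)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}
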
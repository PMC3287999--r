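#' Run the screen analysis pipeline
#'
#' Sequences the full primary-screen analysis over in-memory tables:
#' fit the lipid correction factor from the calibration experiment, apply
#' the correction, normalize (per-plate NPI, screen-wide Z, Z'-factor),
#' call hits with the 2-of-3 threshold rule and attach RSA p-values.
#' Optionally validates hits against a secondary-screen deviation table and
#' classifies ICW phenotypes. Deterministic given its inputs.
#'
#' @param wells Primary-screen well table (see [load_plate_table()]).
#' @param library Library annotation table (`gene_id`, `sirna_id`).
#' @param calibration Calibration table (`dna`, `lipid`).
#' @param secondary_dev Optional secondary-screen deviation table
#'   (`gene_id`, `deviation_pct`).
#' @param icw Optional ICW record table (see [icw_normalize()]).
#' @param z_cut Z-score hit cutoff (default 1.5).
#' @param npi_dev_threshold Secondary/ICW percent threshold (default 20).
#' @return A list of class `screen_result`: `fit`, `normalized`
#'   (`normalized_screen`), `gene_calls`, `validation` (or `NULL`),
#'   `phenotypes` (or `NULL`), `qc` (per-plate stats plus screen Z' and
#'   exclusion counts).
#' @export
run_screen_pipeline <- function(wells, library, calibration,
                                secondary_dev = NULL, icw = NULL,
                                z_cut = 1.5, npi_dev_threshold = 20) {
  stopifnot(z_cut > 0, npi_dev_threshold > 0)
  lib_report <- validate_library(library)
  fit <- fit_correction_factor(calibration)
  corrected <- apply_correction(wells, fit)
  norm <- normalize_screen(corrected)

  scores <- norm$wells[, c("gene_id", "sirna_id", "z")]
  counts <- table(scores$gene_id)
  complete_genes <- names(counts)[counts == 3]
  incomplete <- setdiff(unique(library$gene_id), complete_genes)
  scores <- scores[scores$gene_id %in% complete_genes, ]
  gene_calls <- score_genes(scores, cutoff = z_cut)

  validation <- NULL
  if (!is.null(secondary_dev)) {
    validation <- validate_secondary_screen(secondary_dev, gene_calls,
                                            threshold = npi_dev_threshold)
  }
  phenotypes <- NULL
  if (!is.null(icw)) {
    phenotypes <- classify_phenotype(icw_normalize(icw),
                                     threshold = npi_dev_threshold)
  }
  qc <- list(plate_stats = norm$plate_stats, z_prime = norm$z_prime,
             n_sample_wells = nrow(norm$wells),
             excluded_plates = norm$excluded_plates,
             genes_excluded_missing_sirna = incomplete,
             library_report = lib_report)
  out <- list(fit = fit, normalized = norm, gene_calls = gene_calls,
              validation = validation, phenotypes = phenotypes, qc = qc)
  class(out) <- "screen_result"
  out
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write pipeline reports to disk
#'
#' Writes the result bundle as TSV tables with stable column order plus a
#' JSON run manifest (seed, cutoffs, package version, row counts). Files
#' are written to a temporary name and renamed, so re-runs overwrite
#' atomically.
#'
#' @param result A `screen_result` from [run_screen_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (if any was used upstream).
#' @param config Optional list echoed into the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(result, outdir, seed = NULL, config = NULL) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ",
                                        outdir)
  files <- character()
  fit_df <- data.frame(k = result$fit$k, intercept = result$fit$intercept,
                       r_squared = result$fit$r_squared,
                       n_points = result$fit$n_points)
  files <- c(files, write_tsv_atomic(fit_df,
                                     file.path(outdir, "correction_fit.tsv")))
  qc_df <- result$qc$plate_stats
  files <- c(files, write_tsv_atomic(qc_df, file.path(outdir, "qc_plates.tsv")))
  files <- c(files, write_tsv_atomic(result$gene_calls,
                                     file.path(outdir, "hits.tsv")))
  if (!is.null(result$validation)) {
    files <- c(files, write_tsv_atomic(result$validation,
                                       file.path(outdir, "validation.tsv")))
  }
  if (!is.null(result$phenotypes)) {
    files <- c(files, write_tsv_atomic(result$phenotypes,
                                       file.path(outdir, "phenotypes.tsv")))
  }
  manifest <- list(
    package = "adiposcreen",
    version = as.character(utils::packageVersion("adiposcreen")),
    seed = seed,
    config = config,
    z_prime = result$qc$z_prime,
    n_sample_wells = result$qc$n_sample_wells,
    n_genes_called = sum(result$gene_calls$is_hit),
    n_genes_excluded = length(result$qc$genes_excluded_missing_sirna),
    tables = basename(files)
  )
  mpath <- file.path(outdir, "run_manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(tmp, mpath)
  invisible(c(files, mpath))
}
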
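#' Normalized percent inhibition (NPI)
#'
#' Per-plate rescaling of a readout by that plate's control means:
#' `NPI = (mu_neg - value) / (mu_neg - mu_pos)`. The negative (scrambled
#' siRNA) control maps to 0 and the positive (PPARG siRNA) control to 1, so
#' differences in transfection efficiency between plates cancel.
#'
#' @param value Readout value(s) (AU), vectorized.
#' @param mu_neg,mu_pos Plate means of the negative / positive control.
#' @return NPI value(s), dimensionless.
#' @examples
#' npi_normalize(60, mu_neg = 100, mu_pos = 20)  # 0.5
#' @export
npi_normalize <- function(value, mu_neg, mu_pos) {
  if (any(mu_neg == mu_pos)) {
    stop("controls indistinguishable: mu_neg equals mu_pos")
  }
  (mu_neg - value) / (mu_neg - mu_pos)
}

#' Screen-wide Z-score transformation
#'
#' Standardizes values by the mean and sample standard deviation taken over
#' all sample wells of the screen (controls excluded), scoring each well
#' against the scatter of the whole screen.
#'
#' @param values Numeric vector of sample-well values.
#' @return Vector of Z-scores.
#' @export
zscore <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("Z-score requires at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("Z-score undefined: zero spread")
  (values - mean(values)) / s
}

#' Z'-factor assay quality statistic
#'
#' `Z' = 1 - 3 * (sigma_pos + sigma_neg) / |mu_pos - mu_neg|`, the standard
#' separation statistic of the two control populations. Values above ~0.4
#' indicate acceptable screening quality for a cell-based assay.
#'
#' @param mu_pos,sigma_pos Mean and SD of the positive control.
#' @param mu_neg,sigma_neg Mean and SD of the negative control.
#' @return The Z'-factor (<= 1); `-Inf` with a warning when the control
#'   means coincide.
#' @examples
#' zprime(20, 5, 100, 10)  # 0.4375
#' @export
zprime <- function(mu_pos, sigma_pos, mu_neg, sigma_neg) {
  if (mu_pos == mu_neg) {
    warning("Z' undefined: control means coincide")
    return(-Inf)
  }
  1 - 3 * (sigma_pos + sigma_neg) / abs(mu_pos - mu_neg)
}

#' Q-Q table of Z-scores against the standard normal
#'
#' Pairs the sorted Z-scores with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`. Report-only: the screen's hit tails show up as
#' departures from the diagonal.
#'
#' @param z_values Numeric vector of Z-scores (length >= 2).
#' @return Data frame with columns `theoretical` and `observed`.
#' @export
qq_points <- function(z_values) {
  z_values <- z_values[!is.na(z_values)]
  n <- length(z_values)
  if (n < 2) stop("Q-Q table requires at least 2 values")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             observed = sort(z_values))
}

#' Normalize a corrected screen and compute quality statistics
#'
#' Runs the normalization layer over a corrected well table: per plate, the
#' duplicated control wells are summarized by their arithmetic mean and every
#' sample well is NPI-normalized with that plate's control means; the
#' screen-wide Z-score transformation is then applied to the NPI values of
#' all sample wells. The Z'-factor is computed from the corrected control
#' values pooled over plates. Plates whose control means coincide or whose
#' controls are unusable are flagged and their wells excluded.
#'
#' @param wells Well table with `lipid_corrected` set (see
#'   [apply_correction()]).
#' @param compute_z Compute screen-wide Z-scores (default); disable for
#'   NPI-only use, e.g. the secondary screen or degenerate noiseless input.
#' @return A list of class `normalized_screen`: `wells` (sample wells with
#'   `npi` and `z` columns), `plate_stats` (per-plate control means/SDs),
#'   `z_prime`, `sample_mean` and `sample_sd` (of the NPI values),
#'   `excluded_plates`.
#' @export
normalize_screen <- function(wells, compute_z = TRUE) {
  stopifnot("lipid_corrected" %in% names(wells))
  usable <- wells[wells$qc_flag == "ok" & !is.na(wells$lipid_corrected), ]
  plate_ids <- unique(usable$plate_id)
  stats_list <- lapply(plate_ids, function(p) {
    pw <- usable[usable$plate_id == p, ]
    neg <- pw$lipid_corrected[pw$role == "neg_control"]
    pos <- pw$lipid_corrected[pw$role == "pos_control"]
    data.frame(plate_id = p,
               n_neg = length(neg), n_pos = length(pos),
               mu_neg = if (length(neg) > 0) mean(neg) else NA_real_,
               mu_pos = if (length(pos) > 0) mean(pos) else NA_real_,
               sd_neg = if (length(neg) > 1) stats::sd(neg) else NA_real_,
               sd_pos = if (length(pos) > 1) stats::sd(pos) else NA_real_,
               stringsAsFactors = FALSE)
  })
  plate_stats <- do.call(rbind, stats_list)
  bad <- is.na(plate_stats$mu_neg) | is.na(plate_stats$mu_pos) |
    plate_stats$mu_neg == plate_stats$mu_pos
  excluded_plates <- plate_stats$plate_id[bad]
  if (length(excluded_plates) > 0) {
    warning("excluding plate(s) with unusable controls: ",
            paste(excluded_plates, collapse = ", "))
  }
  plate_stats$excluded <- bad

  samples <- usable[usable$role == "sample" &
                    !(usable$plate_id %in% excluded_plates), ]
  idx <- match(samples$plate_id, plate_stats$plate_id)
  samples$npi <- npi_normalize(samples$lipid_corrected,
                               plate_stats$mu_neg[idx],
                               plate_stats$mu_pos[idx])
  sample_mean <- mean(samples$npi)
  sample_sd <- stats::sd(samples$npi)
  if (compute_z) {
    if (nrow(samples) < 2) stop("Z-score requires at least 2 sample wells")
    if (sample_sd == 0) stop("Z-score undefined: zero spread of NPI values")
    # NPI points from the negative towards the positive (inhibitor) control,
    # i.e. against the lipid axis; Z-scores are reported in lipid orientation
    # (positive Z = lipid accumulation, negative Z = lipid reduction), so the
    # standardized NPI is sign-flipped back onto the lipid axis.
    samples$z <- (sample_mean - samples$npi) / sample_sd
  } else {
    samples$z <- NA_real_
  }

  neg_all <- usable$lipid_corrected[usable$role == "neg_control"]
  pos_all <- usable$lipid_corrected[usable$role == "pos_control"]
  zp <- if (length(neg_all) > 1 && length(pos_all) > 1) {
    zprime(mean(pos_all), stats::sd(pos_all),
           mean(neg_all), stats::sd(neg_all))
  } else {
    NA_real_
  }

  out <- list(wells = samples, plate_stats = plate_stats, z_prime = zp,
              sample_mean = sample_mean, sample_sd = sample_sd,
              excluded_plates = excluded_plates)
  class(out) <- "normalized_screen"
  out
}

#' @export
print.normalized_screen <- function(x, ...) {
  cat(sprintf("normalized screen: %d sample wells on %d plates, Z' = %.3f\n",
              nrow(x$wells), nrow(x$plate_stats), x$z_prime))
  invisible(x)
}

#' Percent deviation of sample wells from the negative control
#'
#' Secondary-screen readout scale: percent deviation of each sample well's
#' corrected lipid value from its plate's negative-control mean. A
#' lipid-reducing phenotype gives negative deviations. No Z-transformation
#' is applied on this scale.
#'
#' @param norm A `normalized_screen` from [normalize_screen()].
#' @return The sample well table with a `deviation_pct` column.
#' @export
secondary_deviations <- function(norm) {
  stopifnot(inherits(norm, "normalized_screen"))
  wells <- norm$wells
  idx <- match(wells$plate_id, norm$plate_stats$plate_id)
  mu_neg <- norm$plate_stats$mu_neg[idx]
  wells$deviation_pct <- 100 * (wells$lipid_corrected - mu_neg) / mu_neg
  wells
}
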
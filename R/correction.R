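#' Fit the lipid data correction factor
#'
#' Ordinary least-squares fit of lipid signal on DNA signal,
#' `L = k * D + b`. The slope `k` is the lipid data correction factor used
#' to remove cell-number dependence from the lipid readout; one factor is
#' fitted per donor / screen phase from its calibration experiment.
#'
#' @param points Data frame with numeric columns `dna` and `lipid`.
#' @return A list of class `calibration_fit` with elements `k`, `intercept`,
#'   `r_squared` and `n_points`.
#' @examples
#' fit <- fit_correction_factor(data.frame(dna = 1:3, lipid = c(1, 3, 5)))
#' fit$k  # 2
#' @export
fit_correction_factor <- function(points) {
  stopifnot(all(c("dna", "lipid") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("dna", "lipid")]), ]
  if (nrow(points) < 3) {
    stop("calibration requires at least 3 points")
  }
  if (stats::var(points$dna) == 0) {
    stop("degenerate regressor: all DNA values identical")
  }
  fit <- stats::lm(lipid ~ dna, data = points)
  # suppressWarnings: noiseless calibration data triggers the benign
  # "essentially perfect fit" note from summary.lm
  out <- list(k = unname(stats::coef(fit)["dna"]),
              intercept = unname(stats::coef(fit)["(Intercept)"]),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              n_points = nrow(points))
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration fit: k = %.4f, intercept = %.3f, R^2 = %.4f (n = %d)\n",
              x$k, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Certify the DNA signal as a cell-number proxy
#'
#' Same least-squares machinery as [fit_correction_factor()], applied to
#' paired (cell count, DNA signal) measurements. Used in QC reports: a high
#' R-squared certifies the Hoechst DNA signal as a linear cell-count proxy,
#' the premise of the lipid correction.
#'
#' @param points Data frame with numeric columns `cells` and `dna`.
#' @return A `calibration_fit` (slope in AU DNA per cell).
#' @export
check_dna_proxy <- function(points) {
  stopifnot(all(c("cells", "dna") %in% names(points)))
  fit <- fit_correction_factor(data.frame(dna = points$cells,
                                          lipid = points$dna))
  fit
}

#' Apply the lipid correction to screen wells
#'
#' Residual-style correction centred on the negative-control DNA level:
#' `L_corr = L - k * (D - D_ref)`. This removes exactly the fitted linear
#' cell-number dependence while preserving the lipid scale, so corrected
#' controls stay comparable across plates. Wells whose QC flag is not `ok`
#' are left unset.
#'
#' @param wells Well table (see [load_plate_table()]).
#' @param fit A `calibration_fit` from [fit_correction_factor()].
#' @param reference_dna Reference DNA level `D_ref` (AU). Defaults to the
#'   screen-wide mean DNA signal of usable negative-control wells.
#' @return `wells` with `lipid_corrected` filled in for usable wells.
#' @export
apply_correction <- function(wells, fit, reference_dna = NULL) {
  stopifnot(inherits(fit, "calibration_fit"), is.finite(fit$k))
  if (is.null(reference_dna)) {
    neg <- wells$role == "neg_control" & wells$qc_flag == "ok"
    if (!any(neg)) {
      stop("no usable negative-control wells to define the reference DNA; ",
           "pass reference_dna explicitly")
    }
    reference_dna <- mean(wells$dna_raw[neg])
  }
  stopifnot(reference_dna > 0)
  ok <- wells$qc_flag == "ok"
  wells$lipid_corrected <- NA_real_
  wells$lipid_corrected[ok] <- wells$lipid_raw[ok] -
    fit$k * (wells$dna_raw[ok] - reference_dna)
  wells
}
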
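#' Normalize In-Cell Western marker signals
#'
#' Marker signals are first normalized to the endogenous reference
#' (`normalized = marker_signal / gapdh_signal`), then expressed as the
#' percent deviation of the normalized signal from the scrambled-siRNA
#' (non-targeting) control mean of the same marker. Records with a
#' non-positive GAPDH signal are flagged and excluded.
#'
#' @param records ICW data frame with columns `gene_id`, `sirna_id`,
#'   `marker`, `marker_signal`, `gapdh_signal` (see [simulate_icw()]).
#' @param control_gene Gene id of the scrambled control records.
#' @return The usable records with `normalized` and `npi_deviation`
#'   (percent) columns; excluded records are dropped with a warning.
#' @export
icw_normalize <- function(records, control_gene = "scrambled") {
  needed <- c("gene_id", "sirna_id", "marker", "marker_signal",
              "gapdh_signal")
  stopifnot(all(needed %in% names(records)))
  bad <- !is.finite(records$gapdh_signal) | records$gapdh_signal <= 0
  if (any(bad)) {
    warning(sum(bad), " ICW record(s) with unusable GAPDH signal excluded")
    records <- records[!bad, ]
  }
  if (!any(records$gene_id == control_gene)) {
    stop("no control records for gene id '", control_gene, "'")
  }
  records$normalized <- records$marker_signal / records$gapdh_signal
  ctrl <- records[records$gene_id == control_gene, ]
  ctrl_mean <- tapply(ctrl$normalized, ctrl$marker, mean)
  missing_m <- setdiff(unique(records$marker), names(ctrl_mean))
  if (length(missing_m) > 0) {
    stop("no control records for marker(s): ",
         paste(missing_m, collapse = ", "))
  }
  records$npi_deviation <- as.numeric(100 *
    (records$normalized / ctrl_mean[records$marker] - 1))
  rownames(records) <- NULL
  records
}

#' Two-marker differentiation versus lipid-turnover classification
#'
#' Per marker, the knock-down direction is `down` when at least
#' `min_sirnas` of the three siRNAs deviate by `-threshold` percent or more,
#' `up` when at least `min_sirnas` deviate by `+threshold` or more, and
#' `flat` otherwise. A gene is classified only when both markers agree:
#' both down = `reduced_differentiation`, both up =
#' `increased_differentiation`, both flat = `no_change` (a lipid-turnover
#' phenotype: lipid changes without the differentiation markers moving);
#' any other combination is `discordant` and needs follow-up.
#'
#' @param deviations Normalized ICW records with `npi_deviation` set (see
#'   [icw_normalize()]); control records are ignored.
#' @param threshold Percent threshold (default 20).
#' @param min_sirnas Minimum concordant siRNAs per marker (default 2 of 3).
#' @param control_gene Gene id of control records to drop.
#' @return Data frame with one row per gene: `gene_id`, `ap2_direction`,
#'   `plin_direction`, `category`.
#' @export
classify_phenotype <- function(deviations, threshold = 20, min_sirnas = 2,
                               control_gene = "scrambled") {
  stopifnot(all(c("gene_id", "marker", "npi_deviation") %in%
                names(deviations)))
  dev <- deviations[deviations$gene_id != control_gene, ]
  genes <- unique(dev$gene_id)
  marker_dir <- function(d) {
    if (sum(d <= -threshold) >= min_sirnas) return("down")
    if (sum(d >= threshold) >= min_sirnas) return("up")
    "flat"
  }
  res <- lapply(genes, function(g) {
    gd <- dev[dev$gene_id == g, ]
    for (m in c("aP2", "PerilipinA")) {
      if (!any(gd$marker == m)) stop("gene ", g, " missing marker ", m)
    }
    a <- marker_dir(gd$npi_deviation[gd$marker == "aP2"])
    p <- marker_dir(gd$npi_deviation[gd$marker == "PerilipinA"])
    category <- if (a == "down" && p == "down") {
      "reduced_differentiation"
    } else if (a == "up" && p == "up") {
      "increased_differentiation"
    } else if (a == "flat" && p == "flat") {
      "no_change"
    } else {
      "discordant"
    }
    data.frame(gene_id = g, ap2_direction = a, plin_direction = p,
               category = category, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Filter genes regulated during adipogenesis
#'
#' Applies the microarray regulation rule to per-probe expression records in
#' the signed-fold convention (FC > 0 up, FC < 0 down, |FC| is the
#' expression ratio; no values inside (-1, 1)): a gene is regulated when at
#' least one record passes `|FC| >= fc_cut` and `p <= p_cut` (both
#' inclusive). With `require_both = TRUE` the rule must hold in each of the
#' d0-vs-d3 and d0-vs-d7 comparisons separately. The reported direction is
#' the sign of the passing record with the largest |FC|.
#'
#' @param records Data frame with columns `gene_id`, `fold_change`,
#'   `p_value`, and (needed only for `require_both`) `comparison`.
#' @param fc_cut Fold-change cutoff (default 2).
#' @param p_cut p-value cutoff (default 0.01).
#' @param require_both Require the rule in both comparisons (default FALSE:
#'   any comparison suffices).
#' @return Data frame with one row per gene: `gene_id`, `regulated`,
#'   `direction` (`up`/`down`/`none`), `max_abs_fc`, `min_p`.
#' @export
filter_expression_regulated <- function(records, fc_cut = 2, p_cut = 0.01,
                                        require_both = FALSE) {
  stopifnot(all(c("gene_id", "fold_change", "p_value") %in% names(records)),
            fc_cut >= 1, p_cut > 0)
  fc <- records$fold_change
  if (any(abs(fc) < 1, na.rm = TRUE)) {
    stop("fold changes inside (-1, 1): expected the signed-fold convention")
  }
  if (require_both && !"comparison" %in% names(records)) {
    stop("require_both needs a 'comparison' column")
  }
  records$pass <- abs(fc) >= fc_cut & records$p_value <= p_cut
  res <- lapply(split(records, records$gene_id), function(gr) {
    passing <- gr[gr$pass, ]
    regulated <- if (require_both) {
      all(c("d0_vs_d3", "d0_vs_d7") %in% passing$comparison)
    } else {
      nrow(passing) > 0
    }
    direction <- "none"
    if (regulated) {
      best <- passing[which.max(abs(passing$fold_change)), ]
      direction <- if (best$fold_change > 0) "up" else "down"
    }
    data.frame(gene_id = gr$gene_id[1], regulated = regulated,
               direction = direction,
               max_abs_fc = max(abs(gr$fold_change)),
               min_p = min(gr$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read an expression table with censored printed values
#'
#' Reads a per-probe expression CSV whose `fold_change` and `p_value`
#' columns may contain censored printed entries such as `">100"` or
#' `"<1E-45"`; these are encoded at their bounds (100, 1e-45), which is
#' conservative for any threshold rule between the bound and infinity.
#'
#' @param path CSV path with at least columns `gene_id` (or `gene_symbol`),
#'   `fold_change`, `p_value`.
#' @return Data frame with numeric `fold_change` and `p_value`.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(raw) && "gene_symbol" %in% names(raw)) {
    raw$gene_id <- raw$gene_symbol
  }
  stopifnot(all(c("gene_id", "fold_change", "p_value") %in% names(raw)))
  parse_censored <- function(x) {
    x <- trimws(x)
    x <- sub("^[<>]", "", x)
    as.numeric(x)
  }
  raw$fold_change <- parse_censored(raw$fold_change)
  raw$p_value <- parse_censored(raw$p_value)
  raw
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,control -
#' Ct_ref,control)`; the relative quantity is `2^-ddCt` (1 when nothing
#' changed), optionally read as percent of control.
#'
#' @param ct_target_sample,ct_ref_sample Target / reference-gene Ct in the
#'   sample condition.
#' @param ct_target_control,ct_ref_control Target / reference-gene Ct in
#'   the control condition.
#' @return List with `ddct`, `rq` (relative quantity) and `percent_control`.
#' @examples
#' ddct_quantify(30, 20, 28, 20)$rq  # 0.25
#' @export
ddct_quantify <- function(ct_target_sample, ct_ref_sample,
                          ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (length(cts) != 4 || anyNA(cts) || any(!is.finite(cts))) {
    stop("all four Ct values must be finite")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  rq <- 2^(-ddct)
  list(ddct = ddct, rq = rq, percent_control = 100 * rq)
}
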
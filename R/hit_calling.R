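#' Primary-screen hit calling by the 2-of-3 threshold rule
#'
#' A gene is a hit when at least two of its three siRNAs show the same
#' phenotype beyond the Z-score cutoff: direction `up` (lipid accumulation)
#' when >= 2 siRNAs have `Z >= cutoff`, `down` (lipid reduction) when >= 2
#' have `Z <= -cutoff`; both thresholds inclusive. Two-of-three in both
#' directions simultaneously is impossible, so every gene gets one call.
#'
#' @param scores Data frame with columns `gene_id`, `sirna_id`, `z`; every
#'   gene must carry exactly three scored siRNAs.
#' @param cutoff Z-score cutoff (default 1.5).
#' @return Data frame with one row per gene: `gene_id`, `direction`
#'   (`up`/`down`/`none`), `n_qualifying`, `is_hit`.
#' @export
call_primary_hits <- function(scores, cutoff = 1.5) {
  stopifnot(all(c("gene_id", "z") %in% names(scores)),
            cutoff > 0)
  counts <- table(scores$gene_id)
  bad <- names(counts)[counts != 3]
  if (length(bad) > 0) {
    stop("gene(s) without exactly 3 scored siRNAs: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(scores$z)) stop("missing Z-scores in input")
  split_z <- split(scores$z, scores$gene_id)
  gene_id <- names(split_z)
  n_up <- vapply(split_z, function(z) sum(z >= cutoff), integer(1))
  n_down <- vapply(split_z, function(z) sum(z <= -cutoff), integer(1))
  direction <- ifelse(n_up >= 2, "up", ifelse(n_down >= 2, "down", "none"))
  n_qual <- ifelse(direction == "up", n_up,
            ifelse(direction == "down", n_down, pmax(n_up, n_down)))
  data.frame(gene_id = gene_id, direction = direction,
             n_qualifying = as.integer(n_qual),
             is_hit = direction != "none",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' RSA gene-level p-value from siRNA ranks
#'
#' The redundant siRNA activity (RSA) statistic: given the ascending ranks
#' `r_1 < ... < r_n` of a gene's siRNAs among all `n_total` ranked siRNAs,
#' compute for each `j` the hypergeometric upper tail
#' `P(X >= j)` with `X ~ Hypergeometric(n_total, n, r_j)` — the probability
#' that a random placement of the gene's `n` siRNAs puts at least `j` of
#' them within the top `r_j` ranks — and return the minimum over `j`. Small
#' values mean the gene's reagents cluster towards the top of the ranking
#' more than chance allows, which is robust to a single off-target reagent.
#'
#' @param ranks Distinct integer ranks in `1..n_total`.
#' @param n_total Total number of ranked siRNAs in the screen.
#' @return The RSA p-value in (0, 1].
#' @examples
#' rsa_gene_pvalue(c(1, 2), 10)  # 1/45
#' @export
rsa_gene_pvalue <- function(ranks, n_total) {
  if (length(ranks) < 1) stop("gene needs at least one ranked siRNA")
  if (anyDuplicated(ranks)) stop("duplicate ranks")
  if (any(ranks < 1 | ranks > n_total)) stop("ranks out of range 1..n_total")
  rsa_pvalue_impl(ranks, n_total)
}

# Tail minimization without the distinctness check: worst-rank tie handling
# in rsa_screen can legitimately hand several siRNAs the same (shared worst)
# rank, for which the tail probabilities remain well defined.
rsa_pvalue_impl <- function(ranks, n_total) {
  n <- length(ranks)
  r <- sort(ranks)
  j <- seq_len(n)
  tails <- stats::phyper(j - 1, m = n, n = n_total - n, k = r,
                         lower.tail = FALSE)
  min(tails)
}

#' RSA over a scored screen, one direction at a time
#'
#' Ranks all siRNAs by Z-score — ascending for `direction = "down"` (most
#' negative, i.e. strongest lipid reduction, first) and descending for
#' `direction = "up"` — and applies [rsa_gene_pvalue()] per gene. Tied
#' scores receive the worst (largest) rank, which is conservative.
#'
#' @param scores Data frame with columns `gene_id`, `sirna_id`, `z`.
#' @param direction `"down"` or `"up"`.
#' @return Data frame with columns `gene_id` and `rsa_p`.
#' @export
rsa_screen <- function(scores, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "z") %in% names(scores)))
  if (anyNA(scores$z)) stop("missing Z-scores in input")
  key <- if (direction == "down") scores$z else -scores$z
  rk <- rank(key, ties.method = "max")
  n_total <- length(rk)
  split_r <- split(rk, scores$gene_id)
  data.frame(gene_id = names(split_r),
             rsa_p = vapply(split_r, rsa_pvalue_impl, numeric(1),
                            n_total = n_total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine threshold calls with RSA p-values
#'
#' The hit flag follows the 2-of-3 threshold rule (the screen's hit
#' definition); RSA p-values are reported alongside for ranking. For a
#' called gene `rsa_p` is the p-value in the called direction; for an
#' uncalled gene it is the smaller of the two directions (best evidence
#' either way).
#'
#' @param scores Data frame with columns `gene_id`, `sirna_id`, `z`.
#' @param cutoff Z-score cutoff for the threshold rule.
#' @return [call_primary_hits()] output plus `rsa_p_down`, `rsa_p_up`,
#'   `rsa_p` and `rsa_logp` (`-log10 rsa_p`) columns.
#' @export
score_genes <- function(scores, cutoff = 1.5) {
  calls <- call_primary_hits(scores, cutoff = cutoff)
  down <- rsa_screen(scores, "down")
  up <- rsa_screen(scores, "up")
  calls$rsa_p_down <- down$rsa_p[match(calls$gene_id, down$gene_id)]
  calls$rsa_p_up <- up$rsa_p[match(calls$gene_id, up$gene_id)]
  calls$rsa_p <- ifelse(calls$direction == "down", calls$rsa_p_down,
                 ifelse(calls$direction == "up", calls$rsa_p_up,
                        pmin(calls$rsa_p_down, calls$rsa_p_up)))
  calls$rsa_logp <- -log10(calls$rsa_p)
  calls
}

#' Secondary-screen validation of a primary hit
#'
#' A primary hit is validated when at least one of the three new-sequence
#' siRNAs deviates beyond the threshold from the non-targeting control in
#' the same direction as the primary phenotype. Deviations are percent
#' changes of the corrected lipid value relative to the scrambled-siRNA
#' control (see [secondary_deviations()]); no Z-transformation is applied in
#' the secondary screen.
#'
#' @param deviations Numeric vector of the gene's three percent deviations.
#' @param primary_direction `"down"` or `"up"`.
#' @param threshold Percent threshold (default 20).
#' @return List with `n_confirming` and `validated`.
#' @export
validate_secondary <- function(deviations, primary_direction,
                               threshold = 20) {
  if (!primary_direction %in% c("down", "up")) {
    stop("unknown primary direction: ", primary_direction)
  }
  stopifnot(threshold > 0)
  deviations <- deviations[!is.na(deviations)]
  n <- if (primary_direction == "down") {
    sum(deviations <= -threshold)
  } else {
    sum(deviations >= threshold)
  }
  list(n_confirming = as.integer(n), validated = n >= 1)
}

#' Validate all primary hits against a secondary screen
#'
#' @param dev_table Data frame with columns `gene_id` and `deviation_pct`
#'   (three new-sequence siRNAs per gene; see [secondary_deviations()]).
#' @param primary_calls Primary [call_primary_hits()] output (only rows with
#'   `is_hit` are validated).
#' @param threshold Percent threshold (default 20).
#' @return Data frame with `gene_id`, `primary_direction`, `n_confirming`,
#'   `validated`.
#' @export
validate_secondary_screen <- function(dev_table, primary_calls,
                                      threshold = 20) {
  hits <- primary_calls[primary_calls$is_hit, ]
  res <- lapply(seq_len(nrow(hits)), function(i) {
    g <- hits$gene_id[i]
    dev <- dev_table$deviation_pct[dev_table$gene_id == g]
    v <- validate_secondary(dev, hits$direction[i], threshold)
    data.frame(gene_id = g, primary_direction = hits$direction[i],
               n_confirming = v$n_confirming, validated = v$validated,
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0) {
    return(data.frame(gene_id = character(), primary_direction = character(),
                      n_confirming = integer(), validated = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Closed-form null probability of the 2-of-3 threshold rule
#'
#' Under the null (no effect, independent standard-normal per-siRNA
#' Z-scores) the one-sided tail probability is `p = P(Z >= cutoff)`, and the
#' probability that a gene with three independent siRNAs is called in a
#' given direction is `3 p^2 (1 - p) + p^3`; summing the two directions
#' gives the per-gene null call probability. Used to calibrate the empirical
#' false-call rate of the composite rule.
#'
#' @param cutoff Z-score cutoff.
#' @return Per-gene null call probability.
#' @export
null_call_probability <- function(cutoff = 1.5) {
  p <- stats::pnorm(-cutoff)
  2 * (3 * p^2 * (1 - p) + p^3)
}
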
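# Independent oracles and small fixture builders used across the suite.

# Exhaustive-enumeration oracle for the RSA tail statistic: over all
# C(n_total, n) equally likely placements of a gene's n siRNA ranks, the
# probability that at least j of them fall within the top r_j ranks,
# minimized over j. Deliberately brute force and independent of phyper.
rsa_oracle <- function(ranks, n_total) {
  n <- length(ranks)
  r <- sort(ranks)
  placements <- utils::combn(n_total, n)
  total <- ncol(placements)
  tails <- vapply(seq_len(n), function(j) {
    hits <- vapply(seq_len(total), function(i) {
      sum(placements[, i] <= r[j]) >= j
    }, logical(1))
    sum(hits) / total
  }, numeric(1))
  min(tails)
}

# Minimal well table: one plate, two duplicated controls of each type and a
# few sample wells, measurements supplied by the caller.
make_mini_plate <- function(plate_id = "P1",
                            neg = c(100, 100), pos = c(20, 20),
                            samples = c(60, 80, 100),
                            dna = 100) {
  n_s <- length(samples)
  data.frame(
    plate_id = plate_id,
    row = c("B", "B", "C", "C", rep("E", n_s)),
    col = c(2, 3, 2, 3, seq(2, 1 + n_s)),
    role = c("neg_control", "neg_control", "pos_control", "pos_control",
             rep("sample", n_s)),
    sirna_id = c(rep(NA_character_, 4), paste0("G1_s", seq_len(n_s))),
    gene_id = c(rep(NA_character_, 4), rep("G1", n_s)),
    lipid_raw = c(neg, pos, samples),
    dna_raw = dna,
    lipid_corrected = NA_real_,
    qc_flag = "ok",
    stringsAsFactors = FALSE
  )
}

# Identity correction (slope 0): corrected value equals the raw value.
identity_fit <- function() {
  structure(list(k = 0, intercept = 0, r_squared = 1, n_points = 3),
            class = "calibration_fit")
}

# Scores table for hit-calling tests: one row per siRNA.
make_scores <- function(z_by_gene) {
  do.call(rbind, lapply(names(z_by_gene), function(g) {
    z <- z_by_gene[[g]]
    data.frame(gene_id = g, sirna_id = paste0(g, "_s", seq_along(z)),
               z = z, stringsAsFactors = FALSE)
  }))
}

# ICW records whose control-normalized percent deviations are exactly the
# requested values (controls sit at the marker base level with no noise).
make_icw_records <- function(dev_by_gene_marker, gapdh = 50) {
  base <- c(aP2 = 1.0, PerilipinA = 1.0)
  rows <- lapply(names(dev_by_gene_marker), function(g) {
    per_marker <- dev_by_gene_marker[[g]]
    do.call(rbind, lapply(names(per_marker), function(m) {
      dev <- per_marker[[m]]
      data.frame(gene_id = g, sirna_id = paste0(g, "_k", seq_along(dev)),
                 marker = m,
                 marker_signal = gapdh * base[[m]] * (1 + dev / 100),
                 gapdh_signal = gapdh, stringsAsFactors = FALSE)
    }))
  })
  ctrl <- expand.grid(sirna = 1:2, marker = c("aP2", "PerilipinA"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrl_df <- data.frame(gene_id = "scrambled",
                        sirna_id = paste0("scr_", ctrl$sirna),
                        marker = ctrl$marker,
                        marker_signal = gapdh * base[ctrl$marker],
                        gapdh_signal = gapdh, stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), ctrl_df)
}
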
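#!/usr/bin/env Rscript
# Secondary screen: re-test the called hits with a validation library of
# new siRNA sequences on cells from a second donor (correction factor
# 1.522). NPI-scale percent deviations from the scrambled control are used
# directly (no Z-transformation); a hit validates when at least one new
# siRNA reproduces the primary phenotype beyond +/-20%.

suppressPackageStartupMessages(library(adiposcreen))

seed <- 2026L
calls <- utils::read.delim("results/hits.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv")
hit_genes <- calls$gene_id[calls$is_hit]

cfg <- sim_config(seed = seed + 10L, n_genes = length(hit_genes),
                  k_true = 1.522)
sim <- simulate_screen(cfg, gene_classes = truth[
  match(hit_genes, truth$gene_id), c("gene_id", "class")],
  phase = "validation")

cal2 <- utils::read.csv("results/data/calibration_donor2.csv")
corrected <- apply_correction(sim$wells, fit_correction_factor(cal2))
norm <- normalize_screen(corrected, compute_z = FALSE)
dev <- secondary_deviations(norm)

val <- validate_secondary_screen(dev[, c("gene_id", "deviation_pct")], calls)
utils::write.table(val, "results/validation.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("retested %d hit genes with new siRNA sequences\n", nrow(val)))
cat(sprintf("validated %d (%.1f%%) with >= 1 confirming siRNA beyond +/-20%%\n",
            sum(val$validated), 100 * mean(val$validated)))
tcls <- truth$class[match(val$gene_id, truth$gene_id)]
cat(sprintf("validation rate among truly planted hits: %.3f; among false calls: %.3f\n",
            mean(val$validated[tcls != "null"]),
            if (any(tcls == "null")) mean(val$validated[tcls == "null"])
            else NA))
cat("wrote results/validation.tsv\n")
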
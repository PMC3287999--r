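#!/usr/bin/env Rscript
# Primary hit calling: corrected screen -> per-plate NPI -> screen-wide
# Z-scores -> 2-of-3 |Z| >= 1.5 threshold rule with RSA p-values alongside.
# Compares the calls with the planted ground truth.

suppressPackageStartupMessages(library(adiposcreen))

wells <- load_plate_table("results/data/primary_plates.csv")
library_tab <- utils::read.csv("results/data/primary_library.csv")
cal <- utils::read.csv("results/data/calibration_donor1.csv")
truth <- utils::read.delim("results/data/ground_truth.tsv")

res <- run_screen_pipeline(wells, library_tab, cal)
calls <- res$gene_calls
utils::write.table(calls, "results/hits.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cls <- truth$class[match(calls$gene_id, truth$gene_id)]
n_hits <- sum(calls$is_hit)
n_down <- sum(calls$direction == "down")
n_up <- sum(calls$direction == "up")
tp <- sum((cls == "hit_down" & calls$direction == "down") |
          (cls == "hit_up" & calls$direction == "up"))
cat(sprintf("called %d hit genes (%d lipid-reduced, %d lipid-increased)\n",
            n_hits, n_down, n_up))
cat(sprintf("vs planted truth: sensitivity %.3f, FDR %.3f\n",
            tp / sum(truth$class != "null"), 1 - tp / n_hits))
cat(sprintf("median RSA -log10 p: planted hits %.2f, nulls %.2f\n",
            median(calls$rsa_logp[cls != "null"]),
            median(calls$rsa_logp[cls == "null"])))
cat("wrote results/hits.tsv\n")
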
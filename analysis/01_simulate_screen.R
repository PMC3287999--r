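#!/usr/bin/env Rscript
# Generate the synthetic study data: a 500-gene primary screen with 10%
# planted hits (both signs), the two donor calibration experiments, and the
# cell-count proxy check. Writes the plate table, library and ground truth
# under results/data/ for the downstream steps.

suppressPackageStartupMessages(library(adiposcreen))

seed <- 2026L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed, n_genes = 500,
                  frac_hits_down = 0.05, frac_hits_up = 0.05)
sim <- simulate_screen(cfg)

write_plate_table(sim$wells, "results/data/primary_plates.csv")
utils::write.csv(sim$library, "results/data/primary_library.csv",
                 row.names = FALSE)
utils::write.table(sim$truth$genes, "results/data/ground_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cal1 <- simulate_calibration(1.7181, n_points = 48, noise_cv = 0.03,
                             seed = seed + 1L)
cal2 <- simulate_calibration(1.522, n_points = 48, noise_cv = 0.03,
                             seed = seed + 2L)
utils::write.csv(cal1, "results/data/calibration_donor1.csv",
                 row.names = FALSE)
utils::write.csv(cal2, "results/data/calibration_donor2.csv",
                 row.names = FALSE)
prox <- simulate_cell_proxy(noise_cv = 0.05, seed = seed + 3L)
utils::write.csv(prox, "results/data/cell_proxy.csv", row.names = FALSE)

n_plates <- length(unique(sim$wells$plate_id))
cat(sprintf("simulated %d genes (%d planted hits) on %d plates; %d wells\n",
            cfg$n_genes, sum(sim$truth$genes$class != "null"), n_plates,
            nrow(sim$wells)))
cat("wrote plate table, library, truth and calibration sets to results/data/\n")
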
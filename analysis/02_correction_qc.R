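#!/usr/bin/env Rscript
# Data correction and screen quality control: fit the lipid correction
# factor for each donor, certify the DNA signal as a cell-count proxy,
# apply the correction to the primary screen and report Z', per-plate
# control statistics and the Q-Q table of Z-scores.

suppressPackageStartupMessages(library(adiposcreen))

dir.create("results", showWarnings = FALSE)

cal1 <- utils::read.csv("results/data/calibration_donor1.csv")
cal2 <- utils::read.csv("results/data/calibration_donor2.csv")
fit1 <- fit_correction_factor(cal1)
fit2 <- fit_correction_factor(cal2)
prox <- check_dna_proxy(utils::read.csv("results/data/cell_proxy.csv"))

cat(sprintf("donor 1 correction factor: %.4f (R^2 = %.4f)\n",
            fit1$k, fit1$r_squared))
cat(sprintf("donor 2 correction factor: %.4f (R^2 = %.4f)\n",
            fit2$k, fit2$r_squared))
cat(sprintf("DNA ~ cell count proxy:    slope %.5f (R^2 = %.4f)\n",
            prox$k, prox$r_squared))

fits <- data.frame(
  set = c("donor1_primary", "donor2_validation", "dna_cell_proxy"),
  k = c(fit1$k, fit2$k, prox$k),
  intercept = c(fit1$intercept, fit2$intercept, prox$intercept),
  r_squared = c(fit1$r_squared, fit2$r_squared, prox$r_squared),
  n_points = c(fit1$n_points, fit2$n_points, prox$n_points))
utils::write.table(fits, "results/correction_fits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

wells <- load_plate_table("results/data/primary_plates.csv")
corrected <- apply_correction(wells, fit1)
ok <- corrected$qc_flag == "ok" & corrected$role == "sample"
cat(sprintf("post-correction |cor(L_corr, D)| over sample wells: %.4f\n",
            abs(stats::cor(corrected$lipid_corrected[ok],
                           corrected$dna_raw[ok]))))

norm <- normalize_screen(corrected)
cat(sprintf("screen Z' = %.3f over %d plates (%d sample wells)\n",
            norm$z_prime, nrow(norm$plate_stats), nrow(norm$wells)))
utils::write.table(norm$plate_stats, "results/qc_plate_controls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.csv(qq_points(norm$wells$z), "results/qq_zscores.csv",
                 row.names = FALSE)
cat("wrote correction_fits.tsv, qc_plate_controls.tsv, qq_zscores.csv\n")
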
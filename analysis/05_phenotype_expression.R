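#!/usr/bin/env Rscript
# Hit characterization: (1) two-marker In-Cell Western classification of
# validated hits into differentiation vs lipid-turnover phenotypes;
# (2) expression-regulation filter (|FC| >= 2, p <= 0.01) on the validated
# genes and on the bundled strong-regulation table; (3) a 2^-ddCt example.

suppressPackageStartupMessages(library(adiposcreen))

seed <- 2026L
val <- utils::read.delim("results/validation.tsv")
validated <- val$gene_id[val$validated]

## ICW classification over the validated hits: plant a phenotype mix the
## classifier must recover (1/3 reduced, 1/3 increased, 1/3 turnover).
icw_classes <- data.frame(
  gene_id = validated,
  class = rep(c("reduced_differentiation", "increased_differentiation",
                "no_change"), length.out = length(validated)))
records <- simulate_icw(icw_classes, seed = seed + 20L)
phen <- classify_phenotype(icw_normalize(records))
utils::write.table(phen, "results/phenotypes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
agree <- mean(phen$category[match(icw_classes$gene_id, phen$gene_id)] ==
              icw_classes$class)
cat(sprintf("ICW classification of %d validated hits: %s\n",
            nrow(phen), paste(names(table(phen$category)),
                              table(phen$category), collapse = ", ")))
cat(sprintf("agreement with planted ICW classes: %.3f\n", agree))

## Expression filter on simulated per-probe records for the validated hits
## (one third planted regulated) and on the bundled printed table.
reg_truth <- data.frame(
  gene_id = validated,
  regulation = rep(c("up", "down", "none"), length.out = length(validated)))
expr <- simulate_expression(reg_truth, seed = seed + 21L)
reg <- filter_expression_regulated(expr)
utils::write.table(reg, "results/expression_regulated.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("expression filter: %d of %d validated hits regulated during adipogenesis\n",
            sum(reg$regulated), nrow(reg)))

tab <- read_expression_table(system.file("extdata", "table1_phenotypeA.csv",
                                         package = "adiposcreen"))
printed <- filter_expression_regulated(tab)
cat(sprintf("printed strong-regulation table: %d/16 pass (%d up, %d down)\n",
            sum(printed$regulated), sum(printed$direction == "up"),
            sum(printed$direction == "down")))

## Relative quantification example: a knock-down leaving the target at a
## quarter of the control level (ddCt = 2).
q <- ddct_quantify(30, 20, 28, 20)
cat(sprintf("2^-ddCt example: ddCt = %g -> %.0f%% of control\n",
            q$ddct, q$percent_control))
cat("wrote results/phenotypes.tsv, results/expression_regulated.tsv\n")
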
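test_that("ICW normalization is GAPDH-ratio based and reported versus the scrambled control", {
  records <- make_icw_records(list(gX = list(aP2 = c(0, -20, 10),
                                             PerilipinA = c(0, 0, 0))))
  norm <- icw_normalize(records)
  gx <- norm[norm$gene_id == "gX" & norm$marker == "aP2", ]
  expect_equal(gx$npi_deviation, c(0, -20, 10), tolerance = 1e-12)
  # marker 40 over gapdh 50 against a control ratio of 1.0 is -20%
  expect_equal(norm$normalized[norm$marker_signal == 40][1], 0.8)

  # common rescaling of marker and reference cancels
  scaled <- records
  scaled$marker_signal <- scaled$marker_signal * 2
  scaled$gapdh_signal <- scaled$gapdh_signal * 2
  expect_equal(icw_normalize(scaled)$npi_deviation, norm$npi_deviation,
               tolerance = 1e-12)

  bad <- records
  bad$gapdh_signal[1] <- 0
  expect_warning(icw_normalize(bad), "GAPDH")
})

test_that("two-marker classification follows the 2-of-3, both-marker rule", {
  devs <- icw_normalize(make_icw_records(list(
    ppar_like = list(aP2 = c(-80, -75, -60), PerilipinA = c(-85, -70, -10)),
    stimulated = list(aP2 = c(25, 30, 40), PerilipinA = c(22, 35, 5)),
    turnover = list(aP2 = c(5, -10, 3), PerilipinA = c(-15, 8, 0)),
    ppapdc1a_like = list(aP2 = c(25, 30, 5), PerilipinA = c(-25, -30, 0)),
    one_marker = list(aP2 = c(-40, -35, -30), PerilipinA = c(-5, 4, -10)))))
  cls <- classify_phenotype(devs)
  got <- cls$category[match(c("ppar_like", "stimulated", "turnover",
                              "ppapdc1a_like", "one_marker"), cls$gene_id)]
  expect_equal(got, c("reduced_differentiation", "increased_differentiation",
                      "no_change", "discordant", "discordant"))
  # classification ignores siRNA ordering
  shuffled <- devs[sample(nrow(devs)), ]
  cls2 <- classify_phenotype(shuffled)
  expect_equal(cls2$category[match(cls$gene_id, cls2$gene_id)], cls$category)

  missing <- devs[devs$marker == "aP2" | devs$gene_id == "scrambled", ]
  expect_error(classify_phenotype(missing), "missing marker")
})

test_that("classifier closes the loop on generator-planted classes", {
  classes <- data.frame(
    gene_id = sprintf("g%02d", 1:30),
    class = rep(c("reduced_differentiation", "increased_differentiation",
                  "no_change"), 10))
  # planted effect (40%) exceeds threshold + 3*noise SD (20 + 9)
  records <- simulate_icw(classes, seed = 5, effect_pct = 40,
                          noise_sd_pct = 3)
  cls <- classify_phenotype(icw_normalize(records))
  expect_equal(cls$category[match(classes$gene_id, cls$gene_id)],
               classes$class)
})

test_that("expression regulation filter honours inclusive cutoffs and the signed-fold convention", {
  records <- data.frame(
    gene_id = c("PPARG", "KRT79", "weak", "insig", "edge"),
    probe_id = paste0("p", 1:5),
    comparison = "d0_vs_d7",
    fold_change = c(32.36, -3.64, 1.9, 4.0, 2.0),
    p_value = c(1e-45, 5.60e-04, 0.001, 0.2, 0.01))
  res <- filter_expression_regulated(records)
  res <- res[match(records$gene_id, res$gene_id), ]
  expect_equal(res$regulated, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$direction, c("up", "down", "none", "none", "up"))

  # a ratio-convention table (values inside (-1,1)) is rejected outright
  bad <- records
  bad$fold_change[2] <- 0.27
  expect_error(filter_expression_regulated(bad), "signed-fold")

  # direction follows the largest-|FC| passing record
  multi <- data.frame(gene_id = "g", probe_id = c("a", "b"),
                      comparison = c("d0_vs_d3", "d0_vs_d7"),
                      fold_change = c(2.5, -6), p_value = c(0.001, 0.001))
  expect_equal(filter_expression_regulated(multi)$direction, "down")

  # BOTH-comparison mode needs the rule in each comparison separately
  one_side <- data.frame(gene_id = "g", probe_id = c("a", "b"),
                         comparison = c("d0_vs_d3", "d0_vs_d7"),
                         fold_change = c(2.5, -1.2), p_value = c(0.001, 0.5))
  expect_true(filter_expression_regulated(one_side)$regulated)
  expect_false(filter_expression_regulated(one_side,
                                           require_both = TRUE)$regulated)
  expect_true(filter_expression_regulated(multi,
                                          require_both = TRUE)$regulated)
})

test_that("bundled expression fixture parses censored printed values at their bounds", {
  path <- system.file("extdata", "table1_phenotypeA.csv",
                      package = "adiposcreen")
  tab <- read_expression_table(path)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$fold_change[tab$gene_id == "PLIN1"], 100)
  expect_equal(tab$p_value[tab$gene_id == "PPARG"], 1e-45)
  expect_equal(tab$fold_change[tab$gene_id == "RB1"], -2.00)
})

test_that("ddCt relative quantification obeys its identities", {
  expect_equal(ddct_quantify(25, 20, 25, 20)$rq, 1)
  q <- ddct_quantify(30, 20, 28, 20)
  expect_equal(q$ddct, 2)
  expect_equal(q$rq, 0.25)
  expect_equal(q$percent_control, 25)
  # one fewer target cycle in the sample doubles the relative quantity
  expect_equal(ddct_quantify(29, 20, 28, 20)$rq, 2 * q$rq)
  expect_error(ddct_quantify(NA, 20, 28, 20), "finite")
})
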
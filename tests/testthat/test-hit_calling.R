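test_that("2-of-3 threshold rule calls direction with inclusive cutoffs", {
  calls <- call_primary_hits(make_scores(list(
    gA = c(1.6, 1.7, -0.2),    # two up
    gB = c(1.6, -1.6, 0.1),    # split: no call
    gC = c(-1.5, -1.5, 3.0),   # inclusive boundary, two down
    gD = c(0.2, -0.3, 0.1))))  # quiet gene
  calls <- calls[match(c("gA", "gB", "gC", "gD"), calls$gene_id), ]
  expect_equal(calls$direction, c("up", "none", "down", "none"))
  expect_equal(calls$is_hit, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$n_qualifying[1], 2L)
  expect_equal(calls$n_qualifying[3], 2L)

  expect_error(call_primary_hits(make_scores(list(gA = c(1, 2)))), "gA")
})

test_that("RSA p-value equals the exhaustive placement enumeration", {
  # frozen values computed from the enumeration oracle
  expect_equal(rsa_gene_pvalue(c(1, 2), 10), 1 / 45, tolerance = 1e-12)
  expect_equal(rsa_gene_pvalue(c(1, 2, 3), 6), 0.05, tolerance = 1e-12)
  expect_equal(rsa_gene_pvalue(12, 12), 1, tolerance = 1e-12)

  # sweep of small instances against the oracle
  set.seed(3)
  for (i in 1:25) {
    n_total <- sample(3:12, 1)
    n <- sample(seq_len(min(3, n_total)), 1)
    ranks <- sort(sample.int(n_total, n))
    expect_equal(rsa_gene_pvalue(ranks, n_total), rsa_oracle(ranks, n_total),
                 tolerance = 1e-12,
                 label = sprintf("ranks {%s} of %d",
                                 paste(ranks, collapse = ","), n_total))
  }

  expect_error(rsa_gene_pvalue(c(2, 2), 10), "duplicate")
  expect_error(rsa_gene_pvalue(c(0, 3), 10), "out of range")
})

test_that("screen-level RSA is rank-invariant, monotone and ties get the worst rank", {
  scores <- make_scores(list(gA = c(-3, -2.5, 0.2), gB = c(-0.1, 0.4, 1.1),
                             gC = c(-2.6, 0.3, 0.8)))
  down <- rsa_screen(scores, "down")
  # permuting input rows changes nothing
  perm <- scores[sample(nrow(scores)), ]
  expect_equal(rsa_screen(perm, "down"), down)
  # the strongly reduced gene ranks best
  expect_lt(down$rsa_p[down$gene_id == "gA"],
            down$rsa_p[down$gene_id == "gB"])

  # improving one siRNA's rank never increases its gene's p
  worse <- rsa_gene_pvalue(c(3, 6), 10)
  better <- rsa_gene_pvalue(c(2, 6), 10)
  expect_lte(better, worse)

  # tied Z-scores share the worst (largest) rank
  tied <- make_scores(list(gA = c(-1, -1, -1), gB = c(-1, -1, -1)))
  p_tied <- rsa_screen(tied, "down")
  expect_equal(p_tied$rsa_p[1], p_tied$rsa_p[2])
  expect_equal(p_tied$rsa_p[1], 1)  # every rank is the worst rank
})

test_that("RSA separates planted hits from nulls on a simulated screen", {
  cfg <- sim_config(seed = 31, n_genes = 150, frac_hits_down = 1 / 3)
  sim <- simulate_screen(cfg)
  res <- run_screen_pipeline(sim$wells, sim$library,
                             simulate_calibration(cfg$k_true, seed = 32))
  down <- rsa_screen(res$normalized$wells[, c("gene_id", "sirna_id", "z")],
                     "down")
  cls <- sim$truth$genes$class[match(down$gene_id, sim$truth$genes$gene_id)]
  expect_lt(median(down$rsa_p[cls == "hit_down"]),
            median(down$rsa_p[cls == "null"]))
})

test_that("secondary validation requires one confirming siRNA in the primary direction", {
  v <- validate_secondary(c(-25, -5, 3), "down")
  expect_true(v$validated)
  expect_equal(v$n_confirming, 1L)
  # deviation beyond threshold but in the wrong direction does not confirm
  expect_false(validate_secondary(c(30, 2, -10), "down")$validated)
  expect_false(validate_secondary(c(-15, 10, 19.9), "down")$validated)
  expect_true(validate_secondary(c(20, -3, 1), "up")$validated)  # inclusive
  expect_error(validate_secondary(c(1, 2, 3), "none"), "unknown primary")

  dev_table <- data.frame(gene_id = rep(c("gA", "gB"), each = 3),
                          deviation_pct = c(-30, -22, 4, 6, -12, 9))
  calls <- data.frame(gene_id = c("gA", "gB"),
                      direction = c("down", "down"),
                      n_qualifying = c(2L, 2L), is_hit = c(TRUE, TRUE))
  out <- validate_secondary_screen(dev_table, calls)
  expect_equal(out$validated, c(TRUE, FALSE))
  expect_equal(out$n_confirming, c(2L, 0L))
})

test_that("gene scoring attaches directional RSA p-values to threshold calls", {
  scores <- make_scores(list(gA = c(-3, -2.5, -2.8), gB = c(0.1, -0.2, 0.3),
                             gC = c(2.5, 2.2, 0.1)))
  g <- score_genes(scores)
  g <- g[match(c("gA", "gB", "gC"), g$gene_id), ]
  expect_equal(g$direction, c("down", "none", "up"))
  expect_equal(g$rsa_p[1], g$rsa_p_down[1])
  expect_equal(g$rsa_p[3], g$rsa_p_up[3])
  expect_equal(g$rsa_p[2], min(g$rsa_p_down[2], g$rsa_p_up[2]))
  expect_equal(g$rsa_logp, -log10(g$rsa_p))
})
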
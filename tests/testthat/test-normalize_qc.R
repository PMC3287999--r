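test_that("NPI maps the controls to 0 and 1 and interpolates linearly", {
  expect_equal(npi_normalize(100, 100, 20), 0)
  expect_equal(npi_normalize(20, 100, 20), 1)
  expect_equal(npi_normalize(60, 100, 20), 0.5)
  expect_error(npi_normalize(50, 80, 80), "indistinguishable")
})

test_that("NPI is invariant under affine rescaling of the raw signal", {
  set.seed(1)
  for (i in 1:20) {
    v <- stats::runif(5, 0, 200)
    mu_n <- stats::runif(1, 100, 200)
    mu_p <- stats::runif(1, 0, 90)
    a <- stats::runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- stats::runif(1, -50, 50)
    expect_equal(npi_normalize(a * v + b, a * mu_n + b, a * mu_p + b),
                 npi_normalize(v, mu_n, mu_p), tolerance = 1e-10)
  }
})

test_that("Z-score transformation standardizes by screen mean and sample SD", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))  # sample SD is 1
  expect_equal(zscore(c(5, 6, 7)), z)  # shift invariance
  expect_error(zscore(c(1)), "at least 2")
  expect_error(zscore(c(2, 2, 2)), "zero spread")
})

test_that("Z'-factor matches its closed form, bounds and monotonicity", {
  expect_equal(zprime(20, 5, 100, 10), 0.4375)  # 1 - 3*15/80
  expect_equal(zprime(20, 0, 100, 0), 1)        # upper bound attained
  expect_warning(z <- zprime(50, 1, 50, 1), "undefined")
  expect_identical(z, -Inf)
  # strictly decreasing in either control SD, increasing in separation
  expect_gt(zprime(20, 4, 100, 10), zprime(20, 5, 100, 10))
  expect_gt(zprime(20, 5, 100, 9), zprime(20, 5, 100, 10))
  expect_gt(zprime(10, 5, 100, 10), zprime(20, 5, 100, 10))
})

test_that("estimated Z' converges to the analytic 0.42 as control replicates grow", {
  # control separation chosen so that the analytic Z' is exactly 0.42:
  # 1 - 3*(7.7333 + 7.7333)/80 = 0.42
  sig <- (1 - 0.42) * 80 / 6
  set.seed(42)
  est <- function(n) {
    pos <- stats::rnorm(n, 20, sig)
    neg <- stats::rnorm(n, 100, sig)
    zprime(mean(pos), stats::sd(pos), mean(neg), stats::sd(neg))
  }
  err_small <- abs(est(20) - 0.42)
  err_large <- abs(est(20000) - 0.42)
  expect_lt(err_large, 0.02)
  expect_lt(err_large, err_small)
})

test_that("Q-Q table pairs sorted scores with normal plotting positions", {
  expect_error(qq_points(c(1)), "at least 2")
  sym <- c(-2, -1, 1, 2)
  qq <- qq_points(sym)
  expect_equal(qq$observed, sort(sym))
  expect_equal(qq$theoretical, -rev(qq$theoretical), tolerance = 1e-12)
  expect_equal(qq$observed, -rev(qq$observed), tolerance = 1e-12)

  set.seed(8)
  qn <- qq_points(stats::rnorm(10000))
  mid <- abs(qn$theoretical) < 2
  expect_lt(max(abs(qn$observed[mid] - qn$theoretical[mid])), 0.1)
})

test_that("screen normalization applies plate-wise NPI and lipid-oriented Z-scores", {
  wells <- rbind(make_mini_plate("P1", neg = c(100, 100), pos = c(20, 20),
                                 samples = c(60, 100, 140)),
                 make_mini_plate("P2", neg = c(210, 190), pos = c(90, 110),
                                 samples = c(150, 200, 250)))
  wells$gene_id[wells$role == "sample"] <- rep(c("G1", "G2"), each = 3)
  wells$sirna_id[wells$role == "sample"] <- paste0(
    rep(c("G1", "G2"), each = 3), "_s", rep(1:3, 2))
  corrected <- apply_correction(wells, identity_fit())
  norm <- normalize_screen(corrected)
  # P2 controls: mu_neg 200, mu_pos 100 -> NPI of 150 is 0.5, same as P1's 60
  npi <- norm$wells$npi
  expect_equal(npi[norm$wells$plate_id == "P1"], c(0.5, 0, -0.5))
  expect_equal(npi[norm$wells$plate_id == "P2"], c(0.5, 0, -0.5))
  # Z is the standardized NPI flipped back onto the lipid axis: the highest
  # relative lipid well carries the most positive Z
  expect_equal(norm$wells$z[3], max(norm$wells$z))
  expect_equal(mean(norm$wells$z), 0, tolerance = 1e-12)

  stats <- norm$plate_stats
  expect_equal(stats$mu_neg[stats$plate_id == "P2"], 200)
  expect_equal(stats$mu_pos[stats$plate_id == "P2"], 100)
})

test_that("plates with indistinguishable controls are flagged and excluded", {
  good <- make_mini_plate("P1", samples = c(60, 80, 90))
  bad <- make_mini_plate("P2", neg = c(50, 50), pos = c(50, 50),
                         samples = c(40, 60, 70))
  corrected <- apply_correction(rbind(good, bad), identity_fit())
  expect_warning(norm <- normalize_screen(corrected), "P2")
  expect_equal(norm$excluded_plates, "P2")
  expect_false(any(norm$wells$plate_id == "P2"))
})

test_that("secondary deviations are percent changes from the plate negative-control mean", {
  wells <- make_mini_plate("P1", neg = c(100, 100), pos = c(20, 20),
                           samples = c(75, 100, 130))
  corrected <- apply_correction(wells, identity_fit())
  norm <- normalize_screen(corrected, compute_z = FALSE)
  dev <- secondary_deviations(norm)
  expect_equal(dev$deviation_pct, c(-25, 0, 30))
})
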
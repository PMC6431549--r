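test_that("Cramer's V matches hand-computed contingency values", {
  expect_equal(cramers_v(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(cramers_v(rbind(c(5, 5), c(5, 5))), 0)
  # chi2 = 20, total = 80, M = 1 -> V = 0.5
  expect_equal(cramers_v(rbind(c(30, 10), c(10, 30))), 0.5)
})

test_that("V is symmetric and permutation invariant; zero marginals drop", {
  ct <- rbind(c(12, 3, 5), c(2, 9, 4))
  expect_equal(cramers_v(ct), cramers_v(t(ct)))
  expect_equal(cramers_v(ct), cramers_v(ct[, c(3, 1, 2)]))
  expect_equal(cramers_v(ct), cramers_v(ct[c(2, 1), ]))

  with_zero <- rbind(c(12, 3, 0), c(2, 9, 0), c(0, 0, 0))
  expect_warning(v <- cramers_v(with_zero), "zero")
  expect_equal(v, cramers_v(rbind(c(12, 3), c(2, 9))))
})

test_that("driver screening drops the weaker member of associated pairs", {
  withr::local_seed(5)
  n <- 40
  base <- matrix(stats::runif(n * n), n, n)
  A <- driver_raster(base, "A", "proximity")
  B <- driver_raster(base + stats::rnorm(n * n, sd = 0.01), "B",
                     "proximity")
  C <- driver_raster(matrix(stats::runif(n * n), n, n), "C", "density")
  # change attracted to low values of A: A is the stronger proxy
  change <- base < 0.2 & stats::runif(n * n) < 0.8

  two_same <- screen_drivers(list(A = A, B = B), change)
  expect_length(two_same$retained, 1L)

  indep <- screen_drivers(list(A = A, C = C), change)
  expect_setequal(indep$retained, c("A", "C"))

  trio <- screen_drivers(list(A = A, B = B, C = C), change)
  expect_true("C" %in% trio$retained)
  expect_length(trio$retained, 2L)
  expect_equal(trio$dropped$driver, "B")  # A ranks higher on the target
})

test_that("independent drivers are retained across seeds", {
  ok <- 0L
  for (seed in 1:10) {
    withr::local_seed(seed)
    d1 <- driver_raster(matrix(stats::runif(900), 30), "d1", "density")
    d2 <- driver_raster(matrix(stats::runif(900), 30), "d2", "density")
    change <- matrix(stats::runif(900) < 0.3, 30)
    v <- cramers_v(contingency(
      lulcsim:::bin_index(d1$values, bin_edges(d1$values, 20)),
      lulcsim:::bin_index(d2$values, bin_edges(d2$values, 20))))
    res <- screen_drivers(list(d1 = d1, d2 = d2), change)
    expect_lt(v, 0.5)
    if (length(res$retained) == 2L) ok <- ok + 1L
  }
  expect_equal(ok, 10L)
})

test_that("W+ follows the log-ratio formula with smoothing only at zeros", {
  # one bin holding 50% of changed and 50% of unchanged cells -> W+ = 0;
  # 80%/20% -> ln 4. Build 1D drivers realizing those counts exactly.
  vals <- matrix(c(rep(0.25, 100), rep(0.75, 100)), 1)
  drv <- driver_raster(vals, "d", "proximity")
  elig <- matrix(TRUE, 1, 200)
  # changed: 40 low + 10 high; unchanged: 10 low + 140 high
  chg <- matrix(FALSE, 1, 200)
  chg[1, c(1:40, 101:110)] <- TRUE
  wt <- compute_woe(chg, elig, drv, bins = c(0, 0.5, 1))
  # low bin: 40/50 of changed vs 60/150 of unchanged -> ln(0.8/0.4)
  expect_equal(wt$w_plus[1], log((40 / 50) / (60 / 150)))

  # exact 80/20 split: 80% of changed vs 20/300 of unchanged in the low bin
  vals3 <- matrix(c(rep(0.25, 100), rep(0.75, 300)), 1)
  drv3 <- driver_raster(vals3, "d", "proximity")
  elig3 <- matrix(TRUE, 1, 400)
  chg3 <- matrix(FALSE, 1, 400)
  chg3[1, c(1:80, 101:120)] <- TRUE  # changed: 80 low, 20 high (n_D = 100)
  # unchanged: 20 low, 280 high (n_!D = 300)
  wt3 <- compute_woe(chg3, elig3, drv3, bins = c(0, 0.5, 1))
  expect_equal(wt3$w_plus[1], log((80 / 100) / (20 / 300)))

  # 50/50 bin -> exactly 0
  vals4 <- matrix(rep(c(0.25, 0.75), each = 100), 1)
  drv4 <- driver_raster(vals4, "d", "proximity")
  chg4 <- matrix(rep(c(TRUE, FALSE), times = 100), 1)
  wt4 <- compute_woe(chg4, matrix(TRUE, 1, 200), drv4,
                     bins = c(0, 0.5, 1))
  expect_equal(wt4$w_plus, c(0, 0))

  # an empty bin stays finite through smoothing
  chg5 <- matrix(c(rep(TRUE, 100), rep(FALSE, 100)), 1)
  wt5 <- compute_woe(chg5, matrix(TRUE, 1, 200), drv4,
                     bins = c(0, 0.5, 1))
  expect_true(all(is.finite(wt5$w_plus)))
})

test_that("planted attraction yields positive low-bin and negative high-bin weights", {
  withr::local_seed(21)
  n <- 50
  vals <- matrix(stats::runif(n * n), n, n)
  drv <- driver_raster(vals, "d", "proximity")
  elig <- matrix(TRUE, n, n)
  med <- stats::median(vals)
  chg <- vals < med & stats::runif(n * n) < 0.5
  wt <- compute_woe(chg, elig, drv, n_bins = 10)
  low <- wt$bin_hi <= med
  expect_true(all(wt$w_plus[low & wt$n_change + wt$n_nochange > 0] > 0))
  expect_true(all(wt$w_plus[!low] < 0))
})

test_that("independent drivers give near-zero weights (5 balanced bins, 1e4 cells)", {
  all_small <- 0L
  for (seed in 1:20) {
    withr::local_seed(seed + 300)
    vals <- matrix(stats::runif(1e4), 100)
    drv <- driver_raster(vals, "d", "proximity")
    chg <- matrix(stats::runif(1e4) < 0.5, 100)
    wt <- compute_woe(chg, matrix(TRUE, 100, 100), drv, n_bins = 5)
    if (all(abs(wt$w_plus) < 0.15)) all_small <- all_small + 1L
  }
  expect_gte(all_small, 18L)  # ~95% of seeds
})

test_that("probability_map combines prior and weights on eligible cells", {
  elig <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  vals <- matrix(c(0.2, 0.8, 0.5, 0.4), 2, 2)
  drv <- driver_raster(vals, "d", "proximity")
  chg <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  wt <- compute_woe(chg, elig, drv, bins = c(0, 1))
  wt$w_plus <- 0
  p0 <- probability_map(list(wt), list(d = drv), 0.2, elig)
  expect_equal(p0[elig], rep(0.2, 3))
  expect_equal(p0[!elig], 0)

  # a single weight ln 4 at prior 0.2: odds 0.25 * 4 = 1 -> P = 0.5
  wt$w_plus <- log(4)
  p1 <- probability_map(list(wt), list(d = drv), 0.2, elig)
  expect_equal(p1[elig], rep(0.5, 3))

  expect_error(probability_map(list(wt), list(d = drv), 1.2, elig),
               "prior")
})

test_that("probability_map is monotone in the weights", {
  withr::local_seed(8)
  vals <- matrix(stats::runif(400), 20)
  drv <- driver_raster(vals, "d", "proximity")
  elig <- matrix(stats::runif(400) < 0.7, 20)
  chg <- elig & stats::runif(400) < 0.3
  wt <- compute_woe(chg, elig, drv, n_bins = 8)
  base <- probability_map(list(wt), list(d = drv), 0.1, elig)
  for (k in seq_len(nrow(wt))) {
    wt2 <- wt
    wt2$w_plus[k] <- wt2$w_plus[k] + 0.7
    bumped <- probability_map(list(wt2), list(d = drv), 0.1, elig)
    expect_true(all(bumped - base >= -1e-12))
  }
})
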
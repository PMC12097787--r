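test_that("removal fraction matches the published assay anchors and limits", {
  # brushing: ~3 s removes 75%; washing: ~3.5 s removes 93%
  expect_equal(removal_fraction(2.97, 0.99), 0.75)
  expect_equal(round(removal_fraction(3.53, 0.27), 2), 0.93)
  expect_equal(removal_fraction(0, 5), 0)
  # half-saturation: g(c) = 1/2 by definition of c
  for (c in c(0.1, 1, 7.3)) expect_equal(removal_fraction(c, c), 0.5)
})

test_that("removal kinetics are increasing, concave and bounded", {
  set.seed(11)
  for (c in stats::runif(20, 0.01, 50)) {
    t <- sort(stats::runif(50, 0, 100))
    g <- removal_fraction(t, c)
    expect_true(all(g >= 0 & g < 1))
    expect_true(all(diff(g) > 0))            # strictly increasing
    expect_true(all(diff(diff(g) / diff(t)) < 1e-12))  # concave
  }
})

test_that("kinetics reject out-of-domain parameters by name", {
  expect_error(removal_fraction(1, 0), "`c`")
  expect_error(removal_fraction(-1, 1), "`t`")
  expect_error(removal_rate(1, 1, 0), "`h`")
  expect_error(optimal_cleaning_time(-1, 1), "`c`")
  expect_error(max_rate(1, -1), "`h`")
})

test_that("removal rate has its single interior maximum at sqrt(c*h)", {
  expect_equal(removal_rate(0, 1, 1), 0)
  expect_equal(removal_rate(1, 1, 1), 1 / 4)
  expect_equal(optimal_cleaning_time(1, 1), 1)
  expect_equal(optimal_cleaning_time(4, 9), 6)       # grid-verified
  expect_equal(optimal_cleaning_time(0.99, 1), sqrt(0.99))
  # independent grid-search oracle at assorted parameter pairs
  for (p in list(c(0.99, 1), c(0.27, 23), c(4, 9), c(12, 0.4))) {
    expect_equal(grid_argmax_rate(p[1], p[2]),
                 optimal_cleaning_time(p[1], p[2]), tolerance = 1e-3)
  }
})

test_that("closed-form max rate equals the rate at the optimum", {
  expect_equal(max_rate(1, 1), 0.25)
  expect_equal(max_rate(4, 9), 1 / 25)
  set.seed(21)
  cs <- stats::runif(200, 0.01, 100)
  hs <- stats::runif(200, 0.01, 100)
  for (i in seq_along(cs)) {
    t_star <- optimal_cleaning_time(cs[i], hs[i])
    expect_equal(max_rate(cs[i], hs[i]),
                 removal_rate(t_star, cs[i], hs[i]), tolerance = 1e-12)
  }
})

test_that("t* rises and the max rate falls in both c and h", {
  grid <- c(0.1, 0.5, 1, 5, 20)
  for (h in grid) {
    expect_true(all(diff(optimal_cleaning_time(grid, h)) > 0))
    expect_true(all(diff(max_rate(grid, h)) < 0))
  }
  for (c in grid) {
    expect_true(all(diff(optimal_cleaning_time(c, grid)) > 0))
    expect_true(all(diff(max_rate(c, grid)) < 0))
  }
})

test_that("tiny c is treated as the immediate-ingestion limit, with warning", {
  expect_warning(t0 <- optimal_cleaning_time(1e-12, 2), "limit")
  expect_lt(t0, 2e-6)
  expect_warning(r0 <- max_rate(1e-12, 2), "limit")
  expect_equal(r0, 1 / 2, tolerance = 1e-5)
})

test_that("inefficiency inversion reproduces the published estimates", {
  b <- inefficiency_from_assay(cleaning_assay("brushing", 2.97, 0.75, 0.07))
  expect_equal(b$c_mean, 0.99)
  expect_equal(round(b$c_sd, 2), 0.38, tolerance = 0.06)
  w <- inefficiency_from_assay(cleaning_assay("washing", 3.53, 0.93, 0.04))
  expect_equal(round(w$c_mean, 2), 0.27)
  expect_equal(w$c_mean, 0.2657, tolerance = 1e-3)
  expect_equal(inefficiency_from_assay(
    cleaning_assay("x", 5, 0.5))$c_mean, 5)  # half-saturation
})

test_that("inversion round-trips the forward kinetics exactly", {
  set.seed(31)
  for (c_true in stats::runif(50, 0.01, 20)) {
    t <- stats::runif(1, 0.1, 30)
    g <- removal_fraction(t, c_true)
    est <- inefficiency_from_assay(cleaning_assay("x", t, g))
    expect_equal(est$c_mean, c_true, tolerance = 1e-12)
  }
})

test_that("degenerate assays (g = 0 or 1) are rejected", {
  expect_error(inefficiency_from_assay(cleaning_assay("x", 3, 0)),
               "degenerate")
  expect_error(inefficiency_from_assay(cleaning_assay("x", 3, 1)),
               "degenerate")
})

test_that("assay records validate their fields", {
  expect_error(cleaning_assay("x", -1, 0.5), "time_s")
  expect_error(cleaning_assay("x", 1, 1.5), "removal_fraction")
  expect_error(cleaning_assay("x", 1, 0.5, -0.1), "removal_fraction_sd")
})

test_that("the strategy frontier conserves sqrt(c) + sqrt(h)", {
  ref <- strategy_params("ref", c_mean = 1, assessment_s = 1)
  fr <- strategy_frontier(ref, c(0.25, 1))
  expect_equal(fr$h[fr$c == 1], 1)            # self-consistency
  expect_equal(fr$h[fr$c == 0.25], 2.25)      # sqrt(0.25)+sqrt(2.25)=2
  set.seed(41)
  ref2 <- strategy_params("ref2", c_mean = 0.99, assessment_s = 1,
                          precleaning_mean_s = 22)
  grid <- stats::runif(100, 0.01, 20)
  fr2 <- suppressWarnings(strategy_frontier(ref2, grid))
  r_ref <- max_rate(0.99, 23)
  expect_true(all(abs(fr2$max_rate - r_ref) < 1e-9))
  expect_true(all(fr2$region == "frontier"))
})

test_that("infeasible frontier grid values are omitted with a warning", {
  ref <- strategy_params("ref", c_mean = 1, assessment_s = 1)  # K = 2
  expect_warning(fr <- strategy_frontier(ref, c(0.25, 4, 9)), "omitted")
  expect_equal(nrow(fr), 1L)
})

test_that("strategies classify into regions by their maximal rate", {
  ref <- strategy_params("ref", c_mean = 1, assessment_s = 1)
  expect_equal(classify_strategy(0.1, 0.1, ref), "II")  # faster than ref
  expect_equal(classify_strategy(9, 9, ref), "I")       # slower than ref
  expect_equal(classify_strategy(1, 1, ref), "frontier")
})

test_that("overcleaning factors compare observed durations to predictions", {
  expect_equal(overcleaning_factor(3.1, 0.98), 3.1 / 0.98)  # ~3.16
  expect_equal(overcleaning_factor(3.3, 2.40), 1.375)
  expect_equal(overcleaning_factor(rep(2.4, 5), 2.4), 1)
  # zero bouts are dropped by default but can be kept
  expect_equal(overcleaning_factor(c(0, 2), 1), 2)
  expect_equal(overcleaning_factor(c(0, 2), 1, include_zeros = TRUE), 1)
  expect_equal(overcleaning_factor(c(1, 2, 9), 1, center = "median"), 2)
  expect_error(overcleaning_factor(c(0, 0), 1), "undefined")
})
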
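test_that("the simulated experiment is deterministic given its seed", {
  a <- simulate_experiment(experiment_sim_config(seed = 5, n_trials = 20))
  b <- simulate_experiment(experiment_sim_config(seed = 5, n_trials = 20))
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  utils::write.csv(a, fa, row.names = FALSE)
  utils::write.csv(b, fb, row.names = FALSE)
  expect_identical(readLines(fa), readLines(fb))  # byte-identical CSVs
  c_ <- simulate_experiment(experiment_sim_config(seed = 6, n_trials = 20))
  expect_false(identical(a$brushing_s, c_$brushing_s))
})

test_that("total zero inflation silences all cleaning", {
  cfg <- experiment_sim_config(
    seed = 1, n_trials = 15,
    brushing_zero = c(low = 1, intermediate = 1, high = 1),
    washing_zero = c(low = 1, intermediate = 1, high = 1))
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$brushing_s == 0))
  expect_true(all(sim$washing_s == 0))
})

test_that("defaults produce treatment-ordered cleaning effort", {
  sim <- simulate_experiment(experiment_sim_config(seed = 2))
  lo_b <- sim$brushing_s[sim$treatment == "low"]
  hi_b <- sim$brushing_s[sim$treatment == "high"]
  expect_lt(t.test(lo_b, hi_b)$p.value, 1e-6)
  expect_lt(mean(lo_b), mean(hi_b))
  lo_w <- sim$washing_s[sim$treatment == "low"]
  hi_w <- sim$washing_s[sim$treatment == "high"]
  expect_lt(t.test(lo_w, hi_w)$p.value, 1e-6)
  s <- treatment_summaries(suppressMessages(filter_trials(sim)))
  for (beh in c("brushing", "washing")) {
    med <- s$median_s[s$behavior == beh][order(s$treatment[s$behavior == beh])]
    expect_true(all(diff(med) > 0))  # low < intermediate < high
  }
})

test_that("washing propensity is quadratic in rank, peaking mid-rank", {
  p <- washing_propensity(1:24, 24)
  expect_lt(p[1], p[12])
  expect_lt(p[24], p[12])
  expect_equal(p[1], p[24])  # symmetric extremes
  sim <- simulate_experiment(experiment_sim_config(seed = 4, n_trials = 300))
  washed <- tapply(sim$washing_s > 0, sim$ordinal_rank, mean)
  mid <- mean(washed[as.character(10:15)])
  ends <- mean(washed[c("1", "2", "23", "24")])
  expect_gt(mid, ends)
})

test_that("washing bouts carry travel times inside the observed range", {
  sim <- simulate_experiment(experiment_sim_config(seed = 3))
  w <- sim[sim$washing_s > 0, ]
  expect_true(all(w$travel_s >= 5 & w$travel_s <= 78))
  expect_true(all(sim$travel_s[sim$washing_s == 0] == 0))
  expect_true(all(sim$brushing_s + sim$washing_s <= sim$bout_duration_s))
})

test_that("infeasible experiment configs are rejected", {
  expect_error(experiment_sim_config(n_individuals = 0), "individual")
  expect_error(experiment_sim_config(
    brushing_zero = c(low = 1.2, intermediate = 0, high = 0)), "\\[0, 1\\]")
  expect_error(experiment_sim_config(
    washing_lambda = c(low = -1, intermediate = 1, high = 2)),
    "non-negative")
})

test_that("simulated assays recover the forward kinetics", {
  noiseless <- simulate_assay(assay_sim_config(true_c = 0.99,
                                               noise_sd = 0,
                                               cleaning_times = c(1, 2.97),
                                               seed = 1))
  expect_equal(noiseless$removal_fraction[noiseless$time_s == 2.97],
               rep(0.75, 30))
  expect_equal(unique(noiseless$removal_fraction[noiseless$time_s == 1]),
               removal_fraction(1, 0.99))
  # CLT: mean of many replicates near g(t; c)
  big <- simulate_assay(assay_sim_config(true_c = 0.5, noise_sd = 0.07,
                                         n_replicates = 1000,
                                         cleaning_times = 2, seed = 2))
  se <- 0.07 / sqrt(1000)
  expect_lt(abs(mean(big$removal_fraction) - removal_fraction(2, 0.5)),
            3 * se)
  expect_warning(assay_sim_config(true_c = 1, noise_sd = 0.6),
                 "uninformative")
})

test_that("aggregation collapses replicates to means and (SE) SDs", {
  reps <- simulate_assay(assay_sim_config(true_c = 1, seed = 3,
                                          cleaning_times = c(1, 2)))
  agg <- aggregate_assay(reps)
  expect_equal(nrow(agg), 2L)
  r1 <- reps$removal_fraction[reps$time_s == 1]
  expect_equal(agg$removal_fraction[agg$time_s == 1], mean(r1))
  expect_equal(agg$removal_fraction_sd[agg$time_s == 1], stats::sd(r1))
  agg_se <- aggregate_assay(reps, sd_of_mean = TRUE)
  expect_equal(agg_se$removal_fraction_sd[1],
               agg$removal_fraction_sd[1] / sqrt(30))
})

test_that("simulated particles match their configured structure", {
  shapes <- simulate_particles(n = 250, seed = 11)
  expect_length(shapes, 250)
  # defaults place about half the sample under the grittiness threshold
  expect_lt(abs(grittiness_fraction(shapes) - 0.5), 0.1)
  # configured negative trend is recovered within 2 SEs
  tr <- circularity_size_trend(shapes)
  expect_lt(abs(tr$slope - (-0.001)), 2 * tr$slope_se)
  # single component, zero trend: flat circularity
  flat <- simulate_particles(n = 100, seed = 12, weights = c(1, 0),
                             trend_slope = 0, noise_sd = 0.02)
  tr0 <- circularity_size_trend(flat)
  expect_lt(abs(tr0$slope), 2 * tr0$slope_se + 1e-4)
  expect_error(simulate_particles(n = 10, weights = c(0.7, 0.7)), "sum to 1")
  expect_error(simulate_particles(n = 10, sdlog = c(-1, 1)), "non-negative")
})

test_that("particle generation is seed-deterministic", {
  a <- simulate_particles(n = 40, seed = 13)
  b <- simulate_particles(n = 40, seed = 13)
  expect_identical(a, b)
})

test_that("the recovery harness is honest at zero noise", {
  rep0 <- recovery_harness(true_c = 0.99, noise_sd = 0, n_replicates = 5,
                           n_reps = 3, seed = 1)
  expect_lt(abs(rep0$bias_c), 1e-9)
  expect_lt(rep0$rmse_c, 1e-9)
  expect_lt(abs(rep0$bias_t_star), 1e-9)
})

test_that("the washing-configuration optimum is recovered", {
  rh <- recovery_harness(true_c = 0.27, h = 23, noise_sd = 0.04,
                         cleaning_times = 3.53, n_replicates = 100,
                         n_reps = 50, seed = 2)
  expect_lt(abs(rh$bias_c), 0.05)
  # t* recovery within 0.2 s of sqrt(0.27 * 23)
  expect_lt(abs(rh$bias_t_star), 0.2)
  expect_equal(rh$t_star_true, sqrt(0.27 * 23))
})
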
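# Per-stream substreams from one global seed: adding a stream never
# perturbs existing ones. Offsets are fixed per stream name.
stream_seed <- function(seed, stream) {
  offsets <- c(experiment = 101L, assay = 211L, particles = 307L,
               recovery = 401L, pipeline = 503L)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}

#' Configuration for the simulated feeding experiment
#'
#' Defaults emulate the field design: ~100 trials at three sand
#' treatments (trays of three cucumber slices), two dozen individuals in
#' a strict linear hierarchy, zero-inflated cleaning durations whose
#' means rise with sand load, a washing propensity that is
#' logit-quadratic in standardized rank (mid-ranked animals wash most;
#' the extremes abstain), and ocean-travel times from a truncated normal
#' clipped to the observed 5-78 s range. Treatment-level duration means
#' and zero-inflation rates are plausible placeholders consistent with
#' the reported treatment-ordered medians, not fitted values.
#'
#' @param n_individuals number of monkeys (default 24: 8 males,
#'   16 females).
#' @param n_trials number of feeding trials (default 101).
#' @param seed global seed; all substreams derive from it.
#' @param brushing_lambda,washing_lambda named per-treatment mean
#'   durations (seconds) of the non-zero-inflated component.
#' @param brushing_zero,washing_zero named per-treatment zero-inflation
#'   probabilities.
#' @param rank_wash_profile `c(b0, b2)` of the logit-quadratic washing
#'   propensity `plogis(b0 + b2 * r^2)` in standardized rank
#'   `r in [-1, 1]` (`b2 < 0` peaks at mid-rank).
#' @param travel_dist `list(mean, sd, clip)` of the ocean-travel time.
#' @param slices_per_tray slices per tray (default 3).
#' @param assessment_s fixed assessment time per bout (default 1).
#' @param max_participants_range trial sizes are drawn uniformly from
#'   this range (some exceed the 3-monkey analysis filter by design).
#' @return an object of class `"experiment_sim_config"`.
#' @export
experiment_sim_config <- function(
    n_individuals = 24L, n_trials = 101L, seed = 1L,
    brushing_lambda = c(low = 0.3, intermediate = 1.8, high = 3.5),
    washing_lambda = c(low = 0.5, intermediate = 2.0, high = 4.0),
    brushing_zero = c(low = 0.80, intermediate = 0.35, high = 0.10),
    washing_zero = c(low = 0.90, intermediate = 0.15, high = 0.05),
    rank_wash_profile = c(b0 = 4, b2 = -9),
    travel_dist = list(mean = 22, sd = 15, clip = c(5, 78)),
    slices_per_tray = 3L, assessment_s = 1,
    max_participants_range = c(1L, 5L)) {
  if (n_individuals < 1L) stop("need at least one individual", call. = FALSE)
  if (n_trials < 1L) stop("need at least one trial", call. = FALSE)
  for (p in list(brushing_zero, washing_zero))
    if (any(p < 0 | p > 1))
      stop("zero-inflation probabilities must lie in [0, 1]", call. = FALSE)
  if (any(brushing_lambda < 0) || any(washing_lambda < 0))
    stop("duration means must be non-negative", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 brushing_lambda = brushing_lambda,
                 washing_lambda = washing_lambda,
                 brushing_zero = brushing_zero,
                 washing_zero = washing_zero,
                 rank_wash_profile = rank_wash_profile,
                 travel_dist = travel_dist,
                 slices_per_tray = as.integer(slices_per_tray),
                 assessment_s = assessment_s,
                 max_participants_range = as.integer(max_participants_range)),
            class = "experiment_sim_config")
}

#' Washing propensity as a function of standardized rank
#'
#' `plogis(b0 + b2 * r^2)` with `r` the rank standardized to `[-1, 1]`
#' (-1 = most dominant, +1 = most subordinate); with `b2 < 0` the
#' propensity peaks at mid-rank and falls toward both extremes.
#'
#' @param ordinal_rank ordinal rank 1..n.
#' @param n_individuals group size n.
#' @param profile `c(b0, b2)` coefficients.
#' @return washing probability in `[0, 1]`.
#' @export
washing_propensity <- function(ordinal_rank, n_individuals,
                               profile = c(b0 = 4, b2 = -9)) {
  r <- if (n_individuals > 1L)
    (ordinal_rank - (n_individuals + 1) / 2) / ((n_individuals - 1) / 2)
  else 0
  stats::plogis(profile[[1]] + profile[[2]] * r^2)
}

# zero-inflated Poisson duration at 0.1 s resolution: zero with
# probability p0, else Poisson(10*lambda)/10 (mean lambda)
rzip_duration <- function(n, lambda, p0) {
  d <- stats::rpois(n, 10 * lambda) / 10
  d[stats::runif(n) < p0] <- 0
  d
}

#' Simulate a feeding experiment
#'
#' Generates a bout table with the statistical structure the analysis
#' assumes: treatment-ordered zero-inflated cleaning durations, a
#' quadratic-in-rank washing propensity, truncated ocean-travel times for
#' washing bouts, and trial sizes spanning the low-competition filter.
#' Deterministic given the config seed.
#'
#' @param cfg an [experiment_sim_config()].
#' @return a bout data frame (columns as in [read_bouts()]), with the
#'   config attached as `attr(, "config")`.
#' @export
simulate_experiment <- function(cfg = experiment_sim_config()) {
  stopifnot(inherits(cfg, "experiment_sim_config"))
  set.seed(stream_seed(cfg$seed, "experiment"))
  n <- cfg$n_individuals
  ids <- sprintf("ind%02d", seq_len(n))
  sexes <- rep(c("M", "F"), c(max(1L, round(n / 3)),
                              n - max(1L, round(n / 3))))
  ranks <- seq_len(n)
  p_wash_ind <- washing_propensity(ranks, n, cfg$rank_wash_profile)

  rows <- vector("list", cfg$n_trials)
  bout_counter <- 0L
  for (tr in seq_len(cfg$n_trials)) {
    k <- sample(seq(cfg$max_participants_range[1],
                    cfg$max_participants_range[2]), 1L)
    k <- min(k, n)
    who <- sample.int(n, k)
    n_bouts <- stats::rpois(k, 2) + 1L
    trial <- lapply(seq_len(k), function(j) {
      i <- who[j]
      nb <- n_bouts[j]
      treatment <- sample(TREATMENT_LEVELS, nb, replace = TRUE)
      brush <- rzip_duration(nb, cfg$brushing_lambda[treatment],
                             cfg$brushing_zero[treatment])
      washes <- stats::runif(nb) < p_wash_ind[i]
      wash <- ifelse(washes,
                     rzip_duration(nb, cfg$washing_lambda[treatment],
                                   cfg$washing_zero[treatment]), 0)
      travel <- ifelse(wash > 0,
                       round(rtruncnorm(nb, cfg$travel_dist$mean,
                                        cfg$travel_dist$sd,
                                        cfg$travel_dist$clip[1],
                                        cfg$travel_dist$clip[2]), 1), 0)
      slices <- sample.int(cfg$slices_per_tray, nb, replace = TRUE)
      eating <- round(stats::rgamma(nb, shape = 4, rate = 0.8), 1)
      data.frame(
        trial_id = sprintf("trial%03d", tr),
        individual_id = ids[i], sex = sexes[i], ordinal_rank = ranks[i],
        age_class = "adult", treatment = treatment,
        brushing_s = brush, washing_s = wash, travel_s = travel,
        slices_consumed = slices,
        bout_duration_s = cfg$assessment_s + brush + wash + travel + eating,
        trial_participants = k)
    })
    rows[[tr]] <- do.call(rbind, trial)
  }
  out <- do.call(rbind, rows)
  out <- cbind(bout_id = sprintf("bout%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  validate_bouts(out)
}

#' Configuration for simulated cleaning-efficacy assays
#'
#' @param true_c true cleaning inefficiency in seconds (`> 0`).
#' @param cleaning_times assay cleaning times in seconds.
#' @param noise_sd SD of the measurement noise on removal fractions; at
#'   0.5 or above the assay is essentially uninformative and a warning is
#'   issued.
#' @param n_replicates replicate measurements per cleaning time (`>= 2`).
#' @param behavior behavior label attached to the assay.
#' @param seed global seed.
#' @return an object of class `"assay_sim_config"`.
#' @export
assay_sim_config <- function(true_c, cleaning_times = c(1, 2.97, 3.53, 6),
                             noise_sd = 0.07, n_replicates = 30L,
                             behavior = "brushing", seed = 1L) {
  check_positive(true_c, "true_c")
  if (n_replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (noise_sd >= 0.5)
    warning("noise_sd >= 0.5: the simulated assay is uninformative",
            call. = FALSE)
  structure(list(true_c = true_c, cleaning_times = cleaning_times,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 behavior = behavior, seed = as.integer(seed)),
            class = "assay_sim_config")
}

#' Simulate cleaning-efficacy assays
#'
#' For each cleaning time `t`, draws replicate removal fractions
#' `clamp(g(t; true_c) + Normal(0, noise_sd), 0, 1)`.
#'
#' @param cfg an [assay_sim_config()].
#' @return a data frame with columns `behavior`, `time_s`, `replicate`,
#'   `removal_fraction`.
#' @seealso [aggregate_assay()] to collapse replicates into
#'   [cleaning_assay()] rows.
#' @export
simulate_assay <- function(cfg) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  set.seed(stream_seed(cfg$seed, "assay"))
  out <- do.call(rbind, lapply(cfg$cleaning_times, function(t) {
    g <- removal_fraction(t, cfg$true_c)
    obs <- pmin(pmax(g + stats::rnorm(cfg$n_replicates, 0, cfg$noise_sd),
                     0), 1)
    data.frame(behavior = cfg$behavior, time_s = t,
               replicate = seq_len(cfg$n_replicates),
               removal_fraction = obs)
  }))
  rownames(out) <- NULL
  out
}

#' Collapse assay replicates to per-time means
#'
#' @param replicates output of [simulate_assay()] (or a data frame with
#'   `behavior`, `time_s`, `removal_fraction`).
#' @param sd_of_mean report the SD of the mean (standard error) instead
#'   of the replicate SD — appropriate when the downstream uncertainty is
#'   about the estimated mean fraction.
#' @return a data frame of assay rows: `behavior`, `time_s`,
#'   `removal_fraction`, `removal_fraction_sd`.
#' @export
aggregate_assay <- function(replicates, sd_of_mean = FALSE) {
  out <- do.call(rbind, lapply(
    split(replicates, list(replicates$behavior, replicates$time_s),
          drop = TRUE),
    function(d) {
      s <- stats::sd(d$removal_fraction)
      if (sd_of_mean) s <- s / sqrt(nrow(d))
      data.frame(behavior = d$behavior[1], time_s = d$time_s[1],
                 removal_fraction = mean(d$removal_fraction),
                 removal_fraction_sd = s)
    }))
  out <- out[order(out$behavior, out$time_s), ]
  rownames(out) <- NULL
  out
}

# circularity of an ellipse with semi-axes 1 and q, discretized to nv
# vertices (matches how generated particles are later measured)
ellipse_circularity <- function(q, nv = 64L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  v <- cbind(cos(th), q * sin(th))
  4 * pi * polygon_area(v) / polygon_perimeter(v)^2
}

#' Simulate sand-particle outlines
#'
#' Particle sizes (mean Feret diameters) follow a two-component lognormal
#' mixture; defaults place about half the sample below the 25-micrometer
#' grittiness threshold, matching the bimodal size structure of
#' beach-sand contamination. Each particle is a discretized ellipse whose
#' elongation is solved so its measured circularity equals
#' `trend_intercept + trend_slope * size + noise` (clipped to
#' `[0.05, 0.999]`), and which is scaled so its mean caliper width equals
#' the drawn size (mean width of a convex body = perimeter / pi), then
#' randomly rotated. Larger particles thus come out more elongated/less
#' circular at a controlled, recoverable rate.
#'
#' @param n number of particles.
#' @param seed global seed.
#' @param weights,meanlog,sdlog two-component lognormal mixture of sizes
#'   in micrometers (weights must sum to 1).
#' @param trend_slope,trend_intercept,noise_sd linear size-circularity
#'   trend (per micrometer) and the SD of the circularity noise.
#' @param min_size_um sizes below this are redrawn (imaging floor).
#' @param n_vertices vertices per particle outline.
#' @return a list of [particle_shape()] objects.
#' @export
simulate_particles <- function(n = 758L, seed = 1L,
                               weights = c(0.5, 0.5),
                               meanlog = log(c(15, 60)),
                               sdlog = c(0.45, 0.8),
                               trend_slope = -0.001,
                               trend_intercept = 0.9,
                               noise_sd = 0.05,
                               min_size_um = 5, n_vertices = 64L) {
  if (any(weights < 0) || any(sdlog < 0))
    stop("mixture parameters must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  set.seed(stream_seed(seed, "particles"))
  comp <- sample.int(2L, n, replace = TRUE, prob = weights)
  size <- stats::rlnorm(n, meanlog[comp], sdlog[comp])
  while (any(size < min_size_um)) {
    i <- which(size < min_size_um)
    comp_i <- sample.int(2L, length(i), replace = TRUE, prob = weights)
    size[i] <- stats::rlnorm(length(i), meanlog[comp_i], sdlog[comp_i])
  }
  target <- pmin(pmax(trend_intercept + trend_slope * size +
                        stats::rnorm(n, 0, noise_sd), 0.05), 0.999)
  circ_max <- ellipse_circularity(1, n_vertices)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  lapply(seq_len(n), function(i) {
    tc <- min(target[i], circ_max - 1e-6)
    q <- stats::uniroot(function(q) ellipse_circularity(q, n_vertices) - tc,
                        c(1e-4, 1), tol = 1e-10)$root
    v <- cbind(cos(th), q * sin(th))
    v <- v * (pi * size[i] / polygon_perimeter(v))  # mean width = size
    phi <- stats::runif(1, 0, pi)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)
    particle_shape(particle_id = sprintf("p%04d", i), vertices = v %*% rot)
  })
}

#' Parameter-recovery harness for the inefficiency estimator
#'
#' Runs the full simulate-then-estimate loop: for each of `n_reps`
#' replicates, simulates an efficacy assay at the true inefficiency,
#' aggregates replicates (SD of the mean), inverts the saturating
#' relationship to estimate `c` with its Monte-Carlo 5-95% interval, and
#' derives the optimal cleaning time at handling time `h`. Reports bias,
#' RMSE and interval coverage for both `c` and `t*`. Generator and
#' estimator share nothing but the simulated data.
#'
#' @param true_c true inefficiency in seconds.
#' @param h handling time used for the `t*` recovery, seconds.
#' @param noise_sd assay measurement noise SD.
#' @param n_replicates replicate measurements per simulated assay.
#' @param n_reps number of simulate-estimate replicates.
#' @param cleaning_times assay cleaning times (default: the single
#'   brushing assay time).
#' @param seed global seed.
#' @return an object of class `"recovery_report"`: a list with `bias_c`,
#'   `rmse_c`, `coverage_c` (90% target), `bias_t_star`, `rmse_t_star`,
#'   the per-replicate estimates, and the settings.
#' @export
recovery_harness <- function(true_c = 0.99, h = 1, noise_sd = 0.07,
                             n_replicates = 100L, n_reps = 100L,
                             cleaning_times = 2.97, seed = 1L) {
  base <- stream_seed(seed, "recovery")
  t_true <- optimal_cleaning_time(true_c, h)
  est <- vapply(seq_len(n_reps), function(r) {
    cfg <- assay_sim_config(true_c = true_c,
                            cleaning_times = cleaning_times,
                            noise_sd = noise_sd,
                            n_replicates = n_replicates,
                            seed = base + r)
    agg <- aggregate_assay(simulate_assay(cfg), sd_of_mean = TRUE)
    fits <- lapply(seq_len(nrow(agg)), function(i)
      inefficiency_from_assay(agg[i, ], seed = base + r))
    c_hat <- mean(vapply(fits, function(f) f$c_mean, numeric(1)))
    ci <- rowMeans(vapply(fits, function(f) f$c_ci, numeric(2)))
    c(c_hat = c_hat, lo = ci[1], hi = ci[2])
  }, numeric(3))
  c_hat <- est["c_hat", ]
  covered <- est["lo", ] <= true_c & true_c <= est["hi", ]
  t_hat <- sqrt(c_hat * h)
  structure(list(
    true_c = true_c, h = h, t_star_true = t_true,
    n_reps = n_reps, n_replicates = n_replicates, noise_sd = noise_sd,
    bias_c = mean(c_hat) - true_c,
    rmse_c = sqrt(mean((c_hat - true_c)^2)),
    coverage_c = mean(covered),
    bias_t_star = mean(t_hat) - t_true,
    rmse_t_star = sqrt(mean((t_hat - t_true)^2)),
    estimates = c_hat, seed = seed), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (simulate -> estimate)\n")
  cat(sprintf("  true c = %.3f s, %d replicates x %d assay measurements\n",
              x$true_c, x$n_reps, x$n_replicates))
  cat(sprintf("  c:  bias %+.4f, RMSE %.4f, 90%% CI coverage %.2f\n",
              x$bias_c, x$rmse_c, x$coverage_c))
  cat(sprintf("  t*: bias %+.4f s, RMSE %.4f s (h = %.1f s)\n",
              x$bias_t_star, x$rmse_t_star, x$h))
  invisible(x)
}
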
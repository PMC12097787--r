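#' Saturating grit-removal kinetics
#'
#' The fraction of sand removed from a food surface after `t` seconds of
#' cleaning follows the saturating (Michaelis-Menten type) relationship
#' \deqn{g(t) = t / (c + t),}
#' where `c` is the *cleaning inefficiency*: the half-saturation constant,
#' i.e. the cleaning time at which half the sand has been removed. Larger
#' `c` means a less efficient cleaning behavior.
#'
#' @param t cleaning time in seconds (vectorized, `t >= 0`).
#' @param c cleaning inefficiency in seconds (`c > 0`).
#' @return the removal fraction `t/(c + t)`, in `[0, 1)`.
#' @examples
#' removal_fraction(2.97, 0.99)  # ~0.75 after ~3 s of brushing
#' removal_fraction(3.53, 0.27)  # ~0.93 after ~3.5 s of washing
#' @seealso [removal_rate()], [optimal_cleaning_time()],
#'   [inefficiency_from_assay()]
#' @export
removal_fraction <- function(t, c) {
  check_positive(c, "c")
  check_nonnegative(t, "t")
  t / (c + t)
}

#' Rate of grit removal
#'
#' The removal fraction achieved per unit of *total* time invested,
#' \deqn{R(t) = g(t) / (h + t) = t / ((c + t)(h + t)),}
#' where `h` is the handling time: a fixed assessment period plus any
#' pre-cleaning activity (for washing, travel to water). `R` is unimodal in
#' `t` with a single interior maximum at [optimal_cleaning_time()].
#'
#' @inheritParams removal_fraction
#' @param h handling time in seconds (`h > 0`).
#' @return removal rate in fraction per second.
#' @export
removal_rate <- function(t, c, h) {
  check_positive(h, "h")
  removal_fraction(t, c) / (h + t)
}

#' Optimal cleaning time
#'
#' The cleaning time maximizing the removal rate `R(t) = t/((c+t)(h+t))`.
#' Setting `dR/dt = 0` gives the interior maximizer
#' \deqn{t^* = \sqrt{c h}.}
#' A forager obeying the marginal-value logic should stop cleaning at
#' `t*`: beyond it the marginal return of further cleaning falls below the
#' average rate already achieved.
#'
#' As `c` approaches 0 the optimum collapses to immediate ingestion
#' (`t* -> 0`, maximal rate `-> 1/h`); values of `c` below `1e-9` are
#' handled as this limit with a warning rather than an error.
#'
#' @inheritParams removal_rate
#' @return the optimal cleaning time `sqrt(c*h)` in seconds.
#' @examples
#' optimal_cleaning_time(0.99, 1)   # brushing: ~0.99 s
#' optimal_cleaning_time(0.27, 23)  # washing with 22 s travel: ~2.49 s
#' @export
optimal_cleaning_time <- function(c, h) {
  check_positive(c, "c", tiny_ok = TRUE)
  check_positive(h, "h")
  sqrt(c * h)
}

#' Maximal removal rate
#'
#' Closed form of the removal rate at the optimal cleaning time:
#' substituting `t* = sqrt(c*h)` into `R(t)` gives
#' \deqn{R(t^*) = 1 / (\sqrt{c} + \sqrt{h})^2.}
#'
#' @inheritParams removal_rate
#' @return maximal rate in fraction per second.
#' @export
max_rate <- function(c, h) {
  check_positive(c, "c", tiny_ok = TRUE)
  check_positive(h, "h")
  1 / (sqrt(c) + sqrt(h))^2
}

#' Cleaning-efficacy assay record
#'
#' Bundles one efficacy measurement: how long a surface was cleaned, the
#' mean fraction of sand removed, and the replicate SD of that fraction.
#'
#' @param behavior behavior label, `"brushing"` or `"washing"`.
#' @param time_s cleaning time in seconds (finite, `> 0`).
#' @param removal_fraction mean fraction of sand removed, in `[0, 1]`.
#' @param removal_fraction_sd replicate SD of the removal fraction (`>= 0`).
#' @return an object of class `"cleaning_assay"` (a named list).
#' @export
cleaning_assay <- function(behavior, time_s, removal_fraction,
                           removal_fraction_sd = 0) {
  stopifnot(is.character(behavior), length(behavior) == 1L)
  if (!is.finite(time_s) || time_s <= 0)
    stop("`time_s` must be finite and positive", call. = FALSE)
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("`removal_fraction` must lie in [0, 1]", call. = FALSE)
  if (removal_fraction_sd < 0)
    stop("`removal_fraction_sd` must be non-negative", call. = FALSE)
  structure(list(behavior = behavior, time_s = time_s,
                 removal_fraction = removal_fraction,
                 removal_fraction_sd = removal_fraction_sd),
            class = "cleaning_assay")
}

#' Estimate cleaning inefficiency from an efficacy assay
#'
#' Inverts the saturating removal relationship at an observed
#' (time, removal fraction) pair:
#' \deqn{c = t (1 - g) / g.}
#' Uncertainty in `c` is propagated by Monte Carlo: removal fractions are
#' drawn from a normal distribution centered on the observed mean with the
#' assay SD, truncated to `g_bounds` (default (0.01, 0.99)) so the
#' inversion stays finite, mapped through the inversion, and summarized by
#' their sample SD and 5-95 percentile interval.
#'
#' @param assay a [cleaning_assay()], or anything coercible to one (a
#'   one-row data frame or named list with the same fields).
#' @param n_draws number of Monte-Carlo draws for the uncertainty in `c`.
#' @param seed integer seed making the draws reproducible.
#' @param g_bounds truncation bounds for the sampled removal fractions.
#' @return a [strategy_params()] object with `c_mean`, `c_sd`, the 5-95
#'   percentile interval `c_ci`, and the Monte-Carlo draws in
#'   `attr(, "c_draws")`.
#' @examples
#' inefficiency_from_assay(cleaning_assay("brushing", 2.97, 0.75, 0.07))
#' @export
inefficiency_from_assay <- function(assay, n_draws = 10000L, seed = 1L,
                                    g_bounds = c(0.01, 0.99)) {
  assay <- as_cleaning_assay(assay)
  g <- assay$removal_fraction
  t <- assay$time_s
  if (g <= 0 || g >= 1)
    stop("degenerate assay: removal fraction of ", g,
         " leaves the inefficiency undefined", call. = FALSE)
  c_mean <- t * (1 - g) / g
  c_sd <- 0
  c_ci <- c(c_mean, c_mean)
  c_draws <- rep(c_mean, 0L)
  if (assay$removal_fraction_sd > 0) {
    set.seed(as.integer(seed))
    g_draws <- rtruncnorm(n_draws, g, assay$removal_fraction_sd,
                          lower = g_bounds[1], upper = g_bounds[2])
    c_draws <- t * (1 - g_draws) / g_draws
    c_sd <- stats::sd(c_draws)
    c_ci <- unname(stats::quantile(c_draws, c(0.05, 0.95)))
  }
  out <- strategy_params(behavior = assay$behavior, c_mean = c_mean,
                         c_sd = c_sd)
  out$c_ci <- c_ci
  attr(out, "c_draws") <- c_draws
  out
}

as_cleaning_assay <- function(x) {
  if (inherits(x, "cleaning_assay")) return(x)
  x <- as.list(x)
  cleaning_assay(as.character(x$behavior), as.numeric(x$time_s),
                 as.numeric(x$removal_fraction),
                 if (is.null(x$removal_fraction_sd)) 0
                 else as.numeric(x$removal_fraction_sd))
}

#' Cleaning-strategy parameters
#'
#' A cleaning strategy is summarized by its inefficiency `c` (with
#' uncertainty) and its handling time `h`, decomposed into a fixed
#' assessment period and a pre-cleaning period (zero for brushing; ocean
#' travel for washing).
#'
#' @param behavior behavior label.
#' @param c_mean mean cleaning inefficiency in seconds (`> 0`).
#' @param c_sd SD of the inefficiency estimate (`>= 0`).
#' @param assessment_s fixed assessment time in seconds (default 1).
#' @param precleaning_mean_s mean pre-cleaning (e.g. travel) time, seconds.
#' @param precleaning_sd_s SD of the pre-cleaning time.
#' @param precleaning_range_s observed `(lo, hi)` range the pre-cleaning
#'   time is clipped to when sampled.
#' @return an object of class `"strategy_params"`.
#' @export
strategy_params <- function(behavior, c_mean, c_sd = 0, assessment_s = 1,
                            precleaning_mean_s = 0, precleaning_sd_s = 0,
                            precleaning_range_s = c(0, Inf)) {
  check_positive(c_mean, "c_mean", tiny_ok = TRUE)
  if (c_sd < 0) stop("`c_sd` must be non-negative", call. = FALSE)
  if (assessment_s < 0) stop("`assessment_s` must be non-negative",
                             call. = FALSE)
  if (precleaning_range_s[1] > precleaning_range_s[2])
    stop("`precleaning_range_s` must satisfy lo <= hi", call. = FALSE)
  structure(list(behavior = behavior, c_mean = c_mean, c_sd = c_sd,
                 assessment_s = assessment_s,
                 precleaning_mean_s = precleaning_mean_s,
                 precleaning_sd_s = precleaning_sd_s,
                 precleaning_range_s = precleaning_range_s),
            class = "strategy_params")
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("Cleaning strategy: %s\n", x$behavior))
  cat(sprintf("  inefficiency c = %.2f +/- %.2f s\n", x$c_mean, x$c_sd))
  cat(sprintf("  handling time h = %.2f s (assessment %.2f + pre-cleaning %.2f)\n",
              handling_time(x), x$assessment_s, x$precleaning_mean_s))
  invisible(x)
}

#' Mean handling time of a strategy
#'
#' `h = assessment + mean pre-cleaning time`.
#'
#' @param params a [strategy_params()] object.
#' @return handling time in seconds.
#' @export
handling_time <- function(params) {
  params$assessment_s + params$precleaning_mean_s
}

#' Equal-rate strategy frontier
#'
#' The locus of (inefficiency, handling time) pairs achieving the same
#' maximal removal rate as a reference strategy. Because the maximal rate
#' is `1/(sqrt(c) + sqrt(h))^2`, the frontier conserves
#' `sqrt(c) + sqrt(h)`: for each `c` on the grid the matching handling
#' time is `h = (K - sqrt(c))^2` with `K = sqrt(c_ref) + sqrt(h_ref)`.
#' The curve separates strategy space into region I (slower maximal
#' removal than the reference: long handling but efficient cleaning, the
#' oceanside-washing corner) and region II (faster: short handling but
#' inefficient cleaning, the immediate-brushing corner).
#'
#' Grid values with `sqrt(c) >= K` admit no positive handling time and are
#' omitted with a warning reporting how many were dropped.
#'
#' @param reference a [strategy_params()] object (or a list with `c_mean`
#'   and handling-time fields) defining the iso-rate level.
#' @param c_grid inefficiency values (seconds) to trace the frontier over.
#' @return a data frame with columns `c`, `h`, `max_rate`, `region`.
#' @seealso [classify_strategy()]
#' @export
strategy_frontier <- function(reference, c_grid) {
  c_ref <- reference$c_mean
  h_ref <- handling_time(reference)
  check_positive(c_ref, "reference c_mean")
  check_positive(h_ref, "reference handling time")
  check_positive(c_grid, "c_grid")
  K <- sqrt(c_ref) + sqrt(h_ref)
  ok <- sqrt(c_grid) < K
  if (any(!ok))
    warning(sum(!ok), " grid value(s) admit no positive handling time ",
            "at the reference rate and were omitted", call. = FALSE)
  cc <- c_grid[ok]
  hh <- (K - sqrt(cc))^2
  data.frame(c = cc, h = hh, max_rate = max_rate(cc, hh),
             region = classify_strategy(cc, hh, reference))
}

#' Classify a strategy against a reference rate
#'
#' Compares the maximal removal rate attainable at `(c, h)` with the
#' reference strategy's: strategies achieving a *higher* maximal rate than
#' the reference fall in region II (the cheaper strategy is preferred),
#' lower in region I; ties (within `tol`) sit on the frontier.
#'
#' @inheritParams removal_rate
#' @param reference a [strategy_params()] object.
#' @param tol relative tolerance for calling a tie.
#' @return character vector of `"I"`, `"II"` or `"frontier"`.
#' @export
classify_strategy <- function(c, h, reference, tol = 1e-9) {
  r_ref <- max_rate(reference$c_mean, handling_time(reference))
  r <- max_rate(c, h)
  out <- ifelse(r > r_ref * (1 + tol), "II",
                ifelse(r < r_ref * (1 - tol), "I", "frontier"))
  out
}

#' Overcleaning factor
#'
#' Ratio of the central tendency of observed cleaning durations to the
#' model-predicted (Monte-Carlo mean) optimal cleaning time. Values above
#' 1 indicate cleaning past the point of diminishing returns.
#'
#' By default zero-duration bouts (food handled without any cleaning) are
#' excluded before taking the center, and the center is the mean; both
#' choices are exposed because reporting conventions differ.
#'
#' @param observed_times observed cleaning durations in seconds.
#' @param predicted an [propagate()] result (class `"optimization_result"`)
#'   or a single positive number giving the predicted optimal time.
#' @param center `"mean"` or `"median"`.
#' @param include_zeros keep zero-duration bouts in the center?
#' @return the dimensionless overcleaning factor.
#' @examples
#' overcleaning_factor(c(3.1), 0.98)  # ~3.2x overbrushing
#' @export
overcleaning_factor <- function(observed_times, predicted,
                                center = c("mean", "median"),
                                include_zeros = FALSE) {
  center <- match.arg(center)
  pred <- if (inherits(predicted, "optimization_result"))
    predicted$mc_mean else as.numeric(predicted)
  check_positive(pred, "predicted optimal time")
  x <- observed_times[is.finite(observed_times)]
  if (!include_zeros) x <- x[x > 0]
  if (length(x) == 0L)
    stop("overcleaning factor undefined: no positive observed durations",
         call. = FALSE)
  obs <- if (center == "mean") mean(x) else stats::median(x)
  obs / pred
}

# -- input checks ------------------------------------------------------------

check_positive <- function(x, name, tiny_ok = FALSE) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("`", name, "` must be positive and finite", call. = FALSE)
  if (tiny_ok && any(x < 1e-9))
    warning("`", name, "` below 1e-9: treating as the c -> 0 limit ",
            "(immediate ingestion)", call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("`", name, "` must be non-negative and finite", call. = FALSE)
  invisible(x)
}
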
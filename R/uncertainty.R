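#' Truncated-normal sampler (rejection)
#'
#' Draws from Normal(mean, sd) conditioned on `[lower, upper]` by
#' rejection, and errors if the overall acceptance rate drops below 50%
#' (a badly specified distribution, e.g. a mean far outside the bounds).
#'
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal.
#' @param lower,upper truncation bounds.
#' @param max_reject_rate rejection rate above which sampling aborts.
#' @return `n` accepted draws.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                       max_reject_rate = 0.5) {
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate sampler: constant ", mean,
           " lies outside [", lower, ", ", upper, "]", call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(0)
  proposed <- 0L
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    proposed <- proposed + n
    out <- c(out, x[x >= lower & x <= upper])
    if (proposed >= 4L * n && length(out) < proposed * (1 - max_reject_rate))
      stop("sampler rejection rate exceeds ", max_reject_rate * 100,
           "%: Normal(", mean, ", ", sd, ") truncated to [", lower, ", ",
           upper, "] is badly specified", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Monte-Carlo samplers for model parameters
#'
#' Constructors for the parameter samplers used by [propagate()]:
#' * `sampler_constant(value)` — a degenerate (zero-variance) draw;
#' * `sampler_truncnorm(mean, sd, lower, upper)` — truncated normal via
#'   rejection, the default family since assays report only mean, SD and
#'   an observed range;
#' * `sampler_bootstrap(values)` — resample observed replicate values with
#'   replacement (an alternative when raw replicates are available);
#' * `sampler_shifted(offset, sampler)` — a fixed offset plus another
#'   sampler's draw (e.g. handling time = 1 s assessment + travel).
#'
#' @param value,offset fixed values in the sampler's units.
#' @param mean,sd,lower,upper truncated-normal parameters.
#' @param values observed replicate values to resample.
#' @param sampler an inner sampler to shift.
#' @return an object of class `"mc_sampler"`.
#' @name mc_samplers
NULL

#' @rdname mc_samplers
#' @export
sampler_constant <- function(value) {
  new_sampler("constant", value = value)
}

#' @rdname mc_samplers
#' @export
sampler_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  new_sampler("truncnorm", mean = mean, sd = sd, lower = lower,
              upper = upper)
}

#' @rdname mc_samplers
#' @export
sampler_bootstrap <- function(values) {
  if (length(values) < 2L)
    stop("bootstrap sampler needs at least 2 observed values", call. = FALSE)
  new_sampler("bootstrap", values = values)
}

#' @rdname mc_samplers
#' @export
sampler_shifted <- function(offset, sampler) {
  stopifnot(inherits(sampler, "mc_sampler"))
  new_sampler("shifted", offset = offset, inner = sampler)
}

new_sampler <- function(type, ...) {
  structure(list(type = type, ...), class = "mc_sampler")
}

draw_sampler <- function(s, n) {
  switch(s$type,
    constant  = rep(s$value, n),
    truncnorm = rtruncnorm(n, s$mean, s$sd, s$lower, s$upper),
    bootstrap = sample(s$values, n, replace = TRUE),
    shifted   = s$offset + draw_sampler(s$inner, n),
    stop("unknown sampler type: ", s$type, call. = FALSE))
}

#' Monte-Carlo configuration
#'
#' Settings for [propagate()]: the number of draws, the seed, and
#' (optionally) explicit samplers overriding those derived from the
#' strategy parameters. At least 1000 draws are required so the reported
#' 5-95 percentile interval is stable.
#'
#' @param n_draws number of Monte-Carlo draws (default 10000).
#' @param seed integer seed; recorded in every result.
#' @param c_sampler,h_sampler optional [mc_samplers] overriding the
#'   defaults built from the strategy parameters.
#' @return an object of class `"mc_config"`.
#' @export
mc_config <- function(n_draws = 10000L, seed = 1L, c_sampler = NULL,
                      h_sampler = NULL) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 1000L)
    stop("`n_draws` must be at least 1000 for stable percentile intervals",
         call. = FALSE)
  structure(list(n_draws = n_draws, seed = as.integer(seed),
                 c_sampler = c_sampler, h_sampler = h_sampler),
            class = "mc_config")
}

default_c_sampler <- function(params) {
  if (params$c_sd > 0)
    sampler_truncnorm(params$c_mean, params$c_sd, lower = 0.01)
  else sampler_constant(params$c_mean)
}

default_h_sampler <- function(params) {
  if (params$precleaning_sd_s > 0)
    sampler_shifted(params$assessment_s,
                    sampler_truncnorm(params$precleaning_mean_s,
                                      params$precleaning_sd_s,
                                      lower = params$precleaning_range_s[1],
                                      upper = params$precleaning_range_s[2]))
  else sampler_constant(params$assessment_s + params$precleaning_mean_s)
}

#' Propagate parameter uncertainty into the optimal cleaning time
#'
#' Draws `(c_i, h_i)` pairs from the strategy's parameter distributions,
#' computes the optimal cleaning time `t_i* = sqrt(c_i h_i)` for each
#' draw, and summarizes the resulting distribution by its mean, SD and
#' 5-95 percentile interval. Deterministic given the configuration seed.
#'
#' Default samplers: inefficiency `c` is truncated-normal
#' (mean `c_mean`, SD `c_sd`, lower bound 0.01 s); handling time `h` is
#' the assessment constant plus a truncated-normal pre-cleaning time
#' clipped to its observed range (or a constant when the pre-cleaning SD
#' is zero).
#'
#' @param params a [strategy_params()] object.
#' @param cfg an [mc_config()].
#' @return an object of class `"optimization_result"`: a list with
#'   `t_star_point` (optimum at the mean parameters), `rate_at_optimum`,
#'   `mc_mean`, `mc_sd`, `ci_5_95`, `n_draws`, `seed` and the raw `draws`.
#' @examples
#' brushing <- strategy_params("brushing", c_mean = 0.99, c_sd = 0.38)
#' propagate(brushing, mc_config(n_draws = 10000, seed = 1))
#' @export
propagate <- function(params, cfg = mc_config()) {
  stopifnot(inherits(params, "strategy_params"), inherits(cfg, "mc_config"))
  cs <- if (is.null(cfg$c_sampler)) default_c_sampler(params) else cfg$c_sampler
  hs <- if (is.null(cfg$h_sampler)) default_h_sampler(params) else cfg$h_sampler
  set.seed(cfg$seed)
  c_draws <- draw_sampler(cs, cfg$n_draws)
  h_draws <- draw_sampler(hs, cfg$n_draws)
  if (any(c_draws <= 0) || any(h_draws <= 0))
    stop("samplers produced non-positive parameter draws", call. = FALSE)
  t_draws <- sqrt(c_draws * h_draws)
  h_mean <- handling_time(params)
  structure(list(
    behavior = params$behavior,
    t_star_point = optimal_cleaning_time(params$c_mean, h_mean),
    rate_at_optimum = max_rate(params$c_mean, h_mean),
    mc_mean = mean(t_draws),
    mc_sd = stats::sd(t_draws),
    ci_5_95 = unname(stats::quantile(t_draws, c(0.05, 0.95))),
    n_draws = cfg$n_draws,
    seed = cfg$seed,
    draws = t_draws), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Optimal cleaning time (%s)\n",
              if (is.null(x$behavior)) "strategy" else x$behavior))
  cat(sprintf("  point optimum  t* = %.2f s (rate %.3f s^-1)\n",
              x$t_star_point, x$rate_at_optimum))
  cat(sprintf("  Monte Carlo    %.2f +/- %.2f s, 5-95%% CI [%.2f, %.2f]\n",
              x$mc_mean, x$mc_sd, x$ci_5_95[1], x$ci_5_95[2]))
  cat(sprintf("  (%d draws, seed %d)\n", x$n_draws, x$seed))
  invisible(x)
}

#' Jensen gap of the Monte-Carlo optimum
#'
#' Diagnostic for the curvature bias of averaging optima: since
#' `sqrt` is concave, `E[sqrt(c h)] <= sqrt(E[c] E[h])` for independent
#' draws, so the gap
#' `sqrt(c_mean * h_mean) - mc_mean` should be non-negative up to
#' Monte-Carlo error.
#'
#' @inheritParams propagate
#' @return the gap in seconds.
#' @export
jensen_gap <- function(params, cfg = mc_config()) {
  res <- propagate(params, cfg)
  res$t_star_point - res$mc_mean
}
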
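#' Fit the optimal-cleaning-time model to efficacy assays
#'
#' The central fitting function of the package. Takes a table of
#' cleaning-efficacy assays (one row per behavior x cleaning time, with
#' the mean removal fraction and its SD) and, per behavior:
#' \enumerate{
#'   \item estimates the cleaning inefficiency `c` by inverting the
#'     saturating removal relationship `g(t) = t/(c + t)` at each assay
#'     point (`c = t(1-g)/g`) and averaging across points, with
#'     Monte-Carlo uncertainty from truncated-normal resampling of the
#'     removal fractions;
#'   \item attaches the behavior's handling-time decomposition
#'     (assessment constant + pre-cleaning/travel distribution);
#'   \item predicts the rate-maximizing optimal cleaning time
#'     `t* = sqrt(c h)` with full Monte-Carlo propagation.
#' }
#'
#' @param data a data frame with columns `behavior`, `time_s`,
#'   `removal_fraction`, `removal_fraction_sd` (see [read_assays()]), or
#'   a single [cleaning_assay()].
#' @param assessment_s fixed assessment time in seconds (default 1),
#'   applied to every behavior.
#' @param precleaning named list, per behavior, of
#'   `list(mean, sd, range)` pre-cleaning (travel) time distributions in
#'   seconds; behaviors not named get zero pre-cleaning time. The default
#'   gives washing the ocean-travel distribution (mean 22, SD 15, clipped
#'   to the observed 5-78 s) and brushing none.
#' @param n_draws Monte-Carlo draws per behavior.
#' @param seed integer seed for all Monte-Carlo stages.
#' @return an object of class `"cleaning_model"`: a list with
#'   `strategies` (named [strategy_params()] per behavior), `optima`
#'   (named [propagate()] results), the assay `data`, `n_draws`, `seed`
#'   and the matched `call`.
#' @examples
#' assays <- data.frame(
#'   behavior = c("brushing", "washing"),
#'   time_s = c(2.97, 3.53),
#'   removal_fraction = c(0.75, 0.93),
#'   removal_fraction_sd = c(0.07, 0.04))
#' fit <- cleaning_model(assays)
#' coef(fit)
#' summary(fit)
#' @export
cleaning_model <- function(data,
                           assessment_s = 1,
                           precleaning = list(
                             washing = list(mean = 22, sd = 15,
                                            range = c(5, 78))),
                           n_draws = 10000L, seed = 1L) {
  if (inherits(data, "cleaning_assay"))
    data <- as.data.frame(unclass(data), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(data),
            all(c("behavior", "time_s", "removal_fraction") %in% names(data)))
  if (!"removal_fraction_sd" %in% names(data)) data$removal_fraction_sd <- 0
  behaviors <- unique(data$behavior)
  strategies <- list()
  optima <- list()
  for (b in behaviors) {
    rows <- data[data$behavior == b, , drop = FALSE]
    fits <- lapply(seq_len(nrow(rows)), function(i)
      inefficiency_from_assay(rows[i, ], n_draws = n_draws, seed = seed + i))
    c_mean <- mean(vapply(fits, function(f) f$c_mean, numeric(1)))
    # combine per-point draws elementwise: MC of the averaged estimator
    draw_mat <- vapply(fits, function(f) {
      d <- attr(f, "c_draws")
      if (length(d) == 0L) rep(f$c_mean, n_draws) else d
    }, numeric(n_draws))
    c_draws <- rowMeans(draw_mat)
    c_sd <- stats::sd(c_draws)
    pc <- precleaning[[b]]
    sp <- strategy_params(
      behavior = b, c_mean = c_mean, c_sd = c_sd,
      assessment_s = assessment_s,
      precleaning_mean_s = if (is.null(pc)) 0 else pc$mean,
      precleaning_sd_s = if (is.null(pc)) 0 else pc$sd,
      precleaning_range_s = if (is.null(pc)) c(0, Inf) else pc$range)
    attr(sp, "c_draws") <- c_draws
    strategies[[b]] <- sp
    optima[[b]] <- propagate(sp, mc_config(n_draws = n_draws, seed = seed))
  }
  structure(list(strategies = strategies, optima = optima, data = data,
                 assessment_s = assessment_s, n_draws = n_draws,
                 seed = as.integer(seed), call = match.call()),
            class = "cleaning_model")
}

#' Read a cleaning-efficacy assay table from CSV
#'
#' Columns: `behavior`, `time_s`, `removal_fraction`,
#' `removal_fraction_sd` (UTF-8, comma-delimited, header required).
#'
#' @param path CSV path.
#' @return a data frame ready for [cleaning_model()].
#' @export
read_assays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("behavior", "time_s", "removal_fraction", "removal_fraction_sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("assay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' @export
print.cleaning_model <- function(x, ...) {
  cat("Optimal cleaning-time model (saturating removal kinetics)\n")
  for (b in names(x$strategies)) {
    s <- x$strategies[[b]]
    o <- x$optima[[b]]
    cat(sprintf("  %-9s c = %.2f +/- %.2f s, h = %.2f s, t* = %.2f +/- %.2f s\n",
                b, s$c_mean, s$c_sd, handling_time(s), o$mc_mean, o$mc_sd))
  }
  invisible(x)
}

#' @export
coef.cleaning_model <- function(object, ...) {
  vapply(object$strategies, function(s) s$c_mean, numeric(1))
}

#' @export
summary.cleaning_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$strategies), function(b) {
    s <- object$strategies[[b]]
    o <- object$optima[[b]]
    data.frame(behavior = b, c_mean = s$c_mean, c_sd = s$c_sd,
               h = handling_time(s),
               t_star_point = o$t_star_point,
               t_star_mc = o$mc_mean, t_star_sd = o$mc_sd,
               ci_lo = o$ci_5_95[1], ci_hi = o$ci_5_95[2],
               max_rate = o$rate_at_optimum)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, n_draws = object$n_draws,
                 seed = object$seed), class = "summary.cleaning_model")
}

#' @export
print.summary.cleaning_model <- function(x, ...) {
  cat("Optimal cleaning-time model\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Monte Carlo: %d draws, seed %d; CI is the 5-95 percentile\n",
              x$n_draws, x$seed))
  invisible(x)
}

#' Predictions from a fitted cleaning model
#'
#' @param object a [cleaning_model()] fit.
#' @param type `"t_star"` (optimal cleaning times, the default),
#'   `"removal"` (removal fraction at times `t`), or `"rate"` (removal
#'   rate at times `t`).
#' @param t cleaning times for `"removal"`/`"rate"` predictions.
#' @param behavior behaviors to predict for (default: all fitted).
#' @param ... unused.
#' @return a data frame of predictions.
#' @export
predict.cleaning_model <- function(object, type = c("t_star", "removal",
                                                    "rate"),
                                   t = NULL, behavior = NULL, ...) {
  type <- match.arg(type)
  bs <- if (is.null(behavior)) names(object$strategies) else behavior
  bad <- setdiff(bs, names(object$strategies))
  if (length(bad) > 0L)
    stop("behavior(s) not in the fit: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (type == "t_star") {
    return(do.call(rbind, lapply(bs, function(b) {
      o <- object$optima[[b]]
      data.frame(behavior = b, t_star_point = o$t_star_point,
                 mc_mean = o$mc_mean, mc_sd = o$mc_sd,
                 ci_lo = o$ci_5_95[1], ci_hi = o$ci_5_95[2])
    })))
  }
  if (is.null(t)) stop("`t` is required for removal/rate predictions",
                       call. = FALSE)
  do.call(rbind, lapply(bs, function(b) {
    s <- object$strategies[[b]]
    val <- if (type == "removal") removal_fraction(t, s$c_mean)
    else removal_rate(t, s$c_mean, handling_time(s))
    data.frame(behavior = b, t = t, value = val, type = type)
  }))
}

#' Residuals of the fitted removal kinetics
#'
#' Observed assay removal fractions minus the fitted saturating curve
#' `g(t) = t/(c_hat + t)` evaluated at the assay cleaning times.
#'
#' @param object a [cleaning_model()] fit.
#' @param ... unused.
#' @return numeric vector, one residual per assay row.
#' @export
residuals.cleaning_model <- function(object, ...) {
  d <- object$data
  fitted_g <- mapply(function(b, t) removal_fraction(t, coef(object)[[b]]),
                     d$behavior, d$time_s)
  unname(d$removal_fraction - fitted_g)
}

#' Simulate assay tables from a fitted cleaning model
#'
#' Parametric simulation: new replicate removal fractions are drawn about
#' the fitted curve at the original assay design points, with each row's
#' observed SD as the noise level.
#'
#' @param object a [cleaning_model()] fit.
#' @param nsim number of simulated assay tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` data frames shaped like the input assays.
#' @export
simulate.cleaning_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  cf <- coef(object)
  lapply(seq_len(nsim), function(k) {
    g_fit <- mapply(function(b, t) removal_fraction(t, cf[[b]]),
                    d$behavior, d$time_s)
    out <- d
    out$removal_fraction <- pmin(pmax(
      g_fit + stats::rnorm(nrow(d), 0, d$removal_fraction_sd), 0), 1)
    out
  })
}

#' Plot fitted removal-rate curves
#'
#' Removal rate `R(t)` against cleaning time for each fitted behavior,
#' with the rate-maximizing optimum marked; the interior maximum is the
#' visual statement of diminishing returns.
#'
#' @param x a [cleaning_model()] fit.
#' @param t_max right edge of the time axis (default: 4x the largest
#'   optimum).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.cleaning_model <- function(x, t_max = NULL, ...) {
  bs <- names(x$strategies)
  t_stars <- vapply(bs, function(b) x$optima[[b]]$t_star_point, numeric(1))
  if (is.null(t_max)) t_max <- 4 * max(t_stars)
  tt <- seq(0, t_max, length.out = 400)
  rates <- vapply(bs, function(b) {
    s <- x$strategies[[b]]
    removal_rate(tt, s$c_mean, handling_time(s))
  }, numeric(length(tt)))
  graphics::matplot(tt, rates, type = "l", lty = 1, lwd = 2,
                    xlab = "cleaning time t (s)",
                    ylab = expression(R(t) == g(t) / (h + t)), ...)
  for (i in seq_along(bs))
    graphics::points(t_stars[i],
                     x$optima[[bs[i]]]$rate_at_optimum, pch = 19, col = i)
  graphics::legend("topright", legend = bs, col = seq_along(bs), lty = 1,
                   lwd = 2, bty = "n")
  invisible(x)
}
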
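#' Sand-particle shape record
#'
#' A particle is described either by its polygon outline (ordered 2-D
#' vertices in micrometers) or directly by its projected area and
#' perimeter. When vertices are supplied, area (shoelace formula) and
#' perimeter (edge-length sum) are recomputed from them; if stored values
#' are also supplied they must agree within 0.1%.
#'
#' @param particle_id particle label.
#' @param vertices optional two-column matrix of `(x, y)` vertex
#'   coordinates in micrometers, in order, not repeating the first point.
#' @param area_um2 projected area in square micrometers.
#' @param perimeter_um perimeter in micrometers.
#' @param composition optional composition label (e.g. `"quartz"`); an
#'   input classification, never computed here.
#' @return an object of class `"particle_shape"`.
#' @export
particle_shape <- function(particle_id = NA_character_, vertices = NULL,
                           area_um2 = NULL, perimeter_um = NULL,
                           composition = NA_character_) {
  if (!is.null(vertices)) {
    vertices <- as.matrix(vertices)
    if (ncol(vertices) != 2L || nrow(vertices) < 3L)
      stop("`vertices` must be an n x 2 matrix with n >= 3", call. = FALSE)
    A <- polygon_area(vertices)
    P <- polygon_perimeter(vertices)
    if (A <= 0 || P <= 0)
      stop("degenerate polygon: non-positive area or perimeter",
           call. = FALSE)
    if (!is.null(area_um2) && abs(area_um2 - A) > 1e-3 * A)
      stop("stored area disagrees with the polygon by more than 0.1%",
           call. = FALSE)
    if (!is.null(perimeter_um) && abs(perimeter_um - P) > 1e-3 * P)
      stop("stored perimeter disagrees with the polygon by more than 0.1%",
           call. = FALSE)
    area_um2 <- A
    perimeter_um <- P
  }
  if (is.null(area_um2) || is.null(perimeter_um))
    stop("supply either `vertices` or both `area_um2` and `perimeter_um`",
         call. = FALSE)
  if (area_um2 <= 0) stop("`area_um2` must be positive", call. = FALSE)
  if (perimeter_um <= 0) stop("`perimeter_um` must be positive",
                              call. = FALSE)
  structure(list(particle_id = particle_id, vertices = vertices,
                 area_um2 = area_um2, perimeter_um = perimeter_um,
                 composition = composition), class = "particle_shape")
}

# shoelace formula; sign-free
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(v) {
  d <- v - v[c(nrow(v), seq_len(nrow(v) - 1L)), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Circularity of a particle
#'
#' The dimensionless shape factor
#' \deqn{4 \pi A / P^2,}
#' equal to 1 for a circle and smaller for elongated or angular outlines
#' (isoperimetric inequality). Values are clipped to `[0, 1]` because
#' digitization of near-circular outlines can push the raw ratio
#' marginally above 1. A convenient 2-D proxy for sphericity.
#'
#' @param shape a [particle_shape()], or a number interpreted as an area
#'   when `perimeter` is also given.
#' @param perimeter perimeter, when `shape` is given as a bare area.
#' @return circularity in `[0, 1]`.
#' @examples
#' circularity(pi, 2 * pi)  # unit circle -> 1
#' circularity(1, 4)        # unit square -> pi/4
#' @export
circularity <- function(shape, perimeter = NULL) {
  if (inherits(shape, "particle_shape")) {
    A <- shape$area_um2; P <- shape$perimeter_um
  } else {
    A <- shape; P <- perimeter
  }
  if (is.null(P) || any(P <= 0))
    stop("`perimeter` must be positive", call. = FALSE)
  pmin(pmax(4 * pi * A / P^2, 0), 1)
}

#' Feret (caliper) diameters of a particle
#'
#' The Feret diameter along a direction is the extent of the particle's
#' projection onto that direction — the opening of a caliper closed on the
#' outline. Concave outlines are measured on their convex hull (caliper
#' semantics). Reported are:
#' * `min` — the smallest caliper width over a 1-degree angular sweep,
#' * `max` — the largest point-pair distance on the convex hull (exact),
#' * `mean` — the average caliper width over the sweep (180 directions).
#'
#' @param shape a [particle_shape()] with vertices, or an n x 2 vertex
#'   matrix.
#' @param step_deg angular step of the sweep in degrees.
#' @return named numeric vector `c(min, max, mean)` in micrometers.
#' @export
feret_diameters <- function(shape, step_deg = 1) {
  v <- if (inherits(shape, "particle_shape")) shape$vertices else
    as.matrix(shape)
  if (is.null(v) || nrow(v) < 3L)
    stop("Feret diameters need a polygon with at least 3 vertices",
         call. = FALSE)
  hull <- v[grDevices::chull(v), , drop = FALSE]
  if (nrow(hull) < 3L || polygon_area(hull) <= 1e-12 * max(1, sum(hull^2)))
    stop("degenerate (collinear) polygon: Feret diameters undefined",
         call. = FALSE)
  theta <- seq(0, pi, by = step_deg * pi / 180)
  theta <- theta[theta < pi]
  proj <- hull %*% rbind(cos(theta), sin(theta))
  widths <- apply(proj, 2L, function(p) max(p) - min(p))
  dmax <- max(stats::dist(hull))
  c(min = min(widths), max = dmax, mean = mean(widths))
}

mean_feret_of <- function(shapes) {
  if (is.data.frame(shapes)) {
    if (!"mean_feret_um" %in% names(shapes))
      stop("data frame input needs a `mean_feret_um` column", call. = FALSE)
    return(shapes$mean_feret_um)
  }
  vapply(shapes, function(s) feret_diameters(s)[["mean"]], numeric(1))
}

#' Fraction of particles below the grittiness threshold
#'
#' The human oral cavity cannot detect grit below roughly 25 micrometers;
#' particles under that size escape detection yet still abrade enamel.
#' Reports the fraction of particles whose mean Feret diameter falls
#' below the threshold.
#'
#' @param shapes a list of [particle_shape()] objects (with vertices), or
#'   a data frame with a `mean_feret_um` column.
#' @param threshold_um grittiness threshold in micrometers (default 25).
#' @return fraction in `[0, 1]`.
#' @export
grittiness_fraction <- function(shapes, threshold_um = 25) {
  mf <- mean_feret_of(shapes)
  if (length(mf) == 0L)
    stop("no particles supplied", call. = FALSE)
  mean(mf < threshold_um)
}

#' Size-circularity trend
#'
#' Ordinary least-squares regression of circularity on mean Feret
#' diameter — a descriptive summary of how angularity scales with particle
#' size (larger particles tend to be less circular, implying sharper
#' attack angles during particle-enamel contact).
#'
#' @inheritParams grittiness_fraction
#' @return a list with `slope` (per micrometer), `intercept`, `slope_se`,
#'   `n`, and the underlying `lm` fit.
#' @export
circularity_size_trend <- function(shapes) {
  if (is.data.frame(shapes)) {
    mf <- shapes$mean_feret_um
    circ <- shapes$circularity
  } else {
    mf <- mean_feret_of(shapes)
    circ <- vapply(shapes, circularity, numeric(1))
  }
  if (length(mf) < 3L || length(unique(mf)) < 2L)
    stop("size-circularity trend undefined: need >= 3 particles with ",
         "at least two distinct sizes", call. = FALSE)
  fit <- stats::lm(circ ~ mf)
  cf <- stats::coef(summary(fit))
  list(slope = cf["mf", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       slope_se = cf["mf", "Std. Error"], n = length(mf), fit = fit)
}

#' Exogenous particulate mass per unit food-surface area
#'
#' The sand load of a food surface: mass of the recovered particulate
#' pellet divided by the surface area of the food object, in
#' mg per square millimeter.
#'
#' @param pellet_mass_mg pellet mass in milligrams (`>= 0`).
#' @param surface_area_mm2 food surface area in square millimeters (`> 0`).
#' @return sand load in mg mm^-2.
#' @export
mass_per_area <- function(pellet_mass_mg, surface_area_mm2) {
  check_nonnegative(pellet_mass_mg, "pellet_mass_mg")
  check_positive(surface_area_mm2, "surface_area_mm2")
  pellet_mass_mg / surface_area_mm2
}

#' Default particle size-bin edges (micrometers)
#'
#' Left-closed, right-open bins spanning the sizes seen on food surfaces;
#' standard contamination-analysis size classes are not published with
#' explicit edges, so these defaults are overridable everywhere they are
#' used.
#' @export
default_size_bins <- function() c(5, 15, 25, 50, 100, 150, 200, 400, 600, 1000)

#' Morphometric summary of a particle sample
#'
#' Computes, per sample: particle count, median and range of mean Feret
#' diameter, the fraction below the grittiness threshold, the OLS
#' size-circularity slope, and a histogram over configurable size bins.
#' Particles below the lower analysis cutoff (default 5 micrometers, the
#' imaging resolution floor) are excluded, with the excluded count
#' reported.
#'
#' @inheritParams grittiness_fraction
#' @param bin_edges size-bin edges in micrometers (left-closed,
#'   right-open).
#' @param min_size_um lower analysis cutoff in micrometers.
#' @return an object of class `"morphometrics_summary"`.
#' @export
morphometrics_summary <- function(shapes, threshold_um = 25,
                                  bin_edges = default_size_bins(),
                                  min_size_um = 5) {
  mf <- mean_feret_of(shapes)
  circ <- if (is.data.frame(shapes)) shapes$circularity else
    vapply(shapes, circularity, numeric(1))
  keep <- mf >= min_size_um
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(n_excluded, " particle(s) below the ", min_size_um,
            " um analysis cutoff excluded")
  mf <- mf[keep]; circ <- circ[keep]
  if (length(mf) == 0L) stop("no particles at or above the size cutoff",
                             call. = FALSE)
  trend <- if (length(mf) >= 3L && length(unique(mf)) >= 2L)
    circularity_size_trend(data.frame(mean_feret_um = mf,
                                      circularity = circ))
  else list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_)
  counts <- table(cut(mf, breaks = c(bin_edges, Inf), right = FALSE,
                      include.lowest = FALSE))
  structure(list(
    n_particles = length(mf),
    n_excluded = n_excluded,
    median_feret_um = stats::median(mf),
    feret_range_um = range(mf),
    frac_below_threshold = mean(mf < threshold_um),
    threshold_um = threshold_um,
    circularity_size_slope = trend$slope,
    circularity_size_intercept = trend$intercept,
    size_bins = counts), class = "morphometrics_summary")
}

#' @export
print.morphometrics_summary <- function(x, ...) {
  cat("Particle morphometrics\n")
  cat(sprintf("  n = %d particles (%d below cutoff excluded)\n",
              x$n_particles, x$n_excluded))
  cat(sprintf("  median mean-Feret %.1f um (range %.1f-%.1f)\n",
              x$median_feret_um, x$feret_range_um[1], x$feret_range_um[2]))
  cat(sprintf("  %.1f%% below the %g um grittiness threshold\n",
              100 * x$frac_below_threshold, x$threshold_um))
  cat(sprintf("  circularity-size slope %.4g per um\n",
              x$circularity_size_slope))
  invisible(x)
}

#' Read a particle table from CSV
#'
#' Accepts either the wide format
#' `particle_id,area_um2,perimeter_um[,composition]` or the long vertex
#' format `particle_id,vertex_index,x_um,y_um[,composition]`.
#'
#' @param path CSV path (UTF-8, header row required).
#' @return a list of [particle_shape()] objects.
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("area_um2", "perimeter_um") %in% names(df))) {
    return(lapply(seq_len(nrow(df)), function(i)
      particle_shape(particle_id = as.character(df$particle_id[i]),
                     area_um2 = df$area_um2[i],
                     perimeter_um = df$perimeter_um[i],
                     composition = if ("composition" %in% names(df))
                       df$composition[i] else NA_character_)))
  }
  if (all(c("vertex_index", "x_um", "y_um") %in% names(df))) {
    split_df <- split(df[order(df$vertex_index), ], df$particle_id)
    return(unname(lapply(split_df, function(d)
      particle_shape(particle_id = as.character(d$particle_id[1]),
                     vertices = cbind(d$x_um, d$y_um),
                     composition = if ("composition" %in% names(d))
                       d$composition[1] else NA_character_))))
  }
  stop("unrecognized particle CSV: need area_um2/perimeter_um or ",
       "vertex_index/x_um/y_um columns", call. = FALSE)
}
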
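# Shared fixtures and independent oracles, built in code at test time.

# the field mean efficacy assay points (brushing and washing)
field_assays <- function() {
  data.frame(behavior = c("brushing", "washing"),
             time_s = c(2.97, 3.53),
             removal_fraction = c(0.75, 0.93),
             removal_fraction_sd = c(0.07, 0.04))
}

# independent grid-search maximizer of R(t) = t/((c+t)(h+t)):
# coarse pass then refinement to `step` resolution; never calls
# optimal_cleaning_time()
grid_argmax_rate <- function(c, h, step = 1e-4) {
  R <- function(t) t / ((c + t) * (h + t))
  hi <- 2 * sqrt(c * h) + 1
  t1 <- seq(step, hi, length.out = 5000L)
  best <- t1[which.max(R(t1))]
  t2 <- seq(max(step, best - 2 * (t1[2] - t1[1])),
            best + 2 * (t1[2] - t1[1]), by = step)
  t2[which.max(R(t2))]
}

# random simple convex polygon: convex hull of uniform points
random_convex_polygon <- function(n_pts = 12, scale = 10) {
  pts <- matrix(stats::runif(2 * n_pts, -scale, scale), ncol = 2)
  pts[grDevices::chull(pts), , drop = FALSE]
}

# O(n^2) all-pairs oracle for the maximum Feret diameter, over every
# vertex (not just the hull)
brute_max_feret <- function(v) {
  best <- 0
  for (i in seq_len(nrow(v) - 1L))
    for (j in (i + 1L):nrow(v))
      best <- max(best, sqrt(sum((v[i, ] - v[j, ])^2)))
  best
}

# brute-force caliper width at a fine angular grid
brute_min_feret <- function(v, step_deg = 0.1) {
  th <- seq(0, pi, by = step_deg * pi / 180)
  widths <- vapply(th, function(a) {
    p <- v %*% c(cos(a), sin(a))
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

regular_ngon <- function(n, diameter = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  (diameter / 2) * cbind(cos(th), sin(th))
}

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

# minimal valid bout table
make_bouts <- function() {
  data.frame(
    bout_id = paste0("b", 1:6),
    trial_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    individual_id = c("a", "b", "a", "c", "b", "c"),
    sex = c("M", "F", "M", "F", "F", "F"),
    ordinal_rank = c(1L, 2L, 1L, 3L, 2L, 3L),
    age_class = "adult",
    treatment = c("low", "high", "intermediate", "high", "low", "high"),
    brushing_s = c(0, 3.4, 1.2, 2, 0, 4),
    washing_s = c(0, 0, 0, 3.1, 0.5, 2.5),
    travel_s = c(0, 0, 0, 21, 15, 30),
    slices_consumed = c(1L, 2L, 1L, 3L, 1L, 2L),
    bout_duration_s = c(5, 10, 8, 40, 25, 45),
    trial_participants = c(2L, 2L, 1L, 1L, 4L, 4L))
}
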
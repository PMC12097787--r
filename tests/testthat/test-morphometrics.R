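test_that("circularity hits its definitional anchors", {
  expect_equal(circularity(pi, 2 * pi), 1)          # circle
  expect_equal(circularity(1, 4), pi / 4)           # unit square
  sq <- particle_shape("sq", vertices = unit_square())
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-9)
  expect_error(circularity(1, 0), "perimeter")
})

test_that("circularity of any simple polygon is at most 1 after clipping", {
  set.seed(5)
  for (i in 1:50) {
    v <- random_convex_polygon(sample(5:20, 1))
    expect_lte(circularity(particle_shape(vertices = v)), 1)
  }
  # a near-circle whose digitized ratio could round above 1 stays clipped
  expect_lte(circularity(particle_shape(vertices = regular_ngon(720))), 1)
})

test_that("circularity is scale-invariant", {
  set.seed(6)
  v <- random_convex_polygon(10)
  base <- circularity(particle_shape(vertices = v))
  for (k in c(1e-3, 0.5, 7, 1e4))
    expect_equal(circularity(particle_shape(vertices = v * k)), base,
                 tolerance = 1e-12)
})

test_that("particle records recompute and cross-check geometry", {
  sq <- particle_shape("sq", vertices = unit_square())
  expect_equal(sq$area_um2, 1)
  expect_equal(sq$perimeter_um, 4)
  expect_silent(particle_shape(vertices = unit_square(), area_um2 = 1.0005))
  expect_error(particle_shape(vertices = unit_square(), area_um2 = 1.1),
               "0.1%")
  expect_error(particle_shape(vertices = unit_square(), perimeter_um = 3),
               "0.1%")
  expect_error(particle_shape(area_um2 = -1, perimeter_um = 2), "positive")
  expect_error(particle_shape(area_um2 = 1), "supply either")
})

test_that("Feret diameters match known geometry", {
  f_sq <- feret_diameters(unit_square())
  expect_equal(unname(f_sq["max"]), sqrt(2))
  expect_equal(unname(f_sq["min"]), 1, tolerance = 1e-3)
  expect_equal(unname(f_sq["min"]), brute_min_feret(unit_square()),
               tolerance = 1e-3)
  # circle approximated by a 360-gon: all three diameters equal d
  f_circ <- feret_diameters(regular_ngon(360, diameter = 2))
  expect_equal(unname(f_circ), c(2, 2, 2), tolerance = 2e-3)
})

test_that("caliper sweep agrees with the all-pairs oracle and orders", {
  set.seed(7)
  for (i in 1:200) {
    v <- random_convex_polygon(sample(4:15, 1))
    f <- feret_diameters(v)
    expect_equal(unname(f["max"]), brute_max_feret(v), tolerance = 1e-9)
    expect_lte(f["min"], f["mean"] + 1e-12)
    expect_lte(f["mean"], f["max"] + 1e-12)
  }
})

test_that("Feret diameters are rotation-equivariant", {
  set.seed(8)
  v <- random_convex_polygon(10)
  f0 <- feret_diameters(v)
  for (a in c(0.3, 1.1, 2.5)) {
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    f1 <- feret_diameters(v %*% rot)
    expect_equal(unname(f1["max"]), unname(f0["max"]), tolerance = 1e-9)
    # sweep-based min/mean move by at most the 1-degree discretization
    expect_equal(unname(f1["mean"]), unname(f0["mean"]), tolerance = 1e-3)
  }
})

test_that("degenerate polygons are rejected", {
  line <- cbind(0:3, 0:3)
  expect_error(feret_diameters(line), "collinear|degenerate")
  expect_error(feret_diameters(rbind(c(0, 0), c(1, 1))), "3 vertices")
})

test_that("grittiness fraction counts particles below threshold", {
  small <- data.frame(mean_feret_um = rep(10, 4))
  big <- data.frame(mean_feret_um = rep(100, 4))
  expect_equal(grittiness_fraction(small), 1)
  expect_equal(grittiness_fraction(big), 0)
  expect_equal(grittiness_fraction(rbind(small, big)), 0.5)
  expect_equal(grittiness_fraction(big, threshold_um = 200), 1)
  expect_error(grittiness_fraction(data.frame(mean_feret_um = numeric(0))),
               "no particles")
})

test_that("size-circularity trend is the OLS slope, with guards", {
  flat <- data.frame(mean_feret_um = c(10, 20, 30, 40),
                     circularity = rep(0.8, 4) + c(1, -1, 1, -1) * 1e-6)
  expect_equal(circularity_size_trend(flat)$slope, 0, tolerance = 1e-6)
  sloped <- data.frame(
    mean_feret_um = c(10, 20, 30, 40),
    circularity = 0.9 - 0.002 * c(10, 20, 30, 40) + c(1, -1, -1, 1) * 1e-5)
  expect_equal(circularity_size_trend(sloped)$slope, -0.002,
               tolerance = 1e-4)
  same <- data.frame(mean_feret_um = rep(25, 5), circularity = runif(5))
  expect_error(circularity_size_trend(same), "distinct sizes")
})

test_that("mass per area is the published ratio", {
  expect_equal(mass_per_area(3.7, 1), 3.7)   # tourist-provisioned surfaces
  expect_equal(mass_per_area(1.8, 1.0), 1.8) # high treatment
  expect_equal(mass_per_area(0, 5), 0)
  expect_error(mass_per_area(1, 0), "surface_area")
})

test_that("morphometric summaries exclude sub-cutoff particles and bin sizes", {
  df <- data.frame(mean_feret_um = c(2, 10, 20, 30, 120),
                   circularity = c(0.9, 0.9, 0.85, 0.8, 0.6))
  expect_message(s <- morphometrics_summary(df), "below the 5")
  expect_equal(s$n_particles, 4L)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$frac_below_threshold, 0.5)
  expect_equal(s$median_feret_um, 25)
  expect_equal(sum(s$size_bins), 4)
  expect_lt(s$circularity_size_slope, 0)
})

test_that("particle CSVs round-trip in both formats", {
  wide <- data.frame(particle_id = c("a", "b"), area_um2 = c(100, 400),
                     perimeter_um = c(40, 75), composition = "quartz")
  f1 <- tempfile(fileext = ".csv")
  utils::write.csv(wide, f1, row.names = FALSE)
  shapes <- read_particles(f1)
  expect_length(shapes, 2)
  expect_equal(shapes[[2]]$area_um2, 400)
  expect_equal(shapes[[1]]$composition, "quartz")

  sq <- unit_square() * 10
  long <- data.frame(particle_id = "p1", vertex_index = 1:4,
                     x_um = sq[, 1], y_um = sq[, 2])
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(long, f2, row.names = FALSE)
  shapes2 <- read_particles(f2)
  expect_equal(shapes2[[1]]$area_um2, 100)
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), f3, row.names = FALSE)
  expect_error(read_particles(f3), "unrecognized")
})
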
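test_that("internodal spacing follows the 100x-diameter convention", {
  expect_equal(internodal_length(4), 0.4)
  expect_equal(internodal_length(12), 1.2)
  expect_error(internodal_length(-1))
})

test_that("the second difference annihilates affine potentials", {
  g <- grid_around(c(0, 0, 0), 10, 0.5)
  ax <- grid_axes(g)
  pot <- array(rep(2 + 3 * ax$x, times = g$dim[2] * g$dim[3]), g$dim)
  sol <- structure(list(grid = g, potential = pot,
                        fixed = array(-1L, g$dim), temporal_scale = 1),
                   class = "field_solution")
  fiber <- cbind(seq(-4, 4, length.out = 40), 0.3, -0.2)
  d2 <- driving_force_profile(sol, fiber, diameter_um = 10)
  expect_true(all(abs(d2) < 1e-9))
})

test_that("point-source driving force at closest approach matches the closed form", {
  sol <- analytic_point_solution(current = -1, sigma = 0.2, spacing = 0.2,
                                 extent = 10)
  # straight fiber at closest approach 1 mm; 10 um fiber -> nodes 1 mm apart
  fiber <- cbind(seq(-3, 3, by = 0.05), 1, 0)
  d2 <- driving_force_profile(sol, fiber, diameter_um = 10)
  nodes <- attr(d2, "nodes")
  k <- which.min(abs(nodes[, 1]))
  # V(0) = 0.3979, V(+/-1) = 0.2814 => second difference magnitude 0.233 V,
  # depolarizing (positive) under cathodic stimulation
  expect_equal(d2[k], 0.2331, tolerance = 0.02)
  expect_gt(d2[k], 0)
})

test_that("wider fibers see a larger driving force from a point source", {
  sol <- analytic_point_solution(current = -1, sigma = 0.2, spacing = 0.2,
                                 extent = 14)
  # symmetric fiber: phase 0 places a node exactly at the closest approach
  # for both node spacings
  fiber <- cbind(seq(-4, 4, by = 0.05), 1, 0)
  peak <- function(diam) {
    d2 <- driving_force_profile(sol, fiber, diameter_um = diam)
    max(d2)
  }
  expect_gt(peak(20), peak(10))
})

test_that("thresholds are reciprocal in peak drive and monotone in pulse width and diameter", {
  sol <- analytic_point_solution(current = -1, sigma = 0.2, spacing = 0.2,
                                 extent = 14)
  fiber <- cbind(seq(-5, 5, by = 0.05), 1.5, 0)
  thr1 <- fiber_threshold(sol, fiber, diameter_um = 6, pulse_width = 60)
  sol2 <- sol
  sol2$potential <- sol$potential * 2
  thr2 <- fiber_threshold(sol2, fiber, diameter_um = 6, pulse_width = 60)
  expect_equal(thr2, thr1 / 2, tolerance = 1e-9)

  thr_long <- fiber_threshold(sol, fiber, diameter_um = 6, pulse_width = 120)
  expect_lte(thr_long, thr1)

  # 12 um thresholds below 4 um thresholds on the same trajectories
  set.seed(5)
  for (i in 1:4) {
    fb <- cbind(seq(-5, 5, by = 0.05), runif(1, 1, 3), runif(1, -1, 1))
    t12 <- fiber_threshold(sol, fb, 12)
    t4 <- fiber_threshold(sol, fb, 4)
    expect_lt(t12, t4)
  }
})

test_that("hyperpolarizing-only or too-short fibers are unevaluable", {
  # a potential concave along the fiber has negative second differences
  # everywhere: no depolarizing node, threshold infinite
  g <- grid_around(c(0, 0, 0), 10, 0.25)
  ax <- grid_axes(g)
  pot <- array(rep(-ax$x^2, times = g$dim[2] * g$dim[3]), g$dim)
  sol <- structure(list(grid = g, potential = pot,
                        fixed = array(-1L, g$dim), temporal_scale = 1),
                   class = "field_solution")
  fiber <- cbind(seq(-4, 4, by = 0.05), 1, 0)
  expect_equal(fiber_threshold(sol, fiber, 10), Inf)
  short <- cbind(seq(0, 0.5, by = 0.05), 1, 0)
  thr <- fiber_threshold(sol, short, 10)
  expect_equal(thr, Inf, ignore_attr = TRUE)
  expect_true(isTRUE(attr(thr, "unevaluable")))
  d2 <- driving_force_profile(sol, short, 10)
  expect_true(isTRUE(attr(d2, "unevaluable")))
})

test_that("percent activation counts thresholds strictly below the amplitude", {
  thr <- c(0.5, 1.5, 2.5, 3.5)
  expect_equal(percent_fibers_activated(thr, 2), 50)
  expect_equal(percent_fibers_activated(thr, 0.1), 0)
  expect_equal(percent_fibers_activated(c(thr, Inf), 100), 80)
  expect_equal(percent_fibers_activated(thr, 10), 100)
})

test_that("the excitability calibration anchors the VTA operating point", {
  k0 <- calibrate_df_k0()
  ex <- df_calibration(k0 = k0)
  # a 3.5 um fiber at the 0.2 V/mm radius of a 3 mA source has threshold 3 mA
  sol <- analytic_point_solution(current = -1, sigma = 0.2, spacing = 0.15,
                                 extent = 12)
  r_star <- sqrt(3 / (4 * pi * 0.2 * 0.2))
  fiber <- cbind(seq(-4, 4, by = 0.02), r_star, 0)
  thr <- fiber_threshold(sol, fiber, 3.5, pulse_width = 60, excitation = ex,
                         n_phase = 21)
  expect_equal(thr, 3, tolerance = 0.05)
})
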
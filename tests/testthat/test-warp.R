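make_grid <- function() vc_grid(c(-12, -12, -12), 2, c(13, 13, 13))

test_that("zero fields are the identity on every geometry type", {
  g <- make_grid()
  fld <- deformation_field(g, array(0, c(g$dim, 3)))
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(apply_warp(pts, fld), pts)
  pw <- pathway("p", list(pts), 4)
  expect_equal(apply_warp(pw, fld)$streamlines[[1]], pts)
  mask <- array(FALSE, g$dim)
  mask[5:7, 6, 6] <- TRUE
  st <- structure3d("s", mask, g)
  expect_identical(apply_warp(st, fld)$mask, mask)
  # synth with zero magnitude and unit scale is also the identity
  fld0 <- synth_deformation(g, mean_mag = 0, global_scale = 1, seed = 1)
  expect_true(all(fld0$displacement == 0))
})

test_that("uniform translation shifts all coordinates exactly", {
  g <- make_grid()
  disp <- array(0, c(g$dim, 3))
  disp[, , , 1] <- 2
  fld <- deformation_field(g, disp)
  pts <- matrix(runif(30, -8, 8), ncol = 3)
  out <- apply_warp(pts, fld)
  expect_equal(out[, 1], pts[, 1] + 2, tolerance = 1e-12)
  expect_equal(out[, 2:3], pts[, 2:3], tolerance = 1e-12)
})

test_that("a pure scaling field scales inter-point distances", {
  g <- make_grid()
  fld <- synth_deformation(g, mean_mag = 0, global_scale = 1.06, seed = 1)
  pts <- matrix(runif(30, -6, 6), ncol = 3)
  out <- apply_warp(pts, fld)
  expect_equal(as.numeric(dist(out)), 1.06 * as.numeric(dist(pts)),
               tolerance = 1e-9)
})

test_that("synthetic fields hit the target magnitude, are seeded and invertible", {
  g <- make_grid()
  f1 <- synth_deformation(g, mean_mag = 1.2, seed = 7)
  expect_equal(f1$magnitude_stat, 1.2, tolerance = 1e-9)
  f2 <- synth_deformation(g, mean_mag = 1.2, seed = 7)
  expect_identical(f1$displacement, f2$displacement)
  f3 <- synth_deformation(g, mean_mag = 1.2, seed = 8)
  expect_false(identical(f1$displacement, f3$displacement))
  expect_true(check_deformation(f1))
})

test_that("warp round-trip through the numerical inverse stays within 0.1 mm", {
  g <- make_grid()
  fld <- synth_deformation(g, mean_mag = 1.0, global_scale = 1.05, seed = 3)
  inv <- invert_deformation(fld)
  pts <- matrix(runif(60, -6, 6), ncol = 3)
  back <- apply_warp(apply_warp(pts, fld), inv)
  expect_lt(max(abs(back - pts)), 0.1)
})

test_that("mask warping keeps masks binary and respects translation", {
  g <- make_grid()
  disp <- array(0, c(g$dim, 3))
  disp[, , , 1] <- 2  # one voxel at 2 mm spacing
  fld <- deformation_field(g, disp)
  mask <- array(FALSE, g$dim)
  mask[5:7, 6:8, 6] <- TRUE
  st <- structure3d("s", mask, g)
  wst <- apply_warp(st, fld)
  expect_type(wst$mask[1], "logical")
  expect_identical(wst$mask[6:8, 6:8, 6], mask[5:7, 6:8, 6])
})

test_that("lead re-straightening recovers straight leads and fits bent ones", {
  lead <- build_lead("MDT3389")
  pl <- lead_placement(c(1, -2, 0.5), c(0.1, 0, 1) / sqrt(1.01), roll = 40)
  g <- make_grid()
  fld0 <- deformation_field(g, array(0, c(g$dim, 3)))
  w <- warp_lead_placement(lead, pl, fld0)
  fit <- restraighten_lead(lead, w)
  expect_equal(fit$tip_position, pl$tip_position, tolerance = 1e-9)
  expect_equal(fit$axis, pl$axis, tolerance = 1e-9)
  expect_equal(attr(fit, "residual_rms"), 0, tolerance = 1e-9)

  # perpendicular perturbations balanced against the axial lever arm:
  # the fitted line is the symmetry axis
  straight <- list(tip = c(0, 0, 0),
                   contacts = rbind(c(0.3, 0, 2), c(-0.3, 0, 4),
                                    c(-0.3, 0, 6), c(0.3, 0, 8)))
  fit2 <- restraighten_lead(lead, straight)
  expect_equal(abs(fit2$axis), c(0, 0, 1), tolerance = 1e-9)

  # residual equals the independent total-least-squares computation
  set.seed(13)
  bent <- list(tip = rnorm(3, sd = 0.1),
               contacts = cbind(rnorm(4, sd = 0.3), rnorm(4, sd = 0.3),
                                c(2, 4, 6, 8)))
  fit3 <- restraighten_lead(lead, bent)
  expect_equal(attr(fit3, "residual_rms"),
               tls_residual(rbind(bent$tip, bent$contacts)), tolerance = 1e-9)

  # idempotence: re-straightening a straight lead's own contacts is stable
  w3 <- list(tip = fit3$tip_position,
             contacts = as.matrix(contact_positions(lead, fit3)[, c("wx", "wy", "wz")]))
  fit4 <- restraighten_lead(lead, w3)
  expect_equal(fit4$axis, fit3$axis, tolerance = 1e-8)
  expect_equal(fit4$tip_position, fit3$tip_position, tolerance = 1e-6)
  expect_error(restraighten_lead(lead, list(tip = c(0, 0, 0),
                                            contacts = rbind(c(0, 0, 2)))),
               "3 points")
})
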
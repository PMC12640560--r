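test_that("voxelized VTA radius matches the closed form within one voxel", {
  fx <- fixture_homog_field()
  vta <- build_vta(fx$sol, threshold = 0.2)
  r_eq <- (3 * vta$volume_mm3 / (4 * pi))^(1 / 3)
  r_theory <- sqrt(1 / (4 * pi * 0.2 * 0.2))  # ~1.41 mm at 1 mA
  expect_lt(abs(r_eq - r_theory), fx$grid$spacing)
})

test_that("VTA thresholding is monotone in amplitude and empty when subthreshold", {
  fx <- fixture_homog_field()
  vta1 <- build_vta(fx$sol, threshold = 0.2)
  s2 <- stim_setting(1, NULL, amplitude = 2, lead = fx$lead)
  vta2 <- build_vta(field_from_basis(fx$basis, s2), threshold = 0.2)
  expect_gt(vta2$volume_mm3, vta1$volume_mm3)
  expect_true(all(vta2$mask[vta1$mask]))  # level sets nest
  empty <- build_vta(fx$sol, threshold = 1e6)
  expect_equal(empty$volume_mm3, 0)
})

test_that("disconnected suprathreshold islands are not part of the VTA", {
  g <- grid_around(c(0, 0, 0), 10, 0.5)
  e <- array(0, g$dim)
  fixed <- array(-1L, g$dim)
  ctr <- (g$dim + 1) %/% 2
  fixed[ctr[1], ctr[2], ctr[3]] <- 0L          # active contact voxel
  e[ctr[1] + (-2:2), ctr[2], ctr[3]] <- 1      # blob attached to the contact
  e[ctr[1] + 8, ctr[2] + 8, ctr[3]] <- 1       # distant island
  sol <- structure(list(grid = g, efield = e, fixed = fixed,
                        active_contacts = 1L,
                        setting = NULL), class = "field_solution")
  vta <- build_vta(sol, threshold = 0.5)
  expect_true(vta$mask[ctr[1] + 2, ctr[2], ctr[3]])
  expect_false(vta$mask[ctr[1] + 8, ctr[2] + 8, ctr[3]])
})

test_that("voxel-overlap percentages are exact counts", {
  vta <- sphere_vta(2, spacing = 0.5, extent = 10)
  inside <- array(FALSE, vta$grid$dim)
  ctr <- (vta$grid$dim + 1) %/% 2
  inside[ctr[1] + 0:1, ctr[2], ctr[3]] <- TRUE
  expect_equal(structure_overlap_voxels(vta, inside), 100)
  outside <- array(FALSE, vta$grid$dim)
  outside[1:2, 1, 1] <- TRUE
  expect_equal(structure_overlap_voxels(vta, outside), 0)
  half <- array(FALSE, vta$grid$dim)
  half[ctr[1] + 0:3, ctr[2], ctr[3]] <- TRUE  # 4 in (r<=2), 4 out
  half[1:4, 1, 1] <- TRUE
  expect_equal(structure_overlap_voxels(vta, half), 50)
  expect_error(structure_overlap_voxels(vta, array(FALSE, vta$grid$dim)),
               "empty")
})

test_that("vertex-overlap uses the containing-voxel floor convention", {
  vta <- sphere_vta(2, spacing = 0.5, extent = 10)
  ins <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, -1, 0))
  expect_equal(structure_overlap_vertices(vta, ins), 100)
  half <- rbind(c(0, 0, 0), c(5, 5, 5))
  expect_equal(structure_overlap_vertices(vta, half), 50)
  expect_error(structure_overlap_vertices(vta, matrix(numeric(0), ncol = 3)),
               "vertices")
  # a vertex exactly on a voxel boundary belongs to the upper voxel
  g <- vc_grid(c(0, 0, 0), 1, c(4, 4, 4))
  mask <- array(FALSE, g$dim)
  mask[3, 1, 1] <- TRUE  # voxel centred at x = 2
  vta2 <- structure(list(mask = mask, grid = g, threshold = 0.2,
                         volume_mm3 = 1, setting = NULL),
                    class = "vta_volume")
  on_boundary <- rbind(c(1.5, 0, 0))  # boundary between voxels at 1 and 2
  expect_equal(structure_overlap_vertices(vta2, on_boundary), 100)
})

test_that("streamline counting matches the brute-force oracle", {
  vta <- sphere_vta(2, spacing = 0.4, extent = 12)
  line_at <- function(d) cbind(seq(-5, 5, length.out = 30), d, 0.1)
  pw <- pathway("toy", list(line_at(0), line_at(1), line_at(4), line_at(5)),
                fiber_diameter = 4)
  pct <- fibers_through_vta(vta, pw)
  expect_equal(as.numeric(pct), 50)  # 2 of 4 cross the r = 2 sphere
  # tangent line at 3 mm from a 2 mm sphere is not counted
  expect_false(attr(fibers_through_vta(vta, pathway("t", list(line_at(3)), 4)),
                    "hits"))
  # empty mask counts nothing
  empty <- vta; empty$mask[] <- FALSE
  expect_equal(as.numeric(fibers_through_vta(empty, pw)), 0)
  expect_error(fibers_through_vta(vta, list(streamlines = list())), "no streamlines")

  # randomized instances against exhaustive 10x-finer point-in-mask testing
  set.seed(21)
  for (rep in 1:3) {
    sls <- lapply(1:15, function(i) {
      start <- runif(3, -5, 5)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      outer(seq(0, 10, length.out = 25), dir) +
        matrix(start, 25, 3, byrow = TRUE)
    })
    pwr <- pathway("rand", sls, 4)
    expect_equal(as.numeric(fibers_through_vta(vta, pwr, step = 0.4)),
                 fibers_through_bruteforce(vta, pwr, step = 0.4))
  }
})

test_that("polyline resampling preserves arc length structure", {
  line <- cbind(seq(0, 10, by = 0.1), 0, 0)
  rs <- resample_polyline(line, step = 1)
  expect_equal(nrow(rs), 11)
  expect_equal(rs[, 1], 0:10, tolerance = 1e-9)
  ph <- resample_polyline(line, step = 1, phase = 0.25)
  expect_equal(ph[1, 1], 0.25, tolerance = 1e-9)
})
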
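test_that("every catalog lead resolves with the expected contact layout", {
  cat <- lead_catalog()
  expect_setequal(names(cat),
                  c("MDT3387", "MDT3389", "BSC2201", "ABT6172", "BSC2202"))
  for (nm in names(cat)) {
    lead <- build_lead(nm)
    expect_gte(nrow(lead$contacts), 4)
    expect_true(all(lead$contacts$z_lo > 0))
    # contacts ordered distal to proximal, never overlapping axially
    by_level <- unique(lead$contacts[, c("level", "z_lo", "z_hi")])
    by_level <- by_level[order(by_level$level), ]
    expect_true(all(diff(by_level$z_lo) > 0))
    expect_true(all(by_level$z_lo[-1] >= by_level$z_hi[-nrow(by_level)]))
  }
  std <- build_lead("MDT3389")
  expect_equal(nrow(std$contacts), 4)
  expect_true(all(std$contacts$full_ring))
  steer <- build_lead("ABT6172")
  expect_equal(nrow(steer$contacts), 8)  # 1-3-3-1
  expect_equal(sum(!steer$contacts$full_ring), 6)
  expect_equal(length(unique(steer$contacts$level[!steer$contacts$full_ring])), 2)
  # segmented sectors of one level are disjoint and sum to < 360 degrees
  segs <- steer$contacts[!steer$contacts$full_ring & steer$contacts$level == 2, ]
  expect_lt(sum(segs$ang_end - segs$ang_start), 360)
})

test_that("unknown lead names give a catalog error listing valid keys", {
  expect_error(build_lead("XYZ"), "MDT3389")
})

test_that("contact positions obey the placement transform", {
  lead <- build_lead("MDT3389")
  identity <- lead_placement(c(0, 0, 0), c(0, 0, 1), 0)
  cp0 <- contact_positions(lead, identity)
  # canonical frame: ring centres on the +z axis
  expect_true(all(abs(cp0$wx) < 1e-12 & abs(cp0$wy) < 1e-12))
  # distal contact centre sits tip_length + height/2 above the tip
  expect_equal(cp0$wz[1], lead$tip_length + lead$contact_height / 2)

  # rotation 90 degrees about x maps +z onto +y; distances are preserved
  rot <- lead_placement(c(0, 0, 0), c(0, 1, 0), 0)
  cp1 <- contact_positions(lead, rot)
  expect_true(all(abs(cp1$wz) < 1e-9 & abs(cp1$wx) < 1e-9))
  d0 <- dist(as.matrix(cp0[, c("wx", "wy", "wz")]))
  d1 <- dist(as.matrix(cp1[, c("wx", "wy", "wz")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)

  expect_error(lead_placement(c(0, 0, 0), c(0, 0, 2)), "unit norm")
})

test_that("rigid-placement isometry holds for random placements", {
  lead <- build_lead("BSC2202")
  cp0 <- contact_positions(lead, lead_placement())
  d0 <- as.numeric(dist(as.matrix(cp0[, c("wx", "wy", "wz")])))
  set.seed(11)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    pl <- lead_placement(rnorm(3, 0, 10), ax, runif(1, 0, 360))
    cp <- contact_positions(lead, pl)
    d <- as.numeric(dist(as.matrix(cp[, c("wx", "wy", "wz")])))
    expect_equal(d, d0, tolerance = 1e-10)
  }
})

test_that("roll rotates segmented sector centroids about the axis", {
  lead <- build_lead("ABT6172")
  cp0 <- contact_positions(lead, lead_placement(roll = 0))
  cp1 <- contact_positions(lead, lead_placement(roll = 120))
  seg0 <- cp0[!cp0$full_ring, ]
  seg1 <- cp1[!cp1$full_ring, ]
  th <- 120 * pi / 180
  expect_equal(seg1$wx, cos(th) * seg0$wx - sin(th) * seg0$wy, tolerance = 1e-10)
  expect_equal(seg1$wy, sin(th) * seg0$wx + cos(th) * seg0$wy, tolerance = 1e-10)
  expect_equal(seg1$wz, seg0$wz)
})

test_that("settings menus expand to the cartesian product", {
  lead <- build_lead("MDT3389")
  s <- enumerate_settings(lead, list(monopolar = "each",
                                     amplitudes_mA = c(1, 3, 5)))
  expect_equal(nrow(s), 12)  # 4 cathodes x 3 amplitudes
  expect_true(all(s$case_return))
  expect_false(any(s$directional))

  b <- enumerate_settings(lead, list(
    bipolar = list(list(cathode = 1, anode = 2)), amplitudes_mA = 2))
  expect_equal(nrow(b), 1)
  expect_false(b$directional)
  expect_false(b$case_return)

  expect_error(enumerate_settings(lead, list()), "empty")
  # pure function: the same menu gives identical settings
  s2 <- enumerate_settings(lead, list(monopolar = "each",
                                      amplitudes_mA = c(1, 3, 5)))
  expect_identical(s, s2)
})

test_that("directional flags follow segmented-contact use, pseudo-ring excluded", {
  lead <- build_lead("ABT6172")
  seg_idx <- lead$contacts$index[!lead$contacts$full_ring &
                                   lead$contacts$level == 2]
  one_seg <- enumerate_settings(lead, list(monopolar = list(seg_idx[1]),
                                           amplitudes_mA = 1))
  expect_true(one_seg$directional)
  pseudo <- enumerate_settings(lead, list(monopolar = list(seg_idx),
                                          amplitudes_mA = 1))
  expect_false(pseudo$directional)
  ring <- enumerate_settings(lead, list(monopolar = list(1L),
                                        amplitudes_mA = 1))
  expect_false(ring$directional)
})

test_that("stim_setting enforces its invariants", {
  lead <- build_lead("MDT3389")
  expect_error(stim_setting(integer(0), NULL, 1), "nonempty")
  expect_error(stim_setting(1, NULL, 0), "amplitude")
  expect_error(stim_setting(1, 1, 2), "disjoint")
  expect_error(stim_setting(9, NULL, 1, lead = lead), "outside")
  s <- stim_setting(1, NULL, 2, lead = lead)
  expect_true(s$case_return)
})
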
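test_that("point-source closed form behaves as the analytic oracle", {
  expect_equal(point_source_potential(1, 0.2, 1), 1 / (4 * pi * 0.2),
               tolerance = 1e-12)
  expect_equal(round(point_source_potential(1, 0.2, 1), 4), 0.3979)
  expect_equal(point_source_potential(0, 0.3, 5), 0)
  expect_equal(point_source_potential(1, 0.2, 2),
               point_source_potential(1, 0.2, 1) / 2)
  expect_error(point_source_potential(1, 0.2, 0), "r must be")
  expect_error(point_source_potential(1, -1, 1), "sigma")
})

test_that("monopolar lead field matches the point source at mid radii and scales linearly", {
  fx <- fixture_homog_field()
  sol <- fx$sol
  ax <- grid_axes(fx$grid)
  cp <- contact_positions(fx$lead, fx$placement)
  kz <- which.min(abs(ax$z - cp$wz[1]))
  jy <- which.min(abs(ax$y))
  # mid radii: within ~2 mm the 1.5 mm cylindrical contact is legitimately
  # not a point source
  for (r in c(3, 4, 6, 8)) {
    i <- which.min(abs(ax$x - r))
    d <- sqrt(ax$x[i]^2 + (ax$z[kz] - cp$wz[1])^2)
    v <- sol$potential[i, jy, kz]
    va <- point_source_potential(-1, 0.2, d)
    expect_lt(abs(v - va) / abs(va), 0.05)
  }
  # amplitude x2 doubles the potential everywhere (linearity)
  s2 <- stim_setting(1, NULL, amplitude = 2, lead = fx$lead)
  sol2 <- field_from_basis(fx$basis, s2)
  expect_equal(sol2$potential, 2 * sol$potential, tolerance = 1e-10)
})

test_that("discretization error decreases under grid refinement", {
  err_at <- function(spacing) {
    g <- grid_around(c(0, 0, 0), 16, spacing)
    sig <- array(0.2, g$dim)
    fixed <- array(-1L, g$dim)
    ctr <- (g$dim + 1) %/% 2
    fixed[ctr[1], ctr[2], ctr[3]] <- 0L
    res <- dbscompare:::sor_solve(as.numeric(sig), as.integer(fixed), 1,
                                  g$dim, spacing, g$origin, c(0, 0, 0), 0L,
                                  2 / (1 + sin(pi / max(g$dim))), 1e-7, 20000)
    cur <- dbscompare:::contact_currents(res$potential, as.numeric(sig),
                                         as.integer(fixed), g$dim, spacing, 1L)
    phi <- res$potential / cur
    ax <- grid_axes(g)
    ctr2 <- ctr[2]
    errs <- vapply(c(2, 3, 4, 6), function(r) {
      i <- which.min(abs(ax$x - r))
      abs(phi[i, ctr2, ctr2] - point_source_potential(1, 0.2, ax$x[i])) /
        point_source_potential(1, 0.2, ax$x[i])
    }, numeric(1))
    max(errs)
  }
  e_coarse <- err_at(1.0)
  e_fine <- err_at(0.5)
  expect_lt(e_fine, 0.05)
  expect_lt(e_fine, e_coarse)
})

test_that("superposition over boundary specs and sign symmetry hold", {
  fx <- fixture_homog_field()
  s_mono1 <- stim_setting(1, NULL, amplitude = 1, lead = fx$lead)
  s_mono3 <- stim_setting(3, NULL, amplitude = 1, lead = fx$lead)
  sol1 <- field_from_basis(fx$basis, s_mono1)
  sol3 <- field_from_basis(fx$basis, s_mono3)
  # two simultaneous cathodes at half current each = sum of halves
  s_pair <- stim_setting(c(1, 3), NULL, amplitude = 1, lead = fx$lead)
  solp <- field_from_basis(fx$basis, s_pair)
  expect_equal(solp$potential, (sol1$potential + sol3$potential) / 2,
               tolerance = 1e-8)
  # reversing cathode and anode negates the field exactly
  bip <- stim_setting(1, 2, amplitude = 2, lead = fx$lead)
  rev <- stim_setting(2, 1, amplitude = 2, lead = fx$lead)
  expect_equal(field_from_basis(fx$basis, bip)$potential,
               -field_from_basis(fx$basis, rev)$potential, tolerance = 1e-10)
})

test_that("floating passive contacts carry no net current and are equipotential", {
  fx <- fixture_homog_field()
  sol <- fx$sol  # cathode at contact 1; contacts 2-4 float
  vox <- dbscompare:::voxelize_lead(fx$lead, fx$placement, fx$grid)
  cur <- dbscompare:::contact_currents(sol$potential,
                                       as.numeric(array(0.2, fx$grid$dim)),
                                       as.integer(vox$fixed), fx$grid$dim,
                                       fx$grid$spacing, 4L)
  expect_lt(max(abs(cur[2:4])), 0.01 * abs(cur[1]))
  expect_equal(cur[1], -1, tolerance = 0.01)
  # Dirichlet construction: each passive contact is one equipotential value
  expect_length(sol$contact_voltages, 4)
  expect_true(all(is.finite(sol$contact_voltages)))
})

test_that("the encapsulation scar raises the potential just outside it at fixed current", {
  fx <- fixture_homog_field()
  cond_scar <- conductivity_df_scar(fx$grid, fx$lead, fx$placement)
  basis_s <- solve_lead_basis(fx$lead, fx$placement, cond_scar, fx$opts)
  s <- stim_setting(1, NULL, amplitude = 1, lead = fx$lead)
  sol_s <- field_from_basis(basis_s, s)
  ax <- grid_axes(fx$grid)
  cp <- contact_positions(fx$lead, fx$placement)
  kz <- which.min(abs(ax$z - cp$wz[1]))
  jy <- which.min(abs(ax$y))
  for (r in c(1.5, 2, 3)) {
    i <- which.min(abs(ax$x - r))
    expect_gt(abs(sol_s$potential[i, jy, kz]),
              abs(fx$sol$potential[i, jy, kz]))
  }
  # and the contact potential magnitude rises with the extra series layer
  expect_gt(abs(sol_s$contact_voltages[1]), abs(fx$sol$contact_voltages[1]))
})

test_that("scar conductivity map validates its resolution precondition", {
  lead <- build_lead("MDT3389")
  pl <- lead_placement()
  g <- grid_around(c(0, 0, 5), 20, 0.6)
  expect_error(conductivity_df_scar(g, lead, pl), "scar thickness")
})

test_that("E-field magnitude matches the analytic point-source field", {
  sol <- analytic_point_solution(current = 1, sigma = 0.2, spacing = 0.2,
                                 extent = 8)
  e <- efield_magnitude(sol)
  ax <- grid_axes(sol$grid)
  ctr <- which.min(abs(ax$x))
  i <- which.min(abs(ax$x - 1))
  # |E| = I/(4 pi sigma r^2) = 0.3979 V/mm at r = 1
  expect_equal(e[i, ctr, ctr], 0.3979, tolerance = 0.05)
  # radial symmetry at equal radii
  expect_equal(e[i, ctr, ctr], e[ctr, i, ctr], tolerance = 1e-9)
  # uniform potential -> zero field
  zero <- sol
  zero$potential <- array(3, sol$grid$dim)
  expect_true(all(efield_magnitude(zero) == 0))
})

test_that("temporal scaling is separable, monotone in pulse width, and validated", {
  fx <- fixture_homog_field()
  f60 <- dbscompare:::temporal_factor(60)
  f120 <- dbscompare:::temporal_factor(120)
  expect_true(f60 >= 0.8 && f60 <= 1)
  expect_lt(f120, f60)
  scaled <- temporal_scale(fx$sol, pulse_width = 60)
  expect_equal(scaled$temporal_scale, f60)
  expect_equal(scaled$potential, fx$sol$potential * f60)
  # spatial argmax of |E| unchanged by scaling
  expect_equal(which.max(scaled$efield), which.max(fx$sol$efield))
  # a pulse width of zero is the t = 0 field: identity
  ident <- temporal_scale(fx$sol, pulse_width = 0)
  expect_equal(ident$potential, fx$sol$potential)
  expect_error(temporal_scale(fx$sol, circuit = list(r_access_ohm = -1,
                                                     c_dl_uF = 1)),
               "positive")
})

test_that("a lead too close to the domain edge is rejected", {
  lead <- build_lead("BSC2201")
  pl <- lead_placement()
  g <- grid_around(c(0, 0, 8), 20, 0.5)  # 8-ring lead spans ~16.6 mm
  cond <- conductivity_homogeneous(g)
  expect_error(solve_lead_basis(lead, pl, cond), "margin")
})
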
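#' Analytic point-source potential
#'
#' Extracellular potential of a monopolar point current source in an
#' infinite homogeneous isotropic medium, `V = I / (4 pi sigma r)`. With
#' current in mA, conductivity in S/m and distance in mm the result is in
#' volts. Serves as the closed-form oracle for the numerical solver.
#'
#' @param current source current, mA.
#' @param sigma conductivity, S/m.
#' @param r distance from the source, mm (> 0).
#' @return potential, V.
#' @examples
#' point_source_potential(1, 0.2, 1)  # 0.3979 V
#' @export
point_source_potential <- function(current, sigma, r) {
  if (any(r <= 0)) stop("r must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  current / (4 * pi * sigma * r)
}

#' Solver options
#'
#' @param spacing grid spacing, mm.
#' @param extent edge length of the cubic solution domain, mm, centred on
#'   the contact array.
#' @param tol SOR convergence tolerance (max per-sweep update relative to
#'   the Dirichlet voltage scale).
#' @param max_iter maximum SOR sweeps.
#' @param omega over-relaxation factor; `NULL` picks the model-problem
#'   optimum `2 / (1 + sin(pi / N))` for the largest grid dimension `N`.
#' @param boundary `"radiation"` (inverse-distance transparent boundary,
#'   ground at infinity; default) or `"ground"` (hard 0 V box).
#' @return list of class `solver_options`.
#' @export
solver_options <- function(spacing = 0.25, extent = 40, tol = 1e-6,
                           max_iter = 20000, omega = NULL,
                           boundary = c("radiation", "ground")) {
  boundary <- match.arg(boundary)
  structure(list(spacing = spacing, extent = extent, tol = tol,
                 max_iter = max_iter, omega = omega, boundary = boundary),
            class = "solver_options")
}

#' Default solution grid for a placed lead
#'
#' Cubic grid centred on the centroid of the contact array.
#' @param lead,placement the placed lead.
#' @param opts a [solver_options()].
#' @return a `vc_grid`.
#' @export
default_solver_grid <- function(lead, placement, opts = solver_options()) {
  cp <- contact_positions(lead, placement)
  grid_around(colMeans(as.matrix(cp[, c("wx", "wy", "wz")])),
              opts$extent, opts$spacing)
}

#' Per-contact unit-voltage basis solutions
#'
#' Solves one Laplace problem per contact (that contact at 1 V, all others
#' at 0 V, outer boundary grounded) and assembles the contact conductance
#' matrix `G` (`G[j, k]` = current in mA into tissue through contact `j`
#' when contact `k` is at 1 V). Any stimulation setting, including ones
#' with floating (passive) contacts, is then a superposition: contact
#' voltages solve `G v = I_injected`, with injected current 0 at passive
#' contacts, which enforces the floating-potential conditions
#' (equipotential surface, zero net current) exactly.
#'
#' @param lead a `dbs_lead`.
#' @param placement a `lead_placement`.
#' @param cond a `conductivity_map`; its grid defines the domain.
#' @param opts a [solver_options()] (tolerances; the grid comes from `cond`).
#' @return a `lead_basis` object.
#' @export
solve_lead_basis <- function(lead, placement, cond, opts = solver_options()) {
  grid <- cond$grid
  vox <- voxelize_lead(lead, placement, grid)
  ncontacts <- nrow(lead$contacts)
  cp <- contact_positions(lead, placement)
  center <- colMeans(as.matrix(cp[, c("wx", "wy", "wz")]))
  margin <- min(abs(c(center - grid$origin,
                      grid$origin + (grid$dim - 1) * grid$spacing - center)))
  span <- diff(contact_span(lead)) / 2
  if (margin - span < 5)
    stop("lead contact array must fit inside the grid with >= 5 mm margin")
  omega <- opts$omega %||% (2 / (1 + sin(pi / max(grid$dim))))
  bnd <- if (opts$boundary == "radiation") 0L else 1L
  fields <- vector("list", ncontacts)
  G <- matrix(0, ncontacts, ncontacts)
  for (k in seq_len(ncontacts)) {
    vals <- numeric(ncontacts)
    vals[k] <- 1
    res <- sor_solve(as.numeric(cond$sigma), as.integer(vox$fixed), vals,
                     grid$dim, grid$spacing, grid$origin, center, bnd,
                     omega, opts$tol, opts$max_iter)
    if (!res$converged)
      stop("SOR solver did not converge within ", opts$max_iter,
           " sweeps (max update ", signif(res$max_delta, 3), " V)")
    fields[[k]] <- res$potential
    G[, k] <- contact_currents(res$potential, as.numeric(cond$sigma),
                               as.integer(vox$fixed), grid$dim, grid$spacing,
                               ncontacts)
  }
  structure(list(lead = lead, placement = placement, grid = grid,
                 fixed = vox$fixed, fields = fields, G = G,
                 provenance = cond$provenance, opts = opts, center = center),
            class = "lead_basis")
}

# injected-current vector (mA) for a setting; cathodic current is negative
setting_currents <- function(setting, ncontacts) {
  b <- numeric(ncontacts)
  ca <- setting$cathodes[[1]]
  an <- setting$anodes[[1]]
  amp <- setting$amplitude_mA
  b[ca] <- b[ca] - amp / length(ca)
  if (!setting$case_return) b[an] <- b[an] + amp / length(an)
  b
}

#' Solve the static field for a stimulation setting
#'
#' Quasi-static potential and E-field magnitude for one stimulation setting,
#' by superposition of the per-contact basis solutions. Passive contacts
#' float (equipotential, zero net current); for monopolar (case-return)
#' settings the return current flows through the grounded outer boundary.
#'
#' @param lead,placement the placed lead.
#' @param setting one-row settings tibble (see [stim_setting()]).
#' @param cond a `conductivity_map`.
#' @param opts a [solver_options()].
#' @param basis optionally a precomputed [solve_lead_basis()] result (must
#'   match the lead/placement/conductivity); avoids re-solving.
#' @return A `field_solution`: list with `grid`, `potential` (V),
#'   `efield` (V/mm), `contact_voltages`, `contact_currents` (mA),
#'   `setting`, `provenance`, `temporal_scale` (1 until
#'   [temporal_scale()] is applied) and the voxel classification `fixed`.
#' @export
solve_static_field <- function(lead, placement, setting, cond,
                               opts = solver_options(), basis = NULL) {
  if (is.null(basis)) basis <- solve_lead_basis(lead, placement, cond, opts)
  field_from_basis(basis, setting)
}

#' Combine basis solutions into a field for one setting
#' @param basis a `lead_basis`.
#' @param setting one-row settings tibble.
#' @return a `field_solution` (see [solve_static_field()]).
#' @export
field_from_basis <- function(basis, setting) {
  n <- nrow(basis$lead$contacts)
  b <- setting_currents(setting, n)
  v <- solve(basis$G, b)
  pot <- array(0, basis$grid$dim)
  for (k in seq_len(n)) if (v[k] != 0) pot <- pot + v[k] * basis$fields[[k]]
  sol <- structure(list(grid = basis$grid, potential = pot,
                        fixed = basis$fixed,
                        contact_voltages = v, contact_currents = b,
                        setting = setting, provenance = basis$provenance,
                        temporal_scale = 1,
                        active_contacts = c(setting$cathodes[[1]],
                                            setting$anodes[[1]])),
                   class = "field_solution")
  sol$efield <- efield_magnitude(sol)
  sol
}

#' E-field magnitude of a field solution
#'
#' Central-difference gradient magnitude of the potential (one-sided at the
#' lattice boundary), in V/mm. Voxels inside the electrode are set to 0.
#'
#' @param sol a `field_solution` (or any list with `potential`, `grid`,
#'   optionally `fixed`).
#' @return 3-D array, V/mm.
#' @export
efield_magnitude <- function(sol) {
  p <- sol$potential
  h <- sol$grid$spacing
  d <- dim(p)
  gd <- function(axis) {
    n <- d[axis]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    den <- (idx_p - idx_m) * h
    if (axis == 1) {
      g <- (p[idx_p, , , drop = FALSE] - p[idx_m, , , drop = FALSE]) /
        array(den, d)
    } else if (axis == 2) {
      g <- (p[, idx_p, , drop = FALSE] - p[, idx_m, , drop = FALSE]) /
        aperm(array(den, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      g <- (p[, , idx_p, drop = FALSE] - p[, , idx_m, drop = FALSE]) /
        aperm(array(den, d[c(3, 1, 2)]), c(2, 3, 1))
    }
    g
  }
  e <- sqrt(gd(1)^2 + gd(2)^2 + gd(3)^2)
  if (!is.null(sol$fixed)) e[sol$fixed != -1L] <- 0
  e
}

#' Equivalent-circuit temporal scaling
#'
#' The separable temporal approximation: the spatial field solved at t = 0
#' is multiplied by the voltage-drop factor of a 1-D equivalent circuit
#' (series access resistance and electrode double-layer capacitance)
#' evaluated at the end of the cathodic pulse,
#' `scale = exp(-pulse_width / (R_a * C_dl))`. Defaults
#' (`R_a` = 100 ohm, `C_dl` = 3.3 uF) give a scale of 0.83 at 60 us.
#'
#' @param sol a `field_solution`.
#' @param circuit list with `r_access_ohm` and `c_dl_uF` (both > 0).
#' @param pulse_width pulse width, microseconds.
#' @return the solution with `potential`, `efield` scaled and
#'   `temporal_scale` recorded; the spatial pattern is unchanged.
#' @export
temporal_scale <- function(sol, circuit = list(r_access_ohm = 100,
                                               c_dl_uF = 3.3),
                           pulse_width = 60) {
  if (circuit$r_access_ohm <= 0 || circuit$c_dl_uF <= 0)
    stop("equivalent-circuit parameters must be positive")
  tau_us <- circuit$r_access_ohm * circuit$c_dl_uF  # ohm * uF = us
  fac <- exp(-pulse_width / tau_us)
  sol$potential <- sol$potential * fac
  sol$efield <- sol$efield * fac
  sol$temporal_scale <- sol$temporal_scale * fac
  sol
}

# scalar temporal factor without a solution object (used by the DF pipeline)
temporal_factor <- function(pulse_width, circuit = list(r_access_ohm = 100,
                                                        c_dl_uF = 3.3)) {
  if (circuit$r_access_ohm <= 0 || circuit$c_dl_uF <= 0)
    stop("equivalent-circuit parameters must be positive")
  exp(-pulse_width / (circuit$r_access_ohm * circuit$c_dl_uF))
}
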
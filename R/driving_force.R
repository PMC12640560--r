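#' Internodal spacing of a myelinated axon
#'
#' Standard myelinated-fiber convention: internodal length is 100 times the
#' fiber diameter, i.e. `L [mm] = 0.1 * diameter [um]`.
#'
#' @param diameter_um fiber diameter, micrometres.
#' @return internodal spacing, mm.
#' @export
internodal_length <- function(diameter_um) {
  stopifnot(all(diameter_um > 0))
  0.1 * diameter_um
}

#' Driving-force excitability calibration
#'
#' The per-fiber threshold surrogate is
#' `threshold [mA] = k0 * (1 + tau_c / PW) / peak unit driving force`,
#' a chronaxie-form strength-duration scaling divided by the peak
#' depolarizing second difference of the extracellular potential per mA.
#' This is a documented stand-in for full multicompartment cable threshold
#' estimation: it preserves reciprocity in peak drive, strength-duration
#' behaviour, and the fiber-diameter effect through the node spacing.
#'
#' By default `k0` is calibrated (see [calibrate_df_k0()]) so that a
#' 3.5 um fiber stimulated at 60 us reaches threshold exactly at the
#' 0.2 V/mm E-field radius of a 3 mA point source in 0.2 S/m — the same
#' axon-model operating point from which the classic VTA threshold was
#' derived — which anchors the two predictors to a common excitability
#' scale. `tau_c` = 65 us is a typical myelinated-axon chronaxie.
#'
#' @param k0 rheobase-like drive constant, V.
#' @param tau_c chronaxie, microseconds.
#' @return list with `k0`, `tau_c`.
#' @export
df_calibration <- function(k0 = calibrate_df_k0(), tau_c = 65) {
  stopifnot(k0 > 0, tau_c > 0)
  list(k0 = k0, tau_c = tau_c)
}

#' Calibrate the driving-force constant against the VTA operating point
#'
#' Computes `k0` such that a straight fiber of `anchor_diameter` passing at
#' the `e_threshold` E-field radius of a point source of `anchor_current`
#' in a homogeneous medium `sigma` has threshold exactly `anchor_current`
#' at pulse width `anchor_pw`.
#'
#' @param anchor_diameter fiber diameter, um.
#' @param anchor_pw pulse width, us.
#' @param anchor_current source current, mA.
#' @param sigma conductivity, S/m.
#' @param e_threshold E-field threshold, V/mm.
#' @param tau_c chronaxie, us.
#' @return `k0`, V.
#' @export
calibrate_df_k0 <- function(anchor_diameter = 3.5, anchor_pw = 60,
                            anchor_current = 3, sigma = 0.2,
                            e_threshold = 0.2, tau_c = 65) {
  r_star <- sqrt(anchor_current / (4 * pi * sigma * e_threshold))
  L <- internodal_length(anchor_diameter)
  # peak unit drive of a straight fiber at closest approach r_star
  drive <- 2 * (point_source_potential(1, sigma, r_star) -
                  point_source_potential(1, sigma, sqrt(r_star^2 + L^2)))
  anchor_current * drive / (1 + tau_c / anchor_pw)
}

# node positions along a streamline: rows = nodes, plus a flag when the
# fiber is too short to host 3 nodes
fiber_nodes <- function(streamline, diameter_um, phase = 0) {
  L <- internodal_length(diameter_um)
  nodes <- resample_polyline(streamline, step = L, phase = phase)
  list(nodes = nodes, evaluable = nrow(nodes) >= 3, L = L)
}

#' Driving-force profile along one fiber
#'
#' Places nodes of Ranvier along the streamline's arc length at the
#' internodal spacing for the given diameter and returns the second
#' difference of the extracellular potential at each interior node,
#' `V[i-1] - 2 V[i] + V[i+1]`. With the package's signed-current
#' convention (cathodic stimulation carries negative potential) a positive
#' value is depolarizing. The second difference annihilates affine
#' potentials exactly.
#'
#' @param sol a `field_solution`.
#' @param fiber n x 3 streamline matrix, mm.
#' @param diameter_um fiber diameter, um.
#' @param phase node-placement phase along the arc, mm.
#' @return numeric vector of interior-node second differences (V), with the
#'   node positions as attribute `"nodes"`; a fiber too short for 3 nodes
#'   returns `NA` with attribute `unevaluable = TRUE`.
#' @export
driving_force_profile <- function(sol, fiber, diameter_um, phase = 0) {
  fn <- fiber_nodes(fiber, diameter_um, phase)
  if (!fn$evaluable) {
    out <- NA_real_
    attr(out, "unevaluable") <- TRUE
    return(out)
  }
  v <- interp_trilinear(sol$potential, sol$grid, fn$nodes)
  n <- length(v)
  d2 <- v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]
  attr(d2, "nodes") <- fn$nodes[2:(n - 1), , drop = FALSE]
  d2
}

#' Per-fiber activation threshold from the unit driving force
#'
#' Threshold (mA) of one fiber under one contact configuration:
#' `k0 (1 + tau_c / PW) / max depolarizing drive per mA`, where the drive
#' is evaluated from the unit-amplitude (1 mA) field solution and the node
#' placement phase is chosen to maximize the peak drive (worst-case
#' alignment; `phase_mode = "fixed"` evaluates phase 0 only). Returns
#' `Inf` when no node is depolarizing or the fiber is unevaluable
#' (attribute `"unevaluable"` set).
#'
#' @param sol_unit `field_solution` computed at 1 mA for the configuration.
#' @param fiber n x 3 streamline matrix.
#' @param diameter_um fiber diameter, um.
#' @param pulse_width pulse width, us.
#' @param excitation a [df_calibration()].
#' @param n_phase number of node-placement phases sampled over one
#'   internodal length.
#' @param phase_mode `"max"` (default, worst-case alignment) or `"fixed"`.
#' @return threshold, mA.
#' @export
fiber_threshold <- function(sol_unit, fiber, diameter_um, pulse_width = 60,
                            excitation = df_calibration(), n_phase = 5,
                            phase_mode = c("max", "fixed")) {
  phase_mode <- match.arg(phase_mode)
  L <- internodal_length(diameter_um)
  phases <- if (phase_mode == "fixed") 0 else seq(0, L, length.out = n_phase + 1)[-(n_phase + 1)]
  peak <- -Inf
  unevaluable <- TRUE
  for (ph in phases) {
    d2 <- driving_force_profile(sol_unit, fiber, diameter_um, phase = ph)
    if (isTRUE(attr(d2, "unevaluable"))) next
    unevaluable <- FALSE
    peak <- max(peak, max(d2))
  }
  if (unevaluable) {
    out <- Inf
    attr(out, "unevaluable") <- TRUE
    return(out)
  }
  if (peak <= 0) return(Inf)
  excitation$k0 * (1 + excitation$tau_c / pulse_width) / peak
}

#' Percent of fibers activated at a stimulation amplitude
#'
#' A fiber is activated when its threshold is strictly below the
#' stimulation amplitude.
#'
#' @param thresholds numeric vector of per-fiber thresholds, mA (may contain
#'   `Inf`).
#' @param amplitude stimulation amplitude, mA.
#' @return percent in `[0, 100]`.
#' @export
percent_fibers_activated <- function(thresholds, amplitude) {
  if (length(thresholds) == 0) return(0)
  100 * mean(thresholds < amplitude)
}
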
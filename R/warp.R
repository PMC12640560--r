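#' Deformation fields and normative-space emulation
#'
#' "Normative" space is emulated operationally: a smooth nonlinear
#' displacement field (random Gaussian bumps of configurable mean
#' magnitude, optionally composed with a global scaling > 1 reflecting
#' that template brains are larger than the average individual) is applied
#' to all geometry; the electric field is then recomputed around an
#' idealized straight lead fitted to the warped contacts. This reproduces
#' the mechanism by which template-space modelling degrades: anatomy is
#' warped, but the field is not.
#'
#' @name deformation
NULL

#' Construct a deformation field
#'
#' @param grid a `vc_grid`.
#' @param displacement 4-D array `c(grid$dim, 3)` of mm displacements.
#' @return A `deformation_field` with `magnitude_stat` (mean |d| over the
#'   lattice).
#' @export
deformation_field <- function(grid, displacement) {
  stopifnot(all(dim(displacement) == c(grid$dim, 3)))
  mag <- sqrt(displacement[, , , 1]^2 + displacement[, , , 2]^2 +
                displacement[, , , 3]^2)
  structure(list(grid = grid, displacement = displacement,
                 magnitude_stat = mean(mag)),
            class = "deformation_field")
}

#' Synthesize a smooth random deformation field
#'
#' Sum of `n_bumps` vector-valued Gaussian bumps, rescaled so the mean
#' displacement magnitude over the lattice equals `mean_mag`, composed
#' with a global scaling about the domain centre. `mean_mag = 0` and
#' `global_scale = 1` give the identity.
#'
#' @param grid a `vc_grid`.
#' @param mean_mag target mean displacement magnitude, mm.
#' @param global_scale global scale factor about the domain centre
#'   (template brains are slightly larger than average: > 1 expands).
#' @param n_bumps number of Gaussian bumps.
#' @param bump_sigma bump width range, mm.
#' @param seed RNG seed (integer) for reproducibility.
#' @return a `deformation_field`.
#' @export
synth_deformation <- function(grid, mean_mag = 1.0, global_scale = 1.0,
                              n_bumps = 12, bump_sigma = c(4, 9),
                              seed = 1L) {
  stopifnot(mean_mag >= 0, global_scale > 0)
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  ctr <- grid$origin + (grid$dim - 1) / 2 * grid$spacing
  disp <- array(0, c(grid$dim, 3))
  if (mean_mag > 0) {
    rs <- get_rng_state()
    on.exit(set_rng_state(rs), add = TRUE)
    set.seed(as.integer(seed))
    lo <- grid$origin
    hi <- grid$origin + (grid$dim - 1) * grid$spacing
    X <- rep(ax$x, times = ny * nz)
    Y <- rep(rep(ax$y, each = nx), times = nz)
    Z <- rep(ax$z, each = nx * ny)
    for (b in seq_len(n_bumps)) {
      c0 <- stats::runif(3, lo, hi)
      s <- stats::runif(1, bump_sigma[1], bump_sigma[2])
      a <- stats::rnorm(3)
      a <- a / sqrt(sum(a^2)) * stats::runif(1, 0.5, 1)
      w <- exp(-((X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2) / (2 * s^2))
      for (q in 1:3) disp[, , , q] <- disp[, , , q] + a[q] * w
    }
    mag <- mean(sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2))
    if (mag > 0) disp <- disp * (mean_mag / mag)
  }
  if (global_scale != 1) {
    ax <- grid_axes(grid)
    X <- rep(ax$x, times = ny * nz)
    Y <- rep(rep(ax$y, each = nx), times = nz)
    Z <- rep(ax$z, each = nx * ny)
    disp[, , , 1] <- disp[, , , 1] + (global_scale - 1) * (X - ctr[1])
    disp[, , , 2] <- disp[, , , 2] + (global_scale - 1) * (Y - ctr[2])
    disp[, , , 3] <- disp[, , , 3] + (global_scale - 1) * (Z - ctr[3])
  }
  deformation_field(grid, disp)
}

#' Check a deformation field for invertibility
#'
#' Finite-difference Jacobian determinant at every interior voxel of the
#' mapping `x -> x + d(x)`; all determinants must be positive for the
#' field to be locally invertible.
#'
#' @param field a `deformation_field`.
#' @return `TRUE` invisibly; errors when a non-positive Jacobian
#'   determinant is found.
#' @export
check_deformation <- function(field) {
  d <- field$displacement
  h <- field$grid$spacing
  gr <- function(a, axis) {
    dm <- dim(a)
    if (axis == 1) (a[c(2:dm[1], dm[1]), , ] - a[c(1, 1:(dm[1] - 1)), , ]) / (2 * h)
    else if (axis == 2) (a[, c(2:dm[2], dm[2]), ] - a[, c(1, 1:(dm[2] - 1)), ]) / (2 * h)
    else (a[, , c(2:dm[3], dm[3])] - a[, , c(1, 1:(dm[3] - 1))]) / (2 * h)
  }
  J11 <- 1 + gr(d[, , , 1], 1); J12 <- gr(d[, , , 1], 2); J13 <- gr(d[, , , 1], 3)
  J21 <- gr(d[, , , 2], 1); J22 <- 1 + gr(d[, , , 2], 2); J23 <- gr(d[, , , 2], 3)
  J31 <- gr(d[, , , 3], 1); J32 <- gr(d[, , , 3], 2); J33 <- 1 + gr(d[, , , 3], 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  if (any(det <= 0))
    stop("deformation field is not invertible: min Jacobian determinant ",
         signif(min(det), 3))
  invisible(TRUE)
}

# displacement vector interpolated at world points (n x 3)
interp_displacement <- function(field, pts) {
  cbind(interp_trilinear(field$displacement[, , , 1], field$grid, pts),
        interp_trilinear(field$displacement[, , , 2], field$grid, pts),
        interp_trilinear(field$displacement[, , , 3], field$grid, pts))
}

#' Apply a deformation field to geometry
#'
#' Points map forward, `x -> x + d(x)`, with trilinear interpolation of
#' the displacement. Masks are warped by inverse-field pull-back with
#' nearest-neighbour sampling (so they stay binary): the inverse mapping is
#' found per voxel by fixed-point iteration.
#'
#' @param geometry an n x 3 point matrix, a `pathway`, a `structure3d`, or
#'   a `lead_placement` together with its lead (see
#'   [warp_lead_placement()]).
#' @param field a `deformation_field`.
#' @return warped geometry of the same class.
#' @export
apply_warp <- function(geometry, field) UseMethod("apply_warp")

#' @export
apply_warp.default <- function(geometry, field) {
  pts <- matrix(as.numeric(geometry), ncol = 3)
  pts + interp_displacement(field, pts)
}

#' @export
apply_warp.pathway <- function(geometry, field) {
  geometry$streamlines <- lapply(geometry$streamlines,
                                 function(sl) apply_warp.default(sl, field))
  geometry
}

#' @export
apply_warp.structure3d <- function(geometry, field) {
  grid <- geometry$grid
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  tgt <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))
  src <- invert_deformation_at(field, tgt)
  vals <- points_in_mask(geometry$mask, grid, src)
  out <- geometry
  out$mask <- array(vals, grid$dim)
  if (!any(out$mask))
    stop("structure '", geometry$name, "' warped entirely out of its lattice")
  out
}

# fixed-point inversion: find y with y + d(y) = x for each row of x
invert_deformation_at <- function(field, x, iters = 5) {
  y <- x
  for (i in seq_len(iters)) y <- x - interp_displacement(field, y)
  y
}

#' Numerically invert a deformation field
#'
#' Fixed-point inversion evaluated at the field's own lattice nodes,
#' returning a `deformation_field` carrying the inverse displacement
#' (so `x -> x + d_inv(x)` undoes `x -> x + d(x)` up to interpolation
#' error).
#'
#' @param field a `deformation_field`.
#' @param iters fixed-point iterations.
#' @return a `deformation_field`.
#' @export
invert_deformation <- function(field, iters = 8) {
  g <- field$grid
  ax <- grid_axes(g)
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  tgt <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))
  src <- invert_deformation_at(field, tgt, iters = iters)
  deformation_field(g, array(src - tgt, c(g$dim, 3)))
}

#' Warp a placed lead's contact frame
#'
#' Warps the tip and world contact centres forward through the field;
#' returns the warped point set (used as input to [restraighten_lead()]).
#'
#' @param lead,placement the placed lead.
#' @param field a `deformation_field`.
#' @return list with `tip` (warped tip, 3-vector), `contacts` (warped
#'   contact centres, n x 3), `roll_marker` (warped roll reference point).
#' @export
warp_lead_placement <- function(lead, placement, field) {
  cp <- contact_positions(lead, placement)
  w <- apply_warp.default(as.matrix(cp[, c("wx", "wy", "wz")]), field)
  tip <- apply_warp.default(rbind(placement$tip_position), field)[1, ]
  marker <- lead_to_world(rbind(c(lead$shaft_radius * 2, 0,
                                  mean(contact_span(lead)))), placement)[1, ]
  list(tip = tip, contacts = w,
       roll_marker = apply_warp.default(rbind(marker), field)[1, ])
}

#' Re-straighten a warped lead
#'
#' Total-least-squares line fit (principal component of the warped tip and
#' contact centres); the returned placement has the fitted direction as
#' axis, the tip at the fitted line's foot of the warped tip, and the
#' rigid contact spacing of the lead model restored. The roll angle is
#' recovered by projecting the warped roll marker onto the plane normal to
#' the fitted axis.
#'
#' @param lead the `dbs_lead` (provides the rigid geometry to restore).
#' @param warped output of [warp_lead_placement()] (or a list with `tip`,
#'   `contacts`, optionally `roll_marker`).
#' @return a `lead_placement` with attribute `"residual_rms"` (mm), the
#'   root-mean-square perpendicular distance of the warped points from the
#'   fitted line.
#' @export
restraighten_lead <- function(lead, warped) {
  pts <- rbind(warped$tip, warped$contacts)
  if (nrow(pts) < 3) stop("need at least 3 points to re-straighten")
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE)
  axis <- pc$rotation[, 1]
  # orient from tip toward contacts
  if (sum((colMeans(warped$contacts) - warped$tip) * axis) < 0) axis <- -axis
  axis <- axis / sqrt(sum(axis^2))
  cent <- sweep(pts, 2, ctr)
  t_along <- cent %*% axis
  perp <- cent - t_along %*% t(axis)
  residual <- sqrt(mean(rowSums(perp^2)))
  tip <- ctr + as.numeric((warped$tip - ctr) %*% axis) * axis
  roll <- 0
  if (!is.null(warped$roll_marker)) {
    # reference frame: the canonical x direction mapped by axis alignment
    R0 <- rot_lead_to_world(axis, 0)
    m <- warped$roll_marker - tip
    m_perp <- m - as.numeric(m %*% axis) * axis
    if (sqrt(sum(m_perp^2)) > 1e-9) {
      xr <- R0[, 1]; yr <- R0[, 2]
      roll <- atan2(sum(m_perp * yr), sum(m_perp * xr)) * 180 / pi
    }
  }
  out <- lead_placement(tip_position = tip, axis = axis, roll = roll)
  attr(out, "residual_rms") <- residual
  out
}
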
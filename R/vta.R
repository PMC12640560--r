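#' Binary volume of tissue activated
#'
#' Thresholds the E-field magnitude of a field solution at a fixed value
#' (default 0.2 V/mm) and keeps only the 26-connected suprathreshold
#' component attached to the active contacts, so disconnected
#' suprathreshold islands do not count toward the activated volume. An
#' empty mask (fully subthreshold field) is a valid result. By convention
#' the VTA ignores pulse width and frequency: it is computed from the
#' static field only.
#'
#' @param sol a `field_solution`.
#' @param threshold E-field magnitude threshold, V/mm.
#' @return A `vta_volume`: list with logical `mask`, `grid`, `threshold`,
#'   `volume_mm3` and the originating `setting`.
#' @export
build_vta <- function(sol, threshold = 0.2) {
  supra <- sol$efield >= threshold
  supra[sol$fixed != -1L] <- FALSE
  # seeds: suprathreshold voxels within one voxel (26-neighbourhood) of an
  # active contact voxel
  act <- array(FALSE, sol$grid$dim)
  for (idx in sol$active_contacts) act <- act | (sol$fixed == idx - 1L)
  dil <- dilate26(act)
  seeds <- which(dil & supra)
  mask <- flood_fill26(supra, seeds)
  structure(list(mask = mask, grid = sol$grid, threshold = threshold,
                 volume_mm3 = sum(mask) * sol$grid$spacing^3,
                 setting = sol$setting),
            class = "vta_volume")
}

# one-step 26-neighbourhood binary dilation
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, di, dj, dk) {
    res <- array(FALSE, d)
    xs <- max(1, 1 + di):min(d[1], d[1] + di)
    ys <- max(1, 1 + dj):min(d[2], d[2] + dj)
    zs <- max(1, 1 + dk):min(d[3], d[3] + dk)
    res[xs, ys, zs] <- m[xs - di, ys - dj, zs - dk]
    res
  }
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- out | sh(mask, di, dj, dk)
  }
  out
}

#' Structure overlap, voxel convention
#'
#' Percent of structure voxels covered by the VTA:
#' `100 * |structure AND vta| / |structure|`. The structure mask must
#' already live on the VTA lattice.
#'
#' @param vta a `vta_volume`.
#' @param structure logical array on the same grid.
#' @return percent in `[0, 100]`.
#' @export
structure_overlap_voxels <- function(vta, structure) {
  stopifnot(all(dim(structure) == dim(vta$mask)))
  n <- sum(structure)
  if (n == 0) stop("structure mask is empty")
  100 * sum(structure & vta$mask) / n
}

#' Structure overlap, vertex convention
#'
#' Percent of surface-mesh vertices lying inside the VTA. A vertex is
#' inside when the voxel containing it is in the mask; the containing voxel
#' is `floor(fractional index + 0.5)`, so a vertex exactly on a voxel
#' boundary is assigned to the upper voxel (floor convention). Vertices
#' outside the lattice are outside the VTA.
#'
#' @param vta a `vta_volume`.
#' @param vertices n x 3 matrix of mesh vertices, world mm (n > 0).
#' @return percent in `[0, 100]`.
#' @export
structure_overlap_vertices <- function(vta, vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  if (nrow(vertices) == 0) stop("mesh has no vertices")
  100 * mean(points_in_mask(vta$mask, vta$grid, vertices))
}

points_in_mask <- function(mask, grid, pts) {
  f <- grid_index(grid, pts)
  idx <- floor(f + 0.5)
  ok <- idx[, 1] >= 1 & idx[, 1] <= grid$dim[1] &
        idx[, 2] >= 1 & idx[, 2] <= grid$dim[2] &
        idx[, 3] >= 1 & idx[, 3] <= grid$dim[3]
  out <- logical(nrow(pts))
  if (any(ok)) {
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * grid$dim[1] +
      (idx[ok, 3] - 1) * grid$dim[1] * grid$dim[2]
    out[ok] <- mask[lin]
  }
  out
}

#' Resample a polyline at fixed arc-length steps
#'
#' @param pts n x 3 matrix (ordered polyline, mm).
#' @param step arc-length step, mm.
#' @param phase arc-length of the first sample, mm (node-placement phase).
#' @return m x 3 matrix of resampled points.
#' @export
resample_polyline <- function(pts, step, phase = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  if (phase > total) return(matrix(numeric(0), ncol = 3))
  at <- seq(phase, total, by = step)
  if (length(at) == 0) return(matrix(numeric(0), ncol = 3))
  cbind(stats::approx(s, pts[, 1], xout = at, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = at, ties = "ordered")$y,
        stats::approx(s, pts[, 3], xout = at, ties = "ordered")$y)
}

#' Percent of pathway streamlines passing through a VTA
#'
#' A fiber counts as activated when any point of the streamline, resampled
#' at a step no coarser than the VTA grid spacing, falls inside the mask
#' (any-point inclusion convention).
#'
#' @param vta a `vta_volume`.
#' @param pathway a `pathway` object (see [pathway()]).
#' @param step resample step, mm; defaults to half the grid spacing.
#' @return percent of fibers in `[0, 100]`, with the per-fiber logical
#'   vector attached as attribute `"hits"`.
#' @export
fibers_through_vta <- function(vta, pathway, step = NULL) {
  if (length(pathway$streamlines) == 0) stop("pathway has no streamlines")
  step <- step %||% (vta$grid$spacing / 2)
  if (step > vta$grid$spacing) step <- vta$grid$spacing
  hits <- vapply(pathway$streamlines, function(sl) {
    p <- resample_polyline(sl, step)
    any(points_in_mask(vta$mask, vta$grid, p))
  }, logical(1))
  out <- 100 * mean(hits)
  attr(out, "hits") <- hits
  out
}
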
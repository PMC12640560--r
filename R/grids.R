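#' Regular 3-D lattice
#'
#' A regular, axis-aligned, isotropic 3-D voxel lattice in world (RAS,
#' millimetre) coordinates. Voxel centres sit at
#' `origin + (index - 1) * spacing` with 1-based indices; the world frame is
#' RAS mm throughout the package.
#'
#' @param origin numeric length-3, world position (mm) of the centre of voxel
#'   `(1, 1, 1)`.
#' @param spacing scalar voxel edge length (mm).
#' @param dim integer length-3, number of voxels along x, y, z.
#' @return An object of class `vc_grid`.
#' @examples
#' g <- vc_grid(origin = c(-10, -10, -10), spacing = 0.5, dim = c(41, 41, 41))
#' grid_world(g, rbind(c(1, 1, 1)))
#' @export
vc_grid <- function(origin, spacing, dim) {
  stopifnot(length(origin) == 3, length(spacing) == 1, spacing > 0,
            length(dim) == 3, all(dim >= 2))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dim = as.integer(dim)),
            class = "vc_grid")
}

#' Build a cubic grid centred on a world point
#'
#' @param center world centre (mm).
#' @param extent edge length of the cube (mm).
#' @param spacing voxel size (mm).
#' @return A `vc_grid` whose voxel centres span `center +/- extent/2`.
#' @export
grid_around <- function(center, extent, spacing) {
  n <- 2L * as.integer(ceiling(extent / (2 * spacing))) + 1L
  origin <- center - (n - 1) / 2 * spacing
  vc_grid(origin, spacing, c(n, n, n))
}

#' @export
print.vc_grid <- function(x, ...) {
  cat(sprintf("<vc_grid> %d x %d x %d voxels, %.3g mm spacing, origin (%.2f, %.2f, %.2f)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel-centre world coordinates
#'
#' @param grid a `vc_grid`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates (mm).
#' @export
grid_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, c(1, 1, 1)) * grid$spacing, 2, grid$origin, `+`)
}

#' World coordinates to (fractional) voxel indices
#'
#' @inheritParams grid_world
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of 1-based fractional indices.
#' @export
grid_index <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts, 2, grid$origin) / grid$spacing + 1
}

#' Axis coordinate vectors of a grid
#' @param grid a `vc_grid`.
#' @return list of numeric vectors `x`, `y`, `z` (voxel-centre coordinates).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing,
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing)
}

#' NIfTI-style affine of a grid (RAS mm, 0-based voxel indices)
#' @param grid a `vc_grid`.
#' @return 4 x 4 affine matrix mapping 0-based voxel indices to world mm.
#' @export
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$spacing, 3), 1))
  aff[1:3, 4] <- grid$origin
  aff
}

#' Grid from a NIfTI-style affine
#'
#' Only axis-aligned, isotropic, positively oriented affines are accepted;
#' anything else is an error (no silent resampling).
#' @param affine 4 x 4 matrix.
#' @param dim integer length-3.
#' @return a `vc_grid`.
#' @export
grid_from_affine <- function(affine, dim) {
  rot <- affine[1:3, 1:3]
  d <- diag(rot)
  if (any(abs(rot - diag(d)) > 1e-6))
    stop("affine is not axis-aligned; this lattice type requires axis-aligned volumes")
  if (any(d <= 0) || diff(range(d)) > 1e-6)
    stop("affine must be isotropic with positive spacing (got ",
         paste(signif(d, 6), collapse = ", "), ")")
  vc_grid(origin = affine[1:3, 4], spacing = mean(d), dim = dim)
}

#' Trilinear interpolation of a scalar field
#'
#' Samples a 3-D array defined on a `vc_grid` at arbitrary world points.
#' Points outside the lattice are clamped to the boundary voxel centres
#' (or return `NA` with `outside = "na"`).
#'
#' @param arr 3-D numeric array with `dim(arr) == grid$dim`.
#' @param grid the `vc_grid` the array lives on.
#' @param pts n x 3 matrix of world points (mm).
#' @param outside `"clamp"` (default) or `"na"`.
#' @return numeric vector of length n.
#' @export
interp_trilinear <- function(arr, grid, pts, outside = c("clamp", "na")) {
  outside <- match.arg(outside)
  stopifnot(all(dim(arr) == grid$dim))
  f <- grid_index(grid, pts)
  oob <- f[, 1] < 1 | f[, 1] > grid$dim[1] |
         f[, 2] < 1 | f[, 2] > grid$dim[2] |
         f[, 3] < 1 | f[, 3] > grid$dim[3]
  f[, 1] <- pmin(pmax(f[, 1], 1), grid$dim[1])
  f[, 2] <- pmin(pmax(f[, 2], 1), grid$dim[2])
  f[, 3] <- pmin(pmax(f[, 3], 1), grid$dim[3])
  i0 <- pmin(floor(f[, 1]), grid$dim[1] - 1); fx <- f[, 1] - i0
  j0 <- pmin(floor(f[, 2]), grid$dim[2] - 1); fy <- f[, 2] - j0
  k0 <- pmin(floor(f[, 3]), grid$dim[3] - 1); fz <- f[, 3] - k0
  nx <- grid$dim[1]; nxy <- grid$dim[1] * grid$dim[2]
  base <- (i0 - 1) + (j0 - 1) * nx + (k0 - 1) * nxy + 1
  v000 <- arr[base];             v100 <- arr[base + 1]
  v010 <- arr[base + nx];        v110 <- arr[base + nx + 1]
  v001 <- arr[base + nxy];       v101 <- arr[base + nxy + 1]
  v011 <- arr[base + nx + nxy];  v111 <- arr[base + nx + nxy + 1]
  out <- (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                          fy  * ((1 - fx) * v010 + fx * v110)) +
              fz  * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
                          fy  * ((1 - fx) * v011 + fx * v111))
  if (outside == "na") out[oob] <- NA_real_
  out
}

#' Connected component of a binary mask grown from seed voxels
#'
#' Flood fill under 26-connectivity, restricted to `mask`, seeded at
#' `seeds` (linear indices). Used to keep only the suprathreshold region
#' attached to the active contacts.
#'
#' @param mask logical 3-D array.
#' @param seeds integer vector of linear indices into `mask`.
#' @return logical array of the same shape: the union of connected
#'   components of `mask` containing at least one seed.
#' @keywords internal
flood_fill26 <- function(mask, seeds) {
  if (length(seeds) == 0) return(array(FALSE, dim(mask)))
  flood26(mask, dim(mask), as.integer(seeds))
}
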
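# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# exact two-sided signed-rank p by full enumeration over all 2^n sign
# assignments (no ties among |d| assumed), mirroring the two-sided
# convention p = min(1, 2 * min(P(W <= w), P(W >= w)))
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force streamline-through-mask test at 10x finer resampling,
# checking voxel membership point by point against the mask array
fibers_through_bruteforce <- function(vta, pathway, step) {
  hits <- vapply(pathway$streamlines, function(sl) {
    p <- resample_polyline(sl, step / 10)
    idx <- floor(grid_index(vta$grid, p) + 0.5)
    ok <- idx[, 1] >= 1 & idx[, 1] <= vta$grid$dim[1] &
      idx[, 2] >= 1 & idx[, 2] <= vta$grid$dim[2] &
      idx[, 3] >= 1 & idx[, 3] <= vta$grid$dim[3]
    any(vapply(which(ok), function(r)
      vta$mask[idx[r, 1], idx[r, 2], idx[r, 3]], logical(1)))
  }, logical(1))
  100 * mean(hits)
}

# total-least-squares line-fit residual by direct SVD on the centred points
tls_residual <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  sqrt(sum(sv$d[2:3]^2) / nrow(pts))
}

# analytic field solution object for a point current source (no solver):
# potential sampled from the closed form on a fine lattice
analytic_point_solution <- function(current = -1, sigma = 0.2, spacing = 0.25,
                                    extent = 12) {
  g <- grid_around(c(0, 0, 0), extent, spacing)
  ax <- grid_axes(g)
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  r <- sqrt(outer(outer(ax$x^2, ax$y^2, `+`), ax$z^2, `+`))
  r[r < spacing / 2] <- spacing / 2
  pot <- current / (4 * pi * sigma * r)
  structure(list(grid = g, potential = pot,
                 fixed = array(-1L, g$dim),
                 temporal_scale = 1, active_contacts = integer(0)),
            class = "field_solution")
}

# synthetic VTA: spherical mask, no solver involved
sphere_vta <- function(radius, spacing = 0.25, extent = 12,
                       center = c(0, 0, 0)) {
  g <- grid_around(c(0, 0, 0), extent, spacing)
  ax <- grid_axes(g)
  r <- sqrt(outer(outer((ax$x - center[1])^2, (ax$y - center[2])^2, `+`),
                  (ax$z - center[3])^2, `+`))
  mask <- r <= radius
  structure(list(mask = mask, grid = g, threshold = 0.2,
                 volume_mm3 = sum(mask) * spacing^3, setting = NULL),
            class = "vta_volume")
}
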
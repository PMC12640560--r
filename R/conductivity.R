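#' Conductivity maps
#'
#' Scalar conductivity (S/m) per voxel on a [vc_grid()], with a provenance
#' tag recording which modelling convention produced it:
#' \describe{
#'   \item{`homogeneous`}{uniform bulk tissue.}
#'   \item{`df_homogeneous_scar`}{driving-force branch: homogeneous bulk
#'     (default 0.2 S/m) with a 0.5 mm encapsulation-scar layer (0.07 S/m)
#'     hugging the lead surface.}
#'   \item{`vta_tissue_classes`}{VTA branch: gray matter 0.33 S/m inside the
#'     supplied gray-matter mask, white matter 0.14 S/m elsewhere.}
#' }
#'
#' @name conductivity
NULL

new_conductivity <- function(grid, sigma, provenance, params = list()) {
  stopifnot(all(dim(sigma) == grid$dim), all(sigma > 0))
  structure(list(grid = grid, sigma = sigma, provenance = provenance,
                 params = params),
            class = "conductivity_map")
}

#' @rdname conductivity
#' @param grid a `vc_grid`.
#' @param sigma bulk conductivity, S/m.
#' @export
conductivity_homogeneous <- function(grid, sigma = 0.2) {
  new_conductivity(grid, array(sigma, grid$dim), "homogeneous",
                   list(sigma_tissue = sigma))
}

#' @rdname conductivity
#' @param lead,placement the lead whose surface the scar layer wraps.
#' @param sigma_tissue bulk tissue conductivity, S/m.
#' @param sigma_scar scar conductivity, S/m.
#' @param scar_thickness scar layer thickness, mm; the grid spacing must not
#'   exceed it (otherwise the layer cannot be resolved).
#' @export
conductivity_df_scar <- function(grid, lead, placement, sigma_tissue = 0.2,
                                 sigma_scar = 0.07, scar_thickness = 0.5) {
  if (grid$spacing > scar_thickness)
    stop("grid spacing (", grid$spacing,
         " mm) exceeds scar thickness (", scar_thickness, " mm)")
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  pts <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))
  pl <- world_to_lead(pts, placement)
  r <- sqrt(pl[, 1]^2 + pl[, 2]^2)
  # distance to the lead body treated as a semi-infinite capsule from the tip
  d_axis <- ifelse(pl[, 3] >= 0, r, sqrt(r^2 + pl[, 3]^2))
  d_surf <- d_axis - lead$shaft_radius
  sig <- array(sigma_tissue, grid$dim)
  sig[d_surf > 0 & d_surf <= scar_thickness] <- sigma_scar
  new_conductivity(grid, sig, "df_homogeneous_scar",
                   list(sigma_tissue = sigma_tissue, sigma_scar = sigma_scar,
                        scar_thickness = scar_thickness))
}

#' @rdname conductivity
#' @param gray_mask logical array on `grid`: TRUE where gray matter.
#' @param sigma_gray,sigma_white tissue-class conductivities, S/m.
#' @export
conductivity_tissue_classes <- function(grid, gray_mask, sigma_gray = 0.33,
                                        sigma_white = 0.14) {
  stopifnot(all(dim(gray_mask) == grid$dim))
  sig <- array(sigma_white, grid$dim)
  sig[gray_mask] <- sigma_gray
  new_conductivity(grid, sig, "vta_tissue_classes",
                   list(sigma_gray = sigma_gray, sigma_white = sigma_white))
}
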
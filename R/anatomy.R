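#' Anatomical structure (voxel mask plus derived surface)
#'
#' @param name structure name (e.g. `"STN"`, `"IC"`).
#' @param mask logical 3-D array.
#' @param grid the `vc_grid` the mask lives on.
#' @return A `structure3d`; its surface mesh is derived lazily by
#'   [mask_surface()].
#' @export
structure3d <- function(name, mask, grid) {
  stopifnot(all(dim(mask) == grid$dim))
  if (!any(mask)) stop("structure '", name, "' has an empty mask")
  structure(list(name = name, mask = mask, grid = grid),
            class = "structure3d")
}

#' Pathway (bundle of streamlines)
#'
#' @param name pathway name (e.g. `"HDP"`, `"CSBT"`).
#' @param streamlines list of n x 3 matrices (world mm polylines).
#' @param fiber_diameter fiber diameter, um.
#' @return A `pathway`.
#' @export
pathway <- function(name, streamlines, fiber_diameter) {
  if (length(streamlines) == 0) stop("pathway '", name, "' has no streamlines")
  streamlines <- lapply(streamlines, function(m) {
    m <- matrix(as.numeric(m), ncol = 3)
    if (!all(is.finite(m))) stop("non-finite streamline coordinates")
    m
  })
  structure(list(name = name, streamlines = streamlines,
                 fiber_diameter = fiber_diameter,
                 n_fibers = length(streamlines)),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s: %d fibers, %.1f um diameter\n",
              x$name, x$n_fibers, x$fiber_diameter))
  invisible(x)
}

#' Surface mesh of a voxel mask
#'
#' Extracts the exposed-face surface of a binary mask: every voxel face
#' separating a mask voxel from a non-mask (or out-of-lattice) voxel
#' contributes its four corner vertices (deduplicated) and two triangles.
#' Vertices sit on the 0.5 iso-level between voxel centres, i.e. on the
#' voxel boundaries.
#'
#' @param structure a `structure3d` (or a list with `mask` and `grid`).
#' @return list with `vertices` (n x 3 world mm) and `faces`
#'   (m x 3 vertex indices).
#' @export
mask_surface <- function(structure) {
  mask <- structure$mask
  grid <- structure$grid
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  # corner offsets (in half-voxel units) of the 4 corners of the exposed
  # face for each of the 6 directions
  dirs <- list(
    list(s = c(-1, 0, 0), c = rbind(c(-1,-1,-1), c(-1, 1,-1), c(-1, 1, 1), c(-1,-1, 1))),
    list(s = c( 1, 0, 0), c = rbind(c( 1,-1,-1), c( 1, 1,-1), c( 1, 1, 1), c( 1,-1, 1))),
    list(s = c(0, -1, 0), c = rbind(c(-1,-1,-1), c( 1,-1,-1), c( 1,-1, 1), c(-1,-1, 1))),
    list(s = c(0,  1, 0), c = rbind(c(-1, 1,-1), c( 1, 1,-1), c( 1, 1, 1), c(-1, 1, 1))),
    list(s = c(0, 0, -1), c = rbind(c(-1,-1,-1), c( 1,-1,-1), c( 1, 1,-1), c(-1, 1,-1))),
    list(s = c(0, 0,  1), c = rbind(c(-1,-1, 1), c( 1,-1, 1), c( 1, 1, 1), c(-1, 1, 1))))
  h <- grid$spacing
  corner_list <- list()
  for (dd in dirs) {
    nb <- pad[1:d[1] + 1 + dd$s[1], 1:d[2] + 1 + dd$s[2], 1:d[3] + 1 + dd$s[3]]
    exp_idx <- which(mask & !nb, arr.ind = TRUE)
    if (nrow(exp_idx) == 0) next
    # 4 corners per exposed face, in half-voxel integer units
    base2 <- 2L * (exp_idx - 1L)  # voxel centre in half-voxel units
    for (q in 1:4)
      corner_list[[length(corner_list) + 1L]] <-
        sweep(base2, 2, as.integer(dd$c[q, ]), `+`)
  }
  if (length(corner_list) == 0) stop("mask is empty; no surface")
  corners <- do.call(rbind, corner_list)
  key <- paste(corners[, 1], corners[, 2], corners[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- sweep(corners[uk, , drop = FALSE] * (h / 2), 2, grid$origin, `+`)
  # faces stored per direction blocks of 4: reshape to quads then triangles
  nquad <- length(vid) / 4
  q <- matrix(vid, ncol = 4)  # columns are corner 1..4 within each dir block
  # rebuild per-block ordering: corner_list appended per q, so rows of each
  # block are contiguous; matrix() above with ncol=4 is only valid when all
  # blocks stacked corner-major -- reconstruct properly:
  q <- NULL
  off <- 0L
  faces <- list()
  for (b in seq_len(length(corner_list) / 4)) {
    nfa <- nrow(corner_list[[(b - 1) * 4 + 1]])
    c1 <- vid[off + seq_len(nfa)]
    c2 <- vid[off + nfa + seq_len(nfa)]
    c3 <- vid[off + 2 * nfa + seq_len(nfa)]
    c4 <- vid[off + 3 * nfa + seq_len(nfa)]
    faces[[length(faces) + 1L]] <- cbind(c1, c2, c3)
    faces[[length(faces) + 1L]] <- cbind(c1, c3, c4)
    off <- off + 4L * nfa
  }
  fm <- do.call(rbind, faces)
  dimnames(fm) <- NULL
  dimnames(verts) <- NULL
  list(vertices = verts, faces = fm)
}
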
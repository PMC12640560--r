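#' Read and write structure masks as NIfTI
#'
#' Masks are written as uint8 volumes with the grid's RAS affine; reading
#' validates that the file is 3-D with an axis-aligned isotropic affine
#' (anything else is a format error — no silent resampling).
#'
#' @param structure a `structure3d`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_structure()` returns a `structure3d` (name from the file
#'   name); `write_structure()` returns `path` invisibly.
#' @export
write_structure <- function(structure, path) {
  img <- RNifti::asNifti(array(as.integer(structure$mask), structure$grid$dim),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(grid_affine(structure$grid),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3-D volume, got ", length(d), "-D: ", path)
  aff <- RNifti::xform(img)
  grid <- grid_from_affine(unclass(aff), d)
  name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure3d(name, array(as.array(img) != 0, d), grid)
}

#' Read and write displacement fields as NIfTI vector volumes
#'
#' Stored as 5-D NIfTI (x, y, z, 1, 3) in mm, the usual layout for
#' nonlinear-registration displacement fields.
#'
#' @param field a `deformation_field`.
#' @param path file path.
#' @export
write_deformation <- function(field, path) {
  arr <- array(field$displacement, c(field$grid$dim, 1, 3))
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid_affine(field$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_deformation
#' @export
read_deformation <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!(length(d) == 5 && d[4] == 1 && d[5] == 3))
    stop("expected a 5-D (x,y,z,1,3) displacement volume: ", path)
  grid <- grid_from_affine(unclass(RNifti::xform(img)), d[1:3])
  deformation_field(grid, array(as.array(img), c(d[1:3], 3)))
}

#' Read and write streamlines
#'
#' Three dialects, all carrying world-space RAS mm coordinates:
#' \describe{
#'   \item{TCK}{MRtrix track format (binary Float32, NaN fiber separators,
#'     Inf terminator); coordinates are stored in world mm directly.}
#'   \item{TRK}{TrackVis v2; points are stored in "voxmm" space and
#'     converted through the header's voxel-to-RAS affine and half-voxel
#'     corner offset on read/write.}
#'   \item{CSV}{plain polyline table with columns `fiber_id, x, y, z`.}
#' }
#' The dialect is chosen by file extension.
#'
#' @param pathway a `pathway`.
#' @param path file path (`.tck`, `.trk` or `.csv`).
#' @param fiber_diameter diameter (um) to attach on read.
#' @param name pathway name on read; defaults to the file stem.
#' @return `read_streamlines()` returns a `pathway`.
#' @export
write_streamlines <- function(pathway, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(pathway$streamlines, path),
         trk = write_trk(pathway$streamlines, path),
         csv = {
           df <- purrr::imap_dfr(pathway$streamlines, function(m, i)
             tibble::tibble(fiber_id = i, x = m[, 1], y = m[, 2], z = m[, 3]))
           utils::write.csv(df, path, row.names = FALSE)
         },
         stop("unsupported streamline format: .", ext))
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path, fiber_diameter = NA_real_, name = NULL) {
  ext <- tolower(tools::file_ext(path))
  sl <- switch(ext,
               tck = read_tck(path),
               trk = read_trk(path),
               csv = {
                 df <- utils::read.csv(path)
                 if (!all(c("fiber_id", "x", "y", "z") %in% names(df)))
                   stop("polyline CSV must have columns fiber_id, x, y, z")
                 lapply(split(df, df$fiber_id),
                        function(g) as.matrix(g[, c("x", "y", "z")]))
               },
               stop("unsupported streamline format: .", ext))
  if (length(sl) == 0) stop("no streamlines in ", path)
  pathway(name %||% sub("\\.[^.]+$", "", basename(path)), sl, fiber_diameter)
}

write_tck <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_lines <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", length(streamlines)))
  # compute offset with a stable two-pass header length
  fmt <- function(off) paste0(paste(c(hdr_lines, sprintf("file: . %d", off)),
                                    collapse = "\n"), "\nEND\n")
  off <- nchar(fmt(0), type = "bytes")
  off <- nchar(fmt(off + 10), type = "bytes") + 10  # pad margin
  hdr <- fmt(off)
  pad <- off - nchar(hdr, type = "bytes")
  writeChar(hdr, con, eos = NULL)
  if (pad > 0) writeChar(strrep(" ", pad), con, eos = NULL)
  for (m in streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0) stop("corrupt TCK header (no END): ", path)
  hdr <- rawToChar(raw[1:(hdr_end + 3)])
  lines <- strsplit(hdr, "\n")[[1]]
  if (!grepl("^mrtrix tracks", lines[1])) stop("not a TCK file: ", path)
  dt <- sub("^datatype:\\s*", "", grep("^datatype:", lines, value = TRUE)[1])
  if (!identical(dt, "Float32LE")) stop("unsupported TCK datatype: ", dt)
  off_line <- grep("^file:", lines, value = TRUE)[1]
  off <- as.integer(sub("^file:\\s*\\.\\s*", "", off_line))
  vals <- readBin(raw[(off + 1):length(raw)], "numeric", size = 4,
                  n = (length(raw) - off) / 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- NULL
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) streamlines[[length(streamlines) + 1L]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, p)
  }
  lapply(streamlines, function(m) { dimnames(m) <- NULL; m })
}

# TrackVis v2 with an RAS-aligned header; world mm <-> voxmm conversion uses
# the header affine and the half-voxel corner offset convention
trk_default_header <- function(voxel_size = c(1, 1, 1), dim = c(1, 1, 1)) {
  list(voxel_size = voxel_size, dim = dim,
       vox_to_ras = diag(c(voxel_size, 1)))
}

write_trk <- function(streamlines, path, voxel_size = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(as.raw(0), con)
  writeBin(as.integer(c(1, 1, 1)), con, size = 2)            # dim
  writeBin(as.numeric(voxel_size), con, size = 4)            # voxel_size
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4)            # origin
  writeBin(as.integer(0), con, size = 2)                     # n_scalars
  writeBin(raw(200), con)                                    # scalar names
  writeBin(as.integer(0), con, size = 2)                     # n_properties
  writeBin(raw(200), con)                                    # property names
  M <- diag(c(voxel_size, 1))                                # vox -> RAS
  writeBin(as.numeric(t(M)), con, size = 4)
  writeBin(raw(444), con)                                    # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)   # orientation
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap
  writeBin(as.integer(length(streamlines)), con, size = 4)   # n_count
  writeBin(as.integer(2), con, size = 4)                     # version
  writeBin(as.integer(1000), con, size = 4)                  # hdr_size
  for (m in streamlines) {
    writeBin(as.integer(nrow(m)), con, size = 4)
    voxmm <- sweep(sweep(m, 2, voxel_size, `/`) + 0.5, 2, voxel_size, `*`)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop("not a TRK file: ", path)
  readBin(con, "raw", 1)
  readBin(con, "integer", 3, size = 2)
  voxel_size <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  M <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000) stop("corrupt TRK header (hdr_size=", hdr_size, ")")
  if (all(M == 0)) M <- diag(c(voxel_size, 1))
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4)
    if (length(np) == 0) break
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4)
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_size, `/`) - 0.5
    ras <- cbind(vox, 1) %*% t(M)
    streamlines[[length(streamlines) + 1L]] <- ras[, 1:3, drop = FALSE]
  }
  if (n_count > 0 && length(streamlines) != n_count)
    warning("TRK count field (", n_count, ") != streamlines read (",
            length(streamlines), ")")
  streamlines
}

#' Read and write evoked-potential amplitude tables
#'
#' CSV with columns `setting_id`, `EP0_uV`, `EP1_uV` (very short- and
#' short-latency cortical evoked-potential amplitudes, arbitrary uV scale).
#'
#' @param ep tibble with those columns.
#' @param path file path.
#' @export
write_ep_table <- function(ep, path) {
  stopifnot(all(c("setting_id", "EP0_uV", "EP1_uV") %in% names(ep)))
  utils::write.csv(ep[, c("setting_id", "EP0_uV", "EP1_uV")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ep_table
#' @export
read_ep_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("setting_id", "EP0_uV", "EP1_uV") %in% names(df)))
    stop("EP table must have columns setting_id, EP0_uV, EP1_uV")
  tibble::as_tibble(df)
}
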
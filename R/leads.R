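#' Lead catalog
#'
#' Reads the parametric DBS lead catalog (vendor-nominal dimensions). The
#' default catalog ships with the package and covers the Medtronic 3387/3389,
#' Boston Scientific Vercise 2201 (standard, 8 rings) and the directional
#' Abbott 6172 / Boston Scientific 2202 leads (1-3-3-1 layout).
#'
#' @param path optional path to a custom catalog YAML.
#' @return named list of catalog entries.
#' @export
lead_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lead_catalog.yaml", package = "dbscompare",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Build a parametric lead model
#'
#' Constructs a `dbs_lead` object from the catalog: contact tibble (one row
#' per physical contact, ordered distal to proximal) plus shaft dimensions.
#' In the lead frame the tip apex is at the origin and +z runs from tip
#' toward shaft; segmented sector centres sit at 0/120/240 degrees before
#' any roll is applied.
#'
#' @param name catalog key, e.g. `"MDT3389"`.
#' @param catalog catalog list as returned by [lead_catalog()].
#' @return A `dbs_lead` with fields `name`, `type`, `shaft_radius`,
#'   `contact_height`, `contact_gap`, `tip_length` (all mm) and `contacts`,
#'   a tibble with columns `index`, `level`, `full_ring`, `ang_start`,
#'   `ang_end` (degrees), `z_lo`, `z_hi`, and lead-frame centre `cx`, `cy`,
#'   `cz`.
#' @examples
#' lead <- build_lead("ABT6172")
#' nrow(lead$contacts)  # 8: ring + 3 + 3 + ring
#' @export
build_lead <- function(name, catalog = lead_catalog()) {
  if (!name %in% names(catalog))
    stop("unknown lead '", name, "'; catalog keys: ",
         paste(names(catalog), collapse = ", "))
  cf <- catalog[[name]]
  stopifnot(cf$shaft_radius_mm > 0, cf$contact_height_mm > 0,
            cf$contact_gap_mm > 0, cf$tip_length_mm > 0)
  seg_levels <- as.integer(unlist(cf$segmented_levels))
  rows <- list()
  idx <- 0L
  for (lev in seq_len(cf$n_levels)) {
    z_lo <- cf$tip_length_mm + (lev - 1) * (cf$contact_height_mm + cf$contact_gap_mm)
    z_hi <- z_lo + cf$contact_height_mm
    z_mid <- (z_lo + z_hi) / 2
    if (lev %in% seg_levels) {
      span <- cf$segment_span_deg
      if (cf$n_segments * span >= 360)
        stop("segment spans must sum to < 360 degrees")
      for (s in seq_len(cf$n_segments)) {
        idx <- idx + 1L
        ctr <- (s - 1) * 360 / cf$n_segments
        rows[[length(rows) + 1L]] <- tibble::tibble(
          index = idx, level = lev, full_ring = FALSE,
          ang_start = ctr - span / 2, ang_end = ctr + span / 2,
          cx = cf$shaft_radius_mm * cos(ctr * pi / 180),
          cy = cf$shaft_radius_mm * sin(ctr * pi / 180),
          cz = z_mid, z_lo = z_lo, z_hi = z_hi)
      }
    } else {
      idx <- idx + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        index = idx, level = lev, full_ring = TRUE,
        ang_start = 0, ang_end = 360,
        cx = 0, cy = 0, cz = z_mid, z_lo = z_lo, z_hi = z_hi)
    }
  }
  structure(list(name = name, type = cf$type,
                 shaft_radius = cf$shaft_radius_mm,
                 contact_height = cf$contact_height_mm,
                 contact_gap = cf$contact_gap_mm,
                 tip_length = cf$tip_length_mm,
                 contacts = dplyr::bind_rows(rows)),
            class = "dbs_lead")
}

#' @export
print.dbs_lead <- function(x, ...) {
  cat(sprintf("<dbs_lead> %s (%s): %d contacts, shaft r=%.3f mm\n",
              x$name, x$type, nrow(x$contacts), x$shaft_radius))
  invisible(x)
}

#' Lead placement in world space
#'
#' @param tip_position 3-vector, world RAS mm of the tip apex.
#' @param axis unit 3-vector, direction from tip toward shaft.
#' @param roll rotation (degrees) of the segmented-contact frame about the
#'   axis.
#' @return A `lead_placement`.
#' @export
lead_placement <- function(tip_position = c(0, 0, 0), axis = c(0, 0, 1),
                           roll = 0) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stop("placement axis must have unit norm")
  structure(list(tip_position = as.numeric(tip_position), axis = axis,
                 roll = as.numeric(roll)),
            class = "lead_placement")
}

# rotation matrix taking the canonical lead frame (+z) into world, roll first
rot_lead_to_world <- function(axis, roll_deg) {
  th <- roll_deg * pi / 180
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s2 <- sum(v^2)
  cth <- sum(z * axis)
  if (s2 < 1e-14) {
    ralign <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    ralign <- diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
  }
  ralign %*% rz
}

# world points -> lead frame (tip at origin, +z up the shaft, roll removed)
world_to_lead <- function(pts, placement) {
  R <- rot_lead_to_world(placement$axis, placement$roll)
  sweep(matrix(as.numeric(pts), ncol = 3), 2, placement$tip_position) %*% R
}

lead_to_world <- function(pts, placement) {
  R <- rot_lead_to_world(placement$axis, placement$roll)
  sweep(matrix(as.numeric(pts), ncol = 3) %*% t(R), 2,
        placement$tip_position, `+`)
}

#' World-frame contact geometry for a placed lead
#'
#' Applies the rigid placement transform (tip translation, axis alignment,
#' roll) to the lead's contact centres.
#'
#' @param lead a `dbs_lead`.
#' @param placement a `lead_placement`.
#' @return The lead's contact tibble with world-frame centre columns
#'   `wx`, `wy`, `wz` appended.
#' @export
contact_positions <- function(lead, placement) {
  stopifnot(inherits(lead, "dbs_lead"), inherits(placement, "lead_placement"))
  w <- lead_to_world(as.matrix(lead$contacts[, c("cx", "cy", "cz")]), placement)
  dplyr::mutate(lead$contacts, wx = w[, 1], wy = w[, 2], wz = w[, 3])
}

#' Axial span of the contact array (lead frame, mm)
#' @param lead a `dbs_lead`.
#' @return numeric length-2: z of the bottom of the distal contact and the
#'   top of the proximal contact.
#' @keywords internal
contact_span <- function(lead) {
  range(c(lead$contacts$z_lo, lead$contacts$z_hi))
}

#' Construct a stimulation setting
#'
#' @param cathodes integer vector of cathodal contact indices (current sinks).
#' @param anodes integer vector of anodal contact indices, or `NULL` for
#'   monopolar stimulation with the case (distant ground) as return.
#' @param amplitude stimulation amplitude, mA (> 0); the cathodic-phase
#'   current, split equally over the cathodes.
#' @param pulse_width pulse width, microseconds.
#' @param frequency stimulation frequency, Hz.
#' @param interphase_gap inter-phase interval of the asymmetric biphasic
#'   waveform, microseconds (carried as metadata; the field model is linear
#'   and uses the cathodic phase only).
#' @param lead optionally, the `dbs_lead` the indices refer to; used to
#'   validate indices and set the `directional` flag (any active contact
#'   segmented).
#' @return one-row tibble describing the setting.
#' @export
stim_setting <- function(cathodes, anodes = NULL, amplitude, pulse_width = 60,
                         frequency = 10, interphase_gap = 70, lead = NULL) {
  cathodes <- as.integer(cathodes)
  if (length(cathodes) == 0) stop("cathodes must be nonempty")
  if (amplitude <= 0) stop("amplitude must be > 0")
  case_return <- is.null(anodes) || length(anodes) == 0
  anodes <- if (case_return) integer(0) else as.integer(anodes)
  if (length(intersect(cathodes, anodes)) > 0)
    stop("cathodes and anodes must be disjoint")
  directional <- FALSE
  if (!is.null(lead)) {
    active <- c(cathodes, anodes)
    if (!all(active %in% lead$contacts$index))
      stop("contact indices outside lead: ",
           paste(setdiff(active, lead$contacts$index), collapse = ", "))
    directional <- any(!lead$contacts$full_ring[lead$contacts$index %in% active])
  }
  tibble::tibble(cathodes = list(cathodes), anodes = list(anodes),
                 case_return = case_return, amplitude_mA = amplitude,
                 pulse_width_us = pulse_width, frequency_Hz = frequency,
                 interphase_gap_us = interphase_gap,
                 directional = directional)
}

#' Enumerate stimulation settings from a menu
#'
#' Expands a settings menu into the cartesian product of the requested
#' contact configurations and amplitudes. Monopolar entries are cathodic
#' with case return; a "pseudo ring" (all segments of one level driven
#' together) is represented as a multi-cathode monopolar setting and is
#' non-directional by convention.
#'
#' @param lead a `dbs_lead` (defines indices and the directional flag).
#' @param menu list with any of:
#'   \describe{
#'     \item{monopolar}{list of cathode index vectors, or `"each"` for every
#'       single contact, or `"levels"` for one (pseudo-)ring per level.}
#'     \item{bipolar}{list of `list(cathode =, anode =)` pairs, or
#'       `"adjacent"` for successive-level ring pairs.}
#'     \item{amplitudes_mA}{numeric vector of amplitudes (default 1:5).}
#'     \item{pulse_width_us, frequency_Hz}{scalars (defaults 60, 10).}
#'   }
#' @return tibble of settings with a `setting_id` column.
#' @examples
#' lead <- build_lead("MDT3389")
#' s <- enumerate_settings(lead, list(monopolar = "each", amplitudes_mA = c(1, 3, 5)))
#' nrow(s)  # 4 contacts x 3 amplitudes
#' @export
enumerate_settings <- function(lead, menu) {
  stopifnot(inherits(lead, "dbs_lead"))
  if (length(menu) == 0 || (is.null(menu$monopolar) && is.null(menu$bipolar)))
    stop("settings menu is empty: supply 'monopolar' and/or 'bipolar' entries")
  amps <- menu$amplitudes_mA %||% 1:5
  if (any(amps <= 0)) stop("amplitudes must be positive")
  pw <- menu$pulse_width_us %||% 60
  fr <- menu$frequency_Hz %||% 10
  configs <- list()
  mono <- menu$monopolar
  if (!is.null(mono)) {
    if (identical(mono, "each"))
      mono <- as.list(lead$contacts$index)
    if (identical(mono, "levels"))
      mono <- lapply(split(lead$contacts$index, lead$contacts$level), identity)
    for (ca in mono)
      configs[[length(configs) + 1L]] <- list(cathodes = ca, anodes = NULL)
  }
  bip <- menu$bipolar
  if (!is.null(bip)) {
    if (identical(bip, "adjacent")) {
      lv <- split(lead$contacts$index, lead$contacts$level)
      bip <- lapply(seq_len(length(lv) - 1),
                    function(l) list(cathode = lv[[l]], anode = lv[[l + 1]]))
    }
    for (p in bip)
      configs[[length(configs) + 1L]] <- list(cathodes = p$cathode, anodes = p$anode)
  }
  # validate each configuration once, then expand over amplitudes in bulk
  for (cfg in configs) {
    if (length(cfg$cathodes) == 0) stop("cathodes must be nonempty")
    if (length(intersect(cfg$cathodes, cfg$anodes)) > 0)
      stop("cathodes and anodes must be disjoint")
    active <- c(cfg$cathodes, cfg$anodes)
    if (!all(active %in% lead$contacts$index))
      stop("contact indices outside lead: ",
           paste(setdiff(active, lead$contacts$index), collapse = ", "))
  }
  ncfg <- length(configs)
  namp <- length(amps)
  out <- tibble::tibble(
    cathodes = rep(lapply(configs, function(c) as.integer(c$cathodes)),
                   each = namp),
    anodes = rep(lapply(configs, function(c)
      if (is.null(c$anodes)) integer(0) else as.integer(c$anodes)),
      each = namp),
    case_return = rep(vapply(configs, function(c)
      is.null(c$anodes) || length(c$anodes) == 0, logical(1)), each = namp),
    amplitude_mA = rep(as.numeric(amps), times = ncfg),
    pulse_width_us = pw, frequency_Hz = fr, interphase_gap_us = 70,
    directional = rep(vapply(configs, function(c) {
      active <- c(c$cathodes, c$anodes)
      any(!lead$contacts$full_ring[lead$contacts$index %in% active])
    }, logical(1)), each = namp))
  # pseudo-ring: all segments of one level driven together act as a ring,
  # so a setting is directional only if some level's active segments are a
  # proper subset of that level's segments
  seg_by_level <- split(lead$contacts$index[!lead$contacts$full_ring],
                        lead$contacts$level[!lead$contacts$full_ring])
  if (length(seg_by_level) > 0 && nrow(out) > 0) {
    is_directional <- function(active) {
      segs <- intersect(active, unlist(seg_by_level))
      any(vapply(seg_by_level, function(lvl_segs) {
        k <- length(intersect(segs, lvl_segs))
        k > 0 && k < length(lvl_segs)
      }, logical(1)))
    }
    out$directional <- vapply(seq_len(nrow(out)), function(i)
      is_directional(c(out$cathodes[[i]], out$anodes[[i]])), logical(1))
  }
  dplyr::mutate(out, setting_id = sprintf("S%03d", dplyr::row_number()),
                .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize a placed lead onto a grid
#'
#' Classifies every voxel as free tissue, electrode interior (excluded from
#' the conduction domain) or part of a contact surface. For segmented levels
#' each electrode-surface voxel in the level's axial span is assigned to the
#' sector whose angular centre is nearest, so every segment is represented
#' at any roll even at coarse spacing.
#'
#' @param lead a `dbs_lead`.
#' @param placement a `lead_placement`.
#' @param grid a `vc_grid`.
#' @return list with `fixed` (integer array: -1 free, -2 excluded,
#'   `k-1` for contact `k`) and `contact_voxels` (per-contact voxel counts).
#' @keywords internal
voxelize_lead <- function(lead, placement, grid) {
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  pts <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))
  pl <- world_to_lead(pts, placement)
  r <- sqrt(pl[, 1]^2 + pl[, 2]^2)
  z <- pl[, 3]
  inside <- r <= lead$shaft_radius & z >= 0
  fixed <- array(-1L, grid$dim)
  fixed[inside] <- -2L
  ang <- (atan2(pl[, 2], pl[, 1]) * 180 / pi) %% 360
  cts <- lead$contacts
  for (lev in unique(cts$level)) {
    sub <- cts[cts$level == lev, ]
    in_lev <- inside & z >= sub$z_lo[1] & z <= sub$z_hi[1]
    if (all(sub$full_ring)) {
      fixed[in_lev] <- sub$index[1] - 1L
    } else {
      centers <- (sub$ang_start + sub$ang_end) / 2
      cand <- which(in_lev & r > lead$shaft_radius / 2)
      if (length(cand) > 0) {
        d <- abs(outer(ang[cand], centers, `-`)) %% 360
        d <- pmin(d, 360 - d)
        pick <- max.col(-d)
        fixed[cand] <- sub$index[pick] - 1L
      }
    }
  }
  counts <- vapply(cts$index, function(i) sum(fixed == i - 1L), integer(1))
  # a tilted lead at coarse spacing can starve a segment of voxels; each
  # contact is guaranteed at least the voxel nearest its surface centre
  for (ci in cts$index[counts == 0]) {
    ctr <- as.numeric(cts[cts$index == ci, c("cx", "cy", "cz")])
    d2 <- (pl[, 1] - ctr[1])^2 + (pl[, 2] - ctr[2])^2 + (pl[, 3] - ctr[3])^2
    for (cand in order(d2)[1:27]) {
      owner <- fixed[cand]
      if (owner == -1L || owner == -2L ||
          sum(fixed == owner) > 1L) {
        fixed[cand] <- ci - 1L
        break
      }
    }
  }
  counts <- vapply(cts$index, function(i) sum(fixed == i - 1L), integer(1))
  if (any(counts == 0))
    stop("grid too coarse: contacts ",
         paste(cts$index[counts == 0], collapse = ", "),
         " have no voxels at spacing ", grid$spacing, " mm")
  list(fixed = fixed, contact_voxels = counts)
}
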
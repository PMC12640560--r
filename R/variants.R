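#' Model variant specification
#'
#' One of the six admissible model variants crossing modelling method
#' (driving force vs binary VTA), imaging space (native vs normative) and
#' anatomical representation (pathway streamlines vs volumetric
#' structures). The driving-force method models axonal activation directly,
#' so the structure representation is inadmissible for it — exactly six
#' variants exist.
#'
#' @param method `"DF"` or `"VTA"`.
#' @param space `"native"` or `"normative"`.
#' @param representation `"pathway"` or `"structure"`.
#' @return list of class `variant_spec`.
#' @export
variant_spec <- function(method = c("DF", "VTA"),
                         space = c("native", "normative"),
                         representation = c("pathway", "structure")) {
  method <- match.arg(method)
  space <- match.arg(space)
  representation <- match.arg(representation)
  if (method == "DF" && representation == "structure")
    stop("the driving-force method models pathway activation only; ",
         "DF + structure is inadmissible")
  structure(list(method = method, space = space,
                 representation = representation),
            class = "variant_spec")
}

#' @rdname variant_spec
#' @param v a `variant_spec`.
#' @export
variant_id <- function(v) {
  paste(v$method,
        c(native = "Native", normative = "Normative")[v$space],
        c(pathway = "Pathway", structure = "Structure")[v$representation],
        sep = "-")
}

#' @rdname variant_spec
#' @param id a variant id string like `"DF-Native-Pathway"`.
#' @export
parse_variant <- function(id) {
  parts <- strsplit(id, "-")[[1]]
  if (length(parts) != 3) stop("malformed variant id: ", id)
  variant_spec(parts[1], tolower(parts[2]), tolower(parts[3]))
}

#' The six admissible model variants
#' @return list of `variant_spec`, named by [variant_id()].
#' @export
all_variants <- function() {
  out <- list()
  for (m in c("DF", "VTA")) for (s in c("native", "normative"))
    for (r in c("pathway", "structure")) {
      if (m == "DF" && r == "structure") next
      v <- variant_spec(m, s, r)
      out[[variant_id(v)]] <- v
    }
  out
}

#' Pipeline numerical options
#'
#' Desk-scale solver and predictor resolutions used by the cohort runner.
#' The driving-force branch must resolve the 0.5 mm encapsulation scar, so
#' its spacing may not exceed 0.5 mm; the VTA branch has no scar and can
#' run slightly coarser.
#'
#' @param df_spacing grid spacing for driving-force-branch fields, mm.
#' @param vta_spacing grid spacing for VTA-branch fields, mm.
#' @param margin solution-domain margin beyond the contact span, mm.
#' @param tol,max_iter SOR convergence controls.
#' @param vta_threshold E-field magnitude threshold for the VTA, V/mm.
#' @param excitation driving-force calibration ([df_calibration()]).
#' @param n_phase node-placement phases per internodal length.
#' @return list of class `pipeline_options`.
#' @export
pipeline_options <- function(df_spacing = 0.5, vta_spacing = 0.6,
                             margin = 7, tol = 2e-6, max_iter = 8000,
                             vta_threshold = 0.2,
                             excitation = df_calibration(), n_phase = 5) {
  if (df_spacing > 0.5)
    stop("df_spacing must be <= the 0.5 mm scar thickness")
  structure(list(df_spacing = df_spacing, vta_spacing = vta_spacing,
                 margin = margin, tol = tol, max_iter = max_iter,
                 vta_threshold = vta_threshold, excitation = excitation,
                 n_phase = n_phase),
            class = "pipeline_options")
}

lead_extent <- function(lead, margin) {
  diff(contact_span(lead)) + 2 * margin
}

subject_uid <- function(subject) {
  subject$uid %||% subject$subject_id
}

# ---- geometry per space -----------------------------------------------------

# returns list(placement, structures, pathways); normative = warped anatomy
# with the field recomputed around the re-straightened idealized lead
space_geometry <- function(subject, space, cache) {
  if (space == "native")
    return(list(placement = subject$placement,
                structures = subject$structures,
                pathways = subject$pathways))
  key <- paste0("geom|", subject_uid(subject), "|normative")
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (is.null(subject$deformation))
    stop("subject ", subject$subject_id,
         " has no deformation field for normative space")
  field <- subject$deformation
  wl <- warp_lead_placement(subject$lead, subject$placement, field)
  placement <- restraighten_lead(subject$lead, wl)
  # all structure masks share one lattice: invert the warp once, pull back
  # every mask through the same source points
  grids_equal <- function(a, b)
    all(a$dim == b$dim) && a$spacing == b$spacing && all(a$origin == b$origin)
  g0 <- subject$structures[[1]]$grid
  stopifnot(all(vapply(subject$structures,
                       function(s) grids_equal(s$grid, g0), logical(1))))
  ax <- grid_axes(g0)
  nx <- g0$dim[1]; ny <- g0$dim[2]; nz <- g0$dim[3]
  tgt <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))
  # invert once on the (coarse) warp lattice, then one interpolation pass
  inv <- invert_deformation(field)
  src <- tgt + interp_displacement(inv, tgt)
  seen <- list()
  structures <- lapply(subject$structures, function(st) {
    for (s2 in seen) if (identical(s2$ref, st$mask)) {
      out <- st; out$mask <- s2$warped; return(out)
    }
    warped <- array(points_in_mask(st$mask, g0, src), g0$dim)
    if (!any(warped))
      stop("structure '", st$name, "' warped entirely out of its lattice")
    seen[[length(seen) + 1L]] <<- list(ref = st$mask, warped = warped)
    out <- st; out$mask <- warped; out
  })
  out <- list(placement = placement,
              structures = structures,
              pathways = lapply(subject$pathways, apply_warp, field = field))
  cache[[key]] <- out
  out
}

# ---- driving-force branch ---------------------------------------------------

df_canonical_basis <- function(lead, opts, cache) {
  key <- paste("dfbasis", lead$name, opts$df_spacing, opts$margin, opts$tol,
               sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  placement0 <- lead_placement(c(0, 0, 0), c(0, 0, 1), 0)
  grid <- grid_around(c(0, 0, mean(contact_span(lead))),
                      lead_extent(lead, opts$margin), opts$df_spacing)
  cond <- conductivity_df_scar(grid, lead, placement0)
  basis <- solve_lead_basis(lead, placement0, cond,
                            solver_options(spacing = opts$df_spacing,
                                           extent = lead_extent(lead, opts$margin),
                                           tol = opts$tol,
                                           max_iter = opts$max_iter))
  cache[[key]] <- basis
  basis
}

# per-fiber thresholds (mA) for every unique contact configuration in
# `settings`; returns list(config_key per setting, thresholds[[key]] matrix)
df_thresholds <- function(basis, placement, pw_settings, pathway_lead, opts) {
  L <- internodal_length(pathway_lead$fiber_diameter)
  phases <- seq(0, L, length.out = opts$n_phase + 1)[-(opts$n_phase + 1)]
  nfib <- length(pathway_lead$streamlines)
  # stack node points for all fibers x phases
  segs <- list(); pts <- list()
  for (f in seq_len(nfib)) for (p in seq_along(phases)) {
    nd <- resample_polyline(pathway_lead$streamlines[[f]], L, phases[p])
    if (nrow(nd) < 3) next
    pts[[length(pts) + 1L]] <- nd
    segs[[length(segs) + 1L]] <- c(f, nrow(nd))
  }
  if (length(pts) == 0)
    return(list(thr = function(key, pw) rep(Inf, nfib)))
  allpts <- do.call(rbind, pts)
  seginfo <- do.call(rbind, segs)
  K <- length(basis$fields)
  P <- matrix(0, nrow(allpts), K)
  for (k in seq_len(K))
    P[, k] <- interp_trilinear(basis$fields[[k]], basis$grid, allpts)
  # index vectors for vectorized second differences over all segments
  ends <- cumsum(seginfo[, 2])
  starts <- ends - seginfo[, 2] + 1
  im <- i0 <- ip <- integer(0)
  segfib <- integer(0)
  for (s in seq_len(nrow(seginfo))) {
    n <- seginfo[s, 2]
    im <- c(im, starts[s]:(ends[s] - 2))
    i0 <- c(i0, (starts[s] + 1):(ends[s] - 1))
    ip <- c(ip, (starts[s] + 2):ends[s])
    segfib <- c(segfib, rep(seginfo[s, 1], n - 2))
  }
  G <- basis$G
  ex <- opts$excitation
  memo <- new.env(parent = emptyenv())
  thr <- function(setting) {
    key <- paste(paste(setting$cathodes[[1]], collapse = "+"),
                 paste(setting$anodes[[1]], collapse = "+"),
                 setting$pulse_width_us, sep = "|")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    s1 <- setting
    s1$amplitude_mA <- 1
    v <- solve(G, setting_currents(s1, K))
    pot <- as.numeric(P %*% v)
    d2 <- pot[im] - 2 * pot[i0] + pot[ip]
    peak <- rep(-Inf, nfib)
    agg <- tapply(d2, segfib, max)
    peak[as.integer(names(agg))] <- agg
    k_pw <- ex$k0 * (1 + ex$tau_c / setting$pulse_width_us)
    out <- ifelse(peak > 0, k_pw / peak, Inf)
    memo[[key]] <- out
    out
  }
  list(thr = thr)
}

# ---- VTA branch -------------------------------------------------------------

vta_basis <- function(subject, space, geom, opts, cache) {
  key <- paste("vtabasis", subject_uid(subject), space, opts$vta_spacing,
               sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  lead <- subject$lead
  cp <- contact_positions(lead, geom$placement)
  grid <- grid_around(colMeans(as.matrix(cp[, c("wx", "wy", "wz")])),
                      lead_extent(lead, opts$margin), opts$vta_spacing)
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  vox_pts <- cbind(rep(ax$x, times = ny * nz),
                   rep(rep(ax$y, each = nx), times = nz),
                   rep(ax$z, each = nx * ny))
  gray <- array(points_in_mask(geom$structures$gray$mask,
                               geom$structures$gray$grid, vox_pts), grid$dim)
  cond <- conductivity_tissue_classes(grid, gray)
  basis <- solve_lead_basis(lead, geom$placement, cond,
                            solver_options(spacing = opts$vta_spacing,
                                           extent = lead_extent(lead, opts$margin),
                                           tol = opts$tol,
                                           max_iter = opts$max_iter))
  cache[[key]] <- basis
  basis
}

# per-setting VTA masks, memoized in the shared cache so the pathway and
# structure representations of the same subject/space reuse them
vta_mask_fun <- function(basis, subject, space, opts, cache) {
  prefix <- paste("vtamask", subject_uid(subject), space, sep = "|")
  fields <- new.env(parent = emptyenv())
  function(setting) {
    cfg <- paste(paste(setting$cathodes[[1]], collapse = "+"),
                 paste(setting$anodes[[1]], collapse = "+"), sep = "|")
    mkey <- paste(prefix, cfg, setting$amplitude_mA, sep = "|")
    got <- cache[[mkey]]
    if (!is.null(got)) return(got)
    ff <- fields[[cfg]]
    if (is.null(ff)) {
      s1 <- setting
      s1$amplitude_mA <- 1
      sol <- field_from_basis(basis, s1)
      sol$efield[sol$fixed != -1L] <- 0
      act <- array(FALSE, basis$grid$dim)
      for (idx in sol$active_contacts) act <- act | (sol$fixed == idx - 1L)
      ff <- list(efield = sol$efield, dil = dilate26(act))
      fields[[cfg]] <- ff
    }
    supra <- ff$efield >= opts$vta_threshold / setting$amplitude_mA
    mask <- flood_fill26(supra, which(ff$dil & supra))
    cache[[mkey]] <- mask
    mask
  }
}

#' Run one model variant on one subject
#'
#' Produces per-setting percent activation for the near (HDP) and far
#' (CSBT) targets under the given variant:
#' \itemize{
#'   \item VTA variants: tissue-class conductivity (gray 0.33 / white
#'     0.14 S/m, electrode removed), fixed 0.2 V/mm E-field threshold;
#'     pathway representation counts streamlines through the VTA, structure
#'     representation maps HDP to the STN-like structure and CSBT to the
#'     capsule-like structure (voxel-overlap convention in normative space,
#'     vertex convention in native space). Pulse width and frequency do not
#'     enter the VTA.
#'   \item DF variants: homogeneous 0.2 S/m bulk with 0.07 S/m
#'     encapsulation layer, floating passive contacts; per-fiber thresholds
#'     from the peak depolarizing driving force at nodes of Ranvier;
#'     percent of fibers with threshold below the setting amplitude.
#'   \item normative space: all geometry warped through the subject's
#'     deformation field, the lead re-straightened, and the field
#'     recomputed around the idealized straight lead.
#' }
#'
#' @param subject a `subject_dataset`.
#' @param variant a [variant_spec()] (or id string).
#' @param opts a [pipeline_options()].
#' @param cache environment for cross-call caching of basis fields and
#'   warped geometry.
#' @return tibble: `subject_id`, `variant`, `method`, `space`,
#'   `representation`, `setting_id`, `target`, `metric_kind`, `value`.
#' @export
run_variant <- function(subject, variant, opts = pipeline_options(),
                        cache = NULL) {
  if (is.character(variant)) variant <- parse_variant(variant)
  cache <- cache %||% new.env(parent = emptyenv())
  geom <- space_geometry(subject, variant$space, cache)
  settings <- subject$settings
  vid <- variant_id(variant)
  v_method <- variant$method; v_space <- variant$space
  v_repr <- variant$representation
  base_row <- function(setting_id, target, metric, value)
    tibble::tibble(subject_id = subject$subject_id, variant = vid,
                   method = v_method, space = v_space,
                   representation = v_repr,
                   setting_id = setting_id, target = target,
                   metric_kind = metric, value = value)

  if (variant$method == "DF") {
    basis <- df_canonical_basis(subject$lead, opts, cache)
    rows <- list()
    for (tg in c("HDP", "CSBT")) {
      pw <- geom$pathways[[tolower(tg)]]
      pw_lead <- pw
      pw_lead$streamlines <- lapply(pw$streamlines, world_to_lead,
                                    placement = geom$placement)
      thrfun <- df_thresholds(basis, geom$placement, settings, pw_lead, opts)
      vals <- vapply(seq_len(nrow(settings)), function(i) {
        thr <- thrfun$thr(settings[i, ])
        percent_fibers_activated(thr, settings$amplitude_mA[i])
      }, numeric(1))
      rows[[tg]] <- base_row(settings$setting_id, tg, "pct_fibers_df", vals)
    }
    return(dplyr::bind_rows(rows))
  }

  # VTA branch
  basis <- vta_basis(subject, variant$space, geom, opts, cache)
  mask_of <- vta_mask_fun(basis, subject, variant$space, opts, cache)
  grid_v <- basis$grid

  if (variant$representation == "pathway") {
    # resample streamlines once; per-setting membership is a mask lookup
    prep <- lapply(c(HDP = "hdp", CSBT = "csbt"), function(nm) {
      sls <- geom$pathways[[nm]]$streamlines
      pts <- lapply(sls, resample_polyline, step = opts$vta_spacing / 2)
      fib <- rep(seq_along(pts), vapply(pts, nrow, integer(1)))
      list(pts = do.call(rbind, pts), fib = fib, n = length(sls))
    })
    vals <- list(HDP = numeric(nrow(settings)), CSBT = numeric(nrow(settings)))
    for (i in seq_len(nrow(settings))) {
      mask <- mask_of(settings[i, ])
      for (tg in c("HDP", "CSBT")) {
        pp <- prep[[tg]]
        hit <- points_in_mask(mask, grid_v, pp$pts)
        vals[[tg]][i] <- 100 * sum(tapply(hit, pp$fib, any)) / pp$n
      }
    }
    return(dplyr::bind_rows(
      base_row(settings$setting_id, "HDP", "pct_fibers_vta", vals$HDP),
      base_row(settings$setting_id, "CSBT", "pct_fibers_vta", vals$CSBT)))
  }

  # structure representation: HDP -> STN-like, CSBT -> capsule-like
  ax <- grid_axes(grid_v)
  nx <- grid_v$dim[1]; ny <- grid_v$dim[2]; nz <- grid_v$dim[3]
  vox_pts <- cbind(rep(ax$x, times = ny * nz),
                   rep(rep(ax$y, each = nx), times = nz),
                   rep(ax$z, each = nx * ny))
  structs <- list(HDP = geom$structures$stn, CSBT = geom$structures$ic)
  if (variant$space == "normative") {
    res <- lapply(structs, function(st)
      array(points_in_mask(st$mask, st$grid, vox_pts), grid_v$dim))
    metric <- "pct_structure_voxels"
  } else {
    res <- lapply(structs, function(st) mask_surface(st)$vertices)
    metric <- "pct_structure_vertices"
  }
  vals <- list(HDP = numeric(nrow(settings)), CSBT = numeric(nrow(settings)))
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    mask <- mask_of(s)
    vta <- structure(list(mask = mask, grid = grid_v,
                          threshold = opts$vta_threshold,
                          volume_mm3 = sum(mask) * grid_v$spacing^3,
                          setting = s), class = "vta_volume")
    for (tg in c("HDP", "CSBT")) {
      vals[[tg]][i] <- if (metric == "pct_structure_voxels")
        structure_overlap_voxels(vta, res[[tg]])
      else structure_overlap_vertices(vta, res[[tg]])
    }
  }
  dplyr::bind_rows(
    base_row(settings$setting_id, "HDP", metric, vals$HDP),
    base_row(settings$setting_id, "CSBT", metric, vals$CSBT))
}

#' Run several variants over a cohort
#'
#' @param cohort a `dbs_cohort` (list of subjects).
#' @param variants list of [variant_spec()] (default: all six).
#' @param opts a [pipeline_options()].
#' @param cache shared cache environment (created if missing).
#' @return long tibble of per-setting activation values.
#' @export
run_cohort <- function(cohort, variants = all_variants(),
                       opts = pipeline_options(), cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  out <- list()
  for (subj in cohort) {
    for (v in variants)
      out[[length(out) + 1L]] <- run_variant(subj, v, opts, cache)
    # drop this subject's cached masks/bases/geometry (lead-frame DF bases
    # are keyed by lead model and kept)
    uid <- subject_uid(subj)
    stale <- grep(uid, ls(cache, all.names = TRUE), value = TRUE, fixed = TRUE)
    rm(list = stale, envir = cache)
  }
  dplyr::bind_rows(out)
}
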
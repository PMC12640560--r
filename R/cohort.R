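#' Reference in-vivo cohort summary
#'
#' Per-patient summary of the 11-patient intraoperative STN-DBS cohort the
#' synthetic generator emulates: numbers of monopolar and bipolar settings
#' modelled, implanted lead model, and lead bottom-contact coordinates
#' relative to the mid-commissural point.
#'
#' @return tibble with columns `patient_code`, `n_monopolar`, `n_bipolar`,
#'   `lead_name`, `lead_type`, `tip_x_mm`, `tip_y_mm`, `tip_z_mm`.
#' @export
invivo_cohort <- function() {
  path <- system.file("extdata", "invivo_cohort.csv", package = "dbscompare",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Evoked-potential generative model
#'
#' Ties synthetic cortical evoked-potential amplitudes to the designated
#' ground-truth pathway activation. EP1 (short latency) indexes
#' hyperdirect-pathway activation; EP0 (very short latency) indexes
#' corticospinal/bulbar-tract activation and is zero-inflated: amplitudes
#' below the detection floor read 0, near-threshold amplitudes (below
#' `near_floor_mult` times the floor) drop to 0 with probability
#' `ep0_zero_inflation`, and settings with no true activation read exactly
#' 0 (an absent response has no amplitude to measure).
#'
#' @param gain uV of EP amplitude per percent activation.
#' @param noise_sd additive measurement noise SD, uV.
#' @param ep0_zero_inflation dropout probability for near-threshold EP0.
#' @param detection_floor uV below which EP0 reads 0.
#' @param near_floor_mult multiple of the floor defining "near threshold".
#' @param truth_variant the model variant that defines ground-truth
#'   activation (a [variant_spec()]); the default is the driving-force
#'   native-space pathway model.
#' @return list of class `ep_model`.
#' @export
ep_model <- function(gain = 1, noise_sd = 5, ep0_zero_inflation = 0.4,
                     detection_floor = 1, near_floor_mult = 3,
                     truth_variant = variant_spec("DF", "native", "pathway")) {
  stopifnot(gain > 0, noise_sd >= 0,
            ep0_zero_inflation >= 0, ep0_zero_inflation <= 1,
            detection_floor >= 0)
  structure(list(gain = gain, noise_sd = noise_sd,
                 ep0_zero_inflation = ep0_zero_inflation,
                 detection_floor = detection_floor,
                 near_floor_mult = near_floor_mult,
                 truth_variant = truth_variant),
            class = "ep_model")
}

#' Synthetic cohort specification
#'
#' Defines the study conditions of a synthetic cohort: number of subjects,
#' lead mix and per-subject setting counts (by default mirroring the
#' reference in-vivo cohort: 8 standard / 3 steerable leads, 15-49 settings
#' per subject), the geometric anatomy parameters, warp magnitude of the
#' emulated normative space, and the evoked-potential model.
#'
#' Anatomy is geometric-primitive-based, in the lead frame (tip at origin,
#' +z up the shaft): an STN-like ellipsoid adjacent to the distal contacts,
#' a thin-fiber (4 um) near bundle passing the lead and terminating in the
#' ellipsoid (hyperdirect-pathway analog), a large-fiber (12 um) coherent
#' far bundle (corticospinal-tract analog) inside an internal-capsule-like
#' tube.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed cohort seed; fixes the whole cohort.
#' @param template per-subject lead/setting template: tibble with columns
#'   `lead_name`, `n_monopolar`, `n_bipolar` (rows recycled to
#'   `n_subjects`); default [invivo_cohort()].
#' @param stn_center,stn_semiaxes STN-like ellipsoid centre and semi-axes,
#'   mm, lead frame.
#' @param hdp_offset,hdp_spread near-bundle closest approach to the lead
#'   axis and per-fiber jitter SD, mm.
#' @param csbt_offset,csbt_spread far-bundle centreline offset and jitter
#'   SD, mm (farther than the near bundle by construction).
#' @param ic_radius radius of the internal-capsule-like tube, mm.
#' @param n_fibers streamlines per bundle.
#' @param hdp_diameter,csbt_diameter fiber diameters, um.
#' @param amplitudes_mA amplitude menu, mA.
#' @param warp_mean_mag mean displacement magnitude of the synthetic
#'   normative warp, mm.
#' @param warp_global_scale global scale factor of the normative space
#'   (template brains are slightly larger than the average individual).
#' @param ep the [ep_model()].
#' @param extent anatomy lattice extent, mm.
#' @param spacing anatomy lattice spacing, mm.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 11, seed = 1,
                        template = invivo_cohort(),
                        stn_center = c(2.5, 1.0, 2.0),
                        stn_semiaxes = c(3.0, 2.0, 4.0),
                        hdp_offset = 2.0, hdp_spread = 0.8,
                        csbt_offset = 7.0, csbt_spread = 0.8,
                        ic_radius = 3.8,
                        n_fibers = 100,
                        hdp_diameter = 4, csbt_diameter = 12,
                        amplitudes_mA = 1:5,
                        warp_mean_mag = 1.0, warp_global_scale = 1.05,
                        ep = ep_model(),
                        extent = 26, spacing = 0.5) {
  stopifnot(n_subjects >= 2, all(stn_semiaxes > 0), hdp_offset > 0,
            csbt_offset > 0, hdp_spread > 0, csbt_spread > 0,
            ic_radius > 0, n_fibers >= 1, warp_mean_mag >= 0)
  if (csbt_offset <= hdp_offset)
    stop("the far bundle must be farther from the lead than the near bundle")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 template = template,
                 stn_center = stn_center, stn_semiaxes = stn_semiaxes,
                 hdp_offset = hdp_offset, hdp_spread = hdp_spread,
                 csbt_offset = csbt_offset, csbt_spread = csbt_spread,
                 ic_radius = ic_radius, n_fibers = n_fibers,
                 hdp_diameter = hdp_diameter, csbt_diameter = csbt_diameter,
                 amplitudes_mA = amplitudes_mA,
                 warp_mean_mag = warp_mean_mag,
                 warp_global_scale = warp_global_scale,
                 ep = ep, extent = extent, spacing = spacing),
            class = "cohort_spec")
}

# quadratic Bezier sampled at n points
bezier3 <- function(p0, p1, p2, n = 25) {
  t <- seq(0, 1, length.out = n)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  b
}

#' Generate one subject's synthetic anatomy
#'
#' Lead placement (jittered tip/axis, random roll for segmented leads),
#' STN-like ellipsoid, near and far fiber bundles, internal-capsule-like
#' tube and the gray-matter map (union of gray structures, here the STN
#' ellipsoid), all deterministic under `subject_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param lead_name catalog key for this subject's lead.
#' @param subject_seed integer seed.
#' @return list with `lead`, `placement`, `grid`, `structures` (named list
#'   of `structure3d`: `stn`, `ic`, `gray`) and `pathways` (named list of
#'   `pathway`: `hdp`, `csbt`).
#' @export
generate_anatomy <- function(spec, lead_name, subject_seed) {
  lead <- build_lead(lead_name)
  with_seed(subject_seed, {
    tip <- stats::rnorm(3, 0, 0.5)
    tilt <- stats::rnorm(2, 0, 0.05)
    axis <- c(tilt[1], tilt[2], 1)
    axis <- axis / sqrt(sum(axis^2))
    roll <- stats::runif(1, 0, 360)
    placement <- lead_placement(tip, axis, roll)

    span <- contact_span(lead)
    ctr_lead <- c(0, 0, mean(span))
    grid <- grid_around(lead_to_world(rbind(ctr_lead), placement)[1, ],
                        spec$extent, spec$spacing)

    # STN-like ellipsoid (gray)
    c_stn <- spec$stn_center + stats::rnorm(3, 0, 0.3)
    ax <- grid_axes(grid)
    nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
    pts <- cbind(rep(ax$x, times = ny * nz),
                 rep(rep(ax$y, each = nx), times = nz),
                 rep(ax$z, each = nx * ny))
    pl <- world_to_lead(pts, placement)
    q <- sweep(pl, 2, c_stn)
    stn_mask <- array(rowSums(sweep(q, 2, spec$stn_semiaxes, `/`)^2) <= 1,
                      grid$dim)
    if (!any(stn_mask))
      stop("anatomy parameters place the STN ellipsoid outside the lattice")

    # near thin-fiber bundle: descends past the lead, ends in the ellipsoid
    hdp <- lapply(seq_len(spec$n_fibers), function(i) {
      off <- spec$hdp_offset + abs(stats::rnorm(1, 0, spec$hdp_spread))
      yy <- stats::rnorm(1, 0.5, spec$hdp_spread)
      p0 <- c(-off - 1.0, yy, 11)
      p1 <- c(-off, yy, 1.0)
      p2 <- c_stn + stats::rnorm(3, 0, 0.4) * spec$stn_semiaxes / 3
      lead_to_world(bezier3(p0, p1, p2, 25), placement)
    })

    # far large-fiber coherent bundle inside the capsule-like tube
    csbt <- lapply(seq_len(spec$n_fibers), function(i) {
      jx <- stats::rnorm(1, 0, spec$csbt_spread)
      jy <- stats::rnorm(1, 0, spec$csbt_spread)
      p0 <- c(-spec$csbt_offset + jx, jy, -11)
      p2 <- c(-spec$csbt_offset + jx + 0.8, jy + 0.5, 11)
      p1 <- (p0 + p2) / 2 + c(stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.3), 0)
      lead_to_world(bezier3(p0, p1, p2, 23), placement)
    })

    # capsule-like tube around the far bundle centreline
    ic_mask <- array(sqrt((pl[, 1] + spec$csbt_offset - 0.4)^2 +
                            pl[, 2]^2) <= spec$ic_radius, grid$dim)

    structures <- list(
      stn = structure3d("STN", stn_mask, grid),
      ic = structure3d("IC", ic_mask, grid),
      gray = structure3d("gray", stn_mask, grid))
    pathways <- list(
      hdp = pathway("HDP", hdp, spec$hdp_diameter),
      csbt = pathway("CSBT", csbt, spec$csbt_diameter))
    list(lead = lead, placement = placement, grid = grid,
         structures = structures, pathways = pathways)
  })
}

# per-subject settings drawn from the full menu to the template counts
generate_settings <- function(spec, lead, subject_seed) {
  menu_mono <- enumerate_settings(lead, list(monopolar = "each",
                                             amplitudes_mA = spec$amplitudes_mA))
  lv <- split(lead$contacts$index, lead$contacts$level)
  pairs <- list()
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (a == b) next
    pairs[[length(pairs) + 1L]] <- list(cathode = lv[[a]], anode = lv[[b]])
  }
  menu_bip <- enumerate_settings(lead, list(bipolar = pairs,
                                            amplitudes_mA = spec$amplitudes_mA))
  with_seed(subject_seed, {
    take <- function(menu, n) {
      if (n == 0) return(menu[0, ])
      menu[sample(nrow(menu), min(n, nrow(menu))), ]
    }
    tpl <- spec$.row_template
    out <- dplyr::bind_rows(take(menu_mono, tpl$n_monopolar),
                            take(menu_bip, tpl$n_bipolar))
    dplyr::mutate(out, setting_id = sprintf("S%03d", dplyr::row_number()))
  })
}

#' Synthetic evoked-potential table from ground-truth activation
#'
#' EP1 tracks near-bundle (HDP) activation, EP0 tracks far-bundle (CSBT)
#' activation, under the generative model of [ep_model()]. Settings with
#' zero true activation read exactly 0 (there is no response to measure);
#' otherwise amplitude = gain x activation + Gaussian noise, floored at 0,
#' with the EP0 detection floor and near-threshold zero-inflation applied.
#'
#' @param truth tibble with columns `setting_id`, `HDP`, `CSBT`
#'   (percent activation under the designated truth variant).
#' @param ep an [ep_model()].
#' @param subject_seed integer seed.
#' @return tibble `setting_id`, `EP0_uV`, `EP1_uV`.
#' @export
generate_ep_table <- function(truth, ep, subject_seed) {
  with_seed(subject_seed, {
    n <- nrow(truth)
    ep1 <- pmax(ep$gain * truth$HDP + stats::rnorm(n, 0, ep$noise_sd), 0)
    ep1[truth$HDP <= 0] <- 0
    ep0 <- pmax(ep$gain * truth$CSBT + stats::rnorm(n, 0, ep$noise_sd), 0)
    ep0[truth$CSBT <= 0] <- 0
    ep0[ep0 < ep$detection_floor] <- 0
    near <- ep0 > 0 & ep0 < ep$near_floor_mult * ep$detection_floor
    drop <- near & (stats::runif(n) < ep$ep0_zero_inflation)
    ep0[drop] <- 0
    tibble::tibble(setting_id = truth$setting_id, EP0_uV = ep0, EP1_uV = ep1)
  })
}

#' Generate a complete synthetic cohort
#'
#' For each subject: anatomy, stimulation settings, the ground-truth
#' activation (computed by running the designated truth variant on the
#' true native-space geometry), the evoked-potential table, and the
#' subject's normative-space deformation field. Fully deterministic under
#' `spec$seed`.
#'
#' The designated-truth construction is deliberately circular: the
#' evaluation's job is ranking recovery, so ground truth must be a known
#' member of the variant family; this is stated plainly in the package
#' documentation.
#'
#' @param spec a [cohort_spec()].
#' @param opts a [pipeline_options()] (solver resolutions for the truth
#'   computation).
#' @param cache optional environment reused across cohorts to cache
#'   lead-frame basis fields.
#' @return list of `subject_dataset` objects (class `dbs_cohort`).
#' @export
generate_cohort <- function(spec, opts = pipeline_options(), cache = NULL) {
  cache <- cache %||% new.env(parent = emptyenv())
  tpl <- spec$template
  rows <- tpl[((seq_len(spec$n_subjects) - 1) %% nrow(tpl)) + 1, ]
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sseed <- derive_seed(spec$seed, i)
    anat <- generate_anatomy(spec, rows$lead_name[i], derive_seed(sseed, 1))
    sp2 <- spec
    sp2$.row_template <- rows[i, ]
    settings <- generate_settings(sp2, anat$lead, derive_seed(sseed, 2))
    warp_grid <- grid_around(anat$grid$origin +
                               (anat$grid$dim - 1) / 2 * anat$grid$spacing,
                             spec$extent + 8, 1.5)
    warp <- synth_deformation(warp_grid, mean_mag = spec$warp_mean_mag,
                              global_scale = spec$warp_global_scale,
                              seed = derive_seed(sseed, 4))
    subj <- structure(list(
      subject_id = sprintf("SUBJ%02d", i),
      uid = sprintf("s%d_%02d", spec$seed, i), space = "native",
      lead_name = rows$lead_name[i], lead = anat$lead,
      placement = anat$placement, grid = anat$grid,
      structures = anat$structures, pathways = anat$pathways,
      settings = settings, deformation = warp), class = "subject_dataset")
    truth_act <- run_variant(subj, spec$ep$truth_variant, opts, cache)
    truth <- tidyr::pivot_wider(
      truth_act[, c("setting_id", "target", "value")],
      names_from = "target", values_from = "value")
    subj$truth <- truth[match(settings$setting_id, truth$setting_id), ]
    subj$ep <- generate_ep_table(subj$truth, spec$ep, derive_seed(sseed, 3))
    subjects[[i]] <- subj
  }
  structure(subjects, class = "dbs_cohort", spec = spec)
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (%s space): lead %s, %d settings\n",
              x$subject_id, x$space, x$lead_name, nrow(x$settings)))
  invisible(x)
}
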
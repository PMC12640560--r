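#' Configuration-driven pipeline
#'
#' Three stages tie the package together behind a single YAML (or list)
#' configuration: [pipeline_generate()] writes a synthetic cohort to disk,
#' [pipeline_run()] computes per-setting activation tables for the
#' requested variants (resumable: completed subject-variant pairs are
#' skipped unless `force`), and [pipeline_evaluate()] produces the
#' comparison report. Every stage copies the fully-resolved configuration
#' into the output directory for provenance, and everything is
#' deterministic under the configured seed.
#'
#' Recognized configuration keys: `seed`, `outdir`, `cohort` (arguments of
#' [cohort_spec()]), `solver` (arguments of [pipeline_options()]),
#' `variants` (list of variant ids or `"all"`), `evaluate`
#' (`contrasts: single_factor|default|none`, `groups`, `alpha`). Unknown
#' keys are rejected.
#'
#' @name pipeline
NULL

pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "outdir", "cohort", "solver", "variants", "evaluate")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outdir)) stop("configuration key 'outdir' is required")
  config$seed <- config$seed %||% 1L
  config$variants <- config$variants %||% "all"
  config
}

config_cohort_spec <- function(config) {
  args <- config$cohort %||% list()
  known <- setdiff(names(formals(cohort_spec)), c("template", "ep"))
  bad <- setdiff(names(args), c(known, "ep"))
  if (length(bad) > 0)
    stop("unknown cohort key(s): ", paste(bad, collapse = ", "))
  if (!is.null(args$ep)) args$ep <- do.call(ep_model, args$ep)
  args$seed <- args$seed %||% config$seed
  do.call(cohort_spec, args)
}

config_options <- function(config) {
  args <- config$solver %||% list()
  bad <- setdiff(names(args), names(formals(pipeline_options)))
  if (length(bad) > 0)
    stop("unknown solver key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_options, args)
}

config_variants <- function(config) {
  v <- config$variants
  if (identical(v, "all")) return(all_variants())
  out <- lapply(unlist(v), parse_variant)
  names(out) <- vapply(out, variant_id, character(1))
  out
}

# ---- subject disk layout ----------------------------------------------------

settings_to_csv <- function(settings, path) {
  df <- dplyr::mutate(settings,
    cathodes = vapply(.data$cathodes, paste, character(1), collapse = "|"),
    anodes = vapply(.data$anodes, function(a)
      if (length(a) == 0) "" else paste(a, collapse = "|"), character(1)))
  utils::write.csv(df, path, row.names = FALSE)
}

settings_from_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path,
                                          colClasses = c(anodes = "character")))
  df$cathodes <- lapply(strsplit(as.character(df$cathodes), "\\|"), as.integer)
  df$anodes <- lapply(strsplit(df$anodes, "\\|"),
                      function(a) as.integer(a[nzchar(a)]))
  df
}

#' Write / read one subject dataset
#'
#' Disk layout per subject: structure masks and the gray-matter map as
#' NIfTI, pathways as TCK, the deformation field as a NIfTI vector volume,
#' settings / EP / truth tables as CSV, and a JSON manifest tying the files
#' together with the lead model and placement.
#'
#' @param subject a `subject_dataset`.
#' @param dir subject directory.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(subject$structures))
    write_structure(subject$structures[[nm]],
                    file.path(dir, paste0(nm, ".nii.gz")))
  for (nm in names(subject$pathways))
    write_streamlines(subject$pathways[[nm]],
                      file.path(dir, paste0(nm, ".tck")))
  if (!is.null(subject$deformation))
    write_deformation(subject$deformation, file.path(dir, "warp.nii.gz"))
  settings_to_csv(subject$settings, file.path(dir, "settings.csv"))
  if (!is.null(subject$ep)) write_ep_table(subject$ep, file.path(dir, "ep.csv"))
  if (!is.null(subject$truth))
    utils::write.csv(subject$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  manifest <- list(
    subject_id = subject$subject_id, uid = subject_uid(subject),
    space = subject$space, lead_name = subject$lead_name,
    placement = list(tip_position = subject$placement$tip_position,
                     axis = subject$placement$axis,
                     roll = subject$placement$roll),
    grid = list(origin = subject$grid$origin, spacing = subject$grid$spacing,
                dim = subject$grid$dim),
    fiber_diameters = lapply(subject$pathways, `[[`, "fiber_diameter"),
    files = list(structures = paste0(names(subject$structures), ".nii.gz"),
                 pathways = paste0(names(subject$pathways), ".tck"),
                 deformation = if (!is.null(subject$deformation)) "warp.nii.gz",
                 settings = "settings.csv", ep = "ep.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  required <- c("settings.csv", unlist(mf$files$structures),
                unlist(mf$files$pathways))
  missing <- required[!file.exists(file.path(dir, required))]
  if (length(missing) > 0)
    stop("subject ", mf$subject_id, " is missing files: ",
         paste(missing, collapse = ", "))
  structures <- list()
  for (f in unlist(mf$files$structures)) {
    nm <- sub("\\.nii(\\.gz)?$", "", f)
    structures[[nm]] <- read_structure(file.path(dir, f))
    structures[[nm]]$name <- nm
  }
  pathways <- list()
  for (f in unlist(mf$files$pathways)) {
    nm <- sub("\\.tck$", "", f)
    pathways[[nm]] <- read_streamlines(file.path(dir, f),
                                       fiber_diameter = mf$fiber_diameters[[nm]],
                                       name = nm)
  }
  deformation <- NULL
  if (!is.null(mf$files$deformation) &&
      file.exists(file.path(dir, mf$files$deformation)))
    deformation <- read_deformation(file.path(dir, mf$files$deformation))
  ep <- NULL
  if (file.exists(file.path(dir, "ep.csv")))
    ep <- read_ep_table(file.path(dir, "ep.csv"))
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv")))
    truth <- tibble::as_tibble(utils::read.csv(file.path(dir, "truth.csv")))
  structure(list(
    subject_id = mf$subject_id, uid = mf$uid, space = mf$space,
    lead_name = mf$lead_name, lead = build_lead(mf$lead_name),
    placement = lead_placement(unlist(mf$placement$tip_position),
                               unlist(mf$placement$axis), mf$placement$roll),
    grid = vc_grid(unlist(mf$grid$origin), mf$grid$spacing,
                   unlist(mf$grid$dim)),
    structures = structures, pathways = pathways,
    settings = settings_from_csv(file.path(dir, "settings.csv")),
    deformation = deformation, ep = ep, truth = truth),
    class = "subject_dataset")
}

#' @rdname pipeline
#' @param config path to a YAML configuration file, or an equivalent list.
#' @return `pipeline_generate()`: the cohort directory, invisibly.
#' @export
pipeline_generate <- function(config) {
  config <- pipeline_config(config)
  spec <- config_cohort_spec(config)
  opts <- config_options(config)
  cohort <- generate_cohort(spec, opts)
  cdir <- file.path(config$outdir, "cohort")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) write_subject(subj, file.path(cdir, subj$subject_id))
  yaml::write_yaml(config, file.path(config$outdir, "config.yaml"))
  jsonlite::write_json(
    list(n_subjects = length(cohort),
         subjects = vapply(cohort, `[[`, character(1), "subject_id")),
    file.path(cdir, "cohort.json"), auto_unbox = TRUE, pretty = TRUE)
  message("wrote ", length(cohort), " subjects to ", cdir)
  invisible(cdir)
}

read_cohort <- function(outdir) {
  cdir <- file.path(outdir, "cohort")
  mf <- jsonlite::read_json(file.path(cdir, "cohort.json"),
                            simplifyVector = TRUE)
  subjects <- lapply(mf$subjects, function(s) read_subject(file.path(cdir, s)))
  structure(subjects, class = "dbs_cohort")
}

#' @rdname pipeline
#' @param force recompute subject-variant tables that already exist.
#' @return `pipeline_run()`: tibble of written activation CSV paths,
#'   invisibly.
#' @export
pipeline_run <- function(config, force = FALSE) {
  config <- pipeline_config(config)
  cohort <- read_cohort(config$outdir)
  opts <- config_options(config)
  variants <- config_variants(config)
  adir <- file.path(config$outdir, "activations")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  cache <- new.env(parent = emptyenv())
  written <- list()
  for (subj in cohort) {
    for (v in variants) {
      path <- file.path(adir, paste0(subj$subject_id, "_", variant_id(v), ".csv"))
      if (file.exists(path) && !force) {
        message("skipping ", basename(path), " (exists; use force = TRUE)")
        next
      }
      act <- run_variant(subj, v, opts, cache)
      utils::write.csv(act, path, row.names = FALSE)
      written[[length(written) + 1L]] <- path
    }
    stale <- grep(subject_uid(subj), ls(cache, all.names = TRUE),
                  value = TRUE, fixed = TRUE)
    rm(list = stale, envir = cache)
  }
  yaml::write_yaml(config, file.path(config$outdir, "config.yaml"))
  invisible(tibble::tibble(path = unlist(written)))
}

#' @rdname pipeline
#' @return `pipeline_evaluate()`: the `dbs_comparison` report (also written
#'   as CSV/JSON under `outdir/report`), invisibly.
#' @export
pipeline_evaluate <- function(config) {
  config <- pipeline_config(config)
  cohort <- read_cohort(config$outdir)
  variants <- config_variants(config)
  adir <- file.path(config$outdir, "activations")
  expected <- as.vector(outer(
    vapply(cohort, `[[`, character(1), "subject_id"),
    vapply(variants, variant_id, character(1)),
    function(s, v) paste0(s, "_", v, ".csv")))
  missing <- expected[!file.exists(file.path(adir, expected))]
  if (length(missing) > 0)
    stop("missing activation tables (run pipeline_run first): ",
         paste(missing, collapse = ", "))
  act <- dplyr::bind_rows(lapply(file.path(adir, expected), function(p)
    tibble::as_tibble(utils::read.csv(p))))
  ev <- config$evaluate %||% list()
  contrasts <- switch(ev$contrasts %||% "default",
                      default = default_contrasts(),
                      single_factor = single_factor_contrasts(),
                      none = NULL,
                      stop("unknown contrasts option: ", ev$contrasts))
  groups <- unlist(ev$groups %||% "all")
  rdir <- file.path(config$outdir, "report")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (g in groups) {
    rep <- compare_variants(act, cohort, contrasts = contrasts, group = g,
                            alpha = ev$alpha %||% 0.05)
    utils::write.csv(rep$r2, file.path(rdir, paste0("r2_", g, ".csv")),
                     row.names = FALSE)
    utils::write.csv(rep$summary,
                     file.path(rdir, paste0("summary_", g, ".csv")),
                     row.names = FALSE)
    if (!is.null(rep$tests))
      utils::write.csv(rep$tests, file.path(rdir, paste0("tests_", g, ".csv")),
                       row.names = FALSE)
    utils::write.csv(rep$fscore,
                     file.path(rdir, paste0("fscore_", g, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(group = g, summary = rep$summary, tests = rep$tests,
           fscore = rep$fscore),
      file.path(rdir, paste0("report_", g, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reports[[g]] <- rep
  }
  invisible(if (length(reports) == 1) reports[[1]] else reports)
}
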
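#' Single-factor contrasts among the six variants
#'
#' Enumerates every pair of admissible variants that differ in exactly one
#' of the three factors (method, space, representation): 3 space pairs,
#' 2 method pairs, 2 representation pairs — 7 in total.
#'
#' @return tibble: `factor`, `variant_a`, `variant_b`.
#' @export
single_factor_contrasts <- function() {
  vs <- all_variants()
  ids <- names(vs)
  rows <- list()
  for (a in seq_along(vs)) for (b in seq_along(vs)) {
    if (a >= b) next
    va <- vs[[a]]; vb <- vs[[b]]
    diffs <- c(method = va$method != vb$method,
               space = va$space != vb$space,
               representation = va$representation != vb$representation)
    if (sum(diffs) == 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        factor = names(diffs)[diffs], variant_a = ids[a], variant_b = ids[b])
  }
  dplyr::bind_rows(rows)
}

#' Compare model variants over a cohort
#'
#' Reproduces the statistical comparison machinery: per-subject
#' coefficients of determination between per-setting model predictions and
#' evoked-potential amplitudes (EP1 for the near pathway, EP0 for the far
#' pathway), variant medians and IQRs (type-7 quantiles), paired Wilcoxon
#' signed-rank tests for the requested contrasts, and presence/absence
#' F-scores for the far pathway with all-zero-subject exclusion.
#' Optionally the analysis is restricted to directional (segmented
#' contact) or non-directional (ring or pseudo-ring) settings.
#'
#' @param activations long tibble from [run_cohort()].
#' @param cohort the `dbs_cohort` the activations came from (supplies EP
#'   tables and setting flags).
#' @param contrasts tibble with columns `variant_a`, `variant_b` (default
#'   [single_factor_contrasts()] plus the conventional pair
#'   DF-Native-Pathway vs VTA-Normative-Structure).
#' @param group `"all"`, `"directional"` or `"nondirectional"`.
#' @param alpha significance level recorded in the report.
#' @return A `dbs_comparison` object with components `r2` (per subject x
#'   variant x target), `summary` (medians/IQRs), `tests` (paired
#'   Wilcoxon results), `fscore`, `excluded` (flagged subjects), `group`.
#'   [tidy()] returns `r2`, [glance()] returns `summary`,
#'   [autoplot()] draws the per-variant R-squared box plots.
#' @export
compare_variants <- function(activations, cohort,
                             contrasts = default_contrasts(),
                             group = c("all", "directional", "nondirectional"),
                             alpha = 0.05) {
  group <- match.arg(group)
  obs <- dplyr::bind_rows(lapply(cohort, function(s) {
    dplyr::bind_rows(
      tibble::tibble(subject_id = s$subject_id,
                     setting_id = s$ep$setting_id, target = "HDP",
                     observed = s$ep$EP1_uV,
                     directional = s$settings$directional),
      tibble::tibble(subject_id = s$subject_id,
                     setting_id = s$ep$setting_id, target = "CSBT",
                     observed = s$ep$EP0_uV,
                     directional = s$settings$directional))
  }))
  joined <- dplyr::inner_join(activations, obs,
                              by = c("subject_id", "setting_id", "target"))
  if (group == "directional") joined <- dplyr::filter(joined, .data$directional)
  if (group == "nondirectional") joined <- dplyr::filter(joined, !.data$directional)
  if (nrow(joined) == 0) stop("no settings left after group filtering")

  r2 <- joined |>
    dplyr::group_by(.data$variant, .data$target, .data$subject_id) |>
    dplyr::summarise(
      n_settings = dplyr::n(),
      r2 = if (dplyr::n() >= 3) as.numeric(r_squared(.data$value, .data$observed))
           else NA_real_,
      all_zero_pred = all(.data$value == 0),
      .groups = "drop")

  excluded <- dplyr::filter(r2, is.na(.data$r2))

  summary <- r2 |>
    dplyr::filter(!is.na(.data$r2)) |>
    dplyr::group_by(.data$variant, .data$target) |>
    dplyr::reframe(median_iqr(.data$r2))

  tests <- NULL
  if (!is.null(contrasts) && nrow(contrasts) > 0) {
    wide <- tidyr::pivot_wider(r2[, c("variant", "target", "subject_id", "r2")],
                               names_from = "variant", values_from = "r2")
    rows <- list()
    for (i in seq_len(nrow(contrasts))) {
      va <- contrasts$variant_a[i]; vb <- contrasts$variant_b[i]
      if (!va %in% names(wide) || !vb %in% names(wide))
        stop("contrast references a variant not present in the activations: ",
             va, " vs ", vb)
      for (tg in unique(wide$target)) {
        sub <- wide[wide$target == tg, ]
        ok <- !is.na(sub[[va]]) & !is.na(sub[[vb]])
        res <- tryCatch(
          wilcoxon_signed_rank(sub[[va]][ok], sub[[vb]][ok]),
          error = function(e) tibble::tibble(statistic = NA_real_,
                                             p_value = NA_real_,
                                             n_used = sum(ok),
                                             method = conditionMessage(e)))
        fac <- if ("factor" %in% names(contrasts)) contrasts$factor[i]
               else NA_character_
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(variant_a = va, variant_b = vb, target = tg,
                         factor = fac),
          res)
      }
    }
    tests <- dplyr::bind_rows(rows)
    tests$significant <- !is.na(tests$p_value) & tests$p_value < alpha
  }

  # far-pathway presence/absence F-score per variant x subject
  fs <- joined |>
    dplyr::filter(.data$target == "CSBT") |>
    dplyr::group_by(.data$variant, .data$subject_id) |>
    dplyr::summarise(
      f = list(f_score_presence(.data$value, .data$observed)),
      .groups = "drop") |>
    dplyr::mutate(
      excluded = purrr::map_lgl(.data$f, ~ isTRUE(attr(.x, "excluded"))),
      f_score = purrr::map_dbl(.data$f, as.numeric),
      precision = purrr::map_dbl(.data$f, ~ attr(.x, "precision") %||% NA_real_),
      recall = purrr::map_dbl(.data$f, ~ attr(.x, "recall") %||% NA_real_)) |>
    dplyr::select(-"f")

  structure(list(r2 = r2, summary = summary, tests = tests, fscore = fs,
                 excluded = excluded, group = group, alpha = alpha),
            class = "dbs_comparison")
}

#' @rdname compare_variants
#' @export
default_contrasts <- function() {
  dplyr::bind_rows(
    single_factor_contrasts(),
    tibble::tibble(factor = "conventional",
                   variant_a = "DF-Native-Pathway",
                   variant_b = "VTA-Normative-Structure"))
}

#' @export
print.dbs_comparison <- function(x, ...) {
  cat("<dbs_comparison> group:", x$group, "\n")
  cat("Per-variant median R^2:\n")
  print(as.data.frame(x$summary), digits = 3)
  if (!is.null(x$tests)) {
    cat("\nPaired Wilcoxon signed-rank contrasts:\n")
    print(as.data.frame(x$tests[, c("variant_a", "variant_b", "target",
                                    "p_value", "significant")]), digits = 3)
  }
  invisible(x)
}

#' @export
tidy.dbs_comparison <- function(x, ...) x$r2

#' @export
glance.dbs_comparison <- function(x, ...) x$summary

#' Box plots of per-subject model performance by variant
#'
#' @param object a `dbs_comparison`.
#' @param ... unused.
#' @return a ggplot object: per-subject R-squared by variant, faceted by
#'   target pathway.
#' @export
autoplot.dbs_comparison <- function(object, ...) {
  df <- dplyr::filter(object$r2, !is.na(.data$r2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~ .data$target) +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = "Per-subject model performance by variant",
                  subtitle = paste("settings group:", object$group)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
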
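#' Coefficient of determination (squared Pearson correlation)
#'
#' Model performance metric: the square of the Pearson correlation between
#' per-setting model predictions and observed evoked-potential amplitudes.
#' Requires at least 3 paired values and non-constant series; a constant
#' series makes the correlation undefined and returns `NA` with attribute
#' `undefined = TRUE` (callers exclude and log such subjects).
#'
#' @param predicted numeric vector of model activation values.
#' @param observed numeric vector of EP amplitudes (same length).
#' @return R-squared in `[0, 1]`, or flagged `NA`.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 3, 2))  # 0.25
#' @export
r_squared <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(predicted) < 3) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(predicted, observed)^2
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on per-subject performance values. Zero
#' differences are dropped; for n <= 25 remaining pairs without ties among
#' the absolute differences the exact signed-rank distribution is used,
#' otherwise the normal approximation with continuity correction (the
#' method actually used is reported). All differences zero gives p = 1
#' with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param alternative passed to the test (default two-sided).
#' @return one-row tibble: `statistic`, `p_value`, `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = NA_real_, p_value = 1, n_used = 0L,
                          method = "degenerate (all differences zero)"))
  }
  if (n < 5) stop("need at least 5 nonzero paired differences (got ", n, ")")
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_used = n,
                 method = if (exact) "exact signed-rank distribution"
                          else "normal approximation (continuity-corrected)")
}

#' F-score on presence/absence of activation
#'
#' Binary agreement between predicted activation presence
#' (`predicted > threshold`) and observed presence (`observed > threshold`),
#' used for the far-bundle (CSBT) comparison where true negatives dominate.
#' F = 2PR / (P + R). Subjects whose observed amplitudes are zero for every
#' setting carry no signal and are excluded (`NA` with attribute
#' `excluded = TRUE`), as are degenerate cases with no positives on either
#' side. When the observed series has positives but the model predicts
#' none, precision is undefined and F is 0 by convention.
#'
#' @param predicted numeric vector of model activation values.
#' @param observed numeric vector of EP0 amplitudes.
#' @param threshold binarization threshold (strictly-greater; default 0).
#' @return F-score in `[0, 1]` with attributes `precision` and `recall`,
#'   or flagged `NA` when excluded.
#' @export
f_score_presence <- function(predicted, observed, threshold = 0) {
  stopifnot(length(predicted) == length(observed))
  pp <- predicted > threshold
  op <- observed > threshold
  if (!any(op)) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  if (!any(pp) && !any(op)) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  tp <- sum(pp & op)
  prec <- if (sum(pp) == 0) 0 else tp / sum(pp)
  rec <- tp / sum(op)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  attr(f, "precision") <- prec
  attr(f, "recall") <- rec
  f
}

# linear-interpolation (type 7) quantiles, the documented convention for
# all medians/IQRs the package prints
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(x), q25 = q[1], median = q[2], q75 = q[3])
}
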
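#' Marker labeling index with SEM
#'
#' Mean percentage of marker-positive nuclei over fields of view. By default
#' every field, across replicates, is an independent unit in the SEM
#' denominator; `unit = "replicate"` first averages fields within each
#' replicate and uses replicate means as units.
#'
#' @param counts Field-count data.frame with columns `n_pos`, `n_total` and,
#'   for `unit = "replicate"`, `replicate`.
#' @param unit SEM unit: `"field"` (default) or `"replicate"`.
#'
#' @return A list: `mean_pct`, `sem_pct`, `n` (number of units), `unit`.
#' @examples
#' marker_index(data.frame(n_pos = c(2, 4), n_total = c(100, 100)))
#' @export
marker_index <- function(counts, unit = c("field", "replicate")) {
  unit <- match.arg(unit)
  if (is.null(counts) || nrow(counts) == 0)
    abort_validation("marker_index requires a non-empty count table")
  if (any(counts$n_total < 1) || any(counts$n_pos < 0 | counts$n_pos > counts$n_total))
    abort_validation("field counts must satisfy 0 <= n_pos <= n_total, n_total >= 1")
  pct <- 100 * counts$n_pos / counts$n_total
  if (unit == "replicate") {
    if (!"replicate" %in% names(counts))
      abort_validation("unit = 'replicate' requires a replicate column")
    pct <- vapply(split(pct, counts$replicate), mean, numeric(1))
  }
  n <- length(pct)
  list(mean_pct = mean(pct),
       sem_pct = if (n > 1) stats::sd(pct) / sqrt(n) else 0,
       n = n, unit = unit)
}

#' Two-tailed Student's t-test on per-field percentages
#'
#' Pooled-variance Student's t-test by default (`equal_var = TRUE`); Welch's
#' correction by flag. Degenerate inputs follow the conventions of the
#' assay's reporting: two constant groups with equal means give `t = 0`,
#' `p = 1`; constant groups with different means give `p = 0`.
#'
#' @param group_a,group_b Numeric vectors (e.g. per-field percentages), each
#'   of length >= 2.
#' @param equal_var Pooled-variance Student statistic if `TRUE` (default),
#'   Welch otherwise.
#'
#' @return A list of class `t_test_result`: `t_stat`, `df`, `p_two_tailed`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`.
#' @examples
#' student_t_two_tailed(c(10, 12, 14), c(16, 18, 20))
#' @export
student_t_two_tailed <- function(group_a, group_b, equal_var = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    abort_validation("each group needs at least 2 observations")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    eq <- mean(group_a) == mean(group_b)
    res <- list(t_stat = if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2,
                p_two_tailed = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = equal_var)
    res <- list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                p_two_tailed = tt$p.value)
  }
  structure(c(res, list(mean_a = mean(group_a), mean_b = mean(group_b),
                        sem_a = sem(group_a), sem_b = sem(group_b),
                        equal_var = equal_var)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Student's t (two-tailed%s): t = %.3f, df = %.2f, p = %.4g\n",
              if (x$equal_var) "" else ", Welch", x$t_stat, x$df, x$p_two_tailed))
  cat(sprintf("  group A: %.3f +/- %.3f; group B: %.3f +/- %.3f\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  invisible(x)
}

#' Per-timepoint t-tests between two labeling time courses
#'
#' One two-tailed Student's t-test per shared timepoint, on per-field
#' labeling percentages. Significance is flagged at `alpha` without
#' multiplicity correction by default (per-timepoint reporting convention);
#' `p_adjust = TRUE` adds Benjamini-Hochberg adjusted p-values and flags on
#' those instead.
#'
#' @param curve_a,curve_b Labeling-curve data.frames sharing a time grid.
#' @param alpha Significance level (default 0.05).
#' @param equal_var Passed to [student_t_two_tailed()].
#' @param p_adjust Apply Benjamini-Hochberg correction (default `FALSE`).
#'
#' @return A data.frame with one row per shared timepoint: group means and
#'   SEMs (percent), `t_stat`, `df`, `p`, optionally `p_adj`, `significant`.
#' @export
timecourse_tests <- function(curve_a, curve_b, alpha = 0.05, equal_var = TRUE,
                             p_adjust = FALSE) {
  validate_labeling_curve(curve_a)
  validate_labeling_curve(curve_b)
  shared <- intersect(unique(curve_a$time_h), unique(curve_b$time_h))
  if (length(shared) == 0)
    abort_validation("curves share no timepoints")
  shared <- sort(shared)
  rows <- lapply(shared, function(tt) {
    pa <- 100 * with(curve_a[curve_a$time_h == tt, ], n_pos / n_total)
    pb <- 100 * with(curve_b[curve_b$time_h == tt, ], n_pos / n_total)
    r <- student_t_two_tailed(pa, pb, equal_var = equal_var)
    data.frame(time_h = tt, mean_a = r$mean_a, sem_a = r$sem_a,
               mean_b = r$mean_b, sem_b = r$sem_b,
               t_stat = r$t_stat, df = r$df, p = r$p_two_tailed)
  })
  out <- do.call(rbind, rows)
  if (p_adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out
}
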
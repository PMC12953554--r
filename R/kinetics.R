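#' Aggregate a labeling curve to per-timepoint means
#'
#' Computes the per-field labeling index `n_pos / n_total` and summarises it
#' per timepoint as the mean over all fields and replicates, with the SEM
#' over the same units (fields pooled across replicates, matching the
#' SEM-over-fields reporting convention of the assay).
#'
#' @param curve A labeling-curve data.frame (`condition`, `replicate`,
#'   `field`, `time_h`, `n_pos`, `n_total`).
#'
#' @return A data.frame with one row per (`condition`, `time_h`):
#'   `mean_index`, `sem_index`, `n_fields`.
#' @export
aggregate_curve <- function(curve) {
  validate_labeling_curve(curve)
  idx <- curve$n_pos / curve$n_total
  key <- interaction(curve$condition, curve$time_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(idx), key), function(i) {
    x <- idx[i]
    data.frame(condition = curve$condition[i[1]], time_h = curve$time_h[i[1]],
               mean_index = mean(x),
               sem_index = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
               n_fields = length(x))
  }))
  agg <- agg[order(agg$condition, agg$time_h), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

validate_labeling_curve <- function(curve) {
  need <- c("condition", "replicate", "field", "time_h", "n_pos", "n_total")
  miss <- setdiff(need, names(curve))
  if (length(miss))
    abort_validation(paste("labeling curve missing columns:", paste(miss, collapse = ", ")))
  if (nrow(curve) == 0) abort_validation("labeling curve is empty")
  bad <- which(curve$n_total < 1)
  if (length(bad))
    abort_validation(sprintf(
      "n_total must be >= 1; first offending record: condition=%s replicate=%s field=%s time_h=%g",
      curve$condition[bad[1]], curve$replicate[bad[1]], curve$field[bad[1]],
      curve$time_h[bad[1]]))
  bad <- which(curve$n_pos < 0 | curve$n_pos > curve$n_total)
  if (length(bad))
    abort_validation(sprintf(
      "need 0 <= n_pos <= n_total; first offending record: condition=%s replicate=%s field=%s time_h=%g",
      curve$condition[bad[1]], curve$replicate[bad[1]], curve$field[bad[1]],
      curve$time_h[bad[1]]))
  invisible(curve)
}

# weighted three-segment (flat-linear-flat) model evaluated at one breakpoint
# pair; returns list(level0, plateau, rss) or NULL if the pair is infeasible
seg_eval <- function(b1, b2, t, y, w) {
  left <- t <= b1
  right <- t >= b2
  if (!any(left) || !any(right)) return(NULL)
  l0 <- stats::weighted.mean(y[left], w[left])
  pl <- stats::weighted.mean(y[right], w[right])
  if (pl < l0) return(NULL)
  mid <- !(left | right)
  pred <- numeric(length(t))
  pred[left] <- l0
  pred[right] <- pl
  pred[mid] <- l0 + (pl - l0) * (t[mid] - b1) / (b2 - b1)
  list(level0 = l0, plateau = pl, rss = sum(w * (y - pred)^2))
}

#' Fit a three-segment (flat-rise-flat) model to an aggregated curve
#'
#' Least-squares formalisation of reading the breakpoints of a cumulative
#' labeling curve off its growing phase: the expected index is constant at
#' `level0` up to `break1`, linear up to `break2`, then constant at
#' `plateau`. `level0` and `plateau` are the weighted means (weights =
#' fields per timepoint) of the points in their segments; the middle segment
#' is the line connecting `(break1, level0)` to `(break2, plateau)`. The
#' residual sum of squares is minimised by exhaustive search over a
#' `grid_step`-spaced grid of `(break1, break2)` pairs spanning the sampled
#' times, with deterministic tie-breaking (smallest `break1`, then smallest
#' `break2`); `refine = TRUE` polishes the grid optimum by continuous
#' Nelder-Mead search.
#'
#' @param agg Aggregated curve from [aggregate_curve()] (single condition).
#' @param grid_step Breakpoint grid spacing, hours (default 0.1).
#' @param refine Logical; continuous refinement of the grid optimum.
#' @param min_rise Minimum fitted `plateau - level0` below which the curve is
#'   declared degenerate (no rise segment; default 0.05).
#' @param rise_tol Maximum allowed rise between the last two timepoints
#'   before declaring that no plateau was reached (default 0.05).
#'
#' @return An object of class `segmented_fit`: `break1`, `break2`, `level0`,
#'   `plateau`, `rss`, `n_points`, `grid_step`, `refined`.
#' @examples
#' pr <- labeling_protocol(mode = "lagged_rise")
#' curve <- generate_lagged_rise_curve(condition_presets()$DMSO, pr, seed = 1)
#' fit_segmented(aggregate_curve(curve))
#' @export
fit_segmented <- function(agg, grid_step = 0.1, refine = FALSE,
                          min_rise = 0.05, rise_tol = 0.05) {
  if (length(unique(agg$condition)) > 1)
    abort_validation("fit_segmented expects a single condition; subset first")
  t <- agg$time_h
  y <- agg$mean_index
  w <- if ("n_fields" %in% names(agg)) agg$n_fields else rep(1, length(t))
  m <- length(t)
  if (m < 5)
    abort_insufficient_data("fit_segmented needs at least 5 timepoints")
  if (y[m] - y[m - 1] > rise_tol)
    abort_no_saturation("curve still rising between the last two timepoints; no plateau detectable")
  if (diff(range(y)) < min_rise)
    abort_no_saturation("curve has no detectable rise segment (flat within min_rise)")

  cand <- round(seq(t[1], t[m], by = grid_step), 9)
  cand <- cand[cand < t[m]]  # invariant: break2 < max sample time
  # Exhaustive search over (break1, break2) pairs, vectorised over break2 for
  # each break1 via prefix/suffix weighted sums. For a fixed break1 the left
  # segment (t <= break1) is fixed; the right-segment mean and RSS depend on
  # break2 only through the first timepoint index at/after it, and the middle
  # RSS expands into three cumulative sums in (y - level0, t - break1).
  sw <- cumsum(w); swy <- cumsum(w * y); swy2 <- cumsum(w * y^2)
  tw <- sw[m]; twy <- swy[m]; twy2 <- swy2[m]
  # suffix sums starting at index j
  suf_w  <- tw  - c(0, sw)[seq_len(m)]
  suf_wy <- twy - c(0, swy)[seq_len(m)]
  suf_wy2 <- twy2 - c(0, swy2)[seq_len(m)]
  i1_all <- findInterval(cand, t)          # points with t <= b1
  js_all <- findInterval(cand, t, left.open = TRUE) + 1L  # first t >= b2
  tie_tol <- 1e-10
  best <- NULL
  best_rss <- Inf
  for (p1 in seq_along(cand)) {
    b1 <- cand[p1]
    i1 <- i1_all[p1]
    sel2 <- which(cand > b1)
    if (!length(sel2)) next
    b2v <- cand[sel2]
    js <- js_all[sel2]
    l0 <- swy[i1] / sw[i1]
    rss_left <- swy2[i1] - swy[i1]^2 / sw[i1]
    pl <- suf_wy[js] / suf_w[js]
    rss_right <- suf_wy2[js] - suf_wy[js]^2 / suf_w[js]
    u <- y - l0
    v <- t - b1
    A <- cumsum(w * u^2); B <- cumsum(w * u * v); C <- cumsum(w * v^2)
    jm <- js - 1L  # last middle index
    A_mid <- ifelse(jm > i1, A[pmax(jm, 1L)] - A[i1], 0)
    B_mid <- ifelse(jm > i1, B[pmax(jm, 1L)] - B[i1], 0)
    C_mid <- ifelse(jm > i1, C[pmax(jm, 1L)] - C[i1], 0)
    s <- (pl - l0) / (b2v - b1)
    rss <- rss_left + rss_right + A_mid - 2 * s * B_mid + s^2 * C_mid
    rss[pl < l0] <- Inf
    k <- which.min(rss)
    if (!is.finite(rss[k])) next
    # earliest b2 among within-tolerance ties of this b1's minimum
    k <- which(rss <= rss[k] + tie_tol * (1 + rss[k]))[1]
    # strict improvement beyond tie tolerance; earlier b1 wins ties
    if (!is.finite(best_rss) || rss[k] < best_rss - tie_tol * (1 + best_rss)) {
      best_rss <- rss[k]
      best <- list(break1 = b1, break2 = b2v[k], level0 = l0,
                   plateau = pl[k], rss = rss[k])
    }
  }
  if (is.null(best))
    abort_no_saturation("no feasible breakpoint pair (plateau never exceeds initial level)")
  best$rss <- max(best$rss, 0)  # guard against negative fp residue on exact fits

  if (refine) {
    obj <- function(par) {
      ev <- seg_eval(par[1], par[2], t, y, w)
      if (is.null(ev) || par[1] <= 0 || par[2] <= par[1] || par[2] >= t[m]) return(1e6)
      ev$rss
    }
    opt <- stats::optim(c(best$break1, best$break2), obj, method = "Nelder-Mead")
    if (opt$value < best$rss) {
      ev <- seg_eval(opt$par[1], opt$par[2], t, y, w)
      best <- list(break1 = opt$par[1], break2 = opt$par[2],
                   level0 = ev$level0, plateau = ev$plateau, rss = ev$rss)
    }
  }
  structure(c(best, list(n_points = m, grid_step = grid_step, refined = refine)),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Segmented fit: break1 = %.2f h, break2 = %.2f h, level0 = %.3f, plateau = %.3f (RSS %.3g, %d points)\n",
    x$break1, x$break2, x$level0, x$plateau, x$rss, x$n_points))
  invisible(x)
}

new_kinetic_estimate <- function(method, gf, ts, tc, ci_gf = NULL, ci_ts = NULL,
                                 ci_tc = NULL, n_boot = 0L, fit = NULL,
                                 boot_draws = NULL) {
  if (!(tc > ts && ts > 0))
    abort_validation("kinetic estimate violates tc > ts > 0")
  structure(list(method = method, gf_hat = gf, ts_hat = ts, tc_hat = tc,
                 tsat_hat = tc - ts, ci_gf = ci_gf, ci_ts = ci_ts,
                 ci_tc = ci_tc, n_boot = n_boot, fit = fit,
                 boot_draws = boot_draws),
            class = "kinetic_estimate")
}

#' Kinetic estimate from a segmented breakpoint fit
#'
#' Reads the cell-cycle kinetics off a three-segment fit of a cumulative
#' labeling curve: the initial constant phase lasts one S-phase length
#' (`ts = break1`), saturation occurs when the last cycling cell enters S
#' (`tsat = break2 = Tc - Ts`), so `tc = break1 + break2`, and the plateau
#' estimates the growth fraction.
#'
#' @param fit A `segmented_fit` from [fit_segmented()].
#' @return A `kinetic_estimate` with `method = "breakpoint"`.
#' @examples
#' pr <- labeling_protocol(mode = "lagged_rise")
#' curve <- generate_lagged_rise_curve(condition_presets()$DMSO, pr, seed = 1)
#' estimate_breakpoint(fit_segmented(aggregate_curve(curve)))
#' @export
estimate_breakpoint <- function(fit) {
  stopifnot(inherits(fit, "segmented_fit"))
  new_kinetic_estimate("breakpoint", gf = fit$plateau, ts = fit$break1,
                       tc = fit$break1 + fit$break2, fit = fit)
}

#' Kinetic estimate under the classical linear-rise model
#'
#' Classical cumulative-labeling model for an asynchronous steady-state
#' population: `index(t) = GF * (t + Ts) / Tc` until saturation at
#' `t = Tc - Ts`, then `GF`. The plateau level is the mean of the maximal
#' suffix of timepoints within `plateau_tolerance` of the final level; a
#' least-squares line `a + b t` through the remaining (pre-plateau) points
#' gives `tc = GF / b` and `ts = a / b`.
#'
#' @param agg Aggregated curve from [aggregate_curve()] (single condition).
#' @param plateau_tolerance Absolute index tolerance for plateau membership
#'   (default 0.03).
#' @return A `kinetic_estimate` with `method = "linear_rise"`.
#' @export
estimate_linear_rise <- function(agg, plateau_tolerance = 0.03) {
  if (length(unique(agg$condition)) > 1)
    abort_validation("estimate_linear_rise expects a single condition; subset first")
  t <- agg$time_h
  y <- agg$mean_index
  w <- if ("n_fields" %in% names(agg)) agg$n_fields else rep(1, length(t))
  m <- length(t)
  final <- y[m]
  i0 <- m
  while (i0 > 1 && abs(y[i0 - 1] - final) <= plateau_tolerance) i0 <- i0 - 1
  plateau_idx <- i0:m
  rise_idx <- seq_len(i0 - 1)
  if (length(plateau_idx) == 1 && m >= 2 && y[m] - y[m - 1] > plateau_tolerance)
    abort_no_saturation("no plateau detectable at the end of the curve")
  if (length(rise_idx) < 3)
    abort_insufficient_data("estimate_linear_rise needs >= 3 pre-plateau timepoints")
  gf <- stats::weighted.mean(y[plateau_idx], w[plateau_idx])
  coefs <- stats::coef(stats::lm(y[rise_idx] ~ t[rise_idx], weights = w[rise_idx]))
  a <- coefs[[1]]
  b <- coefs[[2]]
  if (b <= 0) abort_no_growth("non-positive slope in the growing phase")
  new_kinetic_estimate("linear_rise", gf = gf, ts = a / b, tc = gf / b)
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat(sprintf("Kinetic estimate (%s): GF = %.3f, Ts = %.2f h, Tc = %.2f h, Tsat = %.2f h\n",
              x$method, x$gf_hat, x$ts_hat, x$tc_hat, x$tsat_hat))
  if (x$n_boot > 0) {
    cat(sprintf("  95%% CIs (n_boot = %d): Ts [%.2f, %.2f], Tc [%.2f, %.2f], GF [%.3f, %.3f]\n",
                x$n_boot, x$ci_ts[1], x$ci_ts[2], x$ci_tc[1], x$ci_tc[2],
                x$ci_gf[1], x$ci_gf[2]))
  }
  invisible(x)
}

fit_curve_by_method <- function(agg, method, grid_step, plateau_tolerance) {
  if (method == "breakpoint") {
    estimate_breakpoint(fit_segmented(agg, grid_step = grid_step))
  } else {
    estimate_linear_rise(agg, plateau_tolerance = plateau_tolerance)
  }
}

#' Bootstrap confidence intervals for a kinetic estimate
#'
#' Point estimate from the full curve; percentile 95% CIs from resampling
#' fields with replacement within each (replicate, timepoint) stratum —
#' the field is the sampling unit of the assay. Bootstrap replicates whose
#' fit fails are dropped and counted; more than 20% failures aborts.
#'
#' @param curve A labeling-curve data.frame (single condition).
#' @param method `"breakpoint"` (default) or `"linear_rise"`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the resampling.
#' @param grid_step Grid spacing for the breakpoint fit, hours.
#' @param plateau_tolerance Plateau tolerance for the linear-rise fit.
#'
#' @return A `kinetic_estimate` carrying `ci_ts`, `ci_tc`, `ci_gf`, `n_boot`
#'   and the bootstrap draws (`boot_draws` data.frame).
#' @export
bootstrap_estimate <- function(curve, method = c("breakpoint", "linear_rise"),
                               n_boot = 200, seed = 1, grid_step = 0.1,
                               plateau_tolerance = 0.03) {
  method <- match.arg(method)
  if (n_boot < 100) abort_validation("n_boot must be >= 100")
  validate_labeling_curve(curve)
  if (length(unique(curve$condition)) > 1)
    abort_validation("bootstrap_estimate expects a single condition; subset first")
  point <- fit_curve_by_method(aggregate_curve(curve), method, grid_step,
                               plateau_tolerance)
  strata <- split(seq_len(nrow(curve)),
                  interaction(curve$replicate, curve$time_h, drop = TRUE))
  set.seed(seed)
  draws <- vector("list", n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(i) i[sample.int(length(i), replace = TRUE)]),
                  use.names = FALSE)
    est <- tryCatch(
      fit_curve_by_method(aggregate_curve(curve[idx, , drop = FALSE]),
                          method, grid_step, plateau_tolerance),
      edukinetics_error = function(e) NULL)
    if (is.null(est)) failed <- failed + 1L
    else draws[[b]] <- data.frame(ts = est$ts_hat, tc = est$tc_hat, gf = est$gf_hat)
  }
  if (failed > 0.2 * n_boot)
    abort_unstable_fit(sprintf("unstable fit: %d of %d bootstrap replicates failed",
                               failed, n_boot))
  dd <- do.call(rbind, draws)
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  structure(
    list(method = method, gf_hat = point$gf_hat, ts_hat = point$ts_hat,
         tc_hat = point$tc_hat, tsat_hat = point$tsat_hat,
         ci_gf = ci(dd$gf), ci_ts = ci(dd$ts), ci_tc = ci(dd$tc),
         n_boot = nrow(dd), fit = point$fit, boot_draws = dd,
         n_failed = failed),
    class = "kinetic_estimate")
}

#' Compare the kinetics of two conditions
#'
#' Differences in estimated Ts and Tc between two conditions with, when
#' bootstrap draws are available, bootstrap exceedance probabilities: the
#' fraction of resampled difference draws on the opposite side of zero from
#' the observed difference (a p-value-like quantity; small values mean the
#' difference is stable under field resampling).
#'
#' @param est_a,est_b `kinetic_estimate` objects fitted with the same method
#'   (e.g. from [bootstrap_estimate()]); deltas are b minus a.
#'
#' @return An object of class `condition_comparison`: `delta_ts`, `delta_tc`
#'   (hours) and, with bootstrap draws, `p_delta_ts`, `p_delta_tc`.
#' @export
compare_conditions <- function(est_a, est_b) {
  stopifnot(inherits(est_a, "kinetic_estimate"), inherits(est_b, "kinetic_estimate"))
  if (est_a$method != est_b$method)
    abort_validation("compare_conditions requires both estimates to use the same method")
  delta_ts <- est_b$ts_hat - est_a$ts_hat
  delta_tc <- est_b$tc_hat - est_a$tc_hat
  p_ts <- p_tc <- NA_real_
  if (!is.null(est_a$boot_draws) && !is.null(est_b$boot_draws)) {
    n <- min(nrow(est_a$boot_draws), nrow(est_b$boot_draws))
    exceed <- function(da, db, obs) {
      d <- db[seq_len(n)] - da[seq_len(n)]
      if (obs >= 0) mean(d <= 0) else mean(d >= 0)
    }
    p_ts <- exceed(est_a$boot_draws$ts, est_b$boot_draws$ts, delta_ts)
    p_tc <- exceed(est_a$boot_draws$tc, est_b$boot_draws$tc, delta_tc)
  }
  structure(list(delta_ts = delta_ts, delta_tc = delta_tc,
                 p_delta_ts = p_ts, p_delta_tc = p_tc,
                 method = est_a$method),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s): delta Ts = %.2f h, delta Tc = %.2f h\n",
              x$method, x$delta_ts, x$delta_tc))
  if (!is.na(x$p_delta_ts))
    cat(sprintf("  bootstrap exceedance: Ts %.3f, Tc %.3f\n",
                x$p_delta_ts, x$p_delta_tc))
  invisible(x)
}
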
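#' Generative cell-cycle parameters
#'
#' Bundles the parameters of an asynchronous cycling population: total cycle
#' length (mean and between-cell coefficient of variation), S-phase duration,
#' combined G2+M duration, growth fraction (proportion of cells actively
#' cycling) and label detection efficiency.
#'
#' Phases are ordered G1 -> S -> G2 -> M, with the S window occupying cycle
#' positions `[tc_mean - ts - tg2m, tc_mean - tg2m)` (per cell, scaled to its
#' own cycle length when `tc_cv > 0`).
#'
#' @param tc_mean Mean total cell-cycle length, hours.
#' @param ts S-phase duration, hours.
#' @param growth_fraction Fraction of cells actively cycling, in `[0, 1]`.
#' @param tc_cv Coefficient of variation of per-cell cycle length
#'   (lognormal between-cell variability); 0 gives identical cycle lengths.
#' @param tg2m Combined G2+M duration, hours (used by the marker generators).
#' @param label_efficiency Probability that a cell traversing S during the
#'   exposure window is detected label-positive. A saturating label dose
#'   justifies the default of 1.
#'
#' @return An object of class `cell_cycle_params`.
#' @examples
#' cell_cycle_params(tc_mean = 31, ts = 10, growth_fraction = 0.9)
#' @export
cell_cycle_params <- function(tc_mean, ts, growth_fraction,
                              tc_cv = 0.15, tg2m = 3,
                              label_efficiency = 1) {
  p <- structure(
    list(tc_mean = as.numeric(tc_mean), tc_cv = as.numeric(tc_cv),
         ts = as.numeric(ts), tg2m = as.numeric(tg2m),
         growth_fraction = as.numeric(growth_fraction),
         label_efficiency = as.numeric(label_efficiency)),
    class = "cell_cycle_params")
  validate_cell_cycle_params(p)
  p
}

validate_cell_cycle_params <- function(p) {
  stopifnot(inherits(p, "cell_cycle_params"))
  check <- function(ok, what) {
    if (!isTRUE(ok)) abort_validation(sprintf("invalid cell_cycle_params: %s", what))
  }
  check(is.finite(p$ts) && p$ts > 0, "ts > 0 violated")
  check(is.finite(p$tg2m) && p$tg2m >= 0, "tg2m >= 0 violated")
  check(is.finite(p$tc_mean) && p$ts + p$tg2m < p$tc_mean,
        "ts + tg2m < tc_mean violated")
  check(p$growth_fraction >= 0 && p$growth_fraction <= 1,
        "0 <= growth_fraction <= 1 violated")
  check(is.finite(p$tc_cv) && p$tc_cv >= 0, "tc_cv >= 0 violated")
  check(p$label_efficiency >= 0 && p$label_efficiency <= 1,
        "0 <= label_efficiency <= 1 violated")
  invisible(p)
}

#' Cumulative-labeling sampling protocol
#'
#' Describes how a cumulative-labeling experiment is sampled: exposure times
#' at which cells are fixed and scored, fields of view per sample, biological
#' replicates, and the generative mode.
#'
#' @param sample_times Strictly increasing exposure times, hours (> 0).
#'   Default is the 11-timepoint design 1, 4, 8, 10, 12, 14, 16, 20, 24, 38,
#'   60 h.
#' @param n_fields Fields of view scored per sample (default 5).
#' @param n_replicates Biological replicates (default 3).
#' @param cells_per_field_mean Mean nuclei per field; field sizes are Poisson
#'   around this (default 200).
#' @param mode Generative mode: `"agent"` (per-cell simulation),
#'   `"lagged_rise"` (flat-rise-flat phenomenological curve) or
#'   `"linear_rise"` (classical immediately-rising curve).
#'
#' @return An object of class `labeling_protocol`.
#' @export
labeling_protocol <- function(sample_times = c(1, 4, 8, 10, 12, 14, 16, 20, 24, 38, 60),
                              n_fields = 5, n_replicates = 3,
                              cells_per_field_mean = 200,
                              mode = c("agent", "lagged_rise", "linear_rise")) {
  mode <- match.arg(mode)
  pr <- structure(
    list(sample_times = as.numeric(sample_times),
         n_fields = as.integer(n_fields),
         n_replicates = as.integer(n_replicates),
         cells_per_field_mean = as.numeric(cells_per_field_mean),
         mode = mode),
    class = "labeling_protocol")
  validate_labeling_protocol(pr)
  pr
}

validate_labeling_protocol <- function(pr) {
  if (length(pr$sample_times) == 0)
    abort_validation("invalid labeling_protocol: sample_times is empty")
  if (any(!is.finite(pr$sample_times)) || any(pr$sample_times <= 0))
    abort_validation("invalid labeling_protocol: sample_times must be positive")
  if (is.unsorted(pr$sample_times, strictly = TRUE))
    abort_validation("invalid labeling_protocol: sample_times must be strictly increasing")
  if (pr$n_fields < 1 || pr$n_replicates < 1 || pr$cells_per_field_mean < 1)
    abort_validation("invalid labeling_protocol: counts must be >= 1")
  invisible(pr)
}

#' Lagged-rise curve shape
#'
#' Phenomenological shape of a cumulative-labeling index curve with an
#' initial constant phase: the expected labeling index stays at `level0`
#' until `break1` (the end of the initial plateau), rises linearly to
#' `plateau` at `break2` (saturation onset, when every cycling cell has
#' become label-positive), and stays there. Under the breakpoint reading of
#' such a curve, `break1` estimates the S-phase length Ts and `break2` the
#' saturation time Tc - Ts, so Tc = break1 + break2.
#'
#' @param level0 Initial labeling index (fraction, short-pulse S-phase
#'   occupancy).
#' @param break1 End of the initial constant phase, hours.
#' @param break2 Saturation onset, hours.
#' @param plateau Final labeling index (fraction); equals the growth
#'   fraction.
#'
#' @return An object of class `lagged_rise_shape`.
#' @examples
#' lagged_rise_shape(level0 = 0.436, break1 = 10, break2 = 21, plateau = 0.95)
#' @export
lagged_rise_shape <- function(level0, break1, break2, plateau) {
  s <- structure(
    list(level0 = as.numeric(level0), break1 = as.numeric(break1),
         break2 = as.numeric(break2), plateau = as.numeric(plateau)),
    class = "lagged_rise_shape")
  validate_lagged_rise_shape(s)
  s
}

validate_lagged_rise_shape <- function(s) {
  if (!(s$level0 >= 0 && s$level0 <= s$plateau && s$plateau <= 1))
    abort_validation("invalid lagged_rise_shape: need 0 <= level0 <= plateau <= 1")
  if (!(s$break1 > 0 && s$break2 > s$break1))
    abort_validation("invalid lagged_rise_shape: need 0 < break1 < break2")
  invisible(s)
}

#' Preset condition shapes for the OSCC cumulative-labeling study design
#'
#' Lagged-rise shapes for the three conditions of an SCC25 (oral squamous
#' cell carcinoma) cumulative-EdU experiment: DMSO vehicle control, the
#' Frizzled-4 allosteric inhibitor FzM1, and FzM1 plus a retinoic-acid
#' receptor antagonist (rescue). Conditions are parameter sets only; no
#' pharmacology is modelled. The control and rescue conditions share
#' Ts = 10 h, Tc = 31 h (break1 = 10, break2 = 21); FzM1 has Ts = 16 h,
#' Tc = 42 h (break1 = 16, break2 = 26). Initial levels are the measured
#' short-pulse labeling indices (43.6% control/rescue, 43.4% FzM1); the
#' plateau is set to a growth fraction of 0.95.
#'
#' @return Named list of [lagged_rise_shape()] objects with elements
#'   `DMSO`, `FzM1` and `FzM1_RARi`.
#' @examples
#' condition_presets()$DMSO
#' @export
condition_presets <- function() {
  list(
    DMSO      = lagged_rise_shape(level0 = 0.436, break1 = 10, break2 = 21, plateau = 0.95),
    FzM1      = lagged_rise_shape(level0 = 0.434, break1 = 16, break2 = 26, plateau = 0.95),
    FzM1_RARi = lagged_rise_shape(level0 = 0.436, break1 = 10, break2 = 21, plateau = 0.95)
  )
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat(sprintf(
    "Cell-cycle parameters: Tc = %g h (CV %g), Ts = %g h, G2+M = %g h, GF = %g, label eff. = %g\n",
    x$tc_mean, x$tc_cv, x$ts, x$tg2m, x$growth_fraction, x$label_efficiency))
  invisible(x)
}

#' @export
print.lagged_rise_shape <- function(x, ...) {
  cat(sprintf(
    "Lagged-rise shape: level0 = %g, break1 = %g h, break2 = %g h, plateau = %g\n",
    x$level0, x$break1, x$break2, x$plateau))
  invisible(x)
}

# classed conditions so callers can test errors by class
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("edukinetics_validation_error", "edukinetics_error")))
}

abort_no_saturation <- function(msg) {
  stop(errorCondition(msg, class = c("edukinetics_no_saturation_error", "edukinetics_error")))
}

abort_insufficient_data <- function(msg) {
  stop(errorCondition(msg, class = c("edukinetics_insufficient_data_error", "edukinetics_error")))
}

abort_unstable_fit <- function(msg) {
  stop(errorCondition(msg, class = c("edukinetics_unstable_fit_error", "edukinetics_error")))
}

abort_no_growth <- function(msg) {
  stop(errorCondition(msg, class = c("edukinetics_no_growth_error", "edukinetics_error")))
}
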
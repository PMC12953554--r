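#' Simulate a full synthetic experiment to disk
#'
#' Generates labeling curves for every configured condition (and optionally
#' marker count and qPCR Ct tables), writes them as CSV under `out_dir`, and
#' records a manifest. Per-condition seeds are derived deterministically from
#' the config seed, so a config fully determines its outputs.
#'
#' @param config Named list: `seed`; `protocol` (see [labeling_protocol()]
#'   fields); `conditions`, a named list of either lagged-rise shape fields
#'   (`level0`, `break1`, `break2`, `plateau`) or agent-mode parameter fields
#'   (`tc_mean`, `ts`, `growth_fraction`, ...); optional `markers` (list with
#'   `markers`, `params`, `n_fields`, `n_replicates`) and `qpcr` (list with
#'   `gene_effects`, `noise_sd`, `n_bio`, `n_tech`). Unknown keys are
#'   rejected.
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, the character vector of files written.
#' @examples
#' cfg <- list(seed = 7,
#'             protocol = list(mode = "lagged_rise"),
#'             conditions = list(DMSO = unclass(condition_presets()$DMSO)))
#' out <- cmd_simulate(cfg, out_dir = tempfile("sim"))
#' @export
cmd_simulate <- function(config, out_dir) {
  validate_config(config, "simulate")
  protocol <- config_protocol(config, default_mode = "lagged_rise")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  curves <- lapply(seq_along(config$conditions), function(i) {
    gen <- condition_generator(config$conditions[[i]], protocol)
    gen(seed = config$seed * 100 + i, condition = names(config$conditions)[i])
  })
  labeling_path <- file.path(out_dir, "labeling.csv")
  write_labeling_csv(do.call(rbind, curves), labeling_path)
  files <- c(files, labeling_path)

  if (!is.null(config$markers)) {
    mk <- config$markers
    pspec <- mk$params
    params <- cell_cycle_params(
      tc_mean = pspec$tc_mean, ts = pspec$ts,
      growth_fraction = pspec$growth_fraction,
      tc_cv = pspec$tc_cv %||% 0.15, tg2m = pspec$tg2m %||% 3)
    tabs <- lapply(seq_along(mk$markers), function(i)
      generate_marker_counts(params, mk$markers[[i]],
                             n_fields = mk$n_fields %||% 5,
                             n_replicates = mk$n_replicates %||% 3,
                             seed = config$seed * 100 + 50 + i))
    marker_path <- file.path(out_dir, "markers.csv")
    write_marker_csv(do.call(rbind, tabs), marker_path)
    files <- c(files, marker_path)
  }

  if (!is.null(config$qpcr)) {
    q <- config$qpcr
    ct <- generate_ct_table(unlist(q$gene_effects),
                            base_ct = q$base_ct %||% 25,
                            noise_sd = q$noise_sd %||% 0.2,
                            n_bio = q$n_bio %||% 4,
                            n_tech = q$n_tech %||% 2,
                            seed = config$seed * 100 + 99)
    ct_path <- file.path(out_dir, "ct.csv")
    write_ct_csv(ct, ct_path)
    files <- c(files, ct_path)
  }

  write_manifest(out_dir, "simulate", config, files)
  invisible(files)
}

#' Fit kinetic estimates from a labeling CSV
#'
#' Reads a labeling-curve CSV, fits one kinetic estimate per condition (with
#' bootstrap CIs when `n_boot >= 100`), and writes `estimates.csv`,
#' `estimates.json` and a manifest under `out_dir`.
#'
#' @param curve_csv Path to a labeling CSV (schema of
#'   [write_labeling_csv()]).
#' @param method `"breakpoint"` (default) or `"linear_rise"`.
#' @param n_boot Bootstrap resamples; 0 disables CIs.
#' @param seed Integer seed for the bootstrap.
#' @param grid_step Breakpoint grid spacing, hours.
#' @param out_dir Output directory.
#'
#' @return Invisibly, the estimates data.frame.
#' @export
cmd_fit <- function(curve_csv, out_dir, method = c("breakpoint", "linear_rise"),
                    n_boot = 0, seed = 1, grid_step = 0.1) {
  method <- match.arg(method)
  curve <- read_labeling_csv(curve_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- unique(curve$condition)
  estimates <- lapply(seq_along(conds), function(i) {
    sub <- curve[curve$condition == conds[i], , drop = FALSE]
    if (n_boot >= 100) {
      bootstrap_estimate(sub, method = method, n_boot = n_boot,
                         seed = seed * 100 + i, grid_step = grid_step)
    } else {
      fit_curve_by_method(aggregate_curve(sub), method, grid_step, 0.03)
    }
  })
  names(estimates) <- conds
  tab <- estimates_table(estimates)
  csv_path <- file.path(out_dir, "estimates.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  json_path <- file.path(out_dir, "estimates.json")
  jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_manifest(out_dir, "fit",
                 list(curve_csv = basename(curve_csv), method = method,
                      n_boot = n_boot, seed = seed, grid_step = grid_step),
                 c(csv_path, json_path))
  invisible(tab)
}

#' Parameter-recovery experiment
#'
#' For each configured condition and each of `n_seeds` seeds: simulate a
#' labeling curve from the condition's true parameters, fit it, and compare
#' estimate to truth. Writes a per-seed table (`recovery.csv`), a summary
#' (`recovery_summary.csv`: median estimates, median errors and - when
#' bootstrapping - CI coverage rates) and a manifest.
#'
#' For lagged-rise conditions the generative truth is `ts = break1`,
#' `tc = break1 + break2`, `gf = plateau`; for agent-mode conditions it is
#' `ts`, `tc_mean`, `growth_fraction`.
#'
#' @param config Named list: `seed`, `conditions`, `protocol`, `n_seeds`
#'   (default 20), `method` (default `"breakpoint"`), `grid_step`
#'   (default 0.1), `n_boot` (default 0 = no coverage columns).
#' @param out_dir Output directory.
#'
#' @return Invisibly, a list with elements `per_seed` and `summary`.
#' @export
cmd_recover <- function(config, out_dir) {
  validate_config(config, "recover")
  protocol <- config_protocol(config, default_mode = "lagged_rise")
  n_seeds <- config$n_seeds %||% 20
  method <- config$method %||% "breakpoint"
  grid_step <- config$grid_step %||% 0.1
  n_boot <- config$n_boot %||% 0
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  for (i in seq_along(config$conditions)) {
    spec <- config$conditions[[i]]
    cond <- names(config$conditions)[i]
    if (protocol$mode == "lagged_rise") {
      true_ts <- spec$break1; true_tc <- spec$break1 + spec$break2
    } else {
      true_ts <- spec$ts; true_tc <- spec$tc_mean
    }
    gen <- condition_generator(spec, protocol)
    for (s in seq_len(n_seeds)) {
      seed_s <- config$seed * 1000 + i * 100 + s
      curve <- gen(seed = seed_s, condition = cond)
      est <- tryCatch({
        if (n_boot >= 100)
          bootstrap_estimate(curve, method = method, n_boot = n_boot,
                             seed = seed_s + 1, grid_step = grid_step)
        else
          fit_curve_by_method(aggregate_curve(curve), method, grid_step, 0.03)
      }, edukinetics_error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, seed = seed_s,
        true_ts = true_ts, true_tc = true_tc,
        ts_hat = if (is.null(est)) NA_real_ else est$ts_hat,
        tc_hat = if (is.null(est)) NA_real_ else est$tc_hat,
        gf_hat = if (is.null(est)) NA_real_ else est$gf_hat,
        ts_covered = if (is.null(est) || is.null(est$ci_ts)) NA else
          est$ci_ts[1] <= true_ts && true_ts <= est$ci_ts[2],
        tc_covered = if (is.null(est) || is.null(est$ci_tc)) NA else
          est$ci_tc[1] <= true_tc && true_tc <= est$ci_tc[2])
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_seed, per_seed$condition), function(d) {
    data.frame(condition = d$condition[1],
               true_ts = d$true_ts[1], true_tc = d$true_tc[1],
               median_ts = stats::median(d$ts_hat, na.rm = TRUE),
               median_tc = stats::median(d$tc_hat, na.rm = TRUE),
               median_abs_err_ts = stats::median(abs(d$ts_hat - d$true_ts), na.rm = TRUE),
               median_abs_err_tc = stats::median(abs(d$tc_hat - d$true_tc), na.rm = TRUE),
               ts_coverage = mean(d$ts_covered, na.rm = TRUE),
               tc_coverage = mean(d$tc_covered, na.rm = TRUE),
               n_seeds = nrow(d), n_failed = sum(is.na(d$ts_hat)))
  }))
  rownames(summary) <- NULL
  per_seed_path <- file.path(out_dir, "recovery.csv")
  summary_path <- file.path(out_dir, "recovery_summary.csv")
  utils::write.csv(per_seed, per_seed_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(summary, summary_path, row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "recover", config, c(per_seed_path, summary_path))
  invisible(list(per_seed = per_seed, summary = summary))
}
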
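#' Read / write labeling-curve CSV files
#'
#' Labeling curves are stored as one row per
#' (`condition`, `replicate`, `field`, `time_h`, `n_pos`, `n_total`), with a
#' header, UTF-8, '.' decimal separator. Counts are raw integers; indices are
#' never stored.
#'
#' @param path File path.
#' @return `read_labeling_csv` returns the curve data.frame; the writers
#'   return the path invisibly.
#' @export
read_labeling_csv <- function(path) {
  curve <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_labeling_curve(curve)
  curve
}

#' @rdname read_labeling_csv
#' @param curve Labeling-curve data.frame.
#' @export
write_labeling_csv <- function(curve, path) {
  validate_labeling_curve(curve)
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write marker field-count CSV files
#'
#' Marker tables match the labeling schema without `time_h`:
#' (`condition`, `marker`, `replicate`, `field`, `n_pos`, `n_total`).
#'
#' @param path File path.
#' @return `read_marker_csv` returns the data.frame; the writer returns the
#'   path invisibly.
#' @export
read_marker_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_marker_csv
#' @param counts Marker count data.frame.
#' @export
write_marker_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write qPCR Ct CSV files
#'
#' Columns: `sample`, `condition`, `bio_rep`, `tech_rep`, `gene`, `ct`.
#'
#' @param path File path.
#' @return `read_ct_csv` returns the data.frame; the writer returns the path
#'   invisibly.
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "bio_rep", "tech_rep", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    abort_validation(paste("Ct CSV missing columns:", paste(miss, collapse = ", ")))
  ct
}

#' @rdname read_ct_csv
#' @param ct Ct-table data.frame.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise kinetic estimates
#'
#' One row / JSON record per condition: method, point estimates, CI bounds
#' and bootstrap size.
#'
#' @param estimates Named list of `kinetic_estimate` objects (names =
#'   condition labels).
#' @return A data.frame.
#' @export
estimates_table <- function(estimates) {
  do.call(rbind, lapply(names(estimates), function(cond) {
    e <- estimates[[cond]]
    data.frame(condition = cond, method = e$method,
               gf_hat = e$gf_hat, ts_hat = e$ts_hat, tc_hat = e$tc_hat,
               tsat_hat = e$tsat_hat,
               ci_ts_lo = if (is.null(e$ci_ts)) NA_real_ else e$ci_ts[1],
               ci_ts_hi = if (is.null(e$ci_ts)) NA_real_ else e$ci_ts[2],
               ci_tc_lo = if (is.null(e$ci_tc)) NA_real_ else e$ci_tc[1],
               ci_tc_hi = if (is.null(e$ci_tc)) NA_real_ else e$ci_tc[2],
               ci_gf_lo = if (is.null(e$ci_gf)) NA_real_ else e$ci_gf[1],
               ci_gf_hi = if (is.null(e$ci_gf)) NA_real_ else e$ci_gf[2],
               n_boot = e$n_boot)
  }))
}

# ---- run configuration ----------------------------------------------------

known_config_keys <- list(
  simulate = c("schema_version", "seed", "protocol", "conditions", "markers", "qpcr"),
  recover  = c("schema_version", "seed", "protocol", "conditions", "n_seeds",
               "method", "grid_step", "n_boot")
)

#' Validate a run configuration
#'
#' Configurations are flat JSON-compatible lists; unknown keys are rejected
#' so that typos cannot silently change a run. Every stochastic run must
#' carry a seed.
#'
#' @param config Named list.
#' @param command `"simulate"` or `"recover"`.
#' @return The config, invisibly, or a validation error.
#' @export
validate_config <- function(config, command = c("simulate", "recover")) {
  command <- match.arg(command)
  known <- known_config_keys[[command]]
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    abort_validation(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (is.null(config$seed))
    abort_validation("config must record a seed")
  if (is.null(config$conditions) || is.null(names(config$conditions)))
    abort_validation("config must name its conditions")
  invisible(config)
}

config_protocol <- function(config, default_mode) {
  pp <- config$protocol
  if (is.null(pp)) pp <- list()
  labeling_protocol(
    sample_times = pp$sample_times %||% c(1, 4, 8, 10, 12, 14, 16, 20, 24, 38, 60),
    n_fields = pp$n_fields %||% 5,
    n_replicates = pp$n_replicates %||% 3,
    cells_per_field_mean = pp$cells_per_field_mean %||% 200,
    mode = pp$mode %||% default_mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shape or cell-cycle parameter list -> generator closure(seed, condition)
condition_generator <- function(spec, protocol) {
  if (protocol$mode == "lagged_rise") {
    shape <- lagged_rise_shape(spec$level0, spec$break1, spec$break2, spec$plateau)
    function(seed, condition)
      generate_lagged_rise_curve(shape, protocol, seed, condition = condition)
  } else {
    params <- cell_cycle_params(
      tc_mean = spec$tc_mean, ts = spec$ts,
      growth_fraction = spec$growth_fraction,
      tc_cv = spec$tc_cv %||% 0.15, tg2m = spec$tg2m %||% 3,
      label_efficiency = spec$label_efficiency %||% 1)
    function(seed, condition)
      simulate_cumulative_labeling(params, protocol, seed, condition = condition)
  }
}

#' Write a run manifest
#'
#' Records the exact configuration, package version, timestamp and MD5
#' digests of the files a command produced, so any run can be replayed:
#' re-running with the manifest's config and seed reproduces the data files
#' byte-identically (the manifest's own timestamp differs).
#'
#' @param out_dir Output directory.
#' @param command Command name.
#' @param config Configuration list (echoed verbatim).
#' @param files Character vector of produced file paths.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, config, files) {
  manifest <- list(
    command = command,
    package = "edukinetics",
    version = as.character(utils::packageVersion("edukinetics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
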
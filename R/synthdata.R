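#' Simulate an asynchronous cell population
#'
#' Draws a snapshot of a (possibly partially quiescent) population. Each cell
#' is cycling with probability `growth_fraction`; cycling cells get a cycle
#' length from a lognormal with mean `tc_mean` and coefficient of variation
#' `tc_cv` (degenerate at `tc_mean` when `tc_cv = 0`) and an age (position in
#' their own cycle, hours since division) from the chosen steady-state age
#' distribution.
#'
#' @param params A [cell_cycle_params()] object.
#' @param n_cells Number of cells to draw (>= 1).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param age_dist Age distribution of cycling cells: `"uniform"` over the
#'   cycle (default) or `"exponential"`, the exponentially-growing-population
#'   age density `f(a) = (2 log 2 / tc) 2^(-a/tc)`.
#'
#' @return A data.frame with one row per cell: `cell` (id), `cycling`
#'   (logical), `tc` (cycle length, hours; `NA` for non-cycling cells) and
#'   `age` (hours since division; `NA` for non-cycling cells).
#' @examples
#' cells <- simulate_population(
#'   cell_cycle_params(tc_mean = 31, ts = 10, growth_fraction = 0.9),
#'   n_cells = 100, seed = 1)
#' mean(cells$cycling)
#' @export
simulate_population <- function(params, n_cells, seed,
                                age_dist = c("uniform", "exponential")) {
  validate_cell_cycle_params(params)
  age_dist <- match.arg(age_dist)
  if (n_cells < 1) abort_validation("n_cells must be >= 1")
  set.seed(seed)
  n_cells <- as.integer(n_cells)
  cycling <- stats::runif(n_cells) < params$growth_fraction
  tc <- rep(NA_real_, n_cells)
  age <- rep(NA_real_, n_cells)
  nc <- sum(cycling)
  if (nc > 0) {
    tc[cycling] <- draw_cycle_lengths(nc, params$tc_mean, params$tc_cv)
    age[cycling] <- draw_ages(tc[cycling], age_dist)
  }
  data.frame(cell = seq_len(n_cells), cycling = cycling, tc = tc, age = age)
}

# lognormal with arithmetic mean m and CV cv (point mass when cv = 0)
draw_cycle_lengths <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

draw_ages <- function(tc, age_dist) {
  u <- stats::runif(length(tc))
  if (age_dist == "uniform") return(u * tc)
  # inverse-CDF of f(a) = (2 log 2 / tc) 2^(-a/tc) on [0, tc]
  -tc * log2(1 - u / 2)
}

# Probability-1 labeling indicator: has this cell spent any time in its
# S window during continuous exposure [0, t]? S occupies the scaled window
# [tc - ts - tg2m, tc - tg2m) of each cell's own cycle.
labeled_by <- function(tc, age, t, params) {
  frac_s0 <- (params$tc_mean - params$ts - params$tg2m) / params$tc_mean
  frac_s1 <- (params$tc_mean - params$tg2m) / params$tc_mean
  s0 <- frac_s0 * tc
  s1 <- frac_s1 * tc
  in_s <- age >= s0 & age < s1
  wait <- (s0 - age) %% tc
  in_s | wait < t
}

#' Simulate a cumulative-labeling time course (agent mode)
#'
#' Per-cell simulation of continuous label exposure. At each sample time `t`
#' an independent sample of fields is drawn (cells are fixed for scoring, so
#' timepoints are separate samples); a cycling cell is scored positive iff it
#' spends any time in its S window during `[0, t]`, detected with probability
#' `label_efficiency`. Under zero cycle-length variability, uniform age and
#' perfect detection the expected labeling index is
#' `GF * min(1, (Ts + t) / Tc)`.
#'
#' @param params A [cell_cycle_params()] object.
#' @param protocol A [labeling_protocol()] with `mode = "agent"`.
#' @param seed Integer seed.
#' @param condition Condition label stored in the output (default `"sim"`).
#' @param age_dist Passed to the age draw; see [simulate_population()].
#'
#' @return A labeling-curve data.frame with columns `condition`, `replicate`,
#'   `field`, `time_h`, `n_pos`, `n_total`.
#' @export
simulate_cumulative_labeling <- function(params, protocol, seed,
                                         condition = "sim",
                                         age_dist = c("uniform", "exponential")) {
  validate_cell_cycle_params(params)
  validate_labeling_protocol(protocol)
  age_dist <- match.arg(age_dist)
  if (protocol$mode != "agent")
    abort_validation("simulate_cumulative_labeling requires protocol mode 'agent'")
  set.seed(seed)
  grid <- expand.grid(field = seq_len(protocol$n_fields),
                      replicate = seq_len(protocol$n_replicates),
                      time_h = protocol$sample_times)
  n_total <- pmax(1L, stats::rpois(nrow(grid), protocol$cells_per_field_mean))
  n_pos <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n <- n_total[i]
    cycling <- stats::runif(n) < params$growth_fraction
    nc <- sum(cycling)
    if (nc == 0L) next
    tc <- draw_cycle_lengths(nc, params$tc_mean, params$tc_cv)
    age <- draw_ages(tc, age_dist)
    lab <- labeled_by(tc, age, grid$time_h[i], params)
    if (params$label_efficiency < 1)
      lab <- lab & stats::runif(nc) < params$label_efficiency
    n_pos[i] <- sum(lab)
  }
  out <- data.frame(condition = condition, replicate = grid$replicate,
                    field = grid$field, time_h = grid$time_h,
                    n_pos = n_pos, n_total = n_total)
  out[order(out$replicate, out$field, out$time_h), , drop = FALSE]
}

# expected lagged-rise index at time t
lagged_rise_index <- function(shape, t) {
  ifelse(t <= shape$break1, shape$level0,
         ifelse(t >= shape$break2, shape$plateau,
                shape$level0 + (shape$plateau - shape$level0) *
                  (t - shape$break1) / (shape$break2 - shape$break1)))
}

#' Generate a lagged-rise cumulative-labeling curve
#'
#' Phenomenological generator for cumulative-labeling curves whose index
#' stays constant at `level0` up to `break1`, rises linearly to `plateau` at
#' `break2` and plateaus. Per-field positives are binomial draws around the
#' expected index, with Poisson field sizes.
#'
#' @param shape A [lagged_rise_shape()] object.
#' @param protocol A [labeling_protocol()] with `mode = "lagged_rise"`.
#' @param seed Integer seed.
#' @param condition Condition label stored in the output.
#'
#' @return A labeling-curve data.frame (`condition`, `replicate`, `field`,
#'   `time_h`, `n_pos`, `n_total`).
#' @examples
#' pr <- labeling_protocol(mode = "lagged_rise")
#' curve <- generate_lagged_rise_curve(condition_presets()$DMSO, pr, seed = 1)
#' head(curve)
#' @export
generate_lagged_rise_curve <- function(shape, protocol, seed, condition = "sim") {
  validate_lagged_rise_shape(shape)
  validate_labeling_protocol(protocol)
  if (protocol$mode != "lagged_rise")
    abort_validation("generate_lagged_rise_curve requires protocol mode 'lagged_rise'")
  set.seed(seed)
  grid <- expand.grid(field = seq_len(protocol$n_fields),
                      replicate = seq_len(protocol$n_replicates),
                      time_h = protocol$sample_times)
  p <- lagged_rise_index(shape, grid$time_h)
  n_total <- pmax(1L, stats::rpois(nrow(grid), protocol$cells_per_field_mean))
  n_pos <- stats::rbinom(nrow(grid), n_total, p)
  out <- data.frame(condition = condition, replicate = grid$replicate,
                    field = grid$field, time_h = grid$time_h,
                    n_pos = n_pos, n_total = n_total)
  out[order(out$replicate, out$field, out$time_h), , drop = FALSE]
}

#' Generate marker-positive field counts
#'
#' Binomial per-field counts for a phase marker under a simple occupancy
#' model: Ki67 marks all cycling cells (`P = GF`); phospho-histone H3 marks
#' late G2 and mitosis (`P = GF * ph3_window / tc`); mitotic figures mark M
#' only (`P = GF * m_window / tc`).
#'
#' @param params A [cell_cycle_params()] object.
#' @param marker One of `"ki67"`, `"ph3"`, `"mitotic"`.
#' @param n_fields,n_replicates Sampling design.
#' @param seed Integer seed.
#' @param cells_per_field_mean Mean nuclei per field (Poisson sizes).
#' @param m_window Mitosis duration, hours (default 1).
#' @param ph3_window pH3-positive window, hours; defaults to `params$tg2m`.
#' @param condition Condition label stored in the output.
#'
#' @return A field-count data.frame (`condition`, `marker`, `replicate`,
#'   `field`, `n_pos`, `n_total`).
#' @export
generate_marker_counts <- function(params, marker, n_fields, n_replicates, seed,
                                   cells_per_field_mean = 200,
                                   m_window = 1, ph3_window = NULL,
                                   condition = "sim") {
  validate_cell_cycle_params(params)
  if (!marker %in% c("ki67", "ph3", "mitotic"))
    abort_validation(sprintf("unknown marker '%s'", marker))
  if (is.null(ph3_window)) ph3_window <- params$tg2m
  p <- switch(marker,
    ki67    = params$growth_fraction,
    ph3     = params$growth_fraction * ph3_window / params$tc_mean,
    mitotic = params$growth_fraction * m_window / params$tc_mean)
  if (p < 0 || p > 1)
    abort_validation("marker occupancy probability outside [0, 1]; check windows")
  set.seed(seed)
  grid <- expand.grid(field = seq_len(n_fields), replicate = seq_len(n_replicates))
  n_total <- pmax(1L, stats::rpois(nrow(grid), cells_per_field_mean))
  n_pos <- stats::rbinom(nrow(grid), n_total, p)
  data.frame(condition = condition, marker = marker,
             replicate = grid$replicate, field = grid$field,
             n_pos = n_pos, n_total = n_total)
}

#' Generate a qPCR Ct table
#'
#' Simulates raw Ct values for target genes with known true fold changes
#' between a control and a treated condition, a housekeeping gene (fold
#' change 1), technical replicates and Gaussian well noise. The treated
#' target Ct is `control Ct - log2(fold change)`, so downregulation raises
#' the Ct.
#'
#' @param gene_effects Named numeric vector of true fold changes (> 0),
#'   treated vs control, one per target gene.
#' @param base_ct Baseline target Ct in the control condition (default 25).
#' @param noise_sd Gaussian noise SD per well, Ct cycles (default 0.2).
#' @param n_bio Biological replicates per condition (default 4).
#' @param n_tech Technical replicates per well (default 2).
#' @param seed Integer seed.
#' @param housekeeping Housekeeping gene name (default `"GAPDH"`).
#' @param hk_ct Housekeeping baseline Ct (default 18).
#' @param conditions Length-2 character vector: control then treated
#'   condition labels.
#'
#' @return A Ct-table data.frame (`sample`, `condition`, `bio_rep`,
#'   `tech_rep`, `gene`, `ct`).
#' @examples
#' ct <- generate_ct_table(c(CDK1 = 0.47), noise_sd = 0, seed = 1)
#' head(ct)
#' @export
generate_ct_table <- function(gene_effects, base_ct = 25, noise_sd = 0.2,
                              n_bio = 4, n_tech = 2, seed,
                              housekeeping = "GAPDH", hk_ct = 18,
                              conditions = c("control", "treated")) {
  if (is.null(names(gene_effects)) || any(!nzchar(names(gene_effects))))
    abort_validation("gene_effects must be a named vector")
  if (any(gene_effects <= 0))
    abort_validation("true fold changes must be > 0")
  if (n_bio < 1 || n_tech < 1)
    abort_validation("n_bio and n_tech must be >= 1")
  if (housekeeping %in% names(gene_effects))
    abort_validation("housekeeping gene must not appear in gene_effects")
  set.seed(seed)
  genes <- c(names(gene_effects), housekeeping)
  base <- c(rep(base_ct, length(gene_effects)), hk_ct)
  shift <- c(-log2(gene_effects), 0)  # applied in the treated condition
  grid <- expand.grid(tech_rep = seq_len(n_tech), gene = genes,
                      bio_rep = seq_len(n_bio), condition = conditions,
                      stringsAsFactors = FALSE)
  gi <- match(grid$gene, genes)
  mu <- base[gi] + ifelse(grid$condition == conditions[2], shift[gi], 0)
  ct <- mu + stats::rnorm(nrow(grid), sd = noise_sd)
  data.frame(sample = paste(grid$condition, grid$bio_rep, sep = "_"),
             condition = grid$condition, bio_rep = grid$bio_rep,
             tech_rep = grid$tech_rep, gene = grid$gene, ct = ct)
}
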
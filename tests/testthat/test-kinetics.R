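test_that("aggregate_curve computes mean-of-field indices and SEM", {
  two <- data.frame(condition = "a", replicate = 1, field = 1:2, time_h = 4,
                    n_pos = c(40, 50), n_total = c(100, 100))
  agg <- aggregate_curve(two)
  expect_equal(agg$mean_index, 0.45)
  expect_equal(agg$sem_index, 0.05)
  expect_equal(agg$n_fields, 2)

  one <- data.frame(condition = "a", replicate = 1, field = 1, time_h = 4,
                    n_pos = 0, n_total = 100)
  agg1 <- aggregate_curve(one)
  expect_equal(agg1$mean_index, 0)
  expect_equal(agg1$sem_index, 0)

  bad <- data.frame(condition = "a", replicate = 2, field = 3, time_h = 8,
                    n_pos = 0, n_total = 0)
  expect_error(aggregate_curve(bad), "replicate=2 field=3",
               class = "edukinetics_validation_error")

  # binomial oracle: 15 fields at true index 0.436
  shape <- lagged_rise_shape(0.436, 10, 21, 0.95)
  pr <- labeling_protocol(sample_times = 5, n_fields = 5, n_replicates = 3,
                          mode = "lagged_rise")
  agg15 <- aggregate_curve(generate_lagged_rise_curve(shape, pr, seed = 4))
  expect_lt(abs(agg15$mean_index - 0.436), 3 * max(agg15$sem_index, 1e-3))
})

test_that("fit_segmented recovers noiseless breakpoints and flags degenerate curves", {
  agg <- exact_lagged_agg(0.436, 10, 21, 0.95)
  fit <- fit_segmented(agg, grid_step = 0.1)
  expect_equal(fit$break1, 10, tolerance = 1e-9)
  expect_equal(fit$break2, 21, tolerance = 1e-9)
  expect_equal(fit$level0, 0.436)
  expect_equal(fit$plateau, 0.95)
  expect_lt(fit$rss, 1e-20)

  flat <- data.frame(condition = "f", time_h = study_times,
                     mean_index = 0.5, sem_index = 0, n_fields = 15)
  expect_error(fit_segmented(flat), class = "edukinetics_no_saturation_error")

  rising <- data.frame(condition = "r", time_h = study_times,
                       mean_index = study_times / 60, sem_index = 0, n_fields = 15)
  expect_error(fit_segmented(rising), class = "edukinetics_no_saturation_error")

  expect_error(fit_segmented(exact_lagged_agg(0.4, 5, 10, 0.9, t = c(1, 4, 8, 12))),
               class = "edukinetics_insufficient_data_error")
})

test_that("fit_segmented equals the exhaustive brute-force oracle", {
  set.seed(105)
  pr <- study_protocol()
  for (i in 1:8) {
    level0 <- runif(1, 0.2, 0.5)
    shape <- lagged_rise_shape(level0, runif(1, 5, 15),
                               runif(1, 5, 15) + runif(1, 8, 25),
                               level0 + runif(1, 0.25, 0.45))
    curve <- generate_lagged_rise_curve(shape, pr, seed = 500 + i)
    agg <- aggregate_curve(curve)
    fit <- fit_segmented(agg, grid_step = 1, refine = FALSE)
    oracle <- brute_force_segfit(agg$time_h, agg$mean_index, agg$n_fields,
                                 grid_step = 1)
    expect_equal(fit$break1, oracle$break1)
    expect_equal(fit$break2, oracle$break2)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  }
})

test_that("breakpoint estimates map fit parameters to Ts, Tsat, Tc and GF", {
  mkfit <- function(b1, b2, l0 = 0.44, pl = 0.95)
    structure(list(break1 = b1, break2 = b2, level0 = l0, plateau = pl,
                   rss = 0, n_points = 11, grid_step = 0.1, refined = FALSE),
              class = "segmented_fit")
  e1 <- estimate_breakpoint(mkfit(10, 21))
  expect_equal(e1$ts_hat, 10)
  expect_equal(e1$tc_hat, 31)
  expect_equal(e1$gf_hat, 0.95)
  e2 <- estimate_breakpoint(mkfit(16, 26))
  expect_equal(e2$ts_hat, 16)
  expect_equal(e2$tc_hat, 42)
  # boundary arithmetic keeps tc > ts
  e3 <- estimate_breakpoint(mkfit(5, 5.0001))
  expect_equal(e3$tc_hat, 10.0001)
  expect_gt(e3$tc_hat, e3$ts_hat)
  # identity Tc = Ts + Tsat holds exactly
  for (e in list(e1, e2, e3))
    expect_identical(e$tsat_hat, e$tc_hat - e$ts_hat)
})

test_that("estimate_linear_rise inverts its closed form on noiseless curves", {
  t <- study_times
  mkagg <- function(y) data.frame(condition = "x", time_h = t, mean_index = y,
                                  sem_index = 0, n_fields = 15)
  e1 <- estimate_linear_rise(mkagg(pmin((t + 6) / 24, 1)), plateau_tolerance = 1e-9)
  expect_equal(e1$ts_hat, 6, tolerance = 1e-10)
  expect_equal(e1$tc_hat, 24, tolerance = 1e-10)
  expect_equal(e1$gf_hat, 1)

  e2 <- estimate_linear_rise(mkagg(pmin(0.8 * (t + 10) / 31, 0.8)),
                             plateau_tolerance = 1e-9)
  expect_equal(e2$ts_hat, 10, tolerance = 1e-9)
  expect_equal(e2$tc_hat, 31, tolerance = 1e-9)
  expect_equal(e2$gf_hat, 0.8)
  expect_equal(e2$tsat_hat, e2$tc_hat - e2$ts_hat)

  # shrinking index in the growing phase is not a cumulative-labeling curve
  dec <- mkagg(c(0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.5, 0.4, 0.4, 0.4))
  expect_error(estimate_linear_rise(dec, plateau_tolerance = 0.01),
               class = "edukinetics_no_growth_error")
})

test_that("agent-mode curves are recovered by the linear-rise estimator", {
  pr <- study_protocol("agent")
  for (p in list(c(31, 10), c(42, 16))) {
    params <- cell_cycle_params(tc_mean = p[1], ts = p[2], growth_fraction = 0.9)
    ts <- tc <- numeric(20)
    for (s in 1:20) {
      est <- estimate_linear_rise(aggregate_curve(
        simulate_cumulative_labeling(params, pr, seed = 2000 + s)))
      ts[s] <- est$ts_hat
      tc[s] <- est$tc_hat
    }
    expect_lt(abs(median(ts) - p[2]), 2)
    expect_lt(abs(median(tc) - p[1]), 2)
  }
})

test_that("lagged-rise round trip recovers shape parameters within tolerance", {
  pr <- study_protocol()
  presets <- condition_presets()
  for (cond in names(presets)) {
    shape <- presets[[cond]]
    for (s in 1:5) {
      est <- estimate_breakpoint(fit_segmented(aggregate_curve(
        generate_lagged_rise_curve(shape, pr, seed = 300 + s)), grid_step = 0.1))
      tol <- max(0.1, 1.5)
      expect_lt(abs(est$ts_hat - shape$break1), tol)
      expect_lt(abs(est$tsat_hat - shape$break2), tol)
      expect_lt(abs(est$gf_hat - shape$plateau), 0.05)
    }
  }
})

test_that("bootstrap CIs bracket the point estimate and respect the seed contract", {
  expect_error(bootstrap_estimate(
    generate_lagged_rise_curve(condition_presets()$DMSO, study_protocol(), 1),
    n_boot = 50), class = "edukinetics_validation_error")

  curve <- generate_lagged_rise_curve(condition_presets()$DMSO, study_protocol(),
                                      seed = 17)
  b1 <- bootstrap_estimate(curve, n_boot = 100, seed = 5, grid_step = 0.5)
  b2 <- bootstrap_estimate(curve, n_boot = 100, seed = 6, grid_step = 0.5)
  # point estimate comes from the full data, independent of the bootstrap seed
  expect_identical(b1$ts_hat, b2$ts_hat)
  expect_identical(b1$tc_hat, b2$tc_hat)
  expect_true(b1$ci_ts[1] <= b1$ts_hat && b1$ts_hat <= b1$ci_ts[2])
  expect_true(b1$ci_tc[1] <= b1$tc_hat && b1$tc_hat <= b1$ci_tc[2])
  expect_identical(b1$tsat_hat, b1$tc_hat - b1$ts_hat)
  # same seed reproduces the CIs exactly
  expect_identical(b1$ci_ts,
                   bootstrap_estimate(curve, n_boot = 100, seed = 5,
                                      grid_step = 0.5)$ci_ts)

  # an exact curve replicated over fields has no resampling variance
  exact <- expand.grid(replicate = 1:3, field = 1:5, time_h = study_times)
  p <- ifelse(exact$time_h <= 10, 0.436,
              ifelse(exact$time_h >= 21, 0.95,
                     0.436 + (0.95 - 0.436) * (exact$time_h - 10) / 11))
  exact <- data.frame(condition = "e", exact, n_pos = round(1e6 * p), n_total = 1e6)
  be <- bootstrap_estimate(exact, n_boot = 100, seed = 1, grid_step = 0.5)
  expect_lte(diff(be$ci_ts), 0.5)
  expect_lte(diff(be$ci_tc), 1)
})

test_that("condition comparison reports kinetic differences", {
  mkest <- function(ts, tc, gf = 0.95)
    structure(list(method = "breakpoint", gf_hat = gf, ts_hat = ts, tc_hat = tc,
                   tsat_hat = tc - ts, n_boot = 0, boot_draws = NULL),
              class = "kinetic_estimate")
  dmso <- mkest(10, 31)
  fzm1 <- mkest(16, 42)
  cmp <- compare_conditions(dmso, fzm1)
  expect_equal(cmp$delta_ts, 6)
  expect_equal(cmp$delta_tc, 11)
  # rescue brings the kinetics back: FzM1 vs rescue-like
  expect_equal(compare_conditions(fzm1, mkest(10, 31))$delta_tc, -11)
  expect_equal(compare_conditions(dmso, dmso)$delta_ts, 0)
  lin <- structure(c(unclass(mkest(10, 31))[-1], list(method = "linear_rise")),
                   class = "kinetic_estimate")
  expect_error(compare_conditions(dmso, lin),
               class = "edukinetics_validation_error")

  # with bootstrap draws: clearly separated conditions give ~0 exceedance
  pr <- study_protocol()
  ba <- bootstrap_estimate(
    generate_lagged_rise_curve(condition_presets()$DMSO, pr, seed = 31),
    n_boot = 100, seed = 1, grid_step = 0.5)
  bb <- bootstrap_estimate(
    generate_lagged_rise_curve(condition_presets()$FzM1, pr, seed = 32),
    n_boot = 100, seed = 2, grid_step = 0.5)
  cmp2 <- compare_conditions(ba, bb)
  expect_gt(cmp2$delta_tc, 5)
  expect_lt(cmp2$p_delta_tc, 0.05)
})
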
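# Shared fixtures and independent oracles for the test suite.

# standard 11-timepoint cumulative-exposure design
study_times <- c(1, 4, 8, 10, 12, 14, 16, 20, 24, 38, 60)

study_protocol <- function(mode = "lagged_rise", ...) {
  labeling_protocol(sample_times = study_times, n_fields = 5, n_replicates = 3,
                    cells_per_field_mean = 200, mode = mode, ...)
}

# exact aggregated curve lying on a given lagged-rise expectation (no noise)
exact_lagged_agg <- function(level0, break1, break2, plateau, t = study_times,
                             n_fields = 15) {
  y <- ifelse(t <= break1, level0,
              ifelse(t >= break2, plateau,
                     level0 + (plateau - level0) * (t - break1) / (break2 - break1)))
  data.frame(condition = "exact", time_h = t, mean_index = y,
             sem_index = 0, n_fields = n_fields)
}

# Independent brute-force oracle for the three-segment least-squares fit:
# naive loops, model evaluated from its definition at every grid pair,
# lexicographic tie-break (smallest break1 then break2) within 1e-10.
brute_force_segfit <- function(t, y, w, grid_step) {
  m <- length(t)
  cand <- round(seq(t[1], t[m], by = grid_step), 9)
  cand <- cand[cand < t[m]]
  recs <- matrix(NA_real_, nrow = 0, ncol = 3)
  for (b1 in cand) {
    for (b2 in cand[cand > b1]) {
      left <- t <= b1
      right <- t >= b2
      if (!any(left) || !any(right)) next
      l0 <- sum(w[left] * y[left]) / sum(w[left])
      pl <- sum(w[right] * y[right]) / sum(w[right])
      if (pl < l0) next
      pred <- numeric(m)
      for (k in seq_len(m)) {
        pred[k] <- if (t[k] <= b1) l0
        else if (t[k] >= b2) pl
        else l0 + (pl - l0) * (t[k] - b1) / (b2 - b1)
      }
      recs <- rbind(recs, c(b1, b2, sum(w * (y - pred)^2)))
    }
  }
  minr <- min(recs[, 3])
  el <- recs[recs[, 3] <= minr + 1e-10 * (1 + minr), , drop = FALSE]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  list(break1 = el[1, 1], break2 = el[1, 2], rss = el[1, 3])
}

# textbook pooled-variance two-sample t-test, written from the formula
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}
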
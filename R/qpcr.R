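#' Collapse technical qPCR replicates
#'
#' Arithmetic mean Ct per (condition, bio_rep, gene), flagging groups whose
#' technical-replicate spread (max - min) exceeds `spread_threshold`.
#'
#' @param records Ct-table data.frame (`sample`, `condition`, `bio_rep`,
#'   `tech_rep`, `gene`, `ct`).
#' @param spread_threshold Maximum acceptable within-group spread, Ct cycles
#'   (default 0.5).
#' @param housekeeping Optional housekeeping gene name; if given, every
#'   (condition, bio_rep) must contain it.
#'
#' @return A data.frame (`condition`, `bio_rep`, `gene`, `ct`, `n_tech`,
#'   `spread`, `spread_flag`).
#' @examples
#' ct <- generate_ct_table(c(CDK1 = 0.47), seed = 1)
#' head(collapse_technical(ct))
#' @export
collapse_technical <- function(records, spread_threshold = 0.5,
                               housekeeping = NULL) {
  need <- c("condition", "bio_rep", "gene", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_validation(paste("Ct table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(records) == 0) abort_validation("Ct table is empty")
  if (any(records$ct <= 0)) abort_validation("Ct values must be positive")
  key <- interaction(records$condition, records$bio_rep, records$gene, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    x <- records$ct[i]
    data.frame(condition = records$condition[i[1]],
               bio_rep = records$bio_rep[i[1]],
               gene = records$gene[i[1]],
               ct = mean(x), n_tech = length(x),
               spread = diff(range(x)),
               spread_flag = diff(range(x)) > spread_threshold)
  }))
  rownames(out) <- NULL
  if (!is.null(housekeeping)) {
    wells <- unique(out[, c("condition", "bio_rep")])
    hk <- out[out$gene == housekeeping, c("condition", "bio_rep")]
    missing_hk <- !paste(wells$condition, wells$bio_rep) %in% paste(hk$condition, hk$bio_rep)
    if (any(missing_hk))
      abort_validation(sprintf(
        "housekeeping gene '%s' missing for sample %s (bio_rep %s)",
        housekeeping, wells$condition[missing_hk][1], wells$bio_rep[missing_hk][1]))
  }
  out[order(out$condition, out$bio_rep, out$gene), , drop = FALSE]
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per biological replicate, `dCt = Ct_target - Ct_housekeeping`; `ddCt`
#' references the mean dCt of the control condition, so control replicates
#' scatter around fold change 1; per-replicate fold change is `2^-ddCt`.
#' Condition differences are tested with a two-tailed Student's t-test on the
#' per-replicate dCt values (the additive scale), while fold changes are
#' reported multiplicatively.
#'
#' @param collapsed Collapsed Ct table from [collapse_technical()].
#' @param target Target gene name.
#' @param housekeeping Housekeeping gene name (must differ from `target`).
#' @param control Control condition label (the ddCt reference).
#'
#' @return An object of class `fold_change_result`: `gene`, `summary`
#'   data.frame (per condition: `fc_mean`, `fc_sem`, `n`, `p_two_tailed` vs
#'   control), and `per_rep` data.frame of replicate-level dCt and fold
#'   changes.
#' @examples
#' ct <- generate_ct_table(c(CDK1 = 0.47), noise_sd = 0, seed = 1)
#' ddct_fold_change(collapse_technical(ct), "CDK1", "GAPDH", "control")
#' @export
ddct_fold_change <- function(collapsed, target, housekeeping, control) {
  if (identical(target, housekeeping))
    abort_validation("target and housekeeping genes must differ")
  if (!control %in% collapsed$condition)
    abort_validation(sprintf("control condition '%s' not present", control))
  tg <- collapsed[collapsed$gene == target, c("condition", "bio_rep", "ct")]
  hk <- collapsed[collapsed$gene == housekeeping, c("condition", "bio_rep", "ct")]
  if (nrow(tg) == 0) abort_validation(sprintf("target gene '%s' not present", target))
  if (nrow(hk) == 0) abort_validation(sprintf("housekeeping gene '%s' not present", housekeeping))
  merged <- merge(tg, hk, by = c("condition", "bio_rep"),
                  suffixes = c("_target", "_hk"))
  if (nrow(merged) < nrow(tg))
    abort_validation("some replicates lack a housekeeping measurement")
  merged$dct <- merged$ct_target - merged$ct_hk
  ref <- mean(merged$dct[merged$condition == control])
  merged$ddct <- merged$dct - ref
  merged$fc <- 2^(-merged$ddct)
  conds <- unique(c(control, setdiff(merged$condition, control)))
  dct_ctrl <- merged$dct[merged$condition == control]
  summary <- do.call(rbind, lapply(conds, function(cc) {
    fc <- merged$fc[merged$condition == cc]
    p <- if (cc == control) NA_real_ else
      student_t_two_tailed(dct_ctrl, merged$dct[merged$condition == cc])$p_two_tailed
    data.frame(gene = target, condition = cc, fc_mean = mean(fc),
               fc_sem = if (length(fc) > 1) stats::sd(fc) / sqrt(length(fc)) else 0,
               n = length(fc), p_two_tailed = p)
  }))
  rownames(summary) <- NULL
  structure(list(gene = target, control = control, summary = summary,
                 per_rep = merged[, c("condition", "bio_rep", "dct", "ddct", "fc")]),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("2^-ddCt fold changes for %s (control: %s)\n", x$gene, x$control))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Significance stars for p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf), right = FALSE,
                   labels = c("***", "**", "*", "ns")))
}

#' Tidy fold-change report with significance stars
#'
#' Combines [ddct_fold_change()] results into one table, mapping the
#' treated-vs-control p-values to significance categories.
#'
#' @param results A list of `fold_change_result` objects.
#' @return A data.frame (`gene`, `condition`, `fc_mean`, `fc_sem`, `n`,
#'   `p_two_tailed`, `stars`).
#' @export
fold_change_report <- function(results) {
  if (length(results) == 0)
    abort_validation("fold_change_report requires at least one result")
  out <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "fold_change_result"))
    r$summary
  }))
  out$stars <- ifelse(is.na(out$p_two_tailed), "",
                      significance_stars(out$p_two_tailed))
  rownames(out) <- NULL
  out
}
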
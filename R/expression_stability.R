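# Constitutive-expression classification (maximal fold change and
# coefficient of variation with signal floors) and across-stage
# differential testing with FDR control.

#' Stability-classification thresholds
#'
#' @param mfc_max Maximal fold change must be strictly below this (default 2).
#' @param cv_max Coefficient of variation must be strictly below this
#'   (default 0.05).
#' @param signal_percentile_min The UCE's mean signal must strictly exceed
#'   this percentile of the distribution of all UCE mean signals
#'   (default 5).
#' @param alpha FDR level for across-stage differential calls (default 0.05).
#' @return A validated list of class `stability_config`.
#' @export
stability_config <- function(mfc_max = 2, cv_max = 0.05,
                             signal_percentile_min = 5, alpha = 0.05) {
  if (mfc_max < 1) stopf("mfc_max must be >= 1")
  if (cv_max <= 0) stopf("cv_max must be positive")
  if (signal_percentile_min < 0 || signal_percentile_min >= 100)
    stopf("signal_percentile_min must be in [0, 100)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(mfc_max = mfc_max, cv_max = cv_max,
                 signal_percentile_min = signal_percentile_min,
                 alpha = alpha), class = "stability_config")
}

#' Per-array signal summary for one UCE
#'
#' Mean intensity of a UCE's probes (role `"uce"`) on the requested strand,
#' per array, in array column order.
#'
#' @param m Normalized probe x array intensity matrix.
#' @param meta Probe metadata.
#' @param uce_id Target UCE identifier.
#' @param strand `"+"` or `"-"`.
#' @return Named numeric vector, one value per array.
#' @export
uce_signal_summary <- function(m, meta, uce_id, strand) {
  check_intensity_matrix(m)
  sel <- meta$probe_id[meta$target_id == uce_id & meta$strand == strand &
                         meta$role == "uce"]
  if (length(sel) == 0L)
    stopf("no probes for UCE '%s' on strand '%s'", uce_id, strand)
  colMeans(m[sel, , drop = FALSE])
}

#' Maximal fold change
#'
#' Ratio of the maximum to the minimum of a positive signal vector; 1 for a
#' constant vector.
#'
#' @param values Positive numeric vector.
#' @return `max(values) / min(values)`.
#' @export
compute_mfc <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)) || any(values <= 0))
    stopf("MFC requires positive finite values")
  max(values) / min(values)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector with nonzero mean, length >= 2.
#' @return `sd(values) / mean(values)`.
#' @export
compute_cv <- function(values) {
  if (length(values) < 2L) stopf("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  stats::sd(values) / m
}

#' Classify a UCE as constitutively expressed
#'
#' Constitutive iff all four hold strictly: MFC below `mfc_max`, CV below
#' `cv_max`, mean signal above the `signal_percentile_min` percentile of
#' all UCE mean signals, and mean signal above the negative-control floor.
#'
#' @param signal Per-array signal vector for the UCE (all arrays).
#' @param all_uce_means Mean signals of all UCEs (the reference
#'   distribution for the percentile floor).
#' @param negative_threshold Negative-control floor
#'   (`mean + 2 sd` of negative probes).
#' @param cfg A [stability_config()].
#' @return List: `mfc`, `cv`, `mean_signal`, `constitutive`.
#' @export
classify_constitutive <- function(signal, all_uce_means, negative_threshold,
                                  cfg = stability_config()) {
  mfc <- compute_mfc(signal)
  cv <- compute_cv(signal)
  mean_signal <- mean(signal)
  floor_pct <- stats::quantile(all_uce_means,
                               cfg$signal_percentile_min / 100,
                               type = 7, names = FALSE)
  list(mfc = mfc, cv = cv, mean_signal = mean_signal,
       constitutive = mfc < cfg$mfc_max && cv < cfg$cv_max &&
         mean_signal > floor_pct && mean_signal > negative_threshold)
}

#' Across-stage differential expression test
#'
#' Per UCE, a one-way fixed-effects F test across stages on
#' `log(signal + 1)`, followed by Benjamini-Hochberg adjustment across
#' UCEs. Rows with zero total variance (identical replicate values across
#' all stages) return p = 1 by convention.
#'
#' @param signal_matrix UCE x array matrix of per-array signal summaries.
#' @param stages Stage label per array column.
#' @param alpha FDR significance level (default 0.05).
#' @return Data.frame: `uce_id`, `diff_p`, `diff_p_adjusted`, `significant`.
#' @export
differential_across_stages <- function(signal_matrix, stages, alpha = 0.05) {
  if (!is.matrix(signal_matrix)) signal_matrix <- as.matrix(signal_matrix)
  if (length(stages) != ncol(signal_matrix))
    stopf("stages must label every array column")
  if (length(unique(stages)) < 2L) stopf("need at least 2 stages")
  if (any(table(stages) < 2L)) stopf("need >= 2 replicates in every stage")
  grp <- factor(stages)
  logs <- log(signal_matrix + 1)
  p <- apply(logs, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    res <- tryCatch(stats::oneway.test(v ~ grp, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
    if (!is.finite(res)) 1 else res
  })
  padj <- bh_adjust(p)
  data.frame(uce_id = rownames(signal_matrix) %||% seq_along(p),
             diff_p = unname(p), diff_p_adjusted = unname(padj),
             significant = unname(padj < alpha), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full stability summary for all UCEs
#'
#' Summarizes each UCE's probe signal on its called strand (the strand from
#' the expression profile; `+` when never called), classifies constitutive
#' expression, and runs the across-stage differential test.
#'
#' @param m Normalized intensity matrix.
#' @param meta Probe metadata.
#' @param profile Per-UCE profile from [expression_profile()].
#' @param thresholds Per-array thresholds from [array_thresholds()].
#' @param cfg A [stability_config()].
#' @return Data.frame, one row per UCE: `uce_id`, `strand`, `mfc`, `cv`,
#'   `mean_signal`, `constitutive`, `diff_p`, `diff_p_adjusted`,
#'   `significant`.
#' @export
stability_summary <- function(m, meta, profile, thresholds,
                              cfg = stability_config()) {
  check_intensity_matrix(m)
  labels <- parse_array_labels(colnames(m))
  ids <- profile$uce_id
  strand <- ifelse(profile$strandedness %in% c("single_minus"), "-", "+")
  sig <- t(vapply(seq_along(ids), function(i)
    uce_signal_summary(m, meta, ids[i], strand[i]), numeric(ncol(m))))
  rownames(sig) <- ids
  all_means <- rowMeans(sig)
  neg_floor <- mean(thresholds$negative_threshold)
  cls <- lapply(seq_along(ids), function(i)
    classify_constitutive(sig[i, ], all_means, neg_floor, cfg))
  diff <- differential_across_stages(sig, labels$stage, cfg$alpha)
  data.frame(uce_id = ids, strand = strand,
             mfc = vapply(cls, `[[`, numeric(1), "mfc"),
             cv = vapply(cls, `[[`, numeric(1), "cv"),
             mean_signal = vapply(cls, `[[`, numeric(1), "mean_signal"),
             constitutive = vapply(cls, `[[`, logical(1), "constitutive"),
             diff_p = diff$diff_p, diff_p_adjusted = diff$diff_p_adjusted,
             significant = diff$significant, stringsAsFactors = FALSE)
}
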
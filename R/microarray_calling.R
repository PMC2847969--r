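# Strand-specific expression calling from probe intensities: quantile
# normalization, per-array thresholds (signal-distribution percentile and
# negative-control floor), replicate-agreement probe calls, and per-UCE
# per-stage strand calls.

#' Expression-calling configuration
#'
#' @param percentile Signal-distribution percentile (of non-control probes)
#'   a probe must exceed; default 90.
#' @param min_positive_replicates Replicates in which a probe must pass;
#'   default 2 (of 3 hybridizations).
#' @param replicates Expected replicates per stage; default 3.
#' @param neg_sd_multiplier The negative-control floor is
#'   `mean + neg_sd_multiplier * sd` of negative-control probes; default 2.
#' @param min_probes_for_uce_call Probes (of `probes_per_strand`) that must
#'   be positive to call a UCE strand expressed; default 1.
#' @return A validated list of class `calling_config`.
#' @export
calling_config <- function(percentile = 90, min_positive_replicates = 2L,
                           replicates = 3L, neg_sd_multiplier = 2,
                           min_probes_for_uce_call = 1L) {
  if (percentile <= 0 || percentile >= 100)
    stopf("percentile must be in (0, 100)")
  if (min_positive_replicates > replicates)
    stopf("min_positive_replicates must be <= replicates")
  if (min_positive_replicates < 1L || min_probes_for_uce_call < 1L)
    stopf("minimum counts must be >= 1")
  structure(list(percentile = percentile,
                 min_positive_replicates = as.integer(min_positive_replicates),
                 replicates = as.integer(replicates),
                 neg_sd_multiplier = neg_sd_multiplier,
                 min_probes_for_uce_call = as.integer(min_probes_for_uce_call)),
            class = "calling_config")
}

check_intensity_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stopf("intensities must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("intensity matrix needs probe rownames and array colnames")
  if (any(!is.finite(m)) || any(m < 0)) stopf("intensities must be finite and nonnegative")
  invisible(m)
}

#' Parse array labels of the form `STAGE_repN`
#'
#' @param labels Character vector of array column labels.
#' @return A data.frame with columns `array`, `stage`, `replicate`.
#' @export
parse_array_labels <- function(labels) {
  ok <- grepl("^.+_rep[0-9]+$", labels)
  if (!all(ok)) stopf("malformed array label(s): %s",
                      paste(labels[!ok], collapse = ", "))
  data.frame(array = labels,
             stage = sub("_rep[0-9]+$", "", labels),
             replicate = as.integer(sub("^.*_rep", "", labels)),
             stringsAsFactors = FALSE)
}

#' Quantile-normalize an intensity matrix
#'
#' Standard quantile normalization (sorted-value column means): after
#' normalization every array has the identical sorted value vector; ties
#' within an array receive the mean of the quantile values they span.
#' Row and column labels are preserved.
#'
#' @param m Probe x array numeric matrix with at least 2 arrays.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(m) {
  check_intensity_matrix(m)
  if (ncol(m) < 2L) stopf("quantile normalization needs >= 2 arrays")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-array calling thresholds
#'
#' For each array: the configured percentile of the non-control probe
#' signal distribution (linear interpolation between order statistics), and
#' the negative-control floor `mean + k * sd` of negative-control probes.
#'
#' @param m Probe x array intensity matrix (normalized).
#' @param meta Probe metadata with `probe_id` and `role`.
#' @param cfg A [calling_config()].
#' @return Data.frame with one row per array: `array`,
#'   `percentile_threshold`, `negative_threshold`.
#' @export
array_thresholds <- function(m, meta, cfg = calling_config()) {
  check_intensity_matrix(m)
  if (!all(rownames(m) %in% meta$probe_id))
    stopf("matrix rows missing from probe metadata")
  role <- meta$role[match(rownames(m), meta$probe_id)]
  is_neg <- role == "negative_control"
  if (!any(is_neg)) stopf("no negative-control probes on the array")
  pct <- apply(m[!is_neg, , drop = FALSE], 2, stats::quantile,
               probs = cfg$percentile / 100, type = 7, names = FALSE)
  neg <- m[is_neg, , drop = FALSE]
  neg_sd <- apply(neg, 2, stats::sd)
  neg_sd[is.na(neg_sd)] <- 0  # single negative probe
  data.frame(array = colnames(m), percentile_threshold = unname(pct),
             negative_threshold = unname(colMeans(neg) +
                                           cfg$neg_sd_multiplier * neg_sd),
             stringsAsFactors = FALSE)
}

#' Call a single probe within one stage
#'
#' A probe is positive when its value strictly exceeds both the percentile
#' threshold and the negative-control floor in at least
#' `min_positive_replicates` replicate hybridizations.
#'
#' @param values Numeric vector, one intensity per replicate array.
#' @param thresholds Data.frame (or list) with `percentile_threshold` and
#'   `negative_threshold`, one entry per replicate.
#' @param cfg A [calling_config()].
#' @return Logical scalar.
#' @export
call_probe <- function(values, thresholds, cfg = calling_config()) {
  pt <- thresholds$percentile_threshold
  nt <- thresholds$negative_threshold
  if (length(values) != length(pt) || length(values) != length(nt))
    stopf("replicate count mismatch between values and thresholds")
  sum(values > pt & values > nt) >= cfg$min_positive_replicates
}

strand_call_status <- function(plus_called, minus_called) {
  ifelse(plus_called & minus_called, "both",
         ifelse(plus_called, "single_plus",
                ifelse(minus_called, "single_minus", "none")))
}

#' Aggregate probe calls into a per-UCE, per-stage strand call
#'
#' A strand is called expressed when at least `min_probes_for_uce_call` of
#' its probes are positive.
#'
#' @param probe_calls Named list with logical vectors `plus` and `minus`
#'   (one element per probe).
#' @param cfg A [calling_config()].
#' @return List with `plus_called`, `minus_called`, and `status` (one of
#'   `single_plus`, `single_minus`, `both`, `none`).
#' @export
call_uce_stage <- function(probe_calls, cfg = calling_config()) {
  if (length(probe_calls$plus) == 0L || length(probe_calls$minus) == 0L)
    stopf("empty probe set for a strand")
  plus <- sum(probe_calls$plus) >= cfg$min_probes_for_uce_call
  minus <- sum(probe_calls$minus) >= cfg$min_probes_for_uce_call
  list(plus_called = plus, minus_called = minus,
       status = strand_call_status(plus, minus))
}

#' Call expression for every target across all stages
#'
#' Vectorized pipeline: thresholds per array, replicate-agreement probe
#' calls per stage, then per-target per-strand aggregation for probes of
#' the requested role.
#'
#' @param m Normalized probe x array intensity matrix.
#' @param meta Probe metadata (`probe_id`, `target_id`, `strand`, `role`).
#' @param cfg A [calling_config()].
#' @param role Probe role to aggregate (default `"uce"`).
#' @return Data.frame with one row per target x stage: `uce_id`, `stage`,
#'   `plus_called`, `minus_called`, `status`. The thresholds table is
#'   attached as attribute `thresholds`.
#' @export
call_expression <- function(m, meta, cfg = calling_config(), role = "uce") {
  check_intensity_matrix(m)
  labels <- parse_array_labels(colnames(m))
  stages <- unique(labels$stage)
  reps_per_stage <- table(labels$stage)
  if (length(unique(reps_per_stage)) != 1L)
    stopf("replicate count differs between stages")
  thr <- array_thresholds(m, meta, cfg)
  pt <- matrix(thr$percentile_threshold, nrow(m), ncol(m), byrow = TRUE)
  nt <- matrix(thr$negative_threshold, nrow(m), ncol(m), byrow = TRUE)
  pass <- m > pt & m > nt

  sel <- meta[match(rownames(m), meta$probe_id), ]
  keep <- sel$role == role
  if (!any(keep)) stopf("no probes with role '%s'", role)
  targets <- sort(unique(sel$target_id[keep]))

  rows <- list()
  for (st in stages) {
    cols <- labels$array[labels$stage == st]
    probe_pos <- rowSums(pass[, cols, drop = FALSE]) >= cfg$min_positive_replicates
    for (strand in c("+", "-")) {
      idx <- keep & sel$strand == strand
      cnt <- rowsum(as.integer(probe_pos[idx]), group = sel$target_id[idx])
      called <- stats::setNames(cnt[, 1] >= cfg$min_probes_for_uce_call,
                                rownames(cnt))
      rows[[paste(st, strand)]] <- called[targets]
    }
  }
  out <- data.frame(
    uce_id = rep(targets, times = length(stages)),
    stage = rep(stages, each = length(targets)),
    plus_called = unlist(lapply(stages, function(s) rows[[paste(s, "+")]]),
                         use.names = FALSE),
    minus_called = unlist(lapply(stages, function(s) rows[[paste(s, "-")]]),
                          use.names = FALSE),
    stringsAsFactors = FALSE)
  out$plus_called[is.na(out$plus_called)] <- FALSE
  out$minus_called[is.na(out$minus_called)] <- FALSE
  out$status <- strand_call_status(out$plus_called, out$minus_called)
  attr(out, "thresholds") <- thr
  out
}

#' Summarize per-stage strand calls into a per-UCE expression profile
#'
#' @param calls A strand-call table from [call_expression()] (or rows of
#'   the same shape), covering all configured stages for every UCE.
#' @param stages Character vector of the expected stages (defaults to the
#'   stages present in `calls`).
#' @return Data.frame, one row per UCE: `uce_id`, per-stage status columns
#'   (`status_<stage>`), `any_stage`, `all_stages`, and overall
#'   `strandedness` (`both` if any stage shows both strands, else
#'   `single_plus`/`single_minus` if ever called, else `none`).
#' @export
expression_profile <- function(calls, stages = unique(calls$stage)) {
  miss <- setdiff(stages, unique(calls$stage))
  if (length(miss) > 0) stopf("missing stage(s): %s", paste(miss, collapse = ", "))
  ids <- sort(unique(calls$uce_id))
  per_stage <- lapply(stages, function(st) {
    sub <- calls[calls$stage == st, ]
    if (anyDuplicated(sub$uce_id)) stopf("duplicate calls for stage %s", st)
    if (!setequal(sub$uce_id, ids)) stopf("stage %s does not cover all UCEs", st)
    sub[match(ids, sub$uce_id), ]
  })
  names(per_stage) <- stages
  called_mat <- vapply(per_stage, function(s) s$plus_called | s$minus_called,
                       logical(length(ids)))
  called_mat <- matrix(called_mat, nrow = length(ids))
  plus_any <- Reduce(`|`, lapply(per_stage, `[[`, "plus_called"))
  minus_any <- Reduce(`|`, lapply(per_stage, `[[`, "minus_called"))
  both_any <- Reduce(`|`, lapply(per_stage, function(s) s$status == "both"))
  n_plus <- Reduce(`+`, lapply(per_stage, function(s) as.integer(s$plus_called)))
  n_minus <- Reduce(`+`, lapply(per_stage, function(s) as.integer(s$minus_called)))
  strandedness <- ifelse(both_any, "both",
                         ifelse(plus_any | minus_any,
                                ifelse(n_minus > n_plus, "single_minus",
                                       "single_plus"),
                                "none"))
  out <- data.frame(uce_id = ids, stringsAsFactors = FALSE)
  for (st in stages) out[[paste0("status_", st)]] <- per_stage[[st]]$status
  out$any_stage <- rowSums(called_mat) > 0
  out$all_stages <- rowSums(called_mat) == length(stages)
  out$strandedness <- strandedness
  out
}
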
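# RNA-Seq style coverage quantification over regions, the background-based
# expression cutoff, class comparisons (empirical Z and Wilcoxon), and
# flanking-transcription classification.

track_granges <- function(track) {
  gr <- gi_granges(track)
  S4Vectors::mcols(gr)$depth <- track$depth
  gr
}

region_track_overlap <- function(regions, track, depth_floor = NULL) {
  # Per-region summed depth*width (or covered width when depth_floor set).
  q <- gi_granges(regions)
  steps <- track
  if (!is.null(depth_floor))
    steps <- steps[steps$depth >= depth_floor, , drop = FALSE]
  total <- numeric(nrow(regions))
  if (nrow(steps) > 0L) {
    s <- track_granges(steps)
    # disjoint seqlevels are already reported via warn_absent_chroms
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
    if (length(hits) > 0L) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qh],
                                              IRanges::ranges(s)[sh]))
      contrib <- if (is.null(depth_floor)) w * steps$depth[sh] else w
      agg <- rowsum(contrib, group = qh)
      total[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  total
}

warn_absent_chroms <- function(regions, track) {
  absent <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(absent) > 0)
    warnf("region chromosome(s) absent from coverage track (depth 0): %s",
          paste(absent, collapse = ", "))
}

#' Mean per-base coverage of regions
#'
#' Bases outside any track step count as depth 0; regions on chromosomes
#' absent from the track get mean 0 with a warning.
#'
#' @param regions Interval table.
#' @param track A [coverage_track()].
#' @return Numeric vector of mean depths, one per region.
#' @export
region_mean_coverage <- function(regions, track) {
  if (nrow(regions) == 0L) return(numeric())
  warn_absent_chroms(regions, track)
  region_track_overlap(regions, track) / (regions$end - regions$start)
}

#' Fraction of region bases covered at or above a depth floor
#'
#' @param regions Interval table.
#' @param track A [coverage_track()].
#' @param min_depth Depth floor (default 1).
#' @return Numeric vector in `[0, 1]`, one per region.
#' @export
region_coverage_fraction <- function(regions, track, min_depth = 1) {
  if (nrow(regions) == 0L) return(numeric())
  warn_absent_chroms(regions, track)
  region_track_overlap(regions, track, depth_floor = min_depth) /
    (regions$end - regions$start)
}

#' Expression cutoff from background coverage levels
#'
#' The stated percentile of the mean-depth distribution of random
#' non-transcribed background regions; levels strictly above the cutoff are
#' called expressed.
#'
#' @param background_levels Mean depths of at least 20 background regions.
#' @param percentile Percentile (default 95).
#' @return Numeric cutoff.
#' @export
expression_cutoff <- function(background_levels, percentile = 95) {
  if (length(background_levels) < 20L)
    stopf("need >= 20 background regions for a stable cutoff")
  if (percentile <= 0 || percentile > 100) stopf("percentile must be in (0, 100]")
  stats::quantile(background_levels, percentile / 100, type = 7, names = FALSE)
}

#' Call regions expressed against a coverage cutoff
#'
#' @param levels Mean depths per region.
#' @param cutoff Nonnegative cutoff; a region is expressed iff its level is
#'   strictly above it.
#' @return Logical vector.
#' @export
call_rnaseq_expressed <- function(levels, cutoff) {
  if (cutoff < 0) stopf("cutoff must be nonnegative")
  levels > cutoff
}

#' Flanking-transcription status of UCEs
#'
#' Each UCE's upstream and downstream flank windows (genome coordinates:
#' left and right of the interval) are called expressed by mean coverage
#' against the cutoff. Flanks are clipped at chromosome ends; when more
#' than half of either flank is clipped the UCE is `not_assessable`.
#'
#' @param uces Interval table.
#' @param track A [coverage_track()].
#' @param cutoff Expression cutoff (from [expression_cutoff()]).
#' @param window Flank width in bp (default 500).
#' @param chrom_sizes Named chromosome lengths; defaults to the track's
#'   `chrom_sizes` attribute.
#' @return Character vector per UCE: `both`, `upstream_only`,
#'   `downstream_only`, `none`, or `not_assessable`.
#' @export
flanking_status <- function(uces, track, cutoff, window = 500L,
                            chrom_sizes = attr(track, "chrom_sizes")) {
  if (window <= 0) stopf("window must be positive")
  if (is.null(chrom_sizes)) stopf("chrom_sizes required (or set on the track)")
  n <- nrow(uces)
  if (n == 0L) return(character())
  size <- chrom_sizes[uces$chrom]
  if (any(is.na(size))) stopf("UCE chromosome missing from chrom_sizes")
  up_s <- pmax(0, uces$start - window); up_e <- uces$start
  dn_s <- uces$end; dn_e <- pmin(size, uces$end + window)
  clipped <- (window - (up_e - up_s)) > window / 2 |
    (window - (dn_e - dn_s)) > window / 2
  status <- rep("not_assessable", n)
  ok <- which(!clipped & up_e > up_s & dn_e > dn_s)
  if (length(ok) > 0) {
    up <- genomic_intervals(uces$chrom[ok], up_s[ok], up_e[ok])
    dn <- genomic_intervals(uces$chrom[ok], dn_s[ok], dn_e[ok])
    up_on <- call_rnaseq_expressed(region_mean_coverage(up, track), cutoff)
    dn_on <- call_rnaseq_expressed(region_mean_coverage(dn, track), cutoff)
    status[ok] <- ifelse(up_on & dn_on, "both",
                         ifelse(up_on, "upstream_only",
                                ifelse(dn_on, "downstream_only", "none")))
  }
  status
}

#' Compare coverage levels between region classes
#'
#' For every non-reference class, an [empirical_ztest()] of the class mean
#' against size-matched resamples from the reference class. When both
#' members of `wilcoxon_pair` are present, a Wilcoxon rank-sum test is run
#' for that pair as well (the UCE vs random-background comparison).
#'
#' @param levels_by_class Named list of numeric mean-depth vectors.
#' @param reference_class Name of the reference class (>= 20 values).
#' @param n_samples Resamples for the Z test (default 10000).
#' @param seed Integer seed; class tests use fixed offsets from it.
#' @param wilcoxon_pair Two class names for the rank-sum comparison
#'   (default `c("uce", "random_background")`).
#' @return List: `ztests` (data.frame class/statistic/p_value/mean),
#'   `wilcoxon` (a [test_result()] or `NULL`), `class_means`.
#' @export
class_expression_comparison <- function(levels_by_class, reference_class,
                                        n_samples = 10000L, seed,
                                        wilcoxon_pair = c("uce",
                                                          "random_background")) {
  if (missing(seed)) stopf("seed is required")
  if (!reference_class %in% names(levels_by_class))
    stopf("reference class '%s' absent", reference_class)
  ref <- levels_by_class[[reference_class]]
  if (length(ref) < 20L) stopf("reference class needs >= 20 values")
  others <- setdiff(names(levels_by_class), reference_class)
  zrows <- lapply(seq_along(others), function(i) {
    zt <- empirical_ztest(levels_by_class[[others[i]]], ref,
                          n_samples = n_samples, seed = seed + i)
    data.frame(class = others[i], statistic = zt$statistic,
               p_value = zt$p_value, mean = mean(levels_by_class[[others[i]]]),
               stringsAsFactors = FALSE)
  })
  wilcox <- NULL
  if (all(wilcoxon_pair %in% names(levels_by_class)))
    wilcox <- wilcoxon_rank_sum(levels_by_class[[wilcoxon_pair[1]]],
                                levels_by_class[[wilcoxon_pair[2]]])
  list(ztests = do.call(rbind, zrows), wilcoxon = wilcox,
       class_means = vapply(levels_by_class, mean, numeric(1)))
}
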
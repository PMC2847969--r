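# Shared containers and low-level helpers: genomic intervals (0-based
# half-open, BED dialect), layered annotation sets, and coverage tracks.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

#' Construct a validated table of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention): a feature covering the
#' first 200 bases of a chromosome has `start = 0`, `end = 200`, and
#' `length = end - start`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `0 <= start < end` elementwise.
#' @param strand Strand per interval: `"+"`, `"-"`, or `"."` (unstranded).
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   and optionally `name` and `score`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL,
                              score = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep_len(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stopf("chrom, start, end must have equal length")
  if (n == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     strand = character(), stringsAsFactors = FALSE)
    if (!is.null(name)) df$name <- character()
    if (!is.null(score)) df$score <- numeric()
    return(df)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stopf("interval coordinates must be finite")
  if (any(start < 0)) stopf("interval start must be >= 0")
  if (any(end <= start)) stopf("interval end must be > start")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", ".")))
    stopf("strand must be one of '+', '-', '.'")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), n)
  if (!is.null(score)) df$score <- rep_len(as.numeric(score), n)
  df
}

empty_intervals <- function() genomic_intervals(character(), integer(), integer())

# Convert an interval data.frame to a GRanges (1-based closed internally).
gi_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = "*"
  )
}

#' Test intervals for any overlap with a subject set
#'
#' @param query,subject Interval tables (see [genomic_intervals()]).
#' @return Logical vector: does each query interval overlap (>= 1 bp) any
#'   subject interval?
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(gi_granges(query), gi_granges(subject)) > 0L
}

ANNOTATION_LAYERS <- c("known_exons", "gene_bodies", "predictions_ests",
                       "repeats", "dna_align_features",
                       "protein_align_features", "n_gaps")

#' Construct a layered genome annotation set
#'
#' Bundles the annotation layers used for genomic-context classification and
#' random background-region sampling. Every layer is an interval table as
#' produced by [genomic_intervals()]; missing layers default to empty.
#' `dna_align_features` should carry a `score` column (alignment score used
#' by the background-sampler filter).
#'
#' @param known_exons,gene_bodies,predictions_ests,repeats Interval tables.
#' @param dna_align_features Interval table with a `score` column.
#' @param protein_align_features,n_gaps Interval tables.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return An object of class `annotation_set` (a named list of layers plus
#'   `chrom_sizes`).
#' @export
annotation_set <- function(known_exons = empty_intervals(),
                           gene_bodies = empty_intervals(),
                           predictions_ests = empty_intervals(),
                           repeats = empty_intervals(),
                           dna_align_features = empty_intervals(),
                           protein_align_features = empty_intervals(),
                           n_gaps = empty_intervals(),
                           chrom_sizes = NULL) {
  layers <- list(known_exons = known_exons, gene_bodies = gene_bodies,
                 predictions_ests = predictions_ests, repeats = repeats,
                 dna_align_features = dna_align_features,
                 protein_align_features = protein_align_features,
                 n_gaps = n_gaps)
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    if (!is.data.frame(ly) || !all(c("chrom", "start", "end") %in% names(ly)))
      stopf("annotation layer '%s' must be an interval data.frame", nm)
  }
  if (!is.null(chrom_sizes)) {
    if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
      stopf("chrom_sizes must be a named vector")
    if (any(chrom_sizes <= 0)) stopf("chrom_sizes must be positive")
  }
  structure(c(layers, list(chrom_sizes = chrom_sizes)),
            class = "annotation_set")
}

annotated_chroms <- function(ann) {
  if (!is.null(ann$chrom_sizes)) return(names(ann$chrom_sizes))
  unique(unlist(lapply(ANNOTATION_LAYERS, function(nm) ann[[nm]]$chrom),
                use.names = FALSE))
}

#' Construct a per-base coverage track
#'
#' A coverage track is a set of sorted, non-overlapping step intervals
#' (0-based half-open) with a nonnegative `depth`, equivalent to per-base
#' read depth; bases outside all steps have depth 0. Adjacent steps with
#' equal depth are merged.
#'
#' @param chrom,start,end Interval coordinates (see [genomic_intervals()]).
#' @param depth Nonnegative numeric depth per step.
#' @return A `data.frame` of class `coverage_track` with columns `chrom`,
#'   `start`, `end`, `depth`.
#' @export
coverage_track <- function(chrom = character(), start = integer(),
                           end = integer(), depth = numeric()) {
  if (length(depth) != length(chrom)) stopf("depth must match interval count")
  if (any(depth < 0)) stopf("coverage depth must be nonnegative")
  df <- genomic_intervals(chrom, start, end)
  df$strand <- NULL
  df$depth <- as.numeric(depth)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # reject overlap within chromosome
  if (nrow(df) > 1L) {
    same <- df$chrom[-1L] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1L] < df$end[-nrow(df)]))
      stopf("coverage steps overlap")
    # merge adjacent equal-depth steps
    joinable <- same & df$start[-1L] == df$end[-nrow(df)] &
      df$depth[-1L] == df$depth[-nrow(df)]
    if (any(joinable)) {
      firsts <- which(c(TRUE, !joinable))
      lasts <- c(firsts[-1L] - 1L, nrow(df))
      df <- data.frame(chrom = df$chrom[firsts], start = df$start[firsts],
                       end = df$end[lasts], depth = df$depth[firsts],
                       stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("coverage_track", "data.frame")
  df
}

# Evaluate an expression with a private RNG stream seeded by `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stopf("seed must be a single nonnegative integer")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
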
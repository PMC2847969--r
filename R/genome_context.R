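# Genomic-context classification of UCEs, category enrichment with exact
# tests and Hochberg correction, matched random background sampling with
# annotation filters, and inter-UCE distance comparisons.

CONTEXT_CLASSES <- c("exonic", "possibly_exonic", "intronic", "non_exonic")

#' Classify UCEs by genomic context
#'
#' Strict precedence with a single-nucleotide overlap rule: `exonic` if the
#' UCE overlaps a known exon by >= 1 bp; else `possibly_exonic` if it
#' overlaps EST/gene-prediction evidence; else `intronic` if it lies within
#' a gene body; else `non_exonic`.
#'
#' @param uces Interval table of UCEs.
#' @param ann An [annotation_set()].
#' @return Character vector of context classes, one per UCE (named by the
#'   `name` column when present).
#' @export
classify_context <- function(uces, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(uces) == 0L) return(character())
  known <- annotated_chroms(ann)
  bad <- setdiff(unique(uces$chrom), known)
  if (length(bad) > 0)
    stopf("UCE(s) on unannotated chromosome(s): %s", paste(bad, collapse = ", "))
  cls <- rep("non_exonic", nrow(uces))
  cls[overlaps_any(uces, ann$gene_bodies)] <- "intronic"
  cls[overlaps_any(uces, ann$predictions_ests)] <- "possibly_exonic"
  cls[overlaps_any(uces, ann$known_exons)] <- "exonic"
  if (!is.null(uces$name)) names(cls) <- uces$name
  cls
}

#' Context-category enrichment of a UCE subset
#'
#' For each context class, builds the 2x2 table of (subset vs rest of
#' universe) x (in class vs not), runs the two-sided exact test, and
#' applies Hochberg correction across the four classes. Degenerate tables
#' (class absent from the universe) return p = 1.
#'
#' @param subset_ids UCE ids of the subset of interest.
#' @param universe_ids UCE ids of the universe (superset of `subset_ids`).
#' @param contexts Named character vector of context classes, covering the
#'   universe.
#' @return Data.frame per class: counts `in_subset`, `in_rest`, totals,
#'   `odds_ratio`, `p`, `p_hochberg`.
#' @export
context_enrichment <- function(subset_ids, universe_ids, contexts) {
  if (length(subset_ids) == 0L) stopf("empty subset")
  if (!all(subset_ids %in% universe_ids)) stopf("subset must be within universe")
  if (length(subset_ids) >= length(unique(universe_ids)))
    stopf("subset must be a strict subset of the universe")
  miss <- setdiff(universe_ids, names(contexts))
  if (length(miss) > 0) stopf("contexts missing for %d universe UCE(s)", length(miss))
  ctx <- contexts[universe_ids]
  in_sub <- universe_ids %in% subset_ids
  rows <- lapply(CONTEXT_CLASSES, function(cl) {
    a <- sum(in_sub & ctx == cl); b <- sum(in_sub & ctx != cl)
    c_ <- sum(!in_sub & ctx == cl); d <- sum(!in_sub & ctx != cl)
    degenerate <- (a + c_) == 0 || (b + d) == 0
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      ft <- fisher_exact(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      p <- ft$p_value; or <- ft$statistic
    }
    data.frame(class = cl, in_subset = a, not_in_subset_class = c_,
               subset_total = a + b, universe_total = a + b + c_ + d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_hochberg <- hochberg_adjust(out$p)
  out
}

#' Sample matched random background regions
#'
#' For every requested length, draws `n_per` regions of exactly that length
#' by rejection sampling uniform over the genome (chromosomes weighted by
#' available length). A candidate is rejected if it overlaps (>= 1 bp) any
#' of: DNA alignment features with score above `dna_score_max`, protein
#' alignment features, EST/gene-prediction evidence, repeats, N gaps, known
#' exons, the UCEs themselves (when given), or a previously accepted
#' region.
#'
#' @param ann An [annotation_set()].
#' @param chrom_sizes Named chromosome lengths; defaults to the
#'   annotation's.
#' @param lengths Vector of region lengths (bp), typically the UCE lengths.
#' @param n_per Regions per input length (default 3).
#' @param seed Integer seed; sampling is deterministic given it.
#' @param max_attempts Proposals allowed per region before giving up
#'   (default 10000).
#' @param uces Optional UCE interval table to exclude.
#' @param dna_score_max DNA-alignment score above which a feature excludes
#'   a candidate (default 75).
#' @return Interval table of `length(lengths) * n_per` regions named
#'   `rand_<i>`.
#' @export
select_random_regions <- function(ann, chrom_sizes = ann$chrom_sizes, lengths,
                                  n_per = 3L, seed, max_attempts = 10000L,
                                  uces = NULL, dna_score_max = 75) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(chrom_sizes)) stopf("chrom_sizes required")
  if (length(lengths) == 0L || any(lengths <= 0)) stopf("lengths must be positive")
  if (missing(seed)) stopf("seed is required")
  daf <- ann$dna_align_features
  if (nrow(daf) > 0 && !is.null(daf$score))
    daf <- daf[daf$score > dna_score_max, , drop = FALSE]
  excl <- list(daf, ann$protein_align_features, ann$predictions_ests,
               ann$repeats, ann$n_gaps, ann$known_exons)
  if (!is.null(uces)) excl <- c(excl, list(uces))
  excl <- Filter(function(x) nrow(x) > 0, excl)
  excl_gr <- if (length(excl) > 0) {
    GenomicRanges::reduce(do.call(
      c, lapply(excl, function(df) gi_granges(df))))
  } else GenomicRanges::GRanges()

  wanted <- rep(as.numeric(lengths), each = n_per)
  with_seed(seed, {
    acc_chrom <- character(0); acc_start <- numeric(0); acc_end <- numeric(0)
    acc_gr <- GenomicRanges::GRanges()
    for (i in seq_along(wanted)) {
      len <- wanted[i]
      room <- pmax(chrom_sizes - len + 1, 0)  # pmax(0, x) would drop names
      if (sum(room) == 0) stopf("no chromosome can hold a region of length %d", len)
      attempts <- 0L
      found <- FALSE
      while (attempts < max_attempts) {
        chunk <- min(100L, max_attempts - attempts)
        attempts <- attempts + chunk
        ch <- sample(names(chrom_sizes), chunk, replace = TRUE,
                     prob = room / sum(room))
        st <- floor(stats::runif(chunk) * room[ch])
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1, st + len))
        bad <- GenomicRanges::countOverlaps(cand, excl_gr) > 0L |
          GenomicRanges::countOverlaps(cand, acc_gr) > 0L
        if (any(!bad)) {
          j <- which(!bad)[1L]
          acc_chrom <- c(acc_chrom, ch[j])
          acc_start <- c(acc_start, st[j])
          acc_end <- c(acc_end, st[j] + len)
          acc_gr <- c(acc_gr, cand[j])
          found <- TRUE
          break
        }
      }
      if (!found)
        stopf("could not place a clean region of length %d after %d attempts",
              len, max_attempts)
    }
    genomic_intervals(acc_chrom, acc_start, acc_end,
                      name = sprintf("rand_%04d", seq_along(acc_chrom)))
  })
}

#' Nearest-neighbor distances between UCEs
#'
#' For each UCE, the gap (end-to-start; 0 when overlapping or adjacent) to
#' the nearest other UCE on the same chromosome. UCEs alone on their
#' chromosome get `NA` and are excluded from summaries.
#'
#' @param uces Interval table with at least 2 rows.
#' @return Numeric vector of gaps aligned with the input rows.
#' @export
nearest_neighbor_distances <- function(uces) {
  if (nrow(uces) < 2L) stopf("need at least 2 UCEs")
  out <- rep(NA_real_, nrow(uces))
  for (ch in unique(uces$chrom)) {
    idx <- which(uces$chrom == ch)
    if (length(idx) < 2L) next
    ord <- idx[order(uces$start[idx])]
    s <- uces$start[ord]; e <- uces$end[ord]
    k <- length(ord)
    gap_next <- c(pmax(0, s[-1] - e[-k]), Inf)
    gap_prev <- c(Inf, gap_next[-k])
    out[ord] <- pmin(gap_prev, gap_next)
  }
  out
}

#' Compare inter-UCE distance distributions
#'
#' Wilcoxon rank-sum comparison of nearest-neighbor distances between two
#' groups (e.g. transcribed vs non-transcribed UCEs), with group medians
#' and the direction of the difference.
#'
#' @param transcribed,non_transcribed Numeric distance vectors (`NA`s
#'   dropped).
#' @return List: `test` (a [test_result()]), `median_transcribed`,
#'   `median_non_transcribed`, `direction`.
#' @export
compare_distance_distributions <- function(transcribed, non_transcribed) {
  x <- transcribed[!is.na(transcribed)]
  y <- non_transcribed[!is.na(non_transcribed)]
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be non-empty")
  tr <- wilcoxon_rank_sum(x, y)
  mx <- stats::median(x); my <- stats::median(y)
  list(test = tr, median_transcribed = mx, median_non_transcribed = my,
       direction = if (mx > my) "transcribed_more_distant"
                   else if (mx < my) "transcribed_closer" else "equal")
}
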
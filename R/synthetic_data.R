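# Synthetic-data generator: emulates every input the pipeline consumes
# (annotation, UCE intervals, probe intensities, coverage tracks, external
# call sets) with planted ground truth, so every downstream stage can be
# tested by parameter recovery.
#
# Genome layout: each UCE owns a fixed-size locus laid out deterministically
# along the synthetic chromosomes. Context classes are realized by
# construction: an overlapping known exon (exonic), a host gene body with
# terminal exons only (intronic), an EST/prediction block (possibly
# exonic), or nothing (non-exonic). Decoy features (repeats, DNA/protein
# alignments, N gaps, stray ESTs) populate inter-locus space so the
# background sampler's filters are exercised.

LOCUS_SPAN <- 8000L
LOCUS_MARGIN <- 5000L
UCE_OFFSET <- 3000L  # UCE start within its locus

#' Simulation configuration
#'
#' Parameters of the synthetic dataset. Defaults describe a desk-scale
#' developmental time course: four stages (ES cells plus three embryonic
#' stages), three hybridization replicates per stage, three probes per UCE
#' strand, and 500-bp flank windows implied by the locus layout.
#'
#' @param n_chromosomes,chrom_length Number and length (bp) of synthetic
#'   chromosomes.
#' @param n_uces Number of UCEs to plant.
#' @param uce_length UCE length in bp (>= 200 by definition of a UCE).
#' @param context_mix Named fractions over
#'   `c(exonic, possibly_exonic, intronic, non_exonic)`, summing to 1.
#' @param frac_expressed Fraction of UCEs transcribed in at least one stage.
#' @param frac_both_strands Of expressed UCEs, fraction transcribed from
#'   both strands.
#' @param frac_constitutive_of_expressed Of expressed UCEs, fraction
#'   expressed stably in all stages.
#' @param stage_labels Ordered developmental stage labels.
#' @param n_replicates Hybridization replicates per stage.
#' @param probes_per_strand Probes per UCE strand.
#' @param signal_effect Mean log-signal separation of expressed targets, in
#'   units of `noise_sd`.
#' @param noise_sd Log-scale noise SD of background (unexpressed) probes.
#' @param noise_sd_expressed Log-scale noise SD of expressed probe cells;
#'   high-intensity probes on real arrays show far smaller relative spread
#'   than the background floor.
#' @param probe_affinity_sd SD of the persistent per-probe log-affinity
#'   (sequence-dependent binding efficiency, constant across arrays); it
#'   spreads probe intensities within an expression state without adding
#'   array-to-array variance.
#' @param array_scale_sd SD of the per-array multiplicative (log-additive)
#'   scale jitter that quantile normalization must remove.
#' @param baseline_log_signal Background mean log intensity.
#' @param coverage_means Named per-base mean coverage by region class;
#'   must contain `coding_exon`, `uce_expressed`, `random_background`.
#' @param enhancer_frac Fraction of UCEs with true enhancer activity.
#' @param enhancer_tested_frac Fraction of UCEs covered by the enhancer
#'   assay (others are reported `not_tested`).
#' @param concordance_human Probability that the human expression call
#'   agrees with true mouse transcription.
#' @param human_tested_frac Fraction of UCEs covered by the human set.
#' @param flank_ext_probs Named probabilities that a transcribed UCE's
#'   transcript extends into `both`, `upstream_only`, `downstream_only`, or
#'   `none` of its 500-bp flanks.
#' @param exon_expressed_prob Probability that the host gene of a genic UCE
#'   is itself expressed (drives exon-probe signal and exon coverage).
#' @param stage_on_prob Per-stage inclusion probability when drawing the
#'   stage subset of a non-constitutively expressed UCE.
#' @param seed Master seed; all generator stages derive fixed offsets from
#'   it and are deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L, chrom_length = 1e6, n_uces = 200L,
                       uce_length = 200L,
                       context_mix = c(exonic = 0.25, possibly_exonic = 0.15,
                                       intronic = 0.30, non_exonic = 0.30),
                       frac_expressed = 0.5, frac_both_strands = 0.04,
                       frac_constitutive_of_expressed = 0.56,
                       stage_labels = c("ES", "E12.5", "E14.5", "E16.5"),
                       n_replicates = 3L, probes_per_strand = 3L,
                       signal_effect = 6, noise_sd = 1,
                       noise_sd_expressed = 0.05, probe_affinity_sd = 0.2,
                       array_scale_sd = 0.15, baseline_log_signal = 4,
                       coverage_means = c(coding_exon = 20, uce_expressed = 2,
                                          random_background = 0.05),
                       enhancer_frac = 0.45, enhancer_tested_frac = 0.55,
                       concordance_human = 0.62, human_tested_frac = 0.9,
                       flank_ext_probs = c(both = 0.15, upstream_only = 0.05,
                                           downstream_only = 0.05,
                                           none = 0.75),
                       exon_expressed_prob = 0.15, stage_on_prob = 0.5,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_uces = as.integer(n_uces), uce_length = as.integer(uce_length),
              context_mix = context_mix, frac_expressed = frac_expressed,
              frac_both_strands = frac_both_strands,
              frac_constitutive_of_expressed = frac_constitutive_of_expressed,
              stage_labels = stage_labels,
              n_replicates = as.integer(n_replicates),
              probes_per_strand = as.integer(probes_per_strand),
              signal_effect = signal_effect, noise_sd = noise_sd,
              noise_sd_expressed = noise_sd_expressed,
              probe_affinity_sd = probe_affinity_sd,
              array_scale_sd = array_scale_sd,
              baseline_log_signal = baseline_log_signal,
              coverage_means = coverage_means, enhancer_frac = enhancer_frac,
              enhancer_tested_frac = enhancer_tested_frac,
              concordance_human = concordance_human,
              human_tested_frac = human_tested_frac,
              flank_ext_probs = flank_ext_probs,
              exon_expressed_prob = exon_expressed_prob,
              stage_on_prob = stage_on_prob, seed = as.integer(seed))
  fracs <- c(frac_expressed = frac_expressed,
             frac_both_strands = frac_both_strands,
             frac_constitutive_of_expressed = frac_constitutive_of_expressed,
             enhancer_frac = enhancer_frac,
             enhancer_tested_frac = enhancer_tested_frac,
             concordance_human = concordance_human,
             human_tested_frac = human_tested_frac,
             exon_expressed_prob = exon_expressed_prob,
             stage_on_prob = stage_on_prob)
  if (any(fracs < 0 | fracs > 1))
    stopf("fraction parameter out of [0, 1]: %s",
          paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  ctx_names <- c("exonic", "possibly_exonic", "intronic", "non_exonic")
  if (!setequal(names(context_mix), ctx_names))
    stopf("context_mix must be named over exonic/possibly_exonic/intronic/non_exonic")
  if (abs(sum(context_mix) - 1) > 1e-9) stopf("context_mix must sum to 1")
  if (any(context_mix < 0)) stopf("context_mix fractions must be >= 0")
  if (cfg$uce_length < 200L) stopf("uce_length must be >= 200 bp")
  if (cfg$n_uces < 0L) stopf("n_uces must be >= 0")
  if (cfg$n_chromosomes < 1L || cfg$chrom_length < 2 * LOCUS_MARGIN + LOCUS_SPAN)
    stopf("genome too small: need chrom_length >= %d", 2 * LOCUS_MARGIN + LOCUS_SPAN)
  if (length(stage_labels) < 2L) stopf("need at least 2 stages")
  if (cfg$n_replicates < 1L || cfg$probes_per_strand < 1L)
    stopf("n_replicates and probes_per_strand must be >= 1")
  req <- c("coding_exon", "uce_expressed", "random_background")
  if (!all(req %in% names(coverage_means)))
    stopf("coverage_means must define %s", paste(req, collapse = ", "))
  if (any(coverage_means < 0)) stopf("coverage means must be nonnegative")
  if (!setequal(names(flank_ext_probs),
                c("both", "upstream_only", "downstream_only", "none")) ||
      abs(sum(flank_ext_probs) - 1) > 1e-9)
    stopf("flank_ext_probs must be a distribution over both/upstream_only/downstream_only/none")
  structure(cfg, class = "sim_config")
}

# Largest-remainder rounding of n * fractions to integers summing to n.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the synthetic genome: annotation, UCE intervals, planted truth
#'
#' Places UCEs in constructed genomic contexts realizing `context_mix`
#' exactly (largest-remainder rounding), builds the annotation layers, and
#' draws the planted truth: per-strand stage expression sets, strand status,
#' constitutive flags, enhancer activity, host-gene expression, and flank
#' transcript extension.
#'
#' @param cfg A [sim_config()].
#' @return A list with `annotation` ([annotation_set()]), `uces` (interval
#'   table with `name` = UCE id), and `truth` (class `sim_truth`: a per-UCE
#'   data.frame plus `expr_plus`/`expr_minus` stage matrices).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  S <- length(cfg$stage_labels)
  cap_per_chrom <- floor((cfg$chrom_length - 2 * LOCUS_MARGIN) / LOCUS_SPAN)
  if (cfg$n_uces > cap_per_chrom * cfg$n_chromosomes)
    stopf("genome too small to place %d UCE loci (capacity %d)",
          cfg$n_uces, cap_per_chrom * cfg$n_chromosomes)
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                 paste0("chr", seq_len(cfg$n_chromosomes)))
  with_seed(cfg$seed, {
    n <- cfg$n_uces
    pp <- cfg$probes_per_strand
    ctx_names <- c("exonic", "possibly_exonic", "intronic", "non_exonic")
    counts <- apportion(n, cfg$context_mix[ctx_names])
    context <- if (n > 0) sample(rep(ctx_names, counts)) else character()

    idx <- seq_len(n)
    chrom_i <- ((idx - 1L) %% cfg$n_chromosomes) + 1L
    slot <- (idx - 1L) %/% cfg$n_chromosomes
    locus_start <- LOCUS_MARGIN + slot * LOCUS_SPAN
    u_start <- locus_start + UCE_OFFSET
    u_end <- u_start + cfg$uce_length
    uce_id <- sprintf("uce_%04d", idx)
    chrom <- names(chrom_sizes)[chrom_i]

    uces <- genomic_intervals(chrom, u_start, u_end, strand = ".",
                              name = uce_id)

    # annotation layers realized per context class
    genic <- context %in% c("exonic", "intronic")
    gene_strand <- ifelse(idx %% 2L == 0L, "+", "-")
    exon_rows <- list(); body_rows <- list(); est_rows <- list()
    if (any(genic)) {
      g <- which(genic)
      body_rows$host <- genomic_intervals(
        chrom[g], u_start[g] - 1500, u_end[g] + 1500,
        strand = gene_strand[g], name = paste0("gene_", uce_id[g]))
      # terminal exons (outside UCE and its 500-bp flanks)
      exon_rows$term5 <- genomic_intervals(
        chrom[g], u_start[g] - 1500, u_start[g] - 1350,
        strand = gene_strand[g], name = paste0("gene_", uce_id[g]))
      exon_rows$term3 <- genomic_intervals(
        chrom[g], u_end[g] + 1350, u_end[g] + 1500,
        strand = gene_strand[g], name = paste0("gene_", uce_id[g]))
    }
    ex <- which(context == "exonic")
    if (length(ex) > 0)
      exon_rows$overlap <- genomic_intervals(
        chrom[ex], u_start[ex] - 50, u_end[ex] + 50,
        strand = gene_strand[ex], name = paste0("gene_", uce_id[ex]))
    pe <- which(context == "possibly_exonic")
    if (length(pe) > 0)
      est_rows$uce <- genomic_intervals(
        chrom[pe], u_start[pe] - 100, u_end[pe] + 100, strand = ".",
        name = paste0("est_", uce_id[pe]))

    # decoy features in each locus tail (offsets 6000..7200 within locus,
    # clear of the UCE, its flanks, and the host gene)
    decoy <- function(p, off, len) {
      keep <- stats::runif(n) < p
      if (!any(keep)) return(empty_intervals())
      genomic_intervals(chrom[keep], locus_start[keep] + off,
                        locus_start[keep] + off + len)
    }
    repeats <- decoy(0.5, 6000L, 300L)
    dna_keep <- stats::runif(n) < 0.5
    dna_aligns <- if (any(dna_keep)) {
      genomic_intervals(chrom[dna_keep], locus_start[dna_keep] + 6350L,
                        locus_start[dna_keep] + 6550L,
                        score = stats::runif(sum(dna_keep), 40, 100))
    } else {
      df <- empty_intervals(); df$score <- numeric(); df
    }
    prot_aligns <- decoy(0.3, 6600L, 150L)
    ngaps <- decoy(0.2, 6800L, 100L)
    est_rows$decoy <- decoy(0.3, 6950L, 250L)

    bind <- function(lst) {
      lst <- Filter(function(x) nrow(x) > 0, lst)
      if (length(lst) == 0) return(empty_intervals())
      cols <- unique(unlist(lapply(lst, names)))
      lst <- lapply(lst, function(df) {
        for (cn in setdiff(cols, names(df)))
          df[[cn]] <- if (cn == "score") NA_real_ else NA_character_
        df[cols]
      })
      do.call(rbind, unname(lst))
    }
    ann <- annotation_set(
      known_exons = bind(exon_rows), gene_bodies = bind(body_rows),
      predictions_ests = bind(est_rows), repeats = repeats,
      dna_align_features = dna_aligns, protein_align_features = prot_aligns,
      n_gaps = ngaps, chrom_sizes = chrom_sizes)

    # ---- planted truth -------------------------------------------------
    expressed <- stats::runif(n) < cfg$frac_expressed
    strand_status <- rep("none", n)
    if (any(expressed)) {
      e <- which(expressed)
      both <- stats::runif(length(e)) < cfg$frac_both_strands
      single <- ifelse(stats::runif(length(e)) < 0.5, "plus", "minus")
      strand_status[e] <- ifelse(both, "both", single)
    }
    constitutive <- expressed &
      stats::runif(n) < cfg$frac_constitutive_of_expressed

    gene_expressed <- genic & stats::runif(n) < cfg$exon_expressed_prob
    flank_status <- rep("none", n)
    if (any(expressed))
      flank_status[expressed] <- sample(
        names(cfg$flank_ext_probs), sum(expressed), replace = TRUE,
        prob = cfg$flank_ext_probs)
    n_flanks <- (flank_status %in% c("both", "upstream_only")) +
      (flank_status %in% c("both", "downstream_only"))

    # Stage subsets for non-constitutive expressed UCEs are assigned in a
    # per-stage load-balanced way: subset sizes are random (1..S-1) but the
    # stages are chosen (greedily, weighted by the probe count the UCE
    # strand contributes) to keep the per-stage count of expressed probes
    # nearly constant, as observed in real developmental series.
    stage_load <- rep(0, S)
    draw_subset <- function(weight, must_include = integer()) {
      k <- sample(S - 1L, 1L)
      pick <- must_include
      while (length(pick) < k) {
        rest <- setdiff(seq_len(S), pick)
        lo <- rest[stage_load[rest] == min(stage_load[rest])]
        pick <- c(pick, if (length(lo) > 1L) sample(lo, 1L) else lo)
      }
      on <- seq_len(S) %in% pick
      stage_load <<- stage_load + on * weight
      on
    }
    expr_plus <- matrix(FALSE, n, S,
                        dimnames = list(uce_id, cfg$stage_labels))
    expr_minus <- expr_plus
    for (i in which(expressed)) {
      act_plus <- strand_status[i] %in% c("plus", "both")
      act_minus <- strand_status[i] %in% c("minus", "both")
      w <- pp * (1 + n_flanks[i])  # uce + covered flank probes per strand
      if (constitutive[i]) {
        if (act_plus) expr_plus[i, ] <- TRUE
        if (act_minus) expr_minus[i, ] <- TRUE
      } else {
        p_on <- if (act_plus) draw_subset(w) else rep(FALSE, S)
        m_on <- if (act_minus) {
          # both-strand transcripts share at least one stage
          if (act_plus) {
            shared <- which(p_on)
            draw_subset(w, must_include = shared[sample.int(length(shared), 1L)])
          } else draw_subset(w)
        } else rep(FALSE, S)
        expr_plus[i, ] <- p_on
        expr_minus[i, ] <- m_on
      }
    }
    enhancer <- stats::runif(n) < cfg$enhancer_frac
    es_expressed <- if (n > 0) expr_plus[, 1L] | expr_minus[, 1L] else logical()

    truth <- structure(list(
      uce = data.frame(uce_id = uce_id, chrom = chrom, start = u_start,
                       end = u_end, context = context,
                       gene_strand = ifelse(genic, gene_strand, NA_character_),
                       expressed = expressed, strand_status = strand_status,
                       constitutive = constitutive,
                       gene_expressed = gene_expressed,
                       flank_status = flank_status, enhancer = enhancer,
                       es_expressed = es_expressed,
                       coverage_class = ifelse(es_expressed, "uce_expressed",
                                               "random_background"),
                       stringsAsFactors = FALSE),
      expr_plus = expr_plus, expr_minus = expr_minus,
      stage_labels = cfg$stage_labels), class = "sim_truth")

    list(annotation = ann, uces = uces, truth = truth)
  })
}

#' Generate probe metadata and the raw intensity matrix
#'
#' Designs the synthetic array (per-strand UCE probes, flank probes on both
#' strands, exon probes for genic UCEs, and ~8% negative-control probes) and
#' draws log-normal intensities: expressed probe-cells are shifted by
#' `signal_effect * noise_sd` on the log scale, each array gets a
#' multiplicative scale jitter (so normalization is genuinely exercised),
#' and noise SD is `noise_sd` for background cells and `noise_sd_expressed`
#' for expressed cells.
#'
#' @param truth A `sim_truth` from [generate_genome()].
#' @param cfg The matching [sim_config()].
#' @return A list with `meta` (probe metadata data.frame) and `values`
#'   (probe x array intensity matrix, arrays named `STAGE_repN`).
#' @export
generate_probe_matrix <- function(truth, cfg) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  tu <- truth$uce
  n <- nrow(tu)
  pp <- cfg$probes_per_strand
  S <- length(cfg$stage_labels)

  mk <- function(target, strand, role, j) {
    data.frame(probe_id = sprintf("%s_%s_%s%d", target,
                                  gsub("flank_", "f", role),
                                  ifelse(strand == "+", "p",
                                         ifelse(strand == "-", "m", "x")), j),
               target_id = target, strand = strand, role = role,
               stringsAsFactors = FALSE)
  }
  blocks <- list()
  for (st in c("+", "-")) for (j in seq_len(pp)) {
    blocks[[paste0("u", st, j)]] <- mk(tu$uce_id, st, "uce", j)
    blocks[[paste0("fu", st, j)]] <- mk(tu$uce_id, st, "flank_up", j)
    blocks[[paste0("fd", st, j)]] <- mk(tu$uce_id, st, "flank_down", j)
  }
  genic <- which(!is.na(tu$gene_strand))
  for (j in seq_len(pp)) {
    if (length(genic) > 0)
      blocks[[paste0("e", j)]] <- mk(tu$uce_id[genic], tu$gene_strand[genic],
                                     "exon", j)
  }
  meta <- do.call(rbind, unname(blocks))
  n_neg <- max(2L, ceiling(0.08 * max(1L, nrow(meta))))
  meta <- rbind(meta, data.frame(
    probe_id = sprintf("neg_%04d", seq_len(n_neg)),
    target_id = "negative_control", strand = ".", role = "negative_control",
    stringsAsFactors = FALSE))
  rownames(meta) <- NULL

  arrays <- as.vector(t(outer(cfg$stage_labels, seq_len(cfg$n_replicates),
                              function(s, r) sprintf("%s_rep%d", s, r))))
  stage_of_array <- rep(cfg$stage_labels, each = cfg$n_replicates)

  # per-probe, per-stage expression indicator
  expr_stage <- matrix(FALSE, nrow(meta), S,
                       dimnames = list(meta$probe_id, cfg$stage_labels))
  row_of <- match(meta$target_id, tu$uce_id)
  for (s in seq_len(S)) {
    on_p <- truth$expr_plus[, s]; on_m <- truth$expr_minus[, s]
    is_uce <- meta$role == "uce"
    expr_stage[is_uce, s] <-
      ifelse(meta$strand[is_uce] == "+", on_p[row_of[is_uce]],
             on_m[row_of[is_uce]])
    for (fr in c("flank_up", "flank_down")) {
      is_f <- meta$role == fr
      covered <- tu$flank_status[row_of[is_f]] %in%
        c("both", if (fr == "flank_up") "upstream_only" else "downstream_only")
      strand_on <- ifelse(meta$strand[is_f] == "+", on_p[row_of[is_f]],
                          on_m[row_of[is_f]])
      expr_stage[is_f, s] <- covered & strand_on
    }
    is_e <- meta$role == "exon"
    expr_stage[is_e, s] <- tu$gene_expressed[row_of[is_e]]
  }
  expr_stage[is.na(expr_stage)] <- FALSE

  with_seed(cfg$seed + 1L, {
    E <- expr_stage[, stage_of_array, drop = FALSE]
    affinity <- stats::rnorm(nrow(meta), 0, cfg$probe_affinity_sd)
    mu <- cfg$baseline_log_signal + cfg$signal_effect * cfg$noise_sd * E +
      affinity
    sds <- ifelse(E, cfg$noise_sd_expressed, cfg$noise_sd)
    jitter <- stats::rnorm(length(arrays), 0, cfg$array_scale_sd)
    noise <- matrix(stats::rnorm(length(mu)), nrow(mu)) * sds
    values <- exp(sweep(mu + noise, 2, jitter, `+`))
    dimnames(values) <- list(meta$probe_id, arrays)
    list(meta = meta, values = values)
  })
}

#' Generate an RNA-Seq style coverage track
#'
#' Per-base Poisson coverage over the whole synthetic genome:
#' `random_background` mean everywhere, `coding_exon` mean over known
#' exons, and `uce_expressed` mean over ES-transcribed UCEs plus the
#' 500-bp flanks their transcripts extend into (per planted flank status).
#'
#' @param truth A `sim_truth`.
#' @param annotation The matching [annotation_set()].
#' @param cfg The matching [sim_config()].
#' @param flank_window Flank width in bp (default 500).
#' @return A [coverage_track()] (zero-depth runs omitted) with a
#'   `chrom_sizes` attribute.
#' @export
generate_coverage <- function(truth, annotation, cfg, flank_window = 500L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  cm <- cfg$coverage_means
  if (any(cm < 0)) stopf("coverage means must be nonnegative")
  sizes <- annotation$chrom_sizes
  tu <- truth$uce
  with_seed(cfg$seed + 2L, {
    out <- vector("list", length(sizes))
    for (ci in seq_along(sizes)) {
      chrom <- names(sizes)[ci]
      len <- as.integer(sizes[ci])
      depth <- stats::rpois(len, cm[["random_background"]])
      paint <- function(s, e, mean_depth) {
        s <- max(0L, as.integer(s)); e <- min(len, as.integer(e))
        if (e > s) depth[(s + 1L):e] <<- stats::rpois(e - s, mean_depth)
      }
      ke <- annotation$known_exons
      ke <- ke[ke$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(ke))) paint(ke$start[i], ke$end[i],
                                         cm[["coding_exon"]])
      on <- which(tu$chrom == chrom & tu$es_expressed)
      for (i in on) {
        paint(tu$start[i], tu$end[i], cm[["uce_expressed"]])
        if (tu$flank_status[i] %in% c("both", "upstream_only"))
          paint(tu$start[i] - flank_window, tu$start[i], cm[["uce_expressed"]])
        if (tu$flank_status[i] %in% c("both", "downstream_only"))
          paint(tu$end[i], tu$end[i] + flank_window, cm[["uce_expressed"]])
      }
      r <- rle(depth)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0
      if (any(keep))
        out[[ci]] <- data.frame(chrom = chrom, start = starts[keep],
                                end = ends[keep], depth = r$values[keep],
                                stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    df <- if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 depth = numeric())
    tr <- coverage_track(df$chrom, df$start, df$end, df$depth)
    attr(tr, "chrom_sizes") <- sizes
    tr
  })
}

#' Generate external call sets (enhancer assay, human expression)
#'
#' The enhancer set copies planted enhancer activity for a tested subset of
#' UCEs; the human expression set agrees with true mouse transcription with
#' probability `concordance_human` (flipped otherwise) on its own tested
#' subset. Untested UCEs are reported `not_tested`.
#'
#' @param truth A `sim_truth`.
#' @param cfg The matching [sim_config()].
#' @return A list of two data.frames, `enhancer` (`uce_id`, `status` in
#'   positive/negative/not_tested) and `human` (`uce_id`, `status` in
#'   expressed/not_expressed/not_tested).
#' @export
generate_external_calls <- function(truth, cfg) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  tu <- truth$uce
  n <- nrow(tu)
  with_seed(cfg$seed + 3L, {
    enh_tested <- stats::runif(n) < cfg$enhancer_tested_frac
    enh_status <- ifelse(!enh_tested, "not_tested",
                         ifelse(tu$enhancer, "positive", "negative"))
    hum_tested <- stats::runif(n) < cfg$human_tested_frac
    agree <- stats::runif(n) < cfg$concordance_human
    hum_expr <- ifelse(agree, tu$expressed, !tu$expressed)
    hum_status <- ifelse(!hum_tested, "not_tested",
                         ifelse(hum_expr, "expressed", "not_expressed"))
    list(enhancer = data.frame(uce_id = tu$uce_id, status = enh_status,
                               stringsAsFactors = FALSE),
         human = data.frame(uce_id = tu$uce_id, status = hum_status,
                            stringsAsFactors = FALSE))
  })
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper running all generator stages from one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list: `annotation`, `uces`, `truth`, `probes` (meta + values),
#'   `coverage`, `external` (enhancer + human call tables), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  g <- generate_genome(cfg)
  probes <- generate_probe_matrix(g$truth, cfg)
  coverage <- generate_coverage(g$truth, g$annotation, cfg)
  external <- generate_external_calls(g$truth, cfg)
  list(annotation = g$annotation, uces = g$uces, truth = g$truth,
       probes = probes, coverage = coverage, external = external,
       config = cfg)
}
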
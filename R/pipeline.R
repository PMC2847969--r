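# End-to-end orchestration: simulate inputs, write/read them through the
# format boundary, run calling -> stability -> context -> coverage ->
# integration, and emit a deterministic output set plus a run manifest.

#' Pipeline configuration
#'
#' Validates and assembles the options of a full pipeline run. Unknown keys
#' are rejected.
#'
#' @param sim A [sim_config()] or a list of its arguments.
#' @param calling A [calling_config()] or argument list.
#' @param stability A [stability_config()] or argument list.
#' @param cutoff_percentile Background percentile for the RNA-Seq
#'   expression cutoff (default 95).
#' @param flank_window Flanking window in bp (default 500).
#' @param n_background_per_uce Random background regions per UCE length
#'   (default 3).
#' @param n_resamples Resamples for the class Z tests (default 10000).
#' @param seed Master seed; overrides `sim$seed` when given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), calling = list(), stability = list(),
                            cutoff_percentile = 95, flank_window = 500L,
                            n_background_per_uce = 3L, n_resamples = 10000L,
                            seed = NULL) {
  as_cfg <- function(x, ctor, class) {
    if (inherits(x, class)) return(x)
    if (!is.list(x)) stopf("expected a list or %s", class)
    do.call(ctor, x)
  }
  if (!is.null(seed)) sim$seed <- seed
  cfg <- list(sim = as_cfg(sim, sim_config, "sim_config"),
              calling = as_cfg(calling, calling_config, "calling_config"),
              stability = as_cfg(stability, stability_config, "stability_config"),
              cutoff_percentile = cutoff_percentile,
              flank_window = as.integer(flank_window),
              n_background_per_uce = as.integer(n_background_per_uce),
              n_resamples = as.integer(n_resamples))
  if (cfg$cutoff_percentile <= 0 || cfg$cutoff_percentile > 100)
    stopf("cutoff_percentile must be in (0, 100]")
  if (cfg$flank_window <= 0) stopf("flank_window must be positive")
  if (cfg$n_background_per_uce < 1L) stopf("n_background_per_uce must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The file may define `sim`, `calling`, `stability` blocks and the scalar
#' options of [pipeline_config()]; unknown keys are rejected before any
#' computation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$sim$context_mix)) raw$sim$context_mix <- unlist(raw$sim$context_mix)
  if (!is.null(raw$sim$coverage_means)) raw$sim$coverage_means <- unlist(raw$sim$coverage_means)
  if (!is.null(raw$sim$flank_ext_probs)) raw$sim$flank_ext_probs <- unlist(raw$sim$flank_ext_probs)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline on synthetic data
#'
#' Generates the synthetic dataset, writes all inputs to disk in their
#' native formats (BED, GFF3, wiggle, TSV), reads them back through the
#' format boundary, then runs expression calling, stability
#' classification, context classification and enrichment, background
#' sampling, coverage analysis (cutoff, RNA-Seq calls, class comparison,
#' flanking, coverage fraction, distances), and integration. Outputs and a
#' JSON manifest (with a config hash and the seed) are written to
#' `outdir`; identical config + seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of all in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("ucetx_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  indir <- file.path(outdir, "inputs")
  dir.create(indir, showWarnings = FALSE)
  cfg <- config$sim

  # ---- simulate and serialize inputs ----------------------------------
  ds <- simulate_dataset(cfg)
  write_bed(ds$uces, file.path(indir, "uces.bed"))
  write_chrom_sizes(ds$annotation$chrom_sizes, file.path(indir, "chrom.sizes"))
  write_gff3_genes(ds$annotation$gene_bodies, ds$annotation$known_exons,
                   file.path(indir, "genes.gff3"))
  for (ly in c("predictions_ests", "repeats", "dna_align_features",
               "protein_align_features", "n_gaps"))
    write_bed(ds$annotation[[ly]], file.path(indir, paste0(ly, ".bed")))
  write_wiggle(ds$coverage, file.path(indir, "coverage.wig"))
  write_intensity_table(ds$probes$meta, ds$probes$values,
                        file.path(indir, "intensities.tsv"))
  write_tsv(ds$external$enhancer, file.path(indir, "enhancer_calls.tsv"))
  write_tsv(ds$external$human, file.path(indir, "human_calls.tsv"))

  # ---- read back through the format boundary --------------------------
  uces <- read_bed(file.path(indir, "uces.bed"))
  chrom_sizes <- read_chrom_sizes(file.path(indir, "chrom.sizes"))
  genes <- read_gff3_genes(file.path(indir, "genes.gff3"))
  ann <- annotation_set(
    known_exons = genes$known_exons, gene_bodies = genes$gene_bodies,
    predictions_ests = read_bed(file.path(indir, "predictions_ests.bed")),
    repeats = read_bed(file.path(indir, "repeats.bed")),
    dna_align_features = read_bed(file.path(indir, "dna_align_features.bed")),
    protein_align_features = read_bed(file.path(indir, "protein_align_features.bed")),
    n_gaps = read_bed(file.path(indir, "n_gaps.bed")),
    chrom_sizes = chrom_sizes)
  probes <- read_intensity_table(file.path(indir, "intensities.tsv"))
  track <- read_wiggle(file.path(indir, "coverage.wig"))
  attr(track, "chrom_sizes") <- chrom_sizes
  enhancer <- read_tsv(file.path(indir, "enhancer_calls.tsv"))
  human <- read_tsv(file.path(indir, "human_calls.tsv"))

  # ---- microarray calling + stability ---------------------------------
  norm <- quantile_normalize(probes$values)
  calls <- call_expression(norm, probes$meta, config$calling)
  profile <- expression_profile(calls, cfg$stage_labels)
  stability <- stability_summary(norm, probes$meta, profile,
                                 attr(calls, "thresholds"), config$stability)

  # ---- genomic context ------------------------------------------------
  contexts <- classify_context(uces, ann)
  transcribed_ids <- profile$uce_id[profile$any_stage]
  enrich <- if (length(transcribed_ids) > 0 &&
                length(transcribed_ids) < nrow(uces)) {
    context_enrichment(transcribed_ids, uces$name, contexts)
  } else NULL
  dists <- nearest_neighbor_distances(uces)
  trans <- uces$name %in% transcribed_ids
  dist_cmp <- if (any(trans) && any(!trans))
    compare_distance_distributions(dists[trans], dists[!trans]) else NULL

  # ---- coverage -------------------------------------------------------
  backgrounds <- select_random_regions(
    ann, chrom_sizes, lengths = uces$end - uces$start,
    n_per = config$n_background_per_uce, seed = cfg$seed + 10L, uces = uces)
  bg_levels <- region_mean_coverage(backgrounds, track)
  cutoff <- expression_cutoff(bg_levels, config$cutoff_percentile)
  uce_levels <- region_mean_coverage(uces, track)
  rnaseq_calls <- data.frame(uce_id = uces$name,
                             expressed = call_rnaseq_expressed(uce_levels, cutoff),
                             stringsAsFactors = FALSE)
  exons_clear <- ds$annotation$known_exons[
    !overlaps_any(ds$annotation$known_exons, uces), , drop = FALSE]
  class_cmp <- class_expression_comparison(
    list(uce = uce_levels, coding_exon = region_mean_coverage(exons_clear, track),
         random_background = bg_levels),
    reference_class = "random_background", n_samples = config$n_resamples,
    seed = cfg$seed + 11L)
  flanks <- data.frame(uce_id = uces$name,
                       status = flanking_status(uces, track, cutoff,
                                                config$flank_window,
                                                chrom_sizes),
                       stringsAsFactors = FALSE)
  covered_frac <- region_coverage_fraction(uces, track)

  # ---- integration ----------------------------------------------------
  table <- build_integration_table(
    uce_ids = uces$name, contexts = contexts, profile = profile,
    stability = stability, rnaseq = rnaseq_calls, enhancer = enhancer,
    human = human, flanking = flanks)
  summary <- overlap_summary(table)

  # ---- outputs --------------------------------------------------------
  write_tsv(calls, file.path(outdir, "strand_calls.tsv"))
  write_tsv(profile, file.path(outdir, "expression_profile.tsv"))
  write_tsv(stability, file.path(outdir, "stability.tsv"))
  write_tsv(data.frame(uce_id = names(contexts), context = unname(contexts)),
            file.path(outdir, "contexts.tsv"))
  if (!is.null(enrich)) write_tsv(enrich, file.path(outdir, "context_enrichment.tsv"))
  write_bed(backgrounds, file.path(outdir, "random_regions.bed"))
  write_tsv(data.frame(uce_id = uces$name, distance = dists),
            file.path(outdir, "distances.tsv"))
  write_tsv(data.frame(uce_id = uces$name, mean_depth = uce_levels,
                       covered_fraction = covered_frac,
                       expressed = rnaseq_calls$expressed),
            file.path(outdir, "region_expression.tsv"))
  write_tsv(table, file.path(outdir, "integration.tsv"))
  cfg_json <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_uces = nrow(uces), cutoff = cutoff,
                   outputs = c("strand_calls.tsv", "expression_profile.tsv",
                               "stability.tsv", "contexts.tsv",
                               "random_regions.bed", "distances.tsv",
                               "region_expression.tsv", "integration.tsv"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "manifest.json"))

  invisible(list(dataset = ds, calls = calls, profile = profile,
                 stability = stability, contexts = contexts,
                 enrichment = enrich, distances = dists,
                 distance_comparison = dist_cmp, backgrounds = backgrounds,
                 cutoff = cutoff, rnaseq_calls = rnaseq_calls,
                 class_comparison = class_cmp, flanks = flanks,
                 covered_fraction = covered_frac, table = table,
                 summary = summary, outdir = outdir))
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}
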
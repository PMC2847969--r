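toy_ann <- function() {
  annotation_set(
    known_exons = genomic_intervals("chr1", 1000, 1200),
    gene_bodies = genomic_intervals("chr1", c(800, 5000), c(2000, 8000)),
    predictions_ests = genomic_intervals("chr1", 3000, 3400),
    chrom_sizes = c(chr1 = 1e5, chr2 = 1e5))
}

test_that("classify_context applies the single-nucleotide precedence rule", {
  ann <- toy_ann()
  # 1 bp overlap with the exon at its right edge
  expect_equal(unname(classify_context(
    genomic_intervals("chr1", 1199, 1399), ann)), "exonic")
  # inside gene body, no exon/EST overlap
  expect_equal(unname(classify_context(
    genomic_intervals("chr1", 1500, 1700), ann)), "intronic")
  # EST overlap wins over gene body absence
  expect_equal(unname(classify_context(
    genomic_intervals("chr1", 3399, 3600), ann)), "possibly_exonic")
  expect_equal(unname(classify_context(
    genomic_intervals("chr1", 50000, 50200), ann)), "non_exonic")
  expect_error(classify_context(genomic_intervals("chrX", 0, 200), ann),
               "unannotated")
})

test_that("adding an exon overlap only moves a UCE toward exonic", {
  ann <- toy_ann()
  uces <- genomic_intervals("chr1", c(1500, 3399, 50000),
                            c(1700, 3600, 50200))
  before <- classify_context(uces, ann)
  ann2 <- ann
  ann2$known_exons <- rbind(ann$known_exons,
                            genomic_intervals("chr1", c(1600, 3500, 50100),
                                              c(1620, 3520, 50120)))
  after <- classify_context(uces, ann2)
  expect_true(all(after == "exonic"))
  expect_false(any(before == "exonic"))
})

test_that("context_enrichment reproduces the toy Fisher table", {
  universe <- sprintf("u%d", 1:8)
  contexts <- setNames(rep(c("exonic", "intronic"), each = 4), universe)
  subset <- c("u1", "u2", "u3", "u5")  # 3 of 4 exonic
  res <- context_enrichment(subset, universe, contexts)
  exon_row <- res[res$class == "exonic", ]
  expect_equal(exon_row$p, 34 / 70, tolerance = 1e-6)
  # classes absent from the universe are degenerate with p = 1
  expect_equal(res$p[res$class == "possibly_exonic"], 1)
  expect_equal(res$p_hochberg, hochberg_adjust(res$p))
  expect_error(context_enrichment(character(), universe, contexts), "empty")
  expect_error(context_enrichment(universe, universe, contexts), "strict")
})

test_that("a proportional subset shows no enrichment", {
  universe <- sprintf("u%d", 1:40)
  contexts <- setNames(rep(c("exonic", "possibly_exonic", "intronic",
                             "non_exonic"), each = 10), universe)
  subset <- universe[c(1:5, 11:15, 21:25, 31:35)]
  res <- context_enrichment(subset, universe, contexts)
  expect_true(all(res$p > 0.5))
})

test_that("select_random_regions respects filters, lengths and determinism", {
  sizes <- c(chr1 = 1e5, chr2 = 1e5)
  empty <- annotation_set(chrom_sizes = sizes)
  rr <- select_random_regions(empty, sizes, lengths = 200, n_per = 3,
                              seed = 41)
  expect_equal(nrow(rr), 3)
  expect_true(all(rr$end - rr$start == 200))
  # pairwise disjoint
  ord <- order(rr$chrom, rr$start)
  same <- rr$chrom[ord][-1] == rr$chrom[ord][-3]
  expect_true(all(!same | rr$start[ord][-1] >= rr$end[ord][-3]))
  rr2 <- select_random_regions(empty, sizes, lengths = 200, n_per = 3,
                               seed = 41)
  expect_identical(rr, rr2)
  masked <- annotation_set(repeats = genomic_intervals("chr1", 0, 1e5),
                           chrom_sizes = c(chr1 = 1e5))
  expect_error(select_random_regions(masked, c(chr1 = 1e5), lengths = 200,
                                     n_per = 1, seed = 1,
                                     max_attempts = 200), "attempts")
})

test_that("sampled regions avoid every excluded layer on a synthetic genome", {
  cfg <- small_cfg(seed = 42, n_uces = 40)
  g <- generate_genome(cfg)
  lens <- g$uces$end - g$uces$start
  rr <- select_random_regions(g$annotation, lengths = lens, n_per = 3,
                              seed = 43, uces = g$uces)
  expect_equal(nrow(rr), length(lens) * 3)
  expect_equal(sort(rep(lens, 3)), sort(rr$end - rr$start))
  ann <- g$annotation
  daf_hi <- ann$dna_align_features[ann$dna_align_features$score > 75, ,
                                   drop = FALSE]
  for (layer in list(ann$known_exons, ann$predictions_ests, ann$repeats,
                     ann$protein_align_features, ann$n_gaps, daf_hi, g$uces))
    expect_equal(sum(overlaps_any(rr, layer)), 0)
  # low-scoring DNA alignments are allowed, so they are not excluded per se
  expect_true(all(rr$start >= 0 & rr$end <= cfg$chrom_length))
})

test_that("nearest_neighbor_distances computes same-chromosome gaps", {
  uces <- genomic_intervals("chr1", c(0, 1000, 5000), c(200, 1200, 5200))
  expect_equal(nearest_neighbor_distances(uces), c(800, 800, 3800))
  over <- genomic_intervals("chr1", c(0, 100), c(200, 300))
  expect_equal(nearest_neighbor_distances(over), c(0, 0))
  mixed <- genomic_intervals(c("chr1", "chr1", "chr2"), c(0, 500, 0),
                             c(200, 700, 200))
  d <- nearest_neighbor_distances(mixed)
  expect_equal(d[1:2], c(300, 300))
  expect_true(is.na(d[3]))
  expect_error(nearest_neighbor_distances(genomic_intervals("chr1", 0, 200)),
               "at least 2")
})

test_that("compare_distance_distributions reports direction and exact p", {
  same <- c(10, 20, 30)
  r <- compare_distance_distributions(same, same)
  expect_equal(r$test$p_value, 1)
  set.seed(44)
  big <- rexp(40, rate = 1 / 1e6); small <- rexp(40, rate = 1 / 1e5)
  r2 <- compare_distance_distributions(big, small)
  expect_lt(r2$test$p_value, 0.01)
  expect_equal(r2$direction, "transcribed_more_distant")
  r3 <- compare_distance_distributions(c(1, 2), c(3, 4))
  expect_equal(r3$test$method, "wilcoxon_exact")
  expect_equal(r3$test$p_value, 1 / 3, tolerance = 1e-9)
})
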
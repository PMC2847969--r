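test_that("sim_config validates fractions, mixes and sizes", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_expressed = 1.2), "out of")
  expect_error(sim_config(context_mix = c(exonic = 0.5, possibly_exonic = 0.5,
                                          intronic = 0.2, non_exonic = -0.2)),
               ">= 0")
  expect_error(sim_config(context_mix = c(exonic = 0.5, possibly_exonic = 0.2,
                                          intronic = 0.2, non_exonic = 0.2)),
               "sum to 1")
  expect_error(sim_config(uce_length = 150), "200")
})

test_that("generate_genome realizes the context mix exactly by construction", {
  cfg <- small_cfg(seed = 3, n_uces = 40,
                   context_mix = c(exonic = 0.25, possibly_exonic = 0.25,
                                   intronic = 0.25, non_exonic = 0.25))
  g <- generate_genome(cfg)
  planted <- table(g$truth$uce$context)
  expect_true(all(planted == 10))
  classified <- classify_context(g$uces, g$annotation)
  expect_identical(unname(classified[g$truth$uce$uce_id]),
                   g$truth$uce$context)
})

test_that("generate_genome handles the empty and over-capacity cases", {
  g0 <- generate_genome(small_cfg(n_uces = 0))
  expect_equal(nrow(g0$uces), 0)
  expect_s3_class(g0$annotation, "annotation_set")
  expect_error(generate_genome(small_cfg(n_uces = 5000)), "capacity")
})

test_that("the generator is deterministic given the seed", {
  a <- simulate_dataset(small_cfg(seed = 9, n_uces = 20))
  b <- simulate_dataset(small_cfg(seed = 9, n_uces = 20))
  expect_identical(a$uces, b$uces)
  expect_identical(a$truth$uce, b$truth$uce)
  expect_identical(a$probes$values, b$probes$values)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$external, b$external)
  c <- generate_genome(small_cfg(seed = 10, n_uces = 20))
  expect_false(identical(a$uces$start, c$uces$start) &&
                 identical(a$truth$uce$expressed, c$truth$uce$expressed))
})

test_that("probe design has the expected structure", {
  cfg <- small_cfg(seed = 4, n_uces = 30)
  g <- generate_genome(cfg)
  pm <- generate_probe_matrix(g$truth, cfg)
  meta <- pm$meta
  expect_gte(sum(meta$role == "uce"), 30 * 2 * 3)
  expect_equal(ncol(pm$values), 4 * 3)
  expect_gte(mean(meta$role == "negative_control"), 0.05)
  expect_true(all(meta$strand[meta$role == "negative_control"] == "."))
  per_strand <- table(meta$target_id[meta$role == "uce"],
                      meta$strand[meta$role == "uce"])
  expect_true(all(per_strand == cfg$probes_per_strand))
  expect_identical(meta$probe_id, rownames(pm$values))
})

test_that("coverage means are recovered per planted region class", {
  cfg <- small_cfg(seed = 5, n_uces = 40)
  g <- generate_genome(cfg)
  track <- generate_coverage(g$truth, g$annotation, cfg)
  tr <- g$truth$uce
  on <- which(tr$es_expressed)
  uce_on <- genomic_intervals(tr$chrom[on], tr$start[on], tr$end[on])
  expect_equal(mean(region_mean_coverage(uce_on, track)),
               cfg$coverage_means[["uce_expressed"]], tolerance = 0.1)
  # clean margin at each chromosome start is pure background
  margins <- genomic_intervals(names(g$annotation$chrom_sizes),
                               rep(0, 2), rep(4000, 2))
  expect_equal(mean(region_mean_coverage(margins, track)),
               cfg$coverage_means[["random_background"]], tolerance = 0.1)
  zero <- generate_coverage(
    g$truth, g$annotation,
    small_cfg(seed = 5, n_uces = 40,
              coverage_means = c(coding_exon = 0, uce_expressed = 0,
                                 random_background = 0)))
  expect_equal(nrow(zero), 0)
})

test_that("external call sets follow the planted concordance model", {
  cfg <- small_cfg(seed = 6, n_uces = 40, concordance_human = 1,
                   human_tested_frac = 1)
  g <- generate_genome(cfg)
  ext <- generate_external_calls(g$truth, cfg)
  expect_identical(ext$human$status == "expressed", g$truth$uce$expressed)
  cfg0 <- small_cfg(seed = 6, n_uces = 40, enhancer_frac = 0)
  g0 <- generate_genome(cfg0)
  ext0 <- generate_external_calls(g0$truth, cfg0)
  expect_false(any(ext0$enhancer$status == "positive"))
  cfg62 <- sim_config(n_uces = 300, seed = 8, concordance_human = 0.62,
                      human_tested_frac = 1)
  g62 <- generate_genome(cfg62)
  ext62 <- generate_external_calls(g62$truth, cfg62)
  agree <- (ext62$human$status == "expressed") == g62$truth$uce$expressed
  expect_equal(mean(agree), 0.62, tolerance = 0.08)
})

test_that("planted truth is internally consistent", {
  g <- generate_genome(small_cfg(seed = 7, n_uces = 60))
  tr <- g$truth$uce
  on_plus <- rowSums(g$truth$expr_plus) > 0
  on_minus <- rowSums(g$truth$expr_minus) > 0
  # both-strand UCEs transcribe both strands somewhere
  expect_true(all(on_plus[tr$strand_status == "both"] &
                    on_minus[tr$strand_status == "both"]))
  # constitutive implies all stages on every active strand
  all_plus <- rowSums(g$truth$expr_plus) == ncol(g$truth$expr_plus)
  expect_true(all(all_plus[tr$constitutive &
                             tr$strand_status %in% c("plus", "both")]))
  expect_true(all(!on_plus[tr$strand_status %in% c("none", "minus")]))
})
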
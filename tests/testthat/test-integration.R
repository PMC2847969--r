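toy_profile <- function(ids, any_on = TRUE) {
  data.frame(uce_id = ids,
             status_ES = ifelse(any_on, "single_plus", "none"),
             any_stage = any_on, all_stages = FALSE,
             strandedness = ifelse(any_on, "single_plus", "none"),
             stringsAsFactors = FALSE)
}

test_that("build_integration_table merges sources and marks missing ones", {
  ids <- c("u1", "u2", "u3")
  contexts <- setNames(c("exonic", "intronic", "non_exonic"), ids)
  tab <- build_integration_table(ids, contexts, toy_profile(ids))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$enhancer == "not_tested"))
  expect_true(all(tab$rnaseq_expressed == "not_assessed"))
  expect_true(all(tab$flanking == "not_assessable"))
  dup <- data.frame(uce_id = c("u1", "u1"), status = c("positive", "negative"))
  expect_error(build_integration_table(ids, contexts, toy_profile(ids),
                                       enhancer = dup), "duplicate")
  alien <- data.frame(uce_id = "u9", status = "positive")
  expect_error(build_integration_table(ids, contexts, toy_profile(ids),
                                       enhancer = alien), "unknown")
})

test_that("overlap_summary satisfies inclusion-exclusion and edge cases", {
  ids <- sprintf("u%02d", 1:40)
  contexts <- setNames(rep("non_exonic", 40), ids)
  prof <- toy_profile(ids, any_on = rep(c(TRUE, FALSE), 20))
  enh <- data.frame(uce_id = ids,
                    status = rep(c("positive", "negative"), each = 20))
  tab <- build_integration_table(ids, contexts, prof, enhancer = enh)
  s <- overlap_summary(tab)
  expect_equal(sum(s$subset_counts$count), s$n)
  expect_equal(sum(s$dual), 1)
  expect_equal(unname(s$dual["transcribed_and_enhancer"] +
                        s$dual["transcribed_only"]),
               s$transcribed_mouse_fraction)
  # no positive source at all
  none <- build_integration_table(ids, contexts, toy_profile(ids, FALSE))
  s0 <- overlap_summary(none)
  expect_equal(unname(s0$dual["neither"]), 1)
  expect_error(overlap_summary(tab, character()), "empty")
})

test_that("overlap_summary recovers an independent planted joint", {
  set.seed(61)
  n <- 400
  ids <- sprintf("u%03d", 1:n)
  contexts <- setNames(rep("intronic", n), ids)
  on <- runif(n) < 0.5
  enh_pos <- runif(n) < 0.5
  prof <- toy_profile(ids, any_on = on)
  enh <- data.frame(uce_id = ids,
                    status = ifelse(enh_pos, "positive", "negative"))
  tab <- build_integration_table(ids, contexts, prof, enhancer = enh)
  s <- overlap_summary(tab)
  expect_lt(abs(s$dual[["transcribed_and_enhancer"]] - 0.25), 0.05)
})

test_that("concordance reports agreement with its Wald interval", {
  ids <- sprintf("u%02d", 1:31)
  a <- setNames(rep(c(TRUE, FALSE), c(15, 16)), ids)
  b <- a
  b[14:26] <- !b[14:26]  # 13 disagreements -> 18/31 agreement
  r <- concordance(a, b, ids)
  expect_equal(length(r$agree_pos) + length(r$agree_neg), 18)
  expect_equal(r$fraction, 18 / 31, tolerance = 1e-12)
  expect_equal(unname(r$ci["low"]),
               18 / 31 - qnorm(0.975) * sqrt((18 / 31) * (13 / 31) / 31),
               tolerance = 1e-9)
  expect_equal(concordance(a, a, ids)$fraction, 1)
  expect_equal(concordance(a, !a, ids)$fraction, 0)
  expect_error(concordance(a[-1], b, ids), "missing")
})

test_that("term_enrichment applies the hypergeometric tail per term", {
  u2g <- data.frame(uce_id = sprintf("u%02d", 1:20),
                    gene = sprintf("g%02d", 1:20))
  g2t <- rbind(data.frame(gene = sprintf("g%02d", 1:5), term = "binding"),
               data.frame(gene = sprintf("g%02d", 1:20), term = "everything"))
  subset <- sprintf("u%02d", c(1:4, 11, 12))  # k=4 of K=5, n=6, N=20
  res <- term_enrichment(u2g, g2t, subset, u2g$uce_id)
  expect_equal(res$p[res$term == "binding"], 540 / 38760, tolerance = 1e-9)
  expect_equal(res$p[res$term == "everything"], 1)
  expect_equal(res$p_bh, bh_adjust(res$p))
  expect_error(term_enrichment(u2g, g2t, "u99", u2g$uce_id), "universe")
})

test_that("nearest_genes maps host genes and splits ties", {
  uces <- genomic_intervals("chr1", c(1000, 9000), c(1200, 9200),
                            name = c("u1", "u2"))
  genes <- genomic_intervals("chr1", c(800, 5000, 13000), c(2000, 5200, 13400),
                             name = c("gA", "gB", "gC"))
  r <- nearest_genes(uces, genes)
  expect_equal(r$gene[r$uce_id == "u1"], "gA")
  expect_equal(r$distance[r$uce_id == "u1"], 0)
  # u2 at 9000-9200: gap to gB = 3800, to gC = 3800 -> tie, both reported
  u2 <- r[r$uce_id == "u2", ]
  expect_setequal(u2$gene, c("gB", "gC"))
  expect_equal(u2$distance, c(3800, 3800))
})
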
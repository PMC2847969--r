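toy_matrix <- function(cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%d_rep1", seq_len(ncol(m)))
  m
}

test_that("quantile_normalize equalizes columns via rank-wise means", {
  m <- toy_matrix(list(c(1, 3, 5), c(2, 4, 8)))
  norm <- quantile_normalize(m)
  expect_equal(unname(norm[, 1]), c(1.5, 3.5, 6.5))
  expect_equal(unname(norm[, 2]), c(1.5, 3.5, 6.5))
  expect_identical(dimnames(norm), dimnames(m))
  same <- toy_matrix(list(c(2, 7, 4), c(2, 7, 4)))
  expect_equal(quantile_normalize(same), same)
  set.seed(21)
  big <- toy_matrix(list(rlnorm(50), rlnorm(50), rlnorm(50)))
  nb <- quantile_normalize(big)
  sorted <- apply(nb, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 3])
  expect_error(quantile_normalize(big[, 1, drop = FALSE]), "2 arrays")
})

test_that("array_thresholds computes percentile and negative-control floors", {
  vals <- matrix(c(1:100, 5, 5, 5), ncol = 1)
  rownames(vals) <- c(sprintf("s%d", 1:100), sprintf("n%d", 1:3))
  colnames(vals) <- "ES_rep1"
  meta <- data.frame(probe_id = rownames(vals),
                     target_id = c(rep("t", 100), rep("negative_control", 3)),
                     strand = c(rep("+", 100), rep(".", 3)),
                     role = c(rep("uce", 100), rep("negative_control", 3)))
  thr <- array_thresholds(vals, meta)
  expect_equal(thr$percentile_threshold, 90.1)
  expect_equal(thr$negative_threshold, 5)  # sd = 0
  meta2 <- meta; meta2$role[101:103] <- "uce"
  expect_error(array_thresholds(vals, meta2, calling_config()),
               "negative-control")
})

test_that("call_probe applies the 2-of-3 replicate rule with strict thresholds", {
  thr <- data.frame(percentile_threshold = rep(100, 3),
                    negative_threshold = rep(50, 3))
  expect_true(call_probe(c(150, 120, 90), thr))
  expect_false(call_probe(c(150, 90, 80), thr))
  expect_false(call_probe(c(100, 100, 100), thr))  # equality is not above
  expect_error(call_probe(c(150, 120), thr), "mismatch")
})

test_that("call_uce_stage derives strand status from probe calls", {
  k1 <- calling_config(min_probes_for_uce_call = 1)
  r <- call_uce_stage(list(plus = c(TRUE, FALSE, FALSE),
                           minus = rep(FALSE, 3)), k1)
  expect_equal(r$status, "single_plus")
  r2 <- call_uce_stage(list(plus = c(TRUE, FALSE, FALSE),
                            minus = c(FALSE, TRUE, FALSE)), k1)
  expect_equal(r2$status, "both")
  r3 <- call_uce_stage(list(plus = rep(FALSE, 3), minus = rep(FALSE, 3)), k1)
  expect_equal(r3$status, "none")
  expect_error(call_uce_stage(list(plus = logical(), minus = TRUE), k1),
               "empty probe set")
  k2 <- calling_config(min_probes_for_uce_call = 2)
  expect_equal(call_uce_stage(list(plus = c(TRUE, FALSE, FALSE),
                                   minus = rep(FALSE, 3)), k2)$status, "none")
})

test_that("expression_profile aggregates stages and strandedness", {
  stages <- c("ES", "E12.5")
  calls <- data.frame(
    uce_id = rep(c("u1", "u2", "u3"), times = 2),
    stage = rep(stages, each = 3),
    plus_called = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    minus_called = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  calls$status <- ifelse(calls$plus_called, "single_plus", "none")
  prof <- expression_profile(calls, stages)
  expect_equal(prof$any_stage, c(TRUE, TRUE, FALSE))
  expect_equal(prof$all_stages, c(FALSE, TRUE, FALSE))
  expect_equal(prof$strandedness, c("single_plus", "single_plus", "none"))
  expect_error(expression_profile(calls, c("ES", "E12.5", "E14.5")),
               "missing stage")
})

test_that("at most 10% of non-control probes exceed the percentile threshold", {
  rec <- calling_recovery(small_cfg(seed = 22, n_uces = 30))
  thr <- attr(rec$calls, "thresholds")
  meta <- rec$probes$meta
  nc <- meta$role[match(rownames(rec$norm), meta$probe_id)] != "negative_control"
  for (j in seq_len(ncol(rec$norm))) {
    frac_above <- mean(rec$norm[nc, j] > thr$percentile_threshold[j])
    expect_lte(frac_above, 0.10 + 1e-9)
  }
})

test_that("probe calls are monotone in intensity at fixed thresholds", {
  thr <- data.frame(percentile_threshold = rep(100, 3),
                    negative_threshold = rep(50, 3))
  set.seed(23)
  for (i in 1:50) {
    v <- runif(3, 0, 200)
    base <- call_probe(v, thr)
    bumped <- call_probe(v + c(50, 0, 0), thr)
    expect_true(!base || bumped)
  }
})
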
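test_that("fisher_exact matches exhaustive enumeration on worked examples", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               34 / 70, tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p_value,
               2 / 252, tolerance = 1e-6)
  expect_error(fisher_exact(matrix(0, 2, 2)), "zero margins")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("fisher_exact agrees with the enumeration oracle on random tables", {
  set.seed(11)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9, info = paste(tab, collapse = ","))
  }
})

test_that("hypergeometric_tail matches tail-sum oracle", {
  expect_equal(hypergeometric_tail(4, 5, 6, 20)$p_value, 540 / 38760,
               tolerance = 1e-9)
  expect_equal(hypergeometric_tail(0, 5, 6, 20)$p_value, 1.0)
  expect_equal(hypergeometric_tail(5, 5, 5, 5)$p_value, 1.0)
  expect_error(hypergeometric_tail(6, 5, 6, 20), "min")
  expect_error(hypergeometric_tail(1, 21, 6, 20), "exceed")
  set.seed(12)
  for (i in 1:100) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_tail(k, K, n, N)$p_value,
                 oracle_hyper_tail(k, K, n, N), tolerance = 1e-9)
  }
})

test_that("wilcoxon_rank_sum exact branch agrees with enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-9)
  v <- c(2.5, 7.1, 9.3)
  expect_equal(wilcoxon_rank_sum(v, v)$p_value, 1.0)
  expect_lt(wilcoxon_rank_sum(1:20, 31:50)$p_value, 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
  set.seed(13)
  for (i in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- round(runif(m, 0, 50), 3); y <- round(runif(n, 0, 50), 3)
    if (anyDuplicated(c(x, y))) next
    res <- wilcoxon_rank_sum(x, y)
    expect_equal(res$method, "wilcoxon_exact")
    expect_equal(res$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-9)
  }
})

test_that("hochberg and BH adjustments match hand oracles", {
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.03, 0.04, 0.04, 0.02), tolerance = 1e-12)
  expect_equal(hochberg_adjust(1.0), 1.0)
  expect_equal(hochberg_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:100) {
    p <- runif(sample(1:12, 1))
    expect_equal(hochberg_adjust(p), oracle_hochberg(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("adjustments never decrease p and preserve the raw ordering", {
  set.seed(15)
  for (i in 1:20) {
    p <- runif(10)
    for (f in list(hochberg_adjust, bh_adjust)) {
      adj <- f(p)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw p
      # constant vectors are fixed points (m * p / m at the top rank)
      expect_equal(f(rep(p[1], 6)), rep(p[1], 6), tolerance = 1e-12)
    }
  }
})

test_that("empirical_ztest is deterministic, directional, and validates input", {
  set.seed(16)
  ref <- rnorm(200)
  cls <- rnorm(30)
  a <- empirical_ztest(cls, ref, n_samples = 500, seed = 42)
  b <- empirical_ztest(cls, ref, n_samples = 500, seed = 42)
  expect_identical(a$statistic, b$statistic)
  expect_equal(a$n_resamples, 500L)
  shifted <- empirical_ztest(cls + 10, ref, n_samples = 1000, seed = 1)
  expect_lt(shifted$p_value, 1e-6)
  expect_gt(shifted$statistic, 0)
  expect_error(empirical_ztest(cls, ref, n_samples = 50, seed = 1), ">= 100")
  expect_error(empirical_ztest(cls, rep(2, 50), n_samples = 100, seed = 1),
               "degenerate")
})

test_that("empirical_ztest does not disturb the caller's RNG stream", {
  cls <- rnorm(10); ref <- rnorm(50)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(empirical_ztest(cls, ref, n_samples = 100, seed = 3))
  expect_identical(runif(1), before)
})

test_that("proportion_ci reproduces the Wald interval and clips at [0, 1]", {
  ci <- proportion_ci(12, 31)
  expect_equal(unname(ci["low"]), 0.2156, tolerance = 1e-3)
  expect_equal(unname(ci["high"]), 0.5586, tolerance = 1e-3)
  expect_equal(unname(proportion_ci(0, 10)["low"]), 0)
  expect_equal(unname(proportion_ci(10, 10)["high"]), 1)
  expect_error(proportion_ci(1, 0), "positive")
  expect_error(proportion_ci(5, 3), "exceed")
})
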
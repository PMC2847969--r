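# Statistical primitives shared by the whole pipeline. Standard tests are
# delegated to base R; the resampling Z test (the comparison used for
# coverage-class contrasts) and the Wald proportion interval are implemented
# here directly.

#' Construct a test result
#'
#' Uniform return container for the package's statistical tests.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param method Short method label.
#' @param n_resamples Number of resamples used (0 for exact/analytic tests).
#' @return A list of class `uce_test_result`.
#' @export
test_result <- function(statistic, p_value, method, n_resamples = 0L) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stopf("p_value must be in [0, 1]")
  if (n_resamples < 0) stopf("n_resamples must be nonnegative")
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n_resamples = as.integer(n_resamples)),
            class = "uce_test_result")
}

#' @export
print.uce_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (x$n_resamples > 0L) cat(sprintf(" (%d resamples)", x$n_resamples))
  cat("\n")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test; the p-value sums the probabilities of all tables
#' with the observed margins whose hypergeometric probability does not
#' exceed that of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A [test_result()] with the conditional odds-ratio estimate as the
#'   statistic.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("table must be 2x2")
  if (any(!is.finite(table)) || any(table < 0) || any(table != floor(table)))
    stopf("table cells must be nonnegative integers")
  if (sum(table) == 0) stopf("table has no observations (zero margins)")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  test_result(statistic = ft$estimate, p_value = min(1, ft$p.value),
              method = "fisher_exact")
}

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` marked items. This is the gene-set
#' enrichment test used for term enrichment.
#'
#' @param k Observed number of marked items in the draw.
#' @param K Marked items in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return A [test_result()] with `k` as the statistic.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) if (!is_count(v)) stopf("counts must be nonnegative integers")
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(K, n)) stopf("k must not exceed min(K, n)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  test_result(statistic = k, p_value = min(1, p), method = "hypergeometric_tail")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test. The exact null distribution is used
#' when the pooled sample size is at most 12 and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return A [test_result()] with the Mann-Whitney W statistic.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("samples must be finite")
  exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  test_result(statistic = wt$statistic, p_value = min(1, wt$p.value),
              method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx")
}

check_pvalues <- function(p) {
  if (length(p) == 0L) stopf("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  as.numeric(p)
}

#' Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, order-aligned with the input.
#' @export
hochberg_adjust <- function(p) stats::p.adjust(check_pvalues(p), method = "hochberg")

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, order-aligned with the input.
#' @export
bh_adjust <- function(p) stats::p.adjust(check_pvalues(p), method = "BH")

#' Empirical resampling Z test for a class mean
#'
#' Compares the mean of a class of values against a null distribution of
#' means obtained by repeatedly drawing size-matched samples (with
#' replacement) from a reference pool. The statistic is
#' `(mean(class) - mean(null means)) / sd(null means)` and the p-value is
#' the two-sided standard-normal tail. This is the test used to compare
#' RNA-Seq coverage levels between region classes (UCEs, enhancers, exons)
#' and random background.
#'
#' @param class_values Non-empty numeric vector (the class of interest).
#' @param reference_values Non-empty numeric reference pool.
#' @param n_samples Number of resampled null means; at least 100
#'   (default 10000).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return A [test_result()] with the Z statistic and `n_resamples` set.
#' @export
empirical_ztest <- function(class_values, reference_values, n_samples = 10000L,
                            seed) {
  if (length(class_values) == 0L || length(reference_values) == 0L)
    stopf("class and reference values must be non-empty")
  if (!is_count(n_samples) || n_samples < 100L)
    stopf("n_samples must be an integer >= 100")
  if (missing(seed)) stopf("seed is required")
  k <- length(class_values)
  null_means <- with_seed(seed, {
    draws <- sample(reference_values, n_samples * k, replace = TRUE)
    colMeans(matrix(draws, nrow = k))
  })
  s <- stats::sd(null_means)
  if (s == 0) stopf("degenerate reference: resampled means have zero spread")
  z <- (mean(class_values) - mean(null_means)) / s
  test_result(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
              method = "empirical_ztest", n_resamples = n_samples)
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`,
#' clipped to `[0, 1]`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)` with attributes `estimate`
#'   and `half_width`.
#' @export
proportion_ci <- function(successes, n, level = 0.95) {
  if (!is_count(successes) || !is_count(n)) stopf("counts must be integers")
  if (n == 0) stopf("n must be positive")
  if (successes > n) stopf("successes must not exceed n")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  phat <- successes / n
  half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(phat * (1 - phat) / n)
  structure(c(low = max(0, phat - half), high = min(1, phat + half)),
            estimate = phat, half_width = half)
}
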
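# distribution of the rank-sum of n_a elements drawn from the pooled
# (doubled) midranks; dynamic programme over subset sums, exact under ties
ranksum_distribution <- function(r2, n_a) {
  S <- sum(r2)
  dp <- matrix(0, nrow = n_a + 1, ncol = S + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    jmax <- min(n_a, nrow(dp) - 1)
    for (j in seq(jmax, 1)) {
      nz <- which(dp[j, ] > 0)
      if (length(nz)) dp[j + 1, nz + v] <- dp[j + 1, nz + v] + dp[j, nz]
    }
  }
  dp[n_a + 1, ]  # counts indexed by doubled rank-sum + 1
}

#' Two-sample Wilcoxon (Mann-Whitney) test
#'
#' Two-sided rank-sum test. For small samples (pooled size at most
#' `exact_limit`) the p-value is exact, computed from the conditional
#' distribution of the rank sum given the observed (possibly tied) ranks;
#' larger samples use the tie-corrected normal approximation with continuity
#' correction. The exact path handles ties, which the classical
#' no-tie tables cannot.
#'
#' @param a,b Numeric samples.
#' @param exact_limit Use the exact distribution when
#'   `length(a) + length(b)` is at most this, default 40.
#' @return One-row tibble `statistic` (Mann-Whitney U for `a`), `p_value`,
#'   `method`.
#' @export
wilcoxon_two_sample <- function(a, b, exact_limit = 40) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty.")
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  U <- W - n_a * (n_a + 1) / 2
  if (N <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    counts <- ranksum_distribution(r2, n_a)
    total <- sum(counts)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq(w2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie <- table(r)
    sigma <- sqrt((n_a * n_b / 12) *
                    ((N + 1) - sum(tie^3 - tie) / (N * (N - 1))))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal_tie_corrected"
  }
  tibble(statistic = U, p_value = p, method = method)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by exact hypergeometric enumeration (summing tables
#' with probability at most that observed), reported with the sample
#' (cross-product) odds ratio. Zero cells give an infinite or zero odds
#' ratio unless `continuity = TRUE`, which adds 0.5 to every cell for the
#' odds-ratio estimate only.
#'
#' @param counts 2x2 matrix of non-negative integers; both margins must be
#'   positive.
#' @param continuity Apply the Haldane 0.5 correction to the odds ratio.
#' @return One-row tibble `odds_ratio`, `p_value`.
#' @export
fisher_2x2 <- function(counts, continuity = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort("counts must be a 2x2 table.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("both margins of the 2x2 table must be positive.")
  }
  p <- stats::fisher.test(counts)$p.value
  m <- if (continuity) counts + 0.5 else counts
  num <- m[1, 1] * m[2, 2]
  den <- m[1, 2] * m[2, 1]
  or <- if (den == 0) Inf else num / den
  tibble(odds_ratio = or, p_value = p)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, default 0.05.
#' @param n_tests Number of tests performed.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    abort("n_tests must be a positive integer.")
  }
  alpha / n_tests
}
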
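# Exact and rank statistics used by every downstream stage.
#
# These are deliberately self-contained: the two-sided Fisher tail
# definition, the BH step-up, and the exact rank-sum enumeration are the
# statistical contract of the whole pipeline, so they are implemented
# here and cross-checked against stats::fisher.test / p.adjust /
# wilcox.test in the test suite rather than delegated to them.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional exact test on a 2x2 contingency table with both margins
#' fixed.  The two-sided p-value uses the minimum-likelihood definition:
#' the sum of hypergeometric point probabilities of all tables (with the
#' observed margins) whose probability does not exceed that of the
#' observed table, with a small relative tolerance for ties.  The
#' reported statistic is the sample odds ratio `a*d / (b*c)` (infinite
#' when `b*c == 0` and the numerator is positive).
#'
#' @param table A 2x2 matrix of non-negative integer counts, or a
#'   length-4 vector `c(a, b, c, d)` read row-wise (row 1 = group 1
#'   positive/negative, row 2 = group 2 positive/negative).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#'   One-sided alternatives refer to the (1,1) cell being larger or
#'   smaller than expected under independence.
#' @param two_sided_method `"minlike"` (default) sums all point
#'   probabilities at most that of the observed table;
#'   `"double"` doubles the smaller one-sided tail (capped at 1).
#' @param tie_tol Relative tolerance for counting a table's point
#'   probability as tied with the observed one.
#' @return An object of class `mm_test` with elements `statistic`
#'   (sample odds ratio), `p_value`, `method`, and `sidedness`.
#' @examples
#' fisher_exact(c(3, 1, 1, 3))$p_value  # 34/70
#' @export
fisher_exact <- function(table,
                         alternative = c("two.sided", "greater", "less"),
                         two_sided_method = c("minlike", "double"),
                         tie_tol = 1e-7) {
  alternative <- match.arg(alternative)
  two_sided_method <- match.arg(two_sided_method)
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L)
    stop("`table` must be a 2x2 matrix or a length-4 vector")
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  n <- a + b + cc + d
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)

  if (n == 0) {
    # all-zero table: no information, p = 1 by convention
    return(mm_test(or, 1, "fisher_exact", alternative))
  }

  r1 <- a + b
  c1 <- a + cc
  lo <- max(0L, c1 - (cc + d))
  hi <- min(r1, c1)
  support <- lo:hi
  logd <- stats::dhyper(support, r1, n - r1, c1, log = TRUE)
  logd_obs <- logd[support == a]

  p_greater <- sum(exp(logd[support >= a]))
  p_less <- sum(exp(logd[support <= a]))
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = if (two_sided_method == "minlike") {
      sum(exp(logd[logd <= logd_obs + log1p(tie_tol)]))
    } else {
      2 * min(p_less, p_greater)
    })
  mm_test(or, min(p, 1), "fisher_exact", alternative)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on the sorted p-values,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the
#' original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Count of k-subsets of the integer weights w2 attaining each sum
# (dynamic programme over the subset-sum generating function).
# Returns a vector indexed by sum 0..sum(w2).
subset_sum_counts <- function(w2, k) {
  smax <- sum(w2)
  dp <- matrix(0, nrow = k + 1L, ncol = smax + 1L)
  dp[1L, 1L] <- 1
  for (w in w2) {
    jmax <- k
    for (j in jmax:1L) {
      if (w == 0) {
        dp[j + 1L, ] <- dp[j + 1L, ] + dp[j, ]
      } else {
        idx <- (w + 1L):(smax + 1L)
        dp[j + 1L, idx] <- dp[j + 1L, idx] + dp[j, idx - w]
      }
    }
  }
  dp[k + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum statistic `W` of the smaller sample, with midranks for ties.
#' The p-value is exact -- by full enumeration of the rank-sum null
#' distribution -- when `min(n) <= 10` and the total sample size is at
#' most 25; otherwise a normal approximation with tie correction and a
#' 0.5 continuity correction is used.  The exact two-sided p-value is
#' twice the smaller tail probability, capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`,
#'   referring to the location of the smaller sample.
#' @param exact_max_min,exact_max_total Size limits for the exact path.
#' @return An `mm_test` with `statistic` = W of the smaller sample.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max_min = 10L, exact_max_total = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (anyNA(c(x, y))) stop("samples must not contain NA")
  swap <- length(y) < length(x)
  if (swap) { tmp <- x; x <- y; y <- tmp }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  exact <- n1 <= exact_max_min && N <= exact_max_total
  if (exact) {
    w2 <- as.integer(round(2 * r))   # midranks doubled -> integers
    counts <- subset_sum_counts(w2, n1)
    total <- choose(N, n1)
    W2 <- as.integer(round(2 * W))
    sums <- seq_along(counts) - 1L
    p_le <- sum(counts[sums <= W2]) / total
    p_ge <- sum(counts[sums >= W2]) / total
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le)
    method <- "wilcoxon_rank_sum_exact"
  } else {
    E <- n1 * (N + 1) / 2
    ties <- table(r)
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(W - E) - 0.5) / sqrt(v)
      p <- switch(alternative,
        two.sided = min(1, 2 * stats::pnorm(-z)),
        greater = stats::pnorm((W - E - 0.5) / sqrt(v), lower.tail = FALSE),
        less = stats::pnorm((W - E + 0.5) / sqrt(v)))
    }
    method <- "wilcoxon_rank_sum_normal"
  }
  # report the alternative relative to the sample passed first
  if (swap && alternative != "two.sided")
    alternative <- if (alternative == "greater") "less" else "greater"
  mm_test(W, p, method, alternative)
}

#' Upper tail of the binomial distribution
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, evaluated through the stable
#' regularised-beta tail in [stats::pbinom()].
#'
#' @param k,n Integers with `0 <= k <= n`.
#' @param p Success probability in `[0, 1]`.
#' @return The upper-tail probability.
#' @export
binomial_tail <- function(k, n, p) {
  if (anyNA(c(k, n, p)) || any(k < 0) || any(k > n) || any(p < 0 | p > 1))
    stop("require 0 <= k <= n and p in [0, 1]")
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

mm_test <- function(statistic, p_value, method, sidedness) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, sidedness = sidedness),
            class = "mm_test")
}

#' @export
print.mm_test <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$sidedness, x$statistic, x$p_value))
  invisible(x)
}
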
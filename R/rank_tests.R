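# Exact rank tests. Both tests compute exact two-sided p-values by counting
# over the full permutation/sign reference set — via the shift (subset-sum
# convolution) algorithm, which handles midranks for ties — for small
# samples, and fall back to the tie-corrected normal approximation with
# continuity correction for large ones. Two-sided p is twice the smaller
# one-sided tail, capped at 1, the standard convention for exact rank tests.

# count, over all size-k subsets of `weights` (non-negative integers),
# of each achievable subset sum; returns matrix [k+1, sum+1]
subset_sum_counts <- function(weights, k) {
  S <- sum(weights)
  f <- matrix(0, nrow = k + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (w in weights) {
    for (j in min(k, nrow(f) - 1):1) {
      if (w == 0) f[j + 1, ] <- f[j + 1, ] + f[j, ]
      else f[j + 1, (w + 1):(S + 1)] <- f[j + 1, (w + 1):(S + 1)] +
          f[j, 1:(S + 1 - w)]
    }
  }
  f
}

# counts of each achievable sum over all 2^n subsets of `weights`
sign_sum_counts <- function(weights) {
  S <- sum(weights)
  g <- numeric(S + 1)
  g[1] <- 1
  for (w in weights) {
    if (w == 0) g <- 2 * g
    else g[(w + 1):(S + 1)] <- g[(w + 1):(S + 1)] + g[1:(S + 1 - w)]
  }
  g
}

two_sided_from_counts <- function(counts, obs_doubled) {
  total <- sum(counts)
  sums <- seq_along(counts) - 1
  lower <- sum(counts[sums <= obs_doubled + 1e-9]) / total
  upper <- sum(counts[sums >= obs_doubled - 1e-9]) / total
  min(1, 2 * min(lower, upper))
}

tie_counts <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

#' Exact Mann-Whitney U and Wilcoxon signed-rank tests
#'
#' `kind = "mann_whitney"`: two independent samples; the U statistic is
#' computed by rank counting with midranks for ties, and the two-sided p
#' comes from exact enumeration of the rank-sum distribution over all
#' assignments (shift algorithm) when the combined sample size is at most
#' `exact_limit`, otherwise from the tie-corrected normal approximation
#' with continuity correction.
#'
#' `kind = "wilcoxon_signed"`: paired samples (or a single sample of
#' differences when `y` is `NULL`); zero differences are dropped, the
#' signed-rank statistic W is the sum of |difference| midranks carrying a
#' positive sign, and the exact p enumerates all sign patterns when the
#' number of nonzero differences is at most `exact_limit`.
#'
#' @param x,y Numeric samples. For the signed-rank test, `x` and `y` are
#'   paired (equal length), or `y = NULL` and `x` holds the differences.
#' @param kind `"mann_whitney"` or `"wilcoxon_signed"`.
#' @param exact Force exact enumeration (`TRUE`), the normal approximation
#'   (`FALSE`), or choose by `exact_limit` (`NULL`, default).
#' @param exact_limit Largest sample size (combined for Mann-Whitney,
#'   nonzero-difference count for signed-rank) analysed exactly by default.
#' @return A list of class `rank_test`: `statistic` (U or W), `p_value`
#'   (two-sided), `method`, `exact` (logical), `n`.
#' @export
exact_rank_test <- function(x, y = NULL,
                            kind = c("mann_whitney", "wilcoxon_signed"),
                            exact = NULL, exact_limit = 25) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    if (is.null(y)) stop_param("mann_whitney requires two samples")
    if (length(x) < 1 || length(y) < 1)
      stop_data("each sample needs at least one observation")
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    pooled <- c(x, y)
    r <- rank(pooled)                       # midranks
    r1 <- sum(r[seq_len(n1)])
    u <- r1 - n1 * (n1 + 1) / 2
    use_exact <- exact %||% (N <= exact_limit)
    if (use_exact) {
      counts <- subset_sum_counts(as.integer(round(2 * r)), n1)[n1 + 1, ]
      p <- two_sided_from_counts(counts, 2 * r1)
    } else {
      mu <- n1 * n2 / 2
      sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_counts(r) / (N * (N - 1)))
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    structure(list(statistic = c(U = u), p_value = p,
                   method = "Mann-Whitney U test", exact = use_exact,
                   n = c(n1 = n1, n2 = n2)),
              class = "rank_test")
  } else {
    d <- if (is.null(y)) x else {
      if (length(x) != length(y))
        stop_param("paired samples must have equal length")
      x - y
    }
    d <- d[d != 0]
    if (length(d) == 0)
      stop_degenerate("all paired differences are zero")
    n <- length(d)
    r <- rank(abs(d))                       # midranks of |d|
    w <- sum(r[d > 0])
    use_exact <- exact %||% (n <= exact_limit)
    if (use_exact) {
      counts <- sign_sum_counts(as.integer(round(2 * r)))
      p <- two_sided_from_counts(counts, 2 * w)
    } else {
      mu <- n * (n + 1) / 4
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_counts(r) / 48
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    structure(list(statistic = c(W = w), p_value = p,
                   method = "Wilcoxon signed-rank test", exact = use_exact,
                   n = c(n = n)),
              class = "rank_test")
  }
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s: %s = %.4g, two-sided p = %.5g (%s)\n",
              x$method, names(x$statistic), x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
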
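#' Wilcoxon rank-sum test (exact enumeration or normal approximation)
#'
#' Two-sample rank-sum test reporting the rank-sum of the first sample
#' (mid-ranks for ties) and a two-sided p-value. In exact mode the null
#' distribution of the rank-sum is computed over all `choose(n1+n2, n1)`
#' assignments of the pooled (possibly tied) ranks, via a subset-sum
#' recursion, and the two-sided p is the total null probability of rank-sums
#' at least as far from the null mean as the observed one (both tails
#' accumulated directly, not one tail doubled). The approximation uses the
#' tie-corrected normal with a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"` (exact when `n1 + n2 <= 20`), `"exact"`, or
#'   `"approx"`.
#' @return A list of class `rank_test` with fields `statistic` (rank-sum of
#'   `x`), `n1`, `n2`, `p_two_sided`, `mode` (`"EXACT"` or `"NORMAL_APPROX"`)
#'   and `ties_present`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_two_sided      # 1/3
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_sided # 1/10
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  z <- c(x, y)
  r <- rank(z)
  w <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(z) > 0
  if (mode == "auto") mode <- if (n <= 20) "exact" else "approx"
  mu <- n1 * (n + 1) / 2
  if (mode == "exact") {
    p <- exact_ranksum_p(r, n1, w)
    used <- "EXACT"
  } else {
    tie_tab <- table(z)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- max(abs(w - mu) - 0.5, 0)
      p <- min(1, 2 * stats::pnorm(-dev / sqrt(sigma2)))
    }
    used <- "NORMAL_APPROX"
  }
  structure(list(statistic = w, n1 = n1, n2 = n2, p_two_sided = p,
                 mode = used, ties_present = ties),
            class = "rank_test")
}

# Exact two-sided tail probability of the rank-sum of a size-n1 subset of the
# pooled mid-ranks `r`. Doubled ranks are integers, so the full distribution
# is built by a subset-sum count: cnt[k+1, s+1] = number of k-subsets with
# doubled-rank sum s.
exact_ranksum_p <- function(r, n1, w) {
  d <- as.integer(round(2 * r))
  n <- length(d)
  S <- sum(d)
  cnt <- matrix(0, nrow = n1 + 1, ncol = S + 1)
  cnt[1, 1] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      src <- cnt[k, 1:(S + 1 - d[i])]
      cnt[k + 1, (d[i] + 1):(S + 1)] <- cnt[k + 1, (d[i] + 1):(S + 1)] + src
    }
  }
  counts <- cnt[n1 + 1, ]
  total <- sum(counts)
  sums <- (seq_len(S + 1) - 1) / 2       # back to mid-rank scale
  mu <- n1 * (n + 1) / 2
  dev <- abs(w - mu)
  sum(counts[abs(sums - mu) >= dev - 1e-9]) / total
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W1 = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s%s]\n",
              x$statistic, x$n1, x$n2, x$p_two_sided, x$mode,
              if (x$ties_present) ", ties" else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the family size (default: the number of
#' p-values supplied), capped at 1. The family for one analysis run is every
#' group-pair-by-phenotype test performed; `family_size` can be widened when
#' p-values are corrected in batches.
#'
#' @param raw_p Numeric vector of p-values in `(0, 1]`.
#' @param family_size Family size, at least `length(raw_p)`.
#' @return A list with `raw_p`, `adjusted_p`, `family_size`.
#' @examples
#' bonferroni(0.01, family_size = 5)$adjusted_p  # 0.05
#' @export
bonferroni <- function(raw_p, family_size = NULL) {
  if (any(is.na(raw_p)) || any(raw_p <= 0) || any(raw_p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  if (is.null(family_size)) family_size <- length(raw_p)
  if (family_size < length(raw_p)) {
    abort("`family_size` must be at least the number of p-values.")
  }
  adj <- stats::p.adjust(raw_p, method = "bonferroni", n = family_size)
  list(raw_p = raw_p, adjusted_p = adj, family_size = as.integer(family_size))
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of the mid-ranks of the two vectors, with a
#' t-distribution approximation for the p-value. Constant input has no
#' defined rank correlation; `NA` is returned with a warning.
#'
#' @param x,y Equal-length numeric vectors, length >= 3 after pairwise
#'   removal of missing values.
#' @return A list with `rho`, `p_value`, `n`.
#' @examples
#' spearman_correlation(1:5, c(2, 4, 6, 8, 10))$rho  # 1
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warn("Constant input: rank correlation undefined.")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
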
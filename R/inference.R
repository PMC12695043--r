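# Subgroup statistics reported around the tree: Welch leaf contrasts,
# Fisher / Wilcoxon arm comparisons, trend tests across ordered leaves,
# Pearson correlation.

# Welch two-sample interval/p from sufficient statistics. When both arm
# variances are zero the interval collapses to the point difference and p
# is 0 (diff != 0) or 1 (diff == 0).
welch_from_stats <- function(n1, m1, v1, n0, m0, v0, conf = 0.95) {
  diff <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  if (se2 <= 0) {
    return(list(diff = diff, ci_low = diff, ci_high = diff,
                p = if (diff != 0) 0 else 1, df = NA_real_, se = 0))
  }
  se <- sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  tstat <- diff / se
  list(diff = diff, ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
       p = 2 * stats::pt(-abs(tstat), df), df = df, se = se)
}

#' Leaf-level treatment contrast
#'
#' Difference in mean outcome between the two arms within a subpopulation,
#' with a 95% confidence interval and two-sided p-value from the Welch
#' unequal-variance t procedure (Welch-Satterthwaite degrees of freedom).
#'
#' @param y numeric outcome vector (change in ppFVC, percentage points).
#' @param w 0/1 arm indicator vector.
#' @param leaf_label optional label carried into the result.
#' @return A list of class `subgroup_contrast`: `leaf_label`, `n1`, `n0`,
#'   `mean1`, `mean0`, `diff`, `ci_low`, `ci_high`, `p`.
#' @export
leaf_contrast <- function(y, w, leaf_label = NA_integer_) {
  st <- leaf_stats(y, w)
  wt <- welch_from_stats(st$n1, st$mean1, st$var1, st$n0, st$mean0, st$var0)
  structure(list(leaf_label = leaf_label, n1 = st$n1, n0 = st$n0,
                 mean1 = st$mean1, mean0 = st$mean0, diff = wt$diff,
                 ci_low = wt$ci_low, ci_high = wt$ci_high, p = wt$p),
            class = "subgroup_contrast")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-sum convention: the sum of the
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts; both margins must
#'   be positive.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("Fisher exact test requires positive row and column margins")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Wilcoxon rank-sum test
#'
#' Two-sided p-value comparing two samples. When both samples have at most
#' 10 observations and there are no ties, the exact null distribution of
#' the Mann-Whitney statistic is used; otherwise a normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric sample vectors (non-empty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (m <= 10 && n <= 10 && !ties) {
    p <- 2 * min(stats::pwilcox(u, m, n),
                 stats::pwilcox(u - 1, m, n, lower.tail = FALSE))
    return(min(p, 1))
  }
  mu <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 * ((m + n + 1) -
                            sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Mantel trend test for a binary trait across ordered groups
#'
#' Mantel-Haenszel chi-square trend statistic: expand the per-group counts
#' to patient level, correlate the 0/1 outcome with the group score, and
#' take \eqn{\chi^2 = (N - 1) r^2} on 1 degree of freedom. The statistic is
#' invariant to affine transformations of the scores.
#'
#' @param successes integer vector of per-group trait counts.
#' @param totals integer vector of per-group sizes.
#' @param scores numeric group scores (default equally spaced 1..K).
#' @return A list of class `trend_test`: `method = "mantel"`, `statistic`
#'   (chi-square), `p`, `scores`.
#' @export
mantel_trend <- function(successes, totals, scores = seq_along(totals)) {
  stopifnot(length(successes) == length(totals),
            length(scores) == length(totals), length(totals) >= 2,
            all(successes >= 0), all(successes <= totals))
  y <- unlist(mapply(function(s, t) c(rep(1, s), rep(0, t - s)),
                     successes, totals, SIMPLIFY = FALSE))
  x <- rep(scores, totals)
  N <- sum(totals)
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    stat <- 0; p <- 1
  } else {
    r <- stats::cor(y, x)
    stat <- (N - 1) * r^2
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(method = "mantel", statistic = stat, p = p, scores = scores),
            class = "trend_test")
}

#' Linear trend test for a continuous trait across ordered groups
#'
#' Two-sided p-value of the slope in the least-squares regression of the
#' per-patient value on the group score. With zero residual variance the
#' degenerate convention is p = 0 for a non-zero slope and p = 1 for a flat
#' fit.
#'
#' @param values per-patient numeric values.
#' @param group_scores per-patient numeric scores (at least 2 distinct).
#' @return A list of class `trend_test`: `method = "linear"`, `statistic`
#'   (the slope t), `p`, `scores`.
#' @export
linear_trend <- function(values, group_scores) {
  stopifnot(length(values) == length(group_scores), length(values) >= 3)
  x <- group_scores; y <- values
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("group scores have zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - mean(y) - slope * (x - mean(x))
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  if (s2 <= 0) {
    stat <- if (slope == 0) 0 else Inf * sign(slope)
    p <- if (slope == 0) 1 else 0
  } else {
    stat <- slope / sqrt(s2 / sxx)
    p <- 2 * stats::pt(-abs(stat), df)
  }
  structure(list(method = "linear", statistic = stat, p = p,
                 scores = sort(unique(group_scores))),
            class = "trend_test")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with positive
#'   variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Pearson correlation requires positive variance in both variables")
  stats::cor(x, y)
}
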
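#' Per-arm leaf statistics
#'
#' Computes the building block of the causal tree: per-arm outcome means and
#' sample variances and the treatment-effect estimate
#' `tau_hat = mean(treated) - mean(control)` for one node.
#'
#' @param y numeric outcome vector.
#' @param w 0/1 arm indicator vector of the same length.
#' @return A list of class `leaf_stats` with fields `n1`, `n0`, `mean1`,
#'   `mean0`, `var1`, `var0` (sample variances, `n - 1` denominator; 0 with
#'   `degenerate = TRUE` when an arm has fewer than 2 patients) and
#'   `tau_hat`.
#' @export
leaf_stats <- function(y, w) {
  stopifnot(length(y) == length(w))
  w <- as.integer(w)
  n1 <- sum(w == 1L); n0 <- sum(w == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("leaf_stats requires both arms to be represented")
  y1 <- y[w == 1L]; y0 <- y[w == 0L]
  m1 <- mean(y1); m0 <- mean(y0)
  degenerate <- n1 < 2L || n0 < 2L
  v1 <- if (n1 >= 2L) stats::var(y1) else 0
  v0 <- if (n0 >= 2L) stats::var(y0) else 0
  structure(list(n1 = n1, n0 = n0, mean1 = m1, mean0 = m0,
                 var1 = v1, var0 = v0, tau_hat = m1 - m0,
                 degenerate = degenerate),
            class = "leaf_stats")
}

#' Honest EMSE splitting criterion
#'
#' Evaluates a leaf partition by the (negated) expected mean squared error
#' for treatment-effect estimation: the effect-heterogeneity reward minus a
#' variance penalty,
#' \deqn{\frac{1}{n}\sum_\ell n_\ell \hat\tau_\ell^2 -
#'       \frac{2}{n}\sum_\ell
#'       \left(\frac{s^2_{1\ell}}{p} + \frac{s^2_{0\ell}}{1-p}\right),}
#' where `p` is the treated share and the estimation sample is taken equal
#' in size to the training sample (penalty factor `1/N_tr + 1/N_est = 2/n`).
#' Larger is better.
#'
#' @param leaves list of [leaf_stats()] objects (the partition's leaves).
#' @param n_total total patient count the criterion is normalized by.
#' @param p treated share in (0, 1).
#' @return The criterion value (a scalar; larger is better).
#' @export
emse_criterion <- function(leaves, n_total, p) {
  if (inherits(leaves, "leaf_stats")) leaves <- list(leaves)
  if (!length(leaves)) stop("leaves must be non-empty")
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  reward <- sum(vapply(leaves, function(s) (s$n1 + s$n0) * s$tau_hat^2,
                       numeric(1)))
  penalty <- sum(vapply(leaves, function(s) s$var1 / p + s$var0 / (1 - p),
                        numeric(1)))
  reward / n_total - 2 * penalty / n_total
}

#' Transformed outcome
#'
#' Per-patient unbiased single-observation proxy for the treatment effect
#' under known randomization probability `p`:
#' `y* = w y / p - (1 - w) y / (1 - p)`. Its mean over a group equals the
#' group's difference-in-means effect estimate when `p` is the empirical
#' treated share; it anchors the cross-validation risk used for pruning.
#'
#' @param y numeric outcome vector.
#' @param w 0/1 arm indicator vector.
#' @param p treated share in (0, 1).
#' @return Numeric vector of pseudo-outcomes.
#' @export
transformed_outcome <- function(y, w, p) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  w <- as.numeric(w)
  w * y / p - (1 - w) * y / (1 - p)
}
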
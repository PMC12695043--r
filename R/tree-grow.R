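# Tree growth: exhaustive-midpoint EMSE split search and recursive growing.

# Vectorized search over all admissible cuts of a single feature.
# Returns NULL or list(threshold, crit) for the best cut of this feature.
best_cut_feature <- function(x, y, w, min_per_arm, p, n_total) {
  n <- length(y)
  o <- order(x, method = "radix")
  xs <- x[o]; ys <- y[o]; ws <- w[o]
  cuts <- which(diff(xs) > 0)
  if (!length(cuts)) return(NULL)
  cn1 <- cumsum(ws); cn0 <- seq_len(n) - cn1
  sy <- cumsum(ys); sy1 <- cumsum(ys * ws); sy0 <- sy - sy1
  qy <- cumsum(ys^2); qy1 <- cumsum(ys^2 * ws); qy0 <- qy - qy1
  N1 <- cn1[n]; N0 <- cn0[n]
  S1 <- sy1[n]; S0 <- sy0[n]; Q1 <- qy1[n]; Q0 <- qy0[n]

  l1 <- cn1[cuts]; l0 <- cn0[cuts]
  r1 <- N1 - l1; r0 <- N0 - l0
  ok <- l1 >= min_per_arm & l0 >= min_per_arm &
        r1 >= min_per_arm & r0 >= min_per_arm
  if (!any(ok)) return(NULL)
  cuts <- cuts[ok]; l1 <- l1[ok]; l0 <- l0[ok]; r1 <- r1[ok]; r0 <- r0[ok]

  sl1 <- sy1[cuts]; sl0 <- sy0[cuts]; ql1 <- qy1[cuts]; ql0 <- qy0[cuts]
  sr1 <- S1 - sl1; sr0 <- S0 - sl0; qr1 <- Q1 - ql1; qr0 <- Q0 - ql0

  svar <- function(q, s, m) {
    v <- ifelse(m >= 2, (q - s^2 / pmax(m, 1)) / pmax(m - 1, 1), 0)
    pmax(v, 0)
  }
  tauL <- sl1 / l1 - sl0 / l0
  tauR <- sr1 / r1 - sr0 / r0
  pen <- svar(ql1, sl1, l1) / p + svar(ql0, sl0, l0) / (1 - p) +
         svar(qr1, sr1, r1) / p + svar(qr0, sr0, r0) / (1 - p)
  crit <- ((l1 + l0) * tauL^2 + (r1 + r0) * tauR^2) / n_total -
          2 * pen / n_total
  best <- which.max(crit)  # first max = smallest threshold on ties
  list(threshold = (xs[cuts[best]] + xs[cuts[best] + 1]) / 2,
       crit = crit[best])
}

#' Best admissible EMSE split of a node
#'
#' Enumerates, for every covariate, every midpoint between adjacent distinct
#' observed values (for a 0/1 covariate this is the single threshold 0.5),
#' keeps the candidates whose children each hold at least `min_per_arm`
#' patients of each arm, and returns the candidate maximizing the
#' [emse_criterion()] of the two children. Ties are broken by covariate
#' order in `X`, then by the smaller threshold. Returns `NULL` when the node
#' is too small, no candidate is admissible, or no admissible candidate
#' improves on the unsplit node (`gain > 0`).
#'
#' @param y numeric outcome vector for the node.
#' @param w 0/1 arm indicators for the node.
#' @param X data frame (or matrix) of candidate covariates, columns in
#'   catalog order.
#' @param cfg a [fit_config()]; only `min_per_arm` is used here.
#' @param p treated share used in the criterion.
#' @param n_total normalizing count for the criterion (defaults to the node
#'   size; the argmax is invariant to this choice).
#' @return `NULL`, or a list with `feature`, `threshold`, `gain`,
#'   `criterion` (children), `left_stats` (low side, `< threshold`) and
#'   `right_stats` (high side).
#' @export
best_split <- function(y, w, X, cfg = fit_config(), p = mean(w == 1),
                       n_total = length(y)) {
  w <- as.integer(w)
  m <- cfg$min_per_arm
  if (sum(w == 1L) < 2L * m || sum(w == 0L) < 2L * m) return(NULL)
  X <- as.data.frame(X)
  best <- NULL
  for (nm in names(X)) {
    x <- X[[nm]]
    if (all(is.na(x))) {
      warning("feature '", nm, "' is entirely missing in this node; skipped")
      next
    }
    cand <- best_cut_feature(x, y, w, m, p, n_total)
    if (is.null(cand)) next
    if (is.null(best) || cand$crit > best$crit) {
      best <- cand
      best$feature <- nm
    }
  }
  if (is.null(best)) return(NULL)
  base <- emse_criterion(leaf_stats(y, w), n_total, p)
  gain <- best$crit - base
  if (!(gain > 0)) return(NULL)
  low <- X[[best$feature]] < best$threshold
  list(feature = best$feature, threshold = best$threshold,
       gain = gain, criterion = best$crit,
       left_stats = leaf_stats(y[low], w[low]),
       right_stats = leaf_stats(y[!low], w[!low]))
}

new_node <- function(stats, feature = NULL, threshold = NULL,
                     low = NULL, high = NULL) {
  list(is_leaf = is.null(feature), feature = feature, threshold = threshold,
       low = low, high = high, stats = stats, leaf_label = NA_integer_,
       id = NA_integer_)
}

grow_node <- function(y, w, X, cfg, p, depth) {
  st <- leaf_stats(y, w)
  if (!is.null(cfg$max_depth) && depth >= cfg$max_depth)
    return(new_node(st))
  bs <- best_split(y, w, X, cfg, p)
  if (is.null(bs)) return(new_node(st))
  low <- X[[bs$feature]] < bs$threshold
  new_node(st, feature = bs$feature, threshold = bs$threshold,
           low = grow_node(y[low], w[low], X[low, , drop = FALSE],
                           cfg, p, depth + 1L),
           high = grow_node(y[!low], w[!low], X[!low, , drop = FALSE],
                            cfg, p, depth + 1L))
}

# Assign ids (preorder) and leaf labels (depth-first, high side before low,
# so the first leaf is the one reached by always taking "feature >= cut").
index_tree <- function(root) {
  next_id <- 1L; next_label <- 1L
  walk <- function(node) {
    node$id <- next_id; next_id <<- next_id + 1L
    if (node$is_leaf) {
      node$leaf_label <- next_label; next_label <<- next_label + 1L
    } else {
      node$leaf_label <- NA_integer_
      node$high <- walk(node$high)
      node$low <- walk(node$low)
    }
    node
  }
  walk(root)
}

n_leaves <- function(node) {
  if (node$is_leaf) 1L else n_leaves(node$low) + n_leaves(node$high)
}

tree_leaves <- function(node) {
  if (node$is_leaf) return(list(node))
  c(tree_leaves(node$high), tree_leaves(node$low))
}

#' Grow a full causal tree
#'
#' Recursively applies [best_split()] depth-first until no node yields an
#' admissible positive-gain split (or `max_depth` is reached). The treated
#' share `p` used in the criterion is fixed at the root's empirical share
#' for the whole fit, reflecting trial-wide randomization.
#'
#' @param ds a [trial_dataset()] with `delta_ppfvc` present and complete
#'   covariates.
#' @param cfg a [fit_config()].
#' @return An object of class `causal_tree` (unpruned; `alpha_selected` is
#'   `NA` until [fit_causal_tree()] runs the pruning stage).
#' @export
grow_tree <- function(ds, cfg = fit_config()) {
  if (is.null(ds$delta_ppfvc))
    stop("delta_ppfvc is missing; run compute_delta_ppfvc first")
  X <- ds$covariates[, ds$catalog$name, drop = FALSE]
  if (anyNA(X)) {
    bad <- names(X)[vapply(X, anyNA, logical(1))]
    stop("missing covariate values at fit time (no surrogate splits): ",
         paste(bad, collapse = ", "))
  }
  w <- ds$arm
  if (sum(w == 1L) < cfg$min_per_arm || sum(w == 0L) < cfg$min_per_arm)
    stop("too few patients per arm (need at least ", cfg$min_per_arm,
         " in each arm)")
  p <- mean(w == 1L)
  root <- grow_node(ds$delta_ppfvc, w, X, cfg, p, 0L)
  structure(list(root = index_tree(root), n_train = length(w),
                 p_treated = p, config = cfg,
                 alpha_selected = NA_real_,
                 features = ds$catalog$name),
            class = "causal_tree")
}

#' @export
print.causal_tree <- function(x, ...) {
  cat(sprintf("causal_tree: %d leaves, n_train=%d, p_treated=%.3f%s\n",
              n_leaves(x$root), x$n_train, x$p_treated,
              if (is.na(x$alpha_selected)) " (unpruned)"
              else sprintf(", alpha=%.4g", x$alpha_selected)))
  for (r in tree_rules(x)$rule)
    cat(" ", r, "\n")
  invisible(x)
}
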
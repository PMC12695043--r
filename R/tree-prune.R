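# Weakest-link cost-complexity path and cross-validated alpha selection.

# Risk contribution of one leaf, on the whole-training-set scale so that
# tree risk is additive over leaves: R(leaf) = -EMSE term of that leaf.
leaf_risk <- function(st, n_train, p) {
  -((st$n1 + st$n0) * st$tau_hat^2 / n_train -
      2 * (st$var1 / p + st$var0 / (1 - p)) / n_train)
}

# Annotate: for every internal node compute subtree risk, leaf count and
# the weakest-link value g = (R(collapsed) - R(subtree)) / (leaves - 1).
node_g <- function(node, n_train, p) {
  if (node$is_leaf) {
    return(list(risk = leaf_risk(node$stats, n_train, p), leaves = 1L,
                g = Inf, min_g = Inf))
  }
  lo <- node_g(node$low, n_train, p)
  hi <- node_g(node$high, n_train, p)
  risk <- lo$risk + hi$risk
  leaves <- lo$leaves + hi$leaves
  g <- (leaf_risk(node$stats, n_train, p) - risk) / (leaves - 1L)
  list(risk = risk, leaves = leaves, g = g,
       min_g = min(g, lo$min_g, hi$min_g))
}

collapse_to_leaf <- function(node) {
  node$is_leaf <- TRUE
  node$feature <- NULL; node$threshold <- NULL
  node$low <- NULL; node$high <- NULL
  node
}

# Collapse every internal node whose weakest-link value is <= gmax
# (evaluated on the current tree, top-down: a flagged ancestor absorbs its
# flagged descendants).
collapse_at <- function(node, gmax, n_train, p, tol) {
  if (node$is_leaf) return(node)
  info <- node_g(node, n_train, p)
  if (info$g <= gmax + tol) return(collapse_to_leaf(node))
  node$low <- collapse_at(node$low, gmax, n_train, p, tol)
  node$high <- collapse_at(node$high, gmax, n_train, p, tol)
  node
}

#' Cost-complexity pruning path
#'
#' Computes the weakest-link pruning sequence of a grown tree under the
#' risk `R(T) = -EMSE(leaves of T)` plus `alpha` per leaf: a nested list of
#' subtrees with strictly increasing `alpha`, starting at the full tree
#' (`alpha = 0`) and ending at the root-only tree.
#'
#' @param tree a `causal_tree` from [grow_tree()].
#' @return A list of elements `list(alpha, n_leaves, root)`, each `root`
#'   being the pruned subtree effective from that `alpha` on.
#' @export
cost_complexity_path <- function(tree) {
  n_train <- tree$n_train; p <- tree$p_treated
  root <- tree$root
  path <- list(list(alpha = 0, n_leaves = n_leaves(root), root = root))
  tol <- 1e-12
  while (!root$is_leaf) {
    gmin <- node_g(root, n_train, p)$min_g
    root <- collapse_at(root, gmin, n_train, p, tol * max(1, abs(gmin)))
    path[[length(path) + 1L]] <- list(alpha = gmin,
                                      n_leaves = n_leaves(root), root = root)
  }
  path
}

# Largest subtree whose alpha threshold does not exceed beta.
path_subtree_at <- function(path, beta) {
  alphas <- vapply(path, `[[`, numeric(1), "alpha")
  path[[max(which(alphas <= beta))]]
}

# Vectorized routing: per-row tau_hat (or leaf label) under a subtree root.
route_values <- function(root, X, what = c("tau", "label")) {
  what <- match.arg(what)
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$is_leaf) {
      out[idx] <<- if (what == "tau") node$stats$tau_hat else node$leaf_label
      return(invisible())
    }
    x <- X[[node$feature]][idx]
    if (anyNA(x))
      stop("missing value for routed feature '", node$feature, "'")
    low <- x < node$threshold
    rec(node$low, idx[low])
    rec(node$high, idx[!low])
  }
  rec(root, seq_len(nrow(X)))
  out
}

subset_dataset <- function(ds, idx) {
  ds$patient_id <- ds$patient_id[idx]
  ds$arm <- ds$arm[idx]
  ds$ppfvc <- ds$ppfvc[idx, , drop = FALSE]
  ds$covariates <- ds$covariates[idx, , drop = FALSE]
  if (!is.null(ds$delta_ppfvc)) ds$delta_ppfvc <- ds$delta_ppfvc[idx]
  ds
}

arm_stratified_groups <- function(arm, k, seed) {
  grp <- integer(length(arm))
  with_seed(seed, {
    for (a in c(0L, 1L)) {
      idx <- which(arm == a)
      grp[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  grp
}

#' Cross-validated complexity selection
#'
#' Selects the cost-complexity penalty by `n_folds`-fold cross-validation,
#' stratified by arm and seeded from `cfg$seed`. For each fold a tree is
#' grown on the training folds and, for every candidate penalty (geometric
#' means of consecutive alphas on the master path grown on all data), the
#' validation risk \eqn{\sum_i (y^*_i - \hat\tau_{train}(x_i))^2} is
#' accumulated, with the transformed outcome computed at the training
#' folds' treated share. The returned alpha minimizes the CV risk
#' normalized by the root-only CV risk (minimum-risk rule; ties go to the
#' stronger pruning).
#'
#' @param ds a [trial_dataset()] with the outcome derived.
#' @param cfg a [fit_config()].
#' @return A list with `alpha` (the selected master-path alpha), `index`
#'   (its position on the master path), `path` (the master path) and
#'   `curve` (a data frame with the per-alpha normalized CV risk).
#' @export
cv_select_alpha <- function(ds, cfg = fit_config()) {
  master <- grow_tree(ds, cfg)
  mpath <- cost_complexity_path(master)
  alphas <- vapply(mpath, `[[`, numeric(1), "alpha")
  K <- length(alphas)
  betas <- if (K == 1L) Inf else
    c(sqrt(alphas[-K] * alphas[-1L]), Inf)

  arm <- ds$arm
  if (cfg$n_folds > min(sum(arm == 1L), sum(arm == 0L)))
    stop("n_folds exceeds the smaller arm size; stratified folds impossible")
  fold <- arm_stratified_groups(arm, cfg$n_folds, cfg$seed)

  risk <- numeric(K)
  risk_root <- 0
  for (f in seq_len(cfg$n_folds)) {
    tr <- fold != f
    dtr <- subset_dataset(ds, which(tr))
    ftree <- grow_tree(dtr, cfg)
    fpath <- cost_complexity_path(ftree)
    p_tr <- ftree$p_treated
    Xval <- ds$covariates[!tr, , drop = FALSE]
    ystar <- transformed_outcome(ds$delta_ppfvc[!tr], ds$arm[!tr], p_tr)
    for (k in seq_len(K)) {
      sub <- path_subtree_at(fpath, betas[k])
      tau <- route_values(sub$root, Xval, "tau")
      risk[k] <- risk[k] + sum((ystar - tau)^2)
    }
    tau0 <- fpath[[length(fpath)]]$root$stats$tau_hat
    risk_root <- risk_root + sum((ystar - tau0)^2)
  }
  norm_risk <- risk / risk_root
  best <- max(which(norm_risk <= min(norm_risk) + 1e-12))
  list(alpha = alphas[best], index = best, path = mpath,
       curve = data.frame(alpha = alphas, beta = betas, cv_risk = risk,
                          norm_cv_risk = norm_risk))
}
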
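#' Tree-fitting configuration
#'
#' All tuning knobs of the causal-tree procedure. The defaults reproduce
#' the trial analysis settings: at least 5 patients from each arm in every
#' terminal node, and 5-fold cross-validation for pruning.
#'
#' @param min_per_arm minimum number of patients of each arm in every
#'   terminal node (default 5).
#' @param n_folds number of cross-validation folds for pruning (default 5).
#' @param estimate_mode `"full_sample"` (leaf effects estimated on all
#'   patients reaching the leaf; matches how subpopulation effects are
#'   reported) or `"honest_half"` (arm-stratified half split: structure and
#'   pruning from one half, leaf effects from the other).
#' @param max_depth optional cap on tree depth (`NULL` = unlimited).
#' @param seed integer seed driving fold assignment and the honest half
#'   split.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(min_per_arm = 5L, n_folds = 5L,
                       estimate_mode = c("full_sample", "honest_half"),
                       max_depth = NULL, seed = 1L) {
  estimate_mode <- match.arg(estimate_mode)
  stopifnot(min_per_arm >= 1L, n_folds >= 2L,
            is.null(max_depth) || max_depth >= 0L)
  structure(list(min_per_arm = as.integer(min_per_arm),
                 n_folds = as.integer(n_folds),
                 estimate_mode = estimate_mode,
                 max_depth = if (!is.null(max_depth)) as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Re-estimate every leaf's stats from (y, w, X) routed through the tree.
reestimate_leaves <- function(root, y, w, X) {
  rec <- function(node, idx) {
    if (node$is_leaf) {
      if (!length(idx) || !any(w[idx] == 1L) || !any(w[idx] == 0L))
        stop("estimation sample has an empty arm in a terminal node; ",
             "use estimate_mode = 'full_sample' or a larger sample")
      node$stats <- leaf_stats(y[idx], w[idx])
      return(node)
    }
    x <- X[[node$feature]][idx]
    low <- x < node$threshold
    node$low <- rec(node$low, idx[low])
    node$high <- rec(node$high, idx[!low])
    node
  }
  rec(root, seq_along(y))
}

#' Fit a cross-validation-pruned honest causal tree
#'
#' Orchestrates the full procedure: grow the tree ([grow_tree()]), build the
#' weakest-link cost-complexity path ([cost_complexity_path()]), select the
#' penalty by arm-stratified cross-validation ([cv_select_alpha()]), prune,
#' and estimate the terminal-node treatment effects according to
#' `cfg$estimate_mode`. Terminal nodes are labelled 1..L depth-first with
#' the high side of each split ("feature >= cut") first, so Leaf 1 is the
#' subpopulation satisfying all the high-side conditions of the first
#' splits.
#'
#' @param ds a [trial_dataset()] with `delta_ppfvc` derived.
#' @param cfg a [fit_config()].
#' @return A pruned `causal_tree` with `alpha_selected` set and a `cv`
#'   field holding the cross-validation curve.
#' @export
fit_causal_tree <- function(ds, cfg = fit_config()) {
  X <- ds$covariates[, ds$catalog$name, drop = FALSE]
  if (cfg$estimate_mode == "honest_half") {
    half <- arm_stratified_groups(ds$arm, 2L, cfg$seed)
    d_str <- subset_dataset(ds, which(half == 1L))
    sel <- cv_select_alpha(d_str, cfg)
  } else {
    sel <- cv_select_alpha(ds, cfg)
  }
  pruned <- sel$path[[sel$index]]$root
  if (cfg$estimate_mode == "honest_half") {
    est <- which(half == 2L)
    pruned <- reestimate_leaves(pruned, ds$delta_ppfvc[est], ds$arm[est],
                                X[est, , drop = FALSE])
  }
  tree <- structure(list(root = index_tree(pruned),
                         n_train = length(ds$arm),
                         p_treated = mean(ds$arm == 1L),
                         config = cfg,
                         alpha_selected = sel$alpha,
                         features = ds$catalog$name),
                    class = "causal_tree")
  tree$cv <- sel$curve
  tree
}

#' Route one covariate record to its terminal node
#'
#' Applies the tree's decision rules to a single record: at each split the
#' record goes to the low side when `feature < threshold`, to the high side
#' otherwise (a value exactly at the cut goes high).
#'
#' @param tree a fitted `causal_tree`.
#' @param record a named list, one-row data frame, or named vector holding
#'   every covariate the tree splits on.
#' @return The integer leaf label.
#' @export
assign_leaf <- function(tree, record) {
  record <- as.list(record)
  node <- tree$root
  while (!node$is_leaf) {
    v <- record[[node$feature]]
    if (is.null(v) || is.na(v))
      stop("record is missing routed feature '", node$feature, "'")
    node <- if (v < node$threshold) node$low else node$high
  }
  node$leaf_label
}

# Per-leaf rule conjunctions as interval conditions, tightest bound per
# feature, high-side leaves first (label order).
leaf_conditions <- function(tree) {
  out <- list()
  rec <- function(node, conds) {
    if (node$is_leaf) {
      out[[length(out) + 1L]] <<- list(label = node$leaf_label, conds = conds)
      return(invisible())
    }
    hi <- c(conds, list(list(feature = node$feature, op = ">=",
                             value = node$threshold)))
    lo <- c(conds, list(list(feature = node$feature, op = "<",
                             value = node$threshold)))
    rec(node$high, hi)
    rec(node$low, lo)
  }
  rec(tree$root, list())
  out
}

simplify_conds <- function(conds) {
  if (!length(conds)) return("(all patients)")
  feats <- unique(vapply(conds, `[[`, character(1), "feature"))
  parts <- character(0)
  for (f in feats) {
    lows <- vapply(Filter(function(c) c$feature == f && c$op == ">=", conds),
                   `[[`, numeric(1), "value")
    ups <- vapply(Filter(function(c) c$feature == f && c$op == "<", conds),
                  `[[`, numeric(1), "value")
    if (length(lows)) parts <- c(parts, sprintf("%s >= %g", f, max(lows)))
    if (length(ups)) parts <- c(parts, sprintf("%s < %g", f, min(ups)))
  }
  paste(parts, collapse = " and ")
}

#' Rule table of a fitted tree
#'
#' One row per terminal node, in leaf-label order: the conjunction of
#' interval conditions defining the subpopulation, per-arm counts, the
#' effect estimate and its 95% Welch confidence interval.
#'
#' @param tree a fitted `causal_tree`.
#' @return A data frame with columns `leaf_label`, `rule`, `n1`, `n0`,
#'   `tau`, `ci_low`, `ci_high`, `p`.
#' @export
tree_rules <- function(tree) {
  conds <- leaf_conditions(tree)
  leaves <- tree_leaves(tree$root)
  stopifnot(length(conds) == length(leaves))
  rows <- lapply(seq_along(leaves), function(i) {
    st <- leaves[[i]]$stats
    wt <- welch_from_stats(st$n1, st$mean1, st$var1, st$n0, st$mean0, st$var0)
    data.frame(leaf_label = leaves[[i]]$leaf_label,
               rule = simplify_conds(conds[[i]]$conds),
               n1 = st$n1, n0 = st$n0, tau = st$tau_hat,
               ci_low = wt$ci_low, ci_high = wt$ci_high, p = wt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$leaf_label), , drop = FALSE]
}

flatten_nodes <- function(node) {
  if (node$is_leaf) {
    st <- node$stats
    wt <- welch_from_stats(st$n1, st$mean1, st$var1, st$n0, st$mean0, st$var0)
    return(list(list(id = node$id, type = "leaf", n1 = st$n1, n0 = st$n0,
                     tau = st$tau_hat, ci_low = wt$ci_low,
                     ci_high = wt$ci_high, leaf_label = node$leaf_label)))
  }
  c(list(list(id = node$id, type = "split", feature = node$feature,
              threshold = node$threshold,
              children = c(node$low$id, node$high$id))),
    flatten_nodes(node$low), flatten_nodes(node$high))
}

#' Serialize a fitted tree
#'
#' Emits the human-readable rule table plus a JSON document that fully
#' encodes the tree (splits, thresholds, per-leaf statistics and the fit
#' configuration). `children` lists the low-side (`feature < threshold`)
#' child first, then the high-side child. [parse_tree_json()] restores an
#' object on which [assign_leaf()] reproduces the routing exactly.
#'
#' @param tree a fitted `causal_tree`.
#' @return A list with `rules` (data frame, see [tree_rules()]), `rule_text`
#'   (character vector, one line per leaf) and `json` (a JSON string).
#' @export
tree_to_rules <- function(tree) {
  rules <- tree_rules(tree)
  rule_text <- sprintf("Leaf %d: %s | n=%d+%d | effect=%.2f (%.2f, %.2f)",
                       rules$leaf_label, rules$rule, rules$n1, rules$n0,
                       rules$tau, rules$ci_low, rules$ci_high)
  doc <- list(n_train = tree$n_train, p_treated = tree$p_treated,
              alpha_selected = tree$alpha_selected,
              config = unclass(tree$config),
              nodes = flatten_nodes(tree$root))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  list(rules = rules, rule_text = rule_text, json = as.character(json))
}

#' Restore a tree from its JSON serialization
#'
#' @param json a JSON string or file path produced by [tree_to_rules()].
#' @return A `causal_tree` usable with [assign_leaf()], [tree_rules()] and
#'   [route_leaf_labels()].
#' @export
parse_tree_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- doc$nodes
  byid <- list()
  for (nd in nodes) byid[[as.character(nd$id)]] <- nd
  build <- function(id) {
    nd <- byid[[as.character(id)]]
    if (nd$type == "leaf") {
      st <- structure(list(n1 = nd$n1, n0 = nd$n0, mean1 = NA_real_,
                           mean0 = NA_real_, var1 = NA_real_,
                           var0 = NA_real_, tau_hat = nd$tau,
                           degenerate = NA),
                      class = "leaf_stats")
      node <- new_node(st)
      node$id <- nd$id; node$leaf_label <- nd$leaf_label
      return(node)
    }
    node <- new_node(NULL, feature = nd$feature, threshold = nd$threshold,
                     low = build(nd$children[[1]]),
                     high = build(nd$children[[2]]))
    node$id <- nd$id
    node
  }
  cfg <- doc$config
  structure(list(root = build(nodes[[1]]$id), n_train = doc$n_train,
                 p_treated = doc$p_treated,
                 alpha_selected = doc$alpha_selected,
                 config = cfg, features = NULL),
            class = "causal_tree")
}

#' Leaf labels for every row of a dataset
#'
#' Vectorized companion of [assign_leaf()].
#'
#' @param tree a fitted `causal_tree`.
#' @param ds a [trial_dataset()] (or a data frame of covariates).
#' @return Integer vector of leaf labels, one per row.
#' @export
route_leaf_labels <- function(tree, ds) {
  X <- if (inherits(ds, "trial_dataset")) ds$covariates else as.data.frame(ds)
  as.integer(route_values(tree$root, X, "label"))
}
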
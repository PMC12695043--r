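test_that("leaf_stats arithmetic and brute-force agreement", {
  st <- leaf_stats(c(2, 4, 1, 3), c(1, 1, 0, 0))
  expect_equal(st$tau_hat, 1)
  expect_equal(st$mean1, 3)
  expect_equal(st$mean0, 2)

  expect_equal(leaf_stats(c(5, 7, 5, 7), c(1, 1, 0, 0))$tau_hat, 0)
  expect_error(leaf_stats(1:3, c(1, 1, 1)), "both arms")

  set.seed(3)
  y <- rnorm(10); w <- c(rep(1, 5), rep(0, 5))
  st <- leaf_stats(y, w)
  expect_equal(st$mean1, sum(y[1:5]) / 5)
  expect_equal(st$var1, sum((y[1:5] - mean(y[1:5]))^2) / 4)
  expect_equal(st$var0, sum((y[6:10] - mean(y[6:10]))^2) / 4)
  expect_equal(st$tau_hat, st$mean1 - st$mean0)
})

test_that("EMSE criterion closed forms and formula oracle", {
  # constant data: both terms vanish
  expect_equal(emse_criterion(leaf_stats(rep(3, 6), rep(0:1, 3)), 6, 0.5), 0)

  # two zero-variance children vs the unsplit root (8 patients, p = 1/2)
  left <- leaf_stats(c(-1, -1, 0, 0), c(1, 1, 0, 0))
  right <- leaf_stats(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(emse_criterion(list(left, right), 8, 0.5), 1.0)
  root <- leaf_stats(c(-1, -1, 1, 1, 0, 0, 0, 0),
                     c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(emse_criterion(root, 8, 0.5), -2 / 3)

  expect_error(emse_criterion(list(left), 4, 1.2), "p must lie")

  # arbitrary random partition equals term-by-term recomputation
  set.seed(5)
  y <- rnorm(30); w <- rbinom(30, 1, 0.5); g <- rep(1:3, each = 10)
  w[1:2] <- c(0, 1); w[11:12] <- c(0, 1); w[21:22] <- c(0, 1)
  leaves <- lapply(1:3, function(k) leaf_stats(y[g == k], w[g == k]))
  p <- mean(w)
  manual <- sum(sapply(1:3, function(k) {
    yk <- y[g == k]; wk <- w[g == k]
    nk <- length(yk)
    tau <- mean(yk[wk == 1]) - mean(yk[wk == 0])
    nk * tau^2 / 30 - (2 / 30) * (var(yk[wk == 1]) / p +
                                    var(yk[wk == 0]) / (1 - p))
  }))
  expect_equal(emse_criterion(leaves, 30, p), manual)
})

test_that("transformed outcome formula and mean identity", {
  expect_equal(transformed_outcome(3, 1, 0.5), 6)
  expect_equal(transformed_outcome(3, 0, 0.5), -6)
  ys <- transformed_outcome(c(2, 4, 1, 3), c(1, 1, 0, 0), 0.5)
  expect_equal(ys, c(4, 8, -2, -6))
  expect_equal(mean(ys), 1.0)

  # mean(y*) = root tau_hat to 12 significant digits at the empirical share
  set.seed(7)
  y <- rnorm(57); w <- rbinom(57, 1, 0.4); w[1:2] <- 0:1
  tau <- leaf_stats(y, w)$tau_hat
  expect_equal(mean(transformed_outcome(y, w, mean(w))), tau,
               tolerance = 1e-12)
})

test_that("best_split finds the planted separator with its closed-form gain", {
  y <- c(-1, -1, 0, 0, 1, 1, 0, 0)
  w <- c(1, 1, 0, 0, 1, 1, 0, 0)
  X <- data.frame(f = c(0, 0, 0, 0, 1, 1, 1, 1))
  bs <- best_split(y, w, X, fit_config(min_per_arm = 1), p = 0.5)
  expect_equal(bs$feature, "f")
  expect_equal(bs$threshold, 0.5)
  expect_equal(bs$gain, 5 / 3)
  expect_equal(bs$left_stats$tau_hat, -1)
  expect_equal(bs$right_stats$tau_hat, 1)
})

test_that("best_split returns NULL when the per-arm minimum is unreachable", {
  nd <- random_node(16, 2, seed = 21)
  expect_null(best_split(nd$y, nd$w, nd$X, fit_config(min_per_arm = 5)))
})

test_that("best_split equals exhaustive search on a random node", {
  nd <- random_node(30, 4, seed = 11)
  cfg <- fit_config(min_per_arm = 3)
  bs <- best_split(nd$y, nd$w, nd$X, cfg, p = mean(nd$w))
  oracle <- exhaustive_best_split(nd$y, nd$w, 3, nd$X, mean(nd$w))
  expect_equal(bs$feature, oracle$feature)
  expect_equal(bs$threshold, oracle$threshold)
  expect_equal(bs$criterion, oracle$crit)
})

test_that("grow_tree respects size bounds and finds a planted threshold", {
  # 6 + 6 patients cannot give both children 5 per arm -> root only
  set.seed(1)
  cat1 <- data.frame(name = "x", kind = "continuous", unit = "",
                     description = "")
  cov <- data.frame(x = rnorm(12))
  ds <- trial_dataset(sprintf("P%d", 1:12), rep(0:1, 6),
                      cbind(`0` = rep(80, 12), `24` = rnorm(12, 80)),
                      cov, catalog = cat1)
  ds <- compute_delta_ppfvc(ds, 24)
  tr <- grow_tree(ds, fit_config(min_per_arm = 5))
  expect_true(tr$root$is_leaf)

  # planted single-threshold effect, n = 200, noise sd 1
  set.seed(2)
  n <- 200
  w <- rbinom(n, 1, 0.5)
  x <- runif(n)
  z <- rnorm(n)  # pure-noise competitor feature
  tau <- ifelse(x >= 0.5, 4, -4)
  y <- w * tau + rnorm(n, sd = 1)
  cat2 <- data.frame(name = c("x", "z"), kind = "continuous", unit = "",
                     description = "")
  ds2 <- trial_dataset(sprintf("P%d", 1:n), w,
                       cbind(`0` = rep(80, n), `24` = 80 + y),
                       data.frame(x = x, z = z), catalog = cat2)
  ds2 <- compute_delta_ppfvc(ds2, 24)
  tr2 <- grow_tree(ds2, fit_config())
  expect_equal(tr2$root$feature, "x")
  # the fitted cut sits at the planted boundary, up to a few order
  # statistics of slack at this sample size and noise level
  expect_lt(abs(tr2$root$threshold - 0.5), 0.05)

  # per-arm minimum holds in every terminal node
  leaves <- hctree:::tree_leaves(tr2$root)
  expect_true(all(sapply(leaves, function(l) min(l$stats$n1, l$stats$n0) >= 5)))

  # covariate missingness is a fit-time error
  ds2$covariates$x[3] <- NA
  expect_error(grow_tree(ds2, fit_config()), "missing covariate.*x")
})

test_that("cost-complexity path matches a manual weakest-link computation", {
  # hand-built 3-leaf tree, N = 40, p = 0.5, zero-variance leaves:
  # leaf risks -4, -0.25, -0.5; collapsed stats chosen so that the manual
  # weakest-link values are g(B) = 1.12 and, after collapsing B,
  # g(root) = 3.23.
  L1 <- hand_leaf(make_stats(5, 5, tau = 4))
  L2 <- hand_leaf(make_stats(5, 5, tau = 1))
  L3 <- hand_leaf(make_stats(10, 10, tau = -1))
  B <- hand_split("x2", 0.5, low = L3, high = L2,
                  stats = make_stats(15, 15, tau = -0.2, var1 = 2, var0 = 2))
  root <- hand_split("x1", 0.5, low = B, high = L1,
                     stats = make_stats(20, 20, tau = 1, var1 = 3, var0 = 3))
  tree <- hand_tree(root, n_train = 40, p = 0.5)

  path <- cost_complexity_path(tree)
  alphas <- sapply(path, `[[`, "alpha")
  sizes <- sapply(path, `[[`, "n_leaves")
  expect_equal(alphas, c(0, 1.12, 3.23), tolerance = 1e-10)
  expect_equal(sizes, c(3L, 2L, 1L))
  # inner subtree collapsed B (kept the L1 split), last is root-only
  expect_equal(path[[2]]$root$feature, "x1")
  expect_true(path[[2]]$root$low$is_leaf)
  expect_true(path[[3]]$root$is_leaf)
})

test_that("path alphas strictly increase and subtrees are nested", {
  nd <- random_node(120, 3, seed = 13)
  cat3 <- data.frame(name = names(nd$X), kind = "continuous", unit = "",
                     description = "")
  ds <- trial_dataset(sprintf("P%d", seq_along(nd$y)), nd$w,
                      cbind(`0` = rep(80, length(nd$y)), `24` = 80 + nd$y),
                      nd$X, catalog = cat3)
  ds <- compute_delta_ppfvc(ds, 24)
  tr <- grow_tree(ds, fit_config(min_per_arm = 2))
  path <- cost_complexity_path(tr)
  alphas <- sapply(path, `[[`, "alpha")
  sizes <- sapply(path, `[[`, "n_leaves")
  expect_true(all(diff(alphas) > 0))
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[length(sizes)], 1L)

  # nesting: every split of a later subtree appears in every earlier one
  split_set <- function(node) {
    if (node$is_leaf) return(character(0))
    c(sprintf("%s@%.12g", node$feature, node$threshold),
      split_set(node$low), split_set(node$high))
  }
  sets <- lapply(path, function(e) split_set(e$root))
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
})

test_that("degenerate CV selection returns the root", {
  ds <- compute_delta_ppfvc(
    locf_impute_outcome(
      generate_trial(simulation_config(n = 18, seed = 5)), 24), 24)
  # 9 per arm with min 5/arm: no admissible split, tree is root-only,
  # and the maximal (only) path alpha is selected
  sel <- cv_select_alpha(ds, fit_config(seed = 5))
  expect_equal(sel$index, length(sel$path))
  expect_true(sel$path[[sel$index]]$root$is_leaf)
})

test_that("fit is deterministic and honest_half re-estimates leaves", {
  cfg <- simulation_config(n = 400, noise_sd = 3, seed = 9)
  ds <- compute_delta_ppfvc(locf_impute_outcome(generate_trial(cfg), 24), 24)
  t1 <- fit_causal_tree(ds, fit_config(seed = 4))
  t2 <- fit_causal_tree(ds, fit_config(seed = 4))
  expect_identical(tree_to_rules(t1)$json, tree_to_rules(t2)$json)

  th <- fit_causal_tree(ds, fit_config(seed = 4,
                                       estimate_mode = "honest_half"))
  leaves <- hctree:::tree_leaves(th$root)
  # estimation half holds about half the patients
  expect_lt(sum(sapply(leaves, function(l) l$stats$n1 + l$stats$n0)),
            length(ds$arm))
})

test_that("leaf assignment follows the >= goes-high convention", {
  # tree shaped like the published one: CRP at 0.055, then KL6 at 364
  json <- '{
    "n_train": 48, "p_treated": 0.52, "alpha_selected": 0.1,
    "config": {"min_per_arm": 5},
    "nodes": [
      {"id": 1, "type": "split", "feature": "CRP", "threshold": 0.055,
       "children": [2, 6]},
      {"id": 2, "type": "split", "feature": "KL6", "threshold": 364,
       "children": [5, 4]},
      {"id": 6, "type": "leaf", "n1": 10, "n0": 12, "tau": 8.01,
       "ci_low": 4.4, "ci_high": 11.62, "leaf_label": 1},
      {"id": 4, "type": "leaf", "n1": 8, "n0": 6, "tau": 2.47,
       "ci_low": -1.99, "ci_high": 6.92, "leaf_label": 2},
      {"id": 5, "type": "leaf", "n1": 7, "n0": 5, "tau": -6.85,
       "ci_low": -10.8, "ci_high": -2.91, "leaf_label": 3}
    ]}'
  tree <- parse_tree_json(json)
  expect_equal(assign_leaf(tree, list(CRP = 0.2, KL6 = 100)), 1L)
  expect_equal(assign_leaf(tree, list(CRP = 0.0, KL6 = 500)), 2L)
  expect_equal(assign_leaf(tree, list(CRP = 0.0, KL6 = 200)), 3L)
  # exactly at the threshold goes high
  expect_equal(assign_leaf(tree, list(CRP = 0.055, KL6 = 0)), 1L)
  expect_equal(assign_leaf(tree, list(CRP = 0.054, KL6 = 364)), 2L)
  # low-CRP routing needs KL6; its absence is a named error
  expect_error(assign_leaf(tree, list(CRP = 0.0)), "KL6")
})

test_that("rule text and JSON round trip", {
  L1 <- hand_leaf(make_stats(10, 12, tau = 8.01, var1 = 20, var0 = 18))
  L2 <- hand_leaf(make_stats(8, 6, tau = 2.47, var1 = 15, var0 = 12))
  L3 <- hand_leaf(make_stats(7, 5, tau = -6.85, var1 = 9, var0 = 8))
  B <- hand_split("KL6", 364, low = L3, high = L2,
                  stats = make_stats(15, 11, tau = -1, var1 = 30, var0 = 25))
  root <- hand_split("CRP", 0.055, low = B, high = L1,
                     stats = make_stats(25, 23, tau = 2, var1 = 40, var0 = 35))
  tree <- hand_tree(root, 48, p = 25 / 48)

  ser <- tree_to_rules(tree)
  expect_equal(ser$rules$rule,
               c("CRP >= 0.055", "CRP < 0.055 and KL6 >= 364",
                 "CRP < 0.055 and KL6 < 364"))
  expect_match(ser$rule_text[1], "^Leaf 1: CRP >= 0.055 \\| n=10\\+12")

  # root-only tree
  solo <- hand_tree(hand_leaf(make_stats(25, 23, tau = 1.2, var1 = 2,
                                         var0 = 2)), 48)
  expect_equal(tree_to_rules(solo)$rules$rule, "(all patients)")

  # JSON round trip reproduces routing on 1000 random records
  back <- parse_tree_json(ser$json)
  set.seed(4)
  recs <- data.frame(CRP = round(runif(1000, 0, 0.3), 2),
                     KL6 = round(runif(1000, 50, 1200)))
  for (i in sample(1000, 60))
    expect_equal(assign_leaf(back, recs[i, ]), assign_leaf(tree, recs[i, ]))
  expect_equal(route_leaf_labels(back, recs), route_leaf_labels(tree, recs))
})
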
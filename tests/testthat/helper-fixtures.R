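# Shared fixtures and independent oracles for the test suite.

# Minimal 4-patient dataset with visit weeks 0 and 24 and all-catalog
# covariates filled with valid constants.
tiny_dataset <- function(arm = c(1L, 1L, 0L, 0L),
                         w0 = c(85, 90, 80, 88),
                         w24 = c(86.6, 90, 78, 85)) {
  n <- length(arm)
  catalog <- covariate_catalog()
  cov <- as.data.frame(lapply(seq_len(nrow(catalog)), function(j) {
    if (catalog$kind[j] == "binary") rep(0, n) else rep(1 + j, n)
  }))
  names(cov) <- catalog$name
  ppfvc <- cbind(`0` = w0, `24` = w24)
  trial_dataset(patient_id = sprintf("P%d", seq_len(n)), arm = arm,
                ppfvc = ppfvc, covariates = cov, catalog = catalog)
}

# Random node data for split-search oracles.
random_node <- function(n, n_feat, seed, p_treat = 0.5) {
  withr_seed <- function(code) code  # placeholder, use set.seed directly
  set.seed(seed)
  w <- integer(n)
  w[sample.int(n, round(n * p_treat))] <- 1L
  X <- as.data.frame(matrix(rnorm(n * n_feat), n, n_feat))
  names(X) <- sprintf("f%d", seq_len(n_feat))
  y <- rnorm(n)
  list(y = y, w = w, X = X)
}

# Exhaustive admissible-split search written independently of best_split:
# loops over features and all adjacent-midpoint thresholds, scoring each
# candidate with leaf_stats + emse_criterion directly.
exhaustive_best_split <- function(y, w, m, X, p, n_total = length(y)) {
  best <- NULL
  for (nm in names(X)) {
    x <- X[[nm]]
    xs <- sort(unique(x))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      low <- x < thr
      if (min(sum(w[low] == 1), sum(w[low] == 0),
              sum(w[!low] == 1), sum(w[!low] == 0)) < m) next
      crit <- emse_criterion(list(leaf_stats(y[low], w[low]),
                                  leaf_stats(y[!low], w[!low])),
                             n_total, p)
      if (is.null(best) || crit > best$crit + 1e-12) {
        best <- list(feature = nm, threshold = thr, crit = crit)
      }
    }
  }
  if (is.null(best)) return(NULL)
  base <- emse_criterion(leaf_stats(y, w), n_total, p)
  if (!(best$crit - base > 0)) return(NULL)
  best
}

# leaf_stats object from explicit numbers (mean0 fixed at 0).
make_stats <- function(n1, n0, tau, var1 = 0, var0 = 0) {
  structure(list(n1 = n1, n0 = n0, mean1 = tau, mean0 = 0,
                 var1 = var1, var0 = var0, tau_hat = tau,
                 degenerate = n1 < 2 || n0 < 2),
            class = "leaf_stats")
}

# Hand-built tree node helpers (mirror the documented node fields).
hand_leaf <- function(stats) {
  list(is_leaf = TRUE, feature = NULL, threshold = NULL, low = NULL,
       high = NULL, stats = stats, leaf_label = NA_integer_,
       id = NA_integer_)
}
hand_split <- function(feature, threshold, low, high, stats) {
  list(is_leaf = FALSE, feature = feature, threshold = threshold,
       low = low, high = high, stats = stats, leaf_label = NA_integer_,
       id = NA_integer_)
}
hand_tree <- function(root, n_train, p = 0.5) {
  structure(list(root = hctree:::index_tree(root), n_train = n_train,
                 p_treated = p, config = fit_config(),
                 alpha_selected = NA_real_, features = NULL),
            class = "causal_tree")
}

# Brute-force two-sided Wilcoxon p by complete enumeration of all
# choose(m+n, m) group assignments of the pooled sample.
enumeration_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Generated-then-loaded dataset pair for round-trip tests.
roundtrip_pair <- function(cfg) {
  ds <- generate_trial(cfg)
  path <- tempfile(fileext = ".csv")
  write_trial_table(ds, path)
  list(original = ds, reloaded = load_trial_table(path), path = path)
}
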
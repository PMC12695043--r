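# Synthetic two-arm trial generator with planted threshold-defined
# heterogeneous treatment effects (a stand-in for the non-public
# patient-level trial data; all marginals are calibrated to the published
# baseline table).

default_covariate_params <- function() {
  ln <- function(median, sdlog, round = NA) {
    list(kind = "lognormal", meanlog = log(median), sdlog = sdlog,
         round = round)
  }
  bern <- function(prev) list(kind = "bernoulli", prev = prev)
  list(
    sex = bern(0.917), prev_immunosuppressants = bern(0.542),
    diffuse_cutaneous = bern(0.813), puffy_fingers = bern(0.854),
    skin_ulcer = bern(0.667), reflux_esophagitis = bern(0.917),
    barrett_esophagus = bern(0.146), arthritis = bern(0.271),
    age = ln(48, 0.25, 0), disease_duration = ln(76.5, 1.0, 0),
    MRSS = ln(13.5, 0.2, 0), ATA_titre = ln(93.5, 0.9, 1),
    ACA_titre = ln(4.9, 0.8, 1), ARA_titre = ln(4.9, 0.5, 1),
    CD19 = ln(180, 0.6, 0), CD20 = ln(180, 0.6, 0),
    ppFVC = ln(85.8, 0.13, 1), DLco = ln(79.5, 0.2, 1),
    KL6 = ln(453.5, 0.8, 0),
    SPA = ln(33.1, 0.45, 1), SPD = ln(141.4, 0.6, 1),
    total_protein = ln(7.0, 0.06, 1),
    CRP = list(kind = "zero_inflated_lognormal", p_zero = 0.5,
               meanlog = log(0.15), sdlog = 1.0, round = 2),
    IgG = ln(1305, 0.25, 0), IgM = ln(114.5, 0.5, 0),
    BNP = ln(17.4, 0.8, 1), haemoglobin = ln(12.5, 0.08, 1),
    interstitial_shadow = ln(11, 0.8, 0)
  )
}

#' Simulation configuration
#'
#' Describes the planted world: a two-arm trial whose treatment effect on
#' the change in ppFVC is a step function of baseline CRP and KL-6, with
#' leaf effects and placebo-arm drifts defaulting to the published
#' subpopulation values, covariate marginals calibrated to the published
#' baseline table, and the published pattern of missing week-24 outcomes.
#'
#' @param n number of patients (default 48).
#' @param treat_frac treated share (default 25/48).
#' @param crp_cut CRP threshold in mg/dl (default 0.055).
#' @param kl6_cut KL-6 threshold in U/ml (default 364).
#' @param leaf_effects treatment effects (percentage points of ppFVC) for
#'   the three planted subpopulations (CRP high; CRP low / KL-6 high;
#'   CRP low / KL-6 low); defaults `c(8.01, 2.47, -6.85)`.
#' @param control_means placebo-arm mean change per subpopulation; defaults
#'   `c(-6.40, -3.70, 6.12)`.
#' @param noise_sd residual standard deviation in percentage points
#'   (default 5).
#' @param missing_frac fraction of control patients with a missing week-24
#'   ppFVC (default 3/23).
#' @param covariate_params per-covariate distribution settings; see
#'   the methods vignette for the calibration.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 48L, treat_frac = 25 / 48,
                              crp_cut = 0.055, kl6_cut = 364,
                              leaf_effects = c(8.01, 2.47, -6.85),
                              control_means = c(-6.40, -3.70, 6.12),
                              noise_sd = 5, missing_frac = 3 / 23,
                              covariate_params = default_covariate_params(),
                              seed = 1L) {
  stopifnot(n >= 2, treat_frac > 0, treat_frac < 1,
            length(leaf_effects) == 3, length(control_means) == 3,
            noise_sd >= 0, missing_frac >= 0, missing_frac < 1)
  structure(list(n = as.integer(n), treat_frac = treat_frac,
                 crp_cut = crp_cut, kl6_cut = kl6_cut,
                 leaf_effects = leaf_effects, control_means = control_means,
                 noise_sd = noise_sd, missing_frac = missing_frac,
                 covariate_params = covariate_params,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

round_if <- function(x, digits) if (is.na(digits)) x else round(x, digits)

sample_covariates_impl <- function(cfg, n) {
  params <- cfg$covariate_params
  catalog <- covariate_catalog()
  out <- lapply(catalog$name, function(nm) {
    pr <- params[[nm]]
    if (is.null(pr)) stop("no covariate_params entry for '", nm, "'")
    switch(pr$kind,
      bernoulli = stats::rbinom(n, 1L, pr$prev),
      lognormal = round_if(stats::rlnorm(n, pr$meanlog, pr$sdlog), pr$round),
      zero_inflated_lognormal = {
        nonzero <- stats::rbinom(n, 1L, 1 - pr$p_zero)
        v <- stats::rlnorm(n, pr$meanlog, pr$sdlog)
        round_if(nonzero * v, pr$round)
      },
      stop("unknown covariate distribution kind: ", pr$kind))
  })
  names(out) <- catalog$name
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Draw the baseline covariate table
#'
#' Draws all 28 catalog covariates for `cfg$n` patients under `cfg$seed`:
#' Bernoulli binaries at the published prevalences; right-skewed log-normal
#' continuous variables with medians near the published ones; CRP
#' zero-inflated (point mass at 0, else log-normal) and rounded to 2
#' decimals; KL-6 rounded to integers, so midpoint split thresholds land on
#' values like 0.055 and half-integers.
#'
#' @param cfg a [simulation_config()].
#' @return A data frame with one column per catalog covariate.
#' @export
sample_covariates <- function(cfg) {
  with_seed(cfg$seed, sample_covariates_impl(cfg, cfg$n))
}

#' Planted treatment effect of a covariate record
#'
#' The generator's ground truth: `leaf_effects[1]` when `CRP >= crp_cut`,
#' else `leaf_effects[2]` when `KL6 >= kl6_cut`, else `leaf_effects[3]`.
#'
#' @param record a data frame, named list or named vector with `CRP` and
#'   `KL6` (vectorized over data-frame rows).
#' @param cfg a [simulation_config()].
#' @return Numeric vector of planted effects (percentage points).
#' @export
true_tau <- function(record, cfg = simulation_config()) {
  cfg$leaf_effects[true_leaf(record, cfg)]
}

#' Planted subpopulation of a covariate record
#'
#' @inheritParams true_tau
#' @return Integer vector of planted leaf indices (1 = CRP high,
#'   2 = CRP low / KL-6 high, 3 = CRP low / KL-6 low).
#' @export
true_leaf <- function(record, cfg = simulation_config()) {
  record <- as.list(as.data.frame(as.list(record)))
  crp <- record$CRP; kl6 <- record$KL6
  if (is.null(crp) || is.null(kl6) || anyNA(crp) || anyNA(kl6))
    stop("record must contain non-missing CRP and KL6")
  ifelse(crp >= cfg$crp_cut, 1L, ifelse(kl6 >= cfg$kl6_cut, 2L, 3L))
}

#' Generate a synthetic two-arm trial
#'
#' Composes the planted model into a loadable [trial_dataset()]: exact
#' `round(n * treat_frac)` treated patients by permuted allocation; week-0
#' ppFVC equal to the baseline ppFVC covariate; week-12 and week-24 ppFVC
#' each equal to week-0 plus the subpopulation's control drift, plus the
#' planted effect for treated patients, plus independent Gaussian noise
#' (the drift is fully realized by week 12, so carrying the week-12 value
#' forward leaves the planted effects unbiased); week-24 values of a
#' `missing_frac` share of control patients set missing.
#'
#' @param cfg a [simulation_config()].
#' @return A [trial_dataset()] with visit weeks 0, 12, 24.
#' @export
generate_trial <- function(cfg = simulation_config()) {
  n <- cfg$n
  n1 <- round(n * cfg$treat_frac)
  if (n1 < 1 || n1 > n - 1)
    stop("n and treat_frac leave an arm empty")
  with_seed(cfg$seed, {
    cov <- sample_covariates_impl(cfg, n)
    arm <- integer(n)
    arm[sample.int(n, n1)] <- 1L
    leaf <- true_leaf(cov, cfg)
    mu <- cfg$control_means[leaf] + arm * cfg$leaf_effects[leaf]
    w0 <- cov$ppFVC
    w12 <- w0 + mu + stats::rnorm(n, 0, cfg$noise_sd)
    w24 <- w0 + mu + stats::rnorm(n, 0, cfg$noise_sd)
    ppfvc <- cbind(`0` = w0, `12` = w12, `24` = w24)
    ds <- trial_dataset(patient_id = sprintf("P%04d", seq_len(n)),
                        arm = arm, ppfvc = ppfvc, covariates = cov)
    if (cfg$missing_frac > 0)
      ds <- inject_missing_impl(ds, cfg$missing_frac)
    ds
  })
}

inject_missing_impl <- function(ds, frac) {
  ctrl <- which(ds$arm == 0L)
  k <- round(frac * length(ctrl))
  if (k > 0) {
    drop <- sample(ctrl, k)
    ds$ppfvc[drop, "24"] <- NA_real_
  }
  ds
}

#' Inject missing week-24 outcomes
#'
#' Sets the week-24 ppFVC to missing for a seeded random subset of control
#' patients (`round(frac * n_control)` of them), emulating the published
#' missingness pattern (all missing outcomes on the placebo arm).
#'
#' @param ds a [trial_dataset()] with a week-24 visit.
#' @param frac fraction of control patients to blank, in \[0, 1).
#' @param seed integer seed.
#' @return The modified dataset.
#' @export
inject_missing_outcomes <- function(ds, frac, seed = 1L) {
  if (frac >= 1 || frac < 0) stop("frac must lie in [0, 1)")
  if (frac == 0) return(ds)
  with_seed(seed, inject_missing_impl(ds, frac))
}

#' Read a simulation configuration from a flat key-value file
#'
#' One `key = value` pair per line (`#` starts a comment); keys are the
#' scalar/vector fields of [simulation_config()]; vector values are
#' comma-separated. Unknown keys are an error. Covariate distribution
#' settings are not file-configurable and keep their defaults.
#'
#' @param path path to the config file.
#' @param seed optional seed overriding the file's.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  numeric_keys <- c("n", "treat_frac", "crp_cut", "kl6_cut", "leaf_effects",
                    "control_means", "noise_sd", "missing_frac", "seed")
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(p[2])
    if (!key %in% numeric_keys) stop("unknown config key: ", key)
    args[[key]] <- as.numeric(trimws(strsplit(val, ",")[[1]]))
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_config, args)
}
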
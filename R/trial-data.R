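#' Construct a patient-level trial dataset
#'
#' Container for a two-arm trial table: one row per patient with an arm
#' indicator (0 = placebo, 1 = active), percent-predicted FVC by visit week,
#' and baseline covariates aligned to a covariate catalog
#' (see [covariate_catalog()]).
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param arm integer vector of 0/1 arm indicators (1 = active treatment).
#' @param ppfvc numeric matrix, one row per patient, one column per visit
#'   week; column names are the non-negative integer week numbers. A week-0
#'   column is mandatory and must be complete.
#' @param covariates data frame of baseline covariates, columns named and
#'   typed per `catalog`. Missing values are allowed here (they are flagged)
#'   but are rejected at tree-fitting time.
#' @param catalog covariate catalog data frame; defaults to the 28-entry
#'   SSc-ILD catalog.
#' @param delta_ppfvc optional numeric vector of the derived outcome
#'   (change in ppFVC, percentage points); normally filled in by
#'   [compute_delta_ppfvc()].
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(patient_id, arm, ppfvc, covariates,
                          catalog = covariate_catalog(),
                          delta_ppfvc = NULL) {
  validate_catalog(catalog)
  patient_id <- as.character(patient_id)
  arm <- as.integer(arm)
  ppfvc <- as.matrix(ppfvc)
  storage.mode(ppfvc) <- "double"
  ds <- structure(list(patient_id = patient_id, arm = arm, ppfvc = ppfvc,
                       covariates = covariates, catalog = catalog,
                       delta_ppfvc = delta_ppfvc,
                       locf_imputed = character(0)),
                  class = "trial_dataset")
  validate_trial_dataset(ds)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d patients (%d treated, %d control), weeks %s\n",
              length(x$patient_id), sum(x$arm == 1L), sum(x$arm == 0L),
              paste(trial_weeks(x), collapse = "/")))
  cat(sprintf("  covariates: %d (%d binary, %d continuous)\n",
              nrow(x$catalog), sum(x$catalog$kind == "binary"),
              sum(x$catalog$kind == "continuous")))
  if (!is.null(x$delta_ppfvc))
    cat(sprintf("  delta ppFVC present (mean %.2f)\n",
                mean(x$delta_ppfvc)))
  invisible(x)
}

#' Visit weeks of a dataset
#' @param ds a [trial_dataset()].
#' @return Sorted integer vector of visit weeks.
#' @export
trial_weeks <- function(ds) sort(as.integer(colnames(ds$ppfvc)))

validate_trial_dataset <- function(ds) {
  n <- length(ds$patient_id)
  if (anyDuplicated(ds$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(ds$patient_id[duplicated(ds$patient_id)]), collapse = ", "))
  if (!all(ds$arm %in% c(0L, 1L))) {
    bad <- which(!(ds$arm %in% c(0L, 1L)))
    stop("arm must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  if (sum(ds$arm == 1L) == 0L || sum(ds$arm == 0L) == 0L)
    stop("both arms must be non-empty")
  if (nrow(ds$ppfvc) != n || nrow(ds$covariates) != n)
    stop("ppfvc and covariates must have one row per patient")
  wk <- suppressWarnings(as.integer(colnames(ds$ppfvc)))
  if (anyNA(wk) || any(wk < 0))
    stop("ppfvc columns must be named by non-negative integer week")
  if (!"0" %in% colnames(ds$ppfvc))
    stop("week-0 ppFVC column is required")
  if (anyNA(ds$ppfvc[, "0"]))
    stop("missing week-0 ppFVC for patient(s): ",
         paste(ds$patient_id[is.na(ds$ppfvc[, "0"])], collapse = ", "))
  # covariates must match the catalog and respect their declared kind
  miss_cols <- setdiff(ds$catalog$name, names(ds$covariates))
  if (length(miss_cols))
    stop("covariate column(s) missing: ", paste(miss_cols, collapse = ", "))
  for (j in seq_len(nrow(ds$catalog))) {
    nm <- ds$catalog$name[j]
    v <- ds$covariates[[nm]]
    ok <- is.na(v) |
      (if (ds$catalog$kind[j] == "binary") v %in% c(0, 1) else is.finite(v))
    if (!all(ok))
      stop(sprintf("covariate '%s' has value(s) outside its %s domain", nm,
                   ds$catalog$kind[j]))
  }
  if (!is.null(ds$delta_ppfvc) && length(ds$delta_ppfvc) != n)
    stop("delta_ppfvc length mismatch")
  ds
}

ppfvc_col <- function(week) sprintf("ppfvc_w%d", as.integer(week))

#' Read a trial table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and columns
#' `patient_id`, `arm`, `ppfvc_w<k>` for each visit week `k`, plus one
#' column per catalog covariate. The string `NA` denotes a missing value.
#'
#' @param path path to the CSV file.
#' @param catalog covariate catalog the columns must match.
#' @return A validated [trial_dataset()]; row order is preserved.
#' @export
load_trial_table <- function(path, catalog = covariate_catalog()) {
  validate_catalog(catalog)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "NA")
  expected_fixed <- c("patient_id", "arm")
  ppfvc_cols <- grep("^ppfvc_w[0-9]+$", names(raw), value = TRUE)
  known <- c(expected_fixed, ppfvc_cols, catalog$name)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  miss <- setdiff(c(expected_fixed, catalog$name), names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (!length(ppfvc_cols))
    stop("no ppfvc_w<week> columns found in ", path)
  weeks <- sort(as.integer(sub("^ppfvc_w", "", ppfvc_cols)))
  ppfvc <- as.matrix(raw[, ppfvc_col(weeks), drop = FALSE])
  colnames(ppfvc) <- as.character(weeks)
  trial_dataset(patient_id = raw$patient_id, arm = raw$arm, ppfvc = ppfvc,
                covariates = raw[, catalog$name, drop = FALSE],
                catalog = catalog)
}

#' Write a trial table to CSV
#'
#' Emits the same dialect [load_trial_table()] reads, with a fixed header
#' order: `patient_id`, `arm`, ppFVC columns ascending by week, then the
#' covariates in catalog order. Values are written with enough digits that
#' a load/write/load round trip is value-identical to at least 12
#' significant digits.
#'
#' @param ds a [trial_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(ds, path) {
  weeks <- trial_weeks(ds)
  out <- data.frame(patient_id = ds$patient_id, arm = ds$arm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (w in weeks) out[[ppfvc_col(w)]] <- fmt_num(ds$ppfvc[, as.character(w)])
  for (nm in ds$catalog$name) out[[nm]] <- fmt_num(ds$covariates[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Last-observation-carried-forward imputation of the outcome visit
#'
#' For each patient whose ppFVC at `target_week` is missing, substitutes the
#' value of the latest earlier visit with a non-missing measurement.
#' Patients already complete are untouched. The identifiers of the imputed
#' patients are recorded in the returned dataset's `locf_imputed` field.
#'
#' @param ds a [trial_dataset()].
#' @param target_week the outcome visit week (must be a known visit).
#' @return The dataset with a complete `target_week` column.
#' @export
locf_impute_outcome <- function(ds, target_week = 24L) {
  weeks <- trial_weeks(ds)
  if (!target_week %in% weeks)
    stop("target week ", target_week, " is not a visit week (",
         paste(weeks, collapse = ", "), ")")
  tw <- as.character(target_week)
  missing_idx <- which(is.na(ds$ppfvc[, tw]))
  earlier <- as.character(sort(weeks[weeks < target_week], decreasing = TRUE))
  imputed <- character(0)
  for (i in missing_idx) {
    filled <- FALSE
    for (w in earlier) {
      if (!is.na(ds$ppfvc[i, w])) {
        ds$ppfvc[i, tw] <- ds$ppfvc[i, w]
        filled <- TRUE
        break
      }
    }
    if (!filled)
      stop("no earlier non-missing ppFVC to carry forward for patient(s): ",
           ds$patient_id[i])
    imputed <- c(imputed, ds$patient_id[i])
  }
  ds$locf_imputed <- imputed
  ds
}

#' Derive the change-from-baseline outcome
#'
#' Computes `delta_ppfvc = ppfvc[target_week] - ppfvc[0]` per patient, in
#' percentage points. The target-week column must be complete; run
#' [locf_impute_outcome()] first when measurements are missing.
#'
#' @inheritParams locf_impute_outcome
#' @return The dataset with `delta_ppfvc` filled in.
#' @export
compute_delta_ppfvc <- function(ds, target_week = 24L) {
  weeks <- trial_weeks(ds)
  if (!target_week %in% weeks)
    stop("target week ", target_week, " is not a visit week")
  tw <- as.character(target_week)
  if (anyNA(ds$ppfvc[, tw]))
    stop("missing ppFVC at week ", target_week, " for patient(s): ",
         paste(ds$patient_id[is.na(ds$ppfvc[, tw])], collapse = ", "),
         " (run locf_impute_outcome first)")
  ds$delta_ppfvc <- as.numeric(ds$ppfvc[, tw] - ds$ppfvc[, "0"])
  ds
}
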
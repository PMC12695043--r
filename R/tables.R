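# Table builders: arm-wise baseline comparisons (Fisher / Wilcoxon) and
# leaf-wise trend summaries (Mantel / linear trend, leaf scores 1..L).

fmt_binary_cell <- function(x) {
  x <- x[!is.na(x)]
  sprintf("%d (%.1f%%)", sum(x == 1), round_half_up(100 * mean(x == 1), 1))
}

fmt_cont_cell <- function(x) {
  x <- x[!is.na(x)]
  sprintf("%.1f (%.1f-%.1f)", stats::median(x), min(x), max(x))
}

#' Baseline characteristic tables by arm and by leaf
#'
#' Builds the two standard descriptive tables around a fitted tree. The
#' arm-wise table gives, per covariate, `n (%)` or `median (min-max)` for
#' each arm with a Fisher exact (binary) or Wilcoxon rank-sum (continuous)
#' p-value. The leaf-wise table gives the same cells per terminal node with
#' a Mantel (binary) or linear (continuous) trend p-value across ordered
#' leaves, using leaf scores 1..L. Display percentages are rounded half-up
#' to one decimal; p-values are reported at full precision (the TSV writer
#' prints them to 3 decimals).
#'
#' @param ds a [trial_dataset()].
#' @param leaf_labels integer vector of per-patient leaf labels (from
#'   [route_leaf_labels()]); `NULL` skips the leaf-wise table.
#' @param catalog covariate catalog (defaults to the dataset's).
#' @return A list with data frames `by_arm` and (when labels are given)
#'   `by_leaf`.
#' @export
subpopulation_tables <- function(ds, leaf_labels = NULL,
                                 catalog = ds$catalog) {
  cov <- ds$covariates
  arm <- ds$arm
  by_arm <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(j) {
    nm <- catalog$name[j]
    x <- cov[[nm]]
    keep <- !is.na(x)
    if (catalog$kind[j] == "binary") {
      tab <- matrix(c(sum(x[keep & arm == 0] == 1), sum(x[keep & arm == 0] == 0),
                      sum(x[keep & arm == 1] == 1), sum(x[keep & arm == 1] == 0)),
                    2, 2, byrow = TRUE)
      p <- tryCatch(fisher_exact_2x2(tab), error = function(e) NA_real_)
      cells <- c(fmt_binary_cell(x), fmt_binary_cell(x[arm == 0]),
                 fmt_binary_cell(x[arm == 1]))
    } else {
      p <- wilcoxon_rank_sum(x[keep & arm == 0], x[keep & arm == 1])
      cells <- c(fmt_cont_cell(x), fmt_cont_cell(x[arm == 0]),
                 fmt_cont_cell(x[arm == 1]))
    }
    data.frame(characteristic = nm, total = cells[1], control = cells[2],
               treated = cells[3], p = p, stringsAsFactors = FALSE)
  }))

  out <- list(by_arm = by_arm)
  if (!is.null(leaf_labels)) {
    labels <- sort(unique(leaf_labels))
    by_leaf <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(j) {
      nm <- catalog$name[j]
      x <- cov[[nm]]
      keep <- !is.na(x)
      score <- match(leaf_labels, labels)
      if (catalog$kind[j] == "binary") {
        succ <- vapply(labels, function(l) sum(x[keep & leaf_labels == l] == 1),
                       numeric(1))
        tot <- vapply(labels, function(l) sum(keep & leaf_labels == l),
                      numeric(1))
        p <- mantel_trend(succ, tot, seq_along(labels))$p
        cells <- vapply(labels, function(l) fmt_binary_cell(x[leaf_labels == l]),
                        character(1))
      } else {
        p <- linear_trend(x[keep], score[keep])$p
        cells <- vapply(labels, function(l) fmt_cont_cell(x[leaf_labels == l]),
                        character(1))
      }
      row <- data.frame(characteristic = nm, stringsAsFactors = FALSE)
      for (i in seq_along(labels)) row[[sprintf("leaf%d", labels[i])]] <- cells[i]
      row$p <- p
      row
    }))
    out$by_leaf <- by_leaf
  }
  out
}

#' Per-leaf treatment contrast table
#'
#' Welch contrasts ([leaf_contrast()]) of the outcome between arms within
#' every terminal node of a fitted tree.
#'
#' @param ds a [trial_dataset()] with `delta_ppfvc`.
#' @param tree a fitted `causal_tree`.
#' @return Data frame with one row per leaf: `leaf_label`, `n1`, `n0`,
#'   `mean1`, `mean0`, `diff`, `ci_low`, `ci_high`, `p`.
#' @export
leaf_contrast_table <- function(ds, tree) {
  labels <- route_leaf_labels(tree, ds)
  do.call(rbind, lapply(sort(unique(labels)), function(l) {
    ct <- leaf_contrast(ds$delta_ppfvc[labels == l], ds$arm[labels == l], l)
    as.data.frame(unclass(ct), stringsAsFactors = FALSE)
  }))
}

#' Write a summary table as TSV
#'
#' Fixed column order as built; the `p` column is printed to 3 decimals,
#' other numeric columns at full precision.
#'
#' @param tab a data frame from [subpopulation_tables()] or
#'   [leaf_contrast_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  out <- tab
  if ("p" %in% names(out) && is.numeric(out$p))
    out$p <- ifelse(is.na(out$p), "NA", fmt_p(out$p))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
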
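#' Confusion-matrix cell counts
#'
#' `confusion_counts()` builds the 2x2 cell object directly (cells may be
#' fractional, e.g. fold-averaged means); `confusion_from_predictions()`
#' counts it from label vectors. AD is the positive class throughout, so
#' `tp` counts true-AD predicted-AD.
#'
#' @param tp,fp,fn,tn Nonnegative cell values.
#' @return A one-row tibble of class `confusion_counts` with columns
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_from_predictions(c("AD", "AD", "NC"), c("AD", "NC", "NC"))
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    abort("All confusion cells must be finite and nonnegative.")
  }
  structure(tibble(tp = unname(tp), fp = unname(fp), fn = unname(fn),
                   tn = unname(tn)),
            class = c("confusion_counts", class(tibble())))
}

#' @rdname confusion_counts
#' @param truth,predicted Label vectors over `{"AD","NC"}` of equal length.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  bad <- setdiff(unique(c(truth, predicted)), c("AD", "NC"))
  if (length(bad) > 0) {
    abort(paste0("Labels must be 'AD' or 'NC'; found: ",
                 paste(bad, collapse = ", ")))
  }
  confusion_counts(tp = sum(truth == "AD" & predicted == "AD"),
                   fp = sum(truth == "NC" & predicted == "AD"),
                   fn = sum(truth == "AD" & predicted == "NC"),
                   tn = sum(truth == "NC" & predicted == "NC"))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Six-metric performance report from confusion cells
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' (PPV) `tp/(tp+fp)`, accuracy `(tp+tn)/(tp+fp+fn+tn)`, and NPV `tn/(tn+fn)`
#' from the cells, plus the rank-based AUC when per-sample decision scores
#' are supplied. Any metric whose denominator is zero is reported as `NA`
#' (undefined), never 0 — fold-averaged matrices can have empty cells.
#'
#' @param cc A [confusion_counts()] row.
#' @param truth,scores Optional per-sample true labels and real-valued
#'   decision scores (larger = more AD-like) from which AUC is computed.
#' @param auc Optional precomputed AUC, used when scores are unavailable.
#' @return A one-row tibble of class `metric_report` with columns
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `npv`, `auc`.
#' @examples
#' metric_report(confusion_counts(14, 3, 1, 10))
#' @export
metric_report <- function(cc, truth = NULL, scores = NULL, auc = NA_real_) {
  if (!inherits(cc, "confusion_counts")) {
    abort("`cc` must be a confusion_counts object.")
  }
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  if (total == 0) abort("All confusion cells are zero; metrics undefined.")
  if (!is.null(scores)) auc <- auc_score(truth, scores)
  out <- tibble(
    sensitivity = safe_ratio(cc$tp, cc$tp + cc$fn),
    specificity = safe_ratio(cc$tn, cc$tn + cc$fp),
    precision = safe_ratio(cc$tp, cc$tp + cc$fp),
    accuracy = (cc$tp + cc$tn) / total,
    npv = safe_ratio(cc$tn, cc$tn + cc$fn),
    auc = auc)
  structure(out, class = c("metric_report", class(tibble())))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen AD
#' score exceeds a uniformly chosen NC score, with ties counted one half.
#' Equivalent to trapezoidal integration of the empirical ROC curve and
#' invariant under strictly monotone transforms of the scores.
#'
#' @param truth Labels in `{"AD","NC"}`, at least one of each.
#' @param scores Real decision values, larger = more AD-like.
#' @return The AUC in \[0, 1\].
#' @examples
#' auc_score(c("AD", "AD", "NC", "NC"), c(0.9, 0.4, 0.6, 0.1))
#' @export
auc_score <- function(truth, scores) {
  truth <- as.character(truth)
  if (length(truth) != length(scores)) {
    abort("`truth` and `scores` must have equal length.")
  }
  bad <- setdiff(unique(truth), c("AD", "NC"))
  if (length(bad) > 0) {
    abort(paste0("Labels must be 'AD' or 'NC'; found: ",
                 paste(bad, collapse = ", ")))
  }
  n_pos <- sum(truth == "AD")
  n_neg <- sum(truth == "NC")
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC needs at least one sample of each class.")
  }
  r <- rank(scores)  # average ranks handle ties
  (sum(r[truth == "AD"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Format a metric report as printed percentages
#'
#' Renders each defined metric as a percentage with two decimals (the layout
#' used in published performance tables); undefined metrics render as `"-"`.
#'
#' @param report A [metric_report()] row.
#' @return A one-row tibble of character columns.
#' @export
format_metric_report <- function(report) {
  as_tibble(lapply(report, function(v) {
    if (is.na(v)) "-" else sprintf("%.2f%%", 100 * v)
  }))
}
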
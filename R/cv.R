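#' Classifier and cross-validation configuration
#'
#' `svm_model()` names the base classifier: a soft-margin support vector
#' machine. The default is a linear kernel with cost `C = 1` — the linear
#' kernel supplies the per-feature weights that recursive feature elimination
#' ranks on. Features are z-scored inside each training fold before fitting,
#' so the cost parameter acts on a common scale.
#'
#' `cv_config()` fixes the cross-validation layout: stratified k-fold with
#' `k = 5`, repeated `repeats = 10` times with fresh random splits, all
#' derived deterministically from `seed`.
#'
#' @param kernel e1071 kernel name; `"linear"` unless you have a reason.
#' @param cost Soft-margin cost parameter.
#' @param ... Further arguments passed to [e1071::svm()].
#' @return `svm_model()` an object of class `svm_spec`; `cv_config()` an
#'   object of class `cv_config`.
#' @export
svm_model <- function(kernel = "linear", cost = 1, ...) {
  structure(list(kernel = kernel, cost = cost, args = list(...)),
            class = "svm_spec")
}

#' @rdname svm_model
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent repetitions (>= 1).
#' @param stratified Preserve class proportions within folds?
#' @param seed Integer seed from which per-repeat sub-seeds are derived.
#' @export
cv_config <- function(k = 5, repeats = 10, stratified = TRUE, seed = 1L) {
  if (k < 2) abort("`k` must be at least 2.")
  if (repeats < 1) abort("`repeats` must be at least 1.")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified repeated fold assignments
#'
#' Within each repeat every sample lands in exactly one test fold; under
#' stratification the shuffled members of each class are dealt round-robin
#' over the folds, so per-fold class counts differ from proportionality by
#' at most one sample. Repeat `r` uses a deterministic sub-seed of
#' `config$seed`.
#'
#' @param table A cohort tibble.
#' @param config A [cv_config()].
#' @return A tibble with columns `rep`, `fold` and the list-column
#'   `test_idx` (row indices of the test fold), carrying a `split_hash`
#'   attribute identifying the assignment.
#' @export
stratified_splits <- function(table, config = cv_config()) {
  table <- check_cohort(table)
  n <- nrow(table)
  grp <- as.character(table$group)
  if (config$stratified) {
    cls_n <- table(grp)
    if (min(cls_n) < config$k) {
      abort(paste0("Smallest class has ", min(cls_n),
                   " samples; cannot stratify into k = ", config$k, " folds."))
    }
  } else if (n < config$k) {
    abort("Fewer samples than folds.")
  }
  out <- purrr::map_dfr(seq_len(config$repeats), function(r) {
    set.seed(sub_seed(config$seed, paste0("cv-rep-", r)))
    fold_of <- integer(n)
    if (config$stratified) {
      for (g in unique(grp)) {
        idx <- sample(which(grp == g))
        fold_of[idx] <- rep_len(seq_len(config$k), length(idx))
      }
    } else {
      fold_of[sample(n)] <- rep_len(seq_len(config$k), n)
    }
    tibble(rep = r, fold = seq_len(config$k),
           test_idx = lapply(seq_len(config$k), function(f) which(fold_of == f)))
  })
  attr(out, "split_hash") <- rlang::hash(out[, c("rep", "fold", "test_idx")])
  out
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mu = mu, s = s)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$s, "/")
}

fit_svm <- function(x, y, model) {
  args <- c(list(x = x, y = y, kernel = model$kernel, cost = model$cost,
                 scale = FALSE), model$args)
  do.call(e1071::svm, args)
}

# decision values oriented so that larger = more AD-like
svm_scores <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (colnames(dv)[1] == "AD/NC") 1 else -1
  list(labels = as.character(pr), scores = sgn * as.numeric(dv[, 1]))
}

linear_svm_weights <- function(fit) {
  w <- crossprod(fit$coefs, fit$SV)
  drop(w)
}

#' Repeated stratified cross-validation of a biomarker panel
#'
#' Runs the full harness: for each of `k x repeats` splits the classifier is
#' fit on the training folds — features z-scored with training-fold
#' statistics only, with an optional training-fold-fitted PCA rotation — and
#' evaluated on both the training and the test fold. Confusion cells are
#' averaged over all splits (mean and sd per cell) and the averages are
#' rounded half-away-from-zero to integers; the headline metric reports are
#' computed from the rounded cells, with AUC averaged over per-split AUCs.
#' The mean squared error of the 0/1 test predictions — for hard labels,
#' the misclassification rate — is reported with its across-split sd as an
#' overfitting diagnostic: a flexible model's train-test gap and MSE shrink
#' when uninformative features are removed.
#'
#' Test folds that happen to contain a single class are flagged, excluded
#' from AUC averaging (with a warning), but kept in confusion averaging.
#'
#' @param table A cohort tibble.
#' @param model An [svm_model()].
#' @param config A [cv_config()]; ignored when `splits` is given except for
#'   bookkeeping.
#' @param features Feature columns to use; defaults to all marker columns.
#' @param splits Optional precomputed [stratified_splits()] so several
#'   configurations share identical folds for paired comparison.
#' @param n_pca Optional number of principal components; when set, a PCA is
#'   fitted on the standardized training fold and both folds are projected
#'   onto the leading components before the SVM sees them.
#' @param select_fun Optional fold-internal feature selector: a function
#'   taking the training-fold cohort tibble and returning the feature names
#'   to use for that split (e.g. a wrapper around [rfe()]). This is the
#'   honest-evaluation mode — selecting once on the full table before CV
#'   leaks test information into the choice of panel.
#' @return An object of class `cv_outcome`; see [tidy()][tidy.cv_outcome()]
#'   for per-split records and [glance()][glance.cv_outcome()] for the
#'   one-row summary.
#' @examples
#' cohort <- generate_cohort(planted_signal_spec(1, 2, effect_size = 2, seed = 3))
#' out <- repeated_cv(cohort, config = cv_config(k = 5, repeats = 2, seed = 3))
#' glance(out)
#' @export
repeated_cv <- function(table, model = svm_model(), config = cv_config(),
                        features = NULL, splits = NULL, n_pca = NULL,
                        select_fun = NULL) {
  table <- check_cohort(table)
  features <- features %||% marker_columns(table)
  if (length(features) < 1) abort("No feature columns to train on.")
  x_all <- feature_matrix(table, features)
  y_all <- group_factor(table$group)
  if (min(table(y_all)) < config$k) {
    abort("Each class needs at least k samples.")
  }
  if (is.null(splits)) splits <- stratified_splits(table, config)
  if (!is.null(n_pca) && n_pca > length(features)) {
    abort("`n_pca` exceeds the number of features.")
  }

  folds <- purrr::map_dfr(seq_len(nrow(splits)), function(i) {
    test_i <- splits$test_idx[[i]]
    train_i <- setdiff(seq_len(nrow(table)), test_i)
    feats_i <- features
    if (!is.null(select_fun)) {
      feats_i <- intersect(features, select_fun(table[train_i, , drop = FALSE]))
      if (length(feats_i) < 1) feats_i <- features
    }
    st <- standardizer(x_all[train_i, feats_i, drop = FALSE])
    xtr <- apply_standardizer(x_all[train_i, feats_i, drop = FALSE], st)
    xte <- apply_standardizer(x_all[test_i, feats_i, drop = FALSE], st)
    if (!is.null(n_pca)) {
      rot <- prcomp(xtr, center = FALSE, scale. = FALSE)$rotation
      rot <- rot[, seq_len(min(n_pca, ncol(rot))), drop = FALSE]
      xtr <- xtr %*% rot
      xte <- xte %*% rot
    }
    fit <- fit_svm(xtr, y_all[train_i], model)
    tr <- svm_scores(fit, xtr)
    te <- svm_scores(fit, xte)
    truth_tr <- as.character(y_all[train_i])
    truth_te <- as.character(y_all[test_i])
    cc_tr <- confusion_from_predictions(truth_tr, tr$labels)
    cc_te <- confusion_from_predictions(truth_te, te$labels)
    degenerate <- length(unique(truth_te)) < 2
    tibble(
      rep = splits$rep[i], fold = splits$fold[i],
      n_train = length(train_i), n_test = length(test_i),
      train_tp = cc_tr$tp, train_fp = cc_tr$fp,
      train_fn = cc_tr$fn, train_tn = cc_tr$tn,
      test_tp = cc_te$tp, test_fp = cc_te$fp,
      test_fn = cc_te$fn, test_tn = cc_te$tn,
      train_auc = auc_score(truth_tr, tr$scores),
      test_auc = if (degenerate) NA_real_ else auc_score(truth_te, te$scores),
      train_accuracy = (cc_tr$tp + cc_tr$tn) / length(train_i),
      test_accuracy = (cc_te$tp + cc_te$tn) / length(test_i),
      test_mse = (cc_te$fp + cc_te$fn) / length(test_i),
      degenerate = degenerate)
  })
  if (any(folds$degenerate)) {
    warn(paste0(sum(folds$degenerate),
                " degenerate single-class test fold(s) excluded from AUC averaging."))
  }

  cell_summary <- function(prefix) {
    cells <- c("tp", "fp", "fn", "tn")
    mean_ <- vapply(cells, function(cl) mean(folds[[paste0(prefix, "_", cl)]]),
                    numeric(1))
    sd_ <- vapply(cells, function(cl) sd(folds[[paste0(prefix, "_", cl)]]),
                  numeric(1))
    list(mean = mean_, sd = sd_, rounded = round_half_away(mean_))
  }
  tr_cells <- cell_summary("train")
  te_cells <- cell_summary("test")
  report_from <- function(cells, auc_col) {
    cc <- confusion_counts(cells$rounded["tp"], cells$rounded["fp"],
                           cells$rounded["fn"], cells$rounded["tn"])
    metric_report(cc, auc = mean(folds[[auc_col]], na.rm = TRUE))
  }
  out <- list(
    folds = folds,
    train_cells = tr_cells, test_cells = te_cells,
    train_report = report_from(tr_cells, "train_auc"),
    test_report = report_from(te_cells, "test_auc"),
    mse_mean = sum(folds$test_fp + folds$test_fn) / sum(folds$n_test),
    mse_sd = sd(folds$test_mse),
    config = config, model = model, features = features, n_pca = n_pca,
    split_hash = attr(splits, "split_hash"))
  class(out) <- "cv_outcome"
  out
}

#' @export
print.cv_outcome <- function(x, ...) {
  cat("<cv_outcome> ", x$config$repeats, "x repeated ", x$config$k,
      "-fold CV on ", length(x$features), " features",
      if (!is.null(x$n_pca)) paste0(" (PCA -> ", x$n_pca, ")"), "\n", sep = "")
  cat("  test (rounded cells tp/fp/fn/tn = ",
      paste(x$test_cells$rounded, collapse = "/"), "):\n", sep = "")
  print(format_metric_report(x$test_report))
  cat("  MSE ", sprintf("%.4f +/- %.4f", x$mse_mean, x$mse_sd), "\n", sep = "")
  invisible(x)
}

#' Tidy per-split records of a cross-validation outcome
#'
#' @param x A `cv_outcome`.
#' @param ... Unused.
#' @return One row per (repeat, fold) with train/test confusion cells,
#'   AUCs, accuracies and the per-split test MSE.
#' @export
tidy.cv_outcome <- function(x, ...) x$folds

#' One-row summary of a cross-validation outcome
#'
#' @param x A `cv_outcome`.
#' @param ... Unused.
#' @return A tibble with train/test accuracy and AUC (from the rounded
#'   averaged confusion matrices), the train-test accuracy gap, and the MSE
#'   diagnostic.
#' @export
glance.cv_outcome <- function(x, ...) {
  tibble(
    k = x$config$k, repeats = x$config$repeats,
    n_features = length(x$features),
    train_accuracy = x$train_report$accuracy,
    test_accuracy = x$test_report$accuracy,
    train_auc = x$train_report$auc,
    test_auc = x$test_report$auc,
    accuracy_gap = x$train_report$accuracy - x$test_report$accuracy,
    mse_mean = x$mse_mean, mse_sd = x$mse_sd)
}

#' Report table mirroring the published performance-table layout
#'
#' One row per quantity and evaluation set: averaged confusion cells as
#' `mean +/- sd`, their rounded integer versions, then the six metrics as
#' two-decimal percentages.
#'
#' @param outcome A `cv_outcome`.
#' @return A tibble with columns `set`, `quantity`, `value` (character) and
#'   `numeric` (the underlying number).
#' @export
cv_report <- function(outcome) {
  one_set <- function(set, cells, report) {
    cellrows <- purrr::map_dfr(c("tp", "fp", "fn", "tn"), function(cl) {
      tibble(set = set, quantity = paste0("cell_", cl),
             value = sprintf("%d (%.2f ± %.2f)", as.integer(cells$rounded[cl]),
                             cells$mean[cl], cells$sd[cl]),
             numeric = as.numeric(cells$rounded[cl]))
    })
    metrics <- names(report)
    metrows <- purrr::map_dfr(metrics, function(m) {
      v <- report[[m]]
      tibble(set = set, quantity = m,
             value = if (is.na(v)) "-" else sprintf("%.2f%%", 100 * v),
             numeric = v)
    })
    bind_rows(cellrows, metrows)
  }
  bind_rows(one_set("train", outcome$train_cells, outcome$train_report),
            one_set("test", outcome$test_cells, outcome$test_report))
}

#' Mean squared error of the 0/1 test predictions
#'
#' For hard 0/1 predictions against 0/1 truth the pooled MSE equals the
#' misclassification rate over all test samples across all splits; the sd is
#' taken across per-split MSE values.
#'
#' @param outcome A `cv_outcome`.
#' @return A tibble with `mse_mean` and `mse_sd`.
#' @export
cv_mse <- function(outcome) {
  tibble(mse_mean = outcome$mse_mean, mse_sd = outcome$mse_sd)
}

#' Paired comparison of two cross-validation outcomes
#'
#' Two outcomes produced under identical fold assignments are compared with
#' a paired two-sided t-test across the `k x repeats` per-split test
#' accuracies. When every per-split difference is exactly zero the p-value
#' is 1 by convention.
#'
#' @param a,b `cv_outcome` objects sharing the same `split_hash`.
#' @return A tibble with `statistic` (t), `df`, `p_value` and `mean_diff`
#'   (mean per-split accuracy of `a` minus `b`).
#' @export
compare_outcomes <- function(a, b) {
  if (!identical(a$split_hash, b$split_hash)) {
    abort("Outcomes were not produced under identical fold assignments.")
  }
  d <- a$folds$test_accuracy - b$folds$test_accuracy
  if (all(d == 0)) {
    return(tibble(statistic = 0, df = length(d) - 1, p_value = 1, mean_diff = 0))
  }
  tt <- t.test(d)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = mean(d))
}

#' @describeIn repeated_cv Boxplot of per-split train and test accuracies.
#' @param object A `cv_outcome` (autoplot method).
#' @export
autoplot.cv_outcome <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds[, c("train_accuracy", "test_accuracy")],
                            dplyr::everything(),
                            names_to = "set", values_to = "accuracy")
  df$set <- sub("_accuracy$", "", df$set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Per-split accuracy") +
    ggplot2::theme_minimal()
}
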
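#' Leave-one-out cross-validation error of an SVM on a feature set
#'
#' The error rate used to score candidate feature subsets during recursive
#' elimination: the fold count equals the sample size, so every participant
#' is predicted once by a model trained on all the others. Features are
#' assumed already standardized.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of group labels.
#' @param model An [svm_model()].
#' @return Misclassification rate in \[0, 1\].
#' @keywords internal
loocv_error <- function(x, y, model) {
  args <- c(list(x = x, y = y, kernel = model$kernel, cost = model$cost,
                 scale = FALSE, cross = nrow(x)), model$args)
  fit <- do.call(e1071::svm, args)
  (100 - fit$tot.accuracy) / 100
}

#' Rank features by an SVM criterion
#'
#' `criterion = "weight"` is classical SVM-RFE: the squared coefficient of
#' each (standardized) feature in the fitted linear decision function —
#' removing the smallest-|w| feature perturbs the margin least. A constant
#' feature standardizes to the zero column and so gets criterion 0.
#' `criterion = "performance"` scores each feature by the increase in
#' leave-one-out error when it is removed (error without the feature minus
#' error with it). Larger values mean more important in both modes.
#'
#' @param table A cohort tibble (used as the training set).
#' @param model An [svm_model()]; `"weight"` requires a linear kernel.
#' @param criterion `"weight"` or `"performance"`.
#' @param features Feature columns; defaults to all marker columns.
#' @return A tibble with columns `feature` and `value`, in input column
#'   order.
#' @export
rank_features <- function(table, model = svm_model(),
                          criterion = c("weight", "performance"),
                          features = NULL) {
  criterion <- match.arg(criterion)
  table <- check_cohort(table)
  features <- features %||% marker_columns(table)
  x <- feature_matrix(table, features)
  x <- apply_standardizer(x, standardizer(x))
  y <- group_factor(table$group)
  values <- feature_criteria(x, y, model, criterion)
  tibble(feature = features, value = unname(values))
}

feature_criteria <- function(x, y, model, criterion) {
  if (criterion == "weight") {
    if (model$kernel != "linear") {
      abort(paste0("The weight criterion needs a linear kernel; use ",
                   "criterion = \"performance\" for kernel \"",
                   model$kernel, "\"."))
    }
    w <- linear_svm_weights(fit_svm(x, y, model))
    return(w^2)
  }
  err_all <- loocv_error(x, y, model)
  vapply(seq_len(ncol(x)), function(j) {
    loocv_error(x[, -j, drop = FALSE], y, model) - err_all
  }, numeric(1))
}

#' Recursive feature elimination with a leave-one-out stopping rule
#'
#' Iteratively trains the SVM on the surviving features, eliminates the
#' `step` features with the smallest ranking criterion (ties broken toward
#' the earlier column, so runs are reproducible), and rescores the reduced
#' set by leave-one-out cross-validation. Elimination continues while the
#' error keeps reaching (or tying) its running minimum; once it has risen
#' above the minimum for more than `patience` consecutive eliminations (or a
#' single feature remains) it stops, and the *smallest* feature set that
#' attained the minimum observed error is returned. Plateaus are traversed
#' rather than treated as failures — the leave-one-out error curve is noisy
#' and flat, and the target is the least number of features with the lowest
#' error. `patience = Inf` eliminates all the way down to one feature and
#' then picks the argmin.
#'
#' @param table A cohort tibble; needs at least 2 features and 2 samples per
#'   class.
#' @param model An [svm_model()].
#' @param features Candidate features; defaults to all marker columns.
#' @param step Features removed per iteration (default 1).
#' @param patience Eliminations tolerated beyond the running minimum before
#'   stopping (default 1).
#' @param criterion Ranking criterion, see [rank_features()].
#' @return An object of class `rfe_result` with fields `trace` (one row per
#'   eliminated feature: `step`, `feature`, `criterion_value`,
#'   `n_features_after`, `error_after`), `initial_error`,
#'   `selected_features`, `final_error` (the minimum observed error) and
#'   `ranking` (rank 1 = most important: survivors of the last iteration by
#'   final criterion, then eliminated features in reverse order).
#' @examples
#' cohort <- generate_cohort(planted_signal_spec(1, 3, effect_size = 2.5,
#'                                               n_ad = 30, n_nc = 30, seed = 2))
#' res <- rfe(cohort)
#' res$selected_features
#' @export
rfe <- function(table, model = svm_model(), features = NULL, step = 1,
                patience = 1, criterion = c("weight", "performance")) {
  criterion <- match.arg(criterion)
  table <- check_cohort(table)
  features <- features %||% marker_columns(table)
  if (length(features) < 2) abort("Need at least 2 candidate features.")
  y <- group_factor(table$group)
  if (min(table(y)) < 2) {
    abort(paste0("Leave-one-out CV is infeasible with fewer than 2 samples ",
                 "per class; use repeated_cv() with a small k as a surrogate."))
  }
  x <- feature_matrix(table, features)
  x <- apply_standardizer(x, standardizer(x))

  current <- features
  err <- loocv_error(x, y, model)
  initial_error <- err
  best <- err
  since_best <- 0
  trace <- list()
  snapshots <- list(list(features = current, error = err))
  it <- 0
  final_crit <- setNames(rep(NA_real_, length(current)), current)
  while (length(current) > 1 && since_best <= patience) {
    it <- it + 1
    crit <- feature_criteria(x[, current, drop = FALSE], y, model, criterion)
    names(crit) <- current
    final_crit <- crit
    n_drop <- min(step, length(current) - 1)
    drop_idx <- order(crit)[seq_len(n_drop)]  # ties -> earlier column
    dropped <- current[sort(drop_idx)]
    current <- setdiff(current, dropped)
    err <- loocv_error(x[, current, drop = FALSE], y, model)
    trace[[it]] <- tibble(step = it, feature = dropped,
                          criterion_value = unname(crit[dropped]),
                          n_features_after = length(current),
                          error_after = err)
    snapshots[[length(snapshots) + 1]] <- list(features = current, error = err)
    # plateau-tolerant: ties with the running minimum do not count against
    # patience, so flat stretches of the noisy LOOCV curve are traversed and
    # the smallest set at the minimum can still be reached
    if (err < best) {
      best <- err
      since_best <- 0
    } else if (err > best) {
      since_best <- since_best + 1
    }
  }
  errors <- vapply(snapshots, function(s) s$error, numeric(1))
  sizes <- vapply(snapshots, function(s) length(s$features), numeric(1))
  at_min <- which(errors == min(errors))
  pick <- at_min[which.min(sizes[at_min])]
  survivors <- current
  surv_rank <- survivors[order(-final_crit[survivors])]
  eliminated <- rev(unlist(lapply(rev(trace), function(tr) tr$feature)))
  ranking <- tibble(feature = c(surv_rank, rev(eliminated)),
                    rank = seq_along(features))
  structure(list(
    trace = if (length(trace)) bind_rows(trace) else
      tibble(step = integer(), feature = character(),
             criterion_value = numeric(), n_features_after = integer(),
             error_after = numeric()),
    initial_error = initial_error,
    selected_features = snapshots[[pick]]$features,
    final_error = min(errors),
    ranking = ranking,
    criterion = criterion, features = features, model = model),
    class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result> ", length(x$features), " -> ",
      length(x$selected_features), " features; LOOCV error ",
      sprintf("%.4f -> %.4f", x$initial_error, x$final_error), "\n", sep = "")
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname rfe
#' @param x An `rfe_result` (tidy method).
#' @param ... Unused.
#' @export
tidy.rfe_result <- function(x, ...) x$trace

#' @rdname rfe
#' @param object An `rfe_result` (autoplot method): elimination error curve,
#'   with the selected panel size marked.
#' @export
autoplot.rfe_result <- function(object, ...) {
  curve <- bind_rows(
    tibble(n_features = length(object$features),
           error = object$initial_error),
    dplyr::distinct(object$trace, .data$n_features_after, .data$error_after) %>%
      rename(n_features = "n_features_after", error = "error_after"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_features, y = .data$error)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = length(object$selected_features),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Features remaining", y = "LOOCV error rate") +
    ggplot2::theme_minimal()
}

#' Replace marker columns by principal-component scores
#'
#' Standardizes the feature matrix and projects it onto its first
#' `n_components` principal components; group labels and covariates are
#' preserved. This is the unsupervised dimensionality-reduction baseline
#' against which recursive elimination is compared. Inside cross-validation,
#' [repeated_cv()]'s `n_pca` argument fits the rotation on the training fold
#' only; this function fits on the whole table.
#'
#' @param table A cohort tibble.
#' @param n_components Number of components, at most
#'   `min(n_samples, n_features)`.
#' @param features Feature columns; defaults to all marker columns.
#' @return A cohort tibble whose features are `PC1 ... PCn`.
#' @export
pca_reduce <- function(table, n_components, features = NULL) {
  table <- check_cohort(table)
  features <- features %||% marker_columns(table)
  x <- feature_matrix(table, features)
  if (n_components > min(nrow(x), ncol(x))) {
    abort("`n_components` exceeds min(n_samples, n_features).")
  }
  x <- apply_standardizer(x, standardizer(x))
  scores <- prcomp(x, center = FALSE, scale. = FALSE)$x
  keep <- setdiff(names(table), features)
  out <- as_tibble(table[, keep, drop = FALSE])
  for (j in seq_len(n_components)) out[[paste0("PC", j)]] <- scores[, j]
  out
}

#' Fit a panel SVM on a whole cohort
#'
#' Standardizes the selected features, fits the SVM, and packages the
#' standardizer with the fit so new tables are prepared identically.
#'
#' @param table A cohort tibble.
#' @param model An [svm_model()].
#' @param features Feature columns; defaults to all marker columns.
#' @return An object of class `panel_svm`.
#' @export
fit_panel_svm <- function(table, model = svm_model(), features = NULL) {
  table <- check_cohort(table)
  features <- features %||% marker_columns(table)
  x <- feature_matrix(table, features)
  st <- standardizer(x)
  fit <- fit_svm(apply_standardizer(x, st), group_factor(table$group), model)
  structure(list(fit = fit, st = st, features = features, model = model),
            class = "panel_svm")
}

#' @rdname fit_panel_svm
#' @param object A `panel_svm`.
#' @param newdata A cohort tibble to predict.
#' @param ... Unused.
#' @return `predict()` returns a character vector of `"AD"`/`"NC"` labels.
#' @export
predict.panel_svm <- function(object, newdata, ...) {
  x <- apply_standardizer(feature_matrix(newdata, object$features), object$st)
  svm_scores(object$fit, x)$labels
}

#' Permutation importance of panel features
#'
#' Scores each feature by the mean decrease in whole-table accuracy over
#' `m` random permutations of that feature's column, clipped at zero.
#' Signal-free features score about 0 (within permutation noise of order
#' `1/sqrt(m * n)`), dominant features score highest. Deterministic given
#' `seed`.
#'
#' @param fit A [fit_panel_svm()] object.
#' @param table The cohort to score on (typically the training table).
#' @param m Permutations per feature.
#' @param seed Integer seed.
#' @return A tibble of class `importance_scores` with columns `feature`,
#'   `score`, `rank` (rank 1 = most important; ranks are a permutation of
#'   `1..n_features`).
#' @export
importance_scores <- function(fit, table, m = 30, seed = 1L) {
  table <- check_cohort(table)
  truth <- as.character(table$group)
  base_acc <- mean(predict(fit, table) == truth)
  n <- nrow(table)
  score <- vapply(fit$features, function(f) {
    set.seed(sub_seed(seed, paste0("perm-", f)))
    drops <- vapply(seq_len(m), function(i) {
      perm <- table
      perm[[f]] <- perm[[f]][sample(n)]
      base_acc - mean(predict(fit, perm) == truth)
    }, numeric(1))
    max(mean(drops), 0)
  }, numeric(1))
  out <- tibble(feature = fit$features, score = unname(score))
  out$rank <- rank(-out$score, ties.method = "first")
  structure(out[order(out$rank), ],
            class = c("importance_scores", class(tibble())))
}

#' @rdname importance_scores
#' @param object An `importance_scores` tibble (autoplot method).
#' @param ... Unused.
#' @export
autoplot.importance_scores <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature[order(df$rank)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean accuracy decrease", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-marker-out evaluation of a panel
#'
#' For each marker in the panel, reruns [repeated_cv()] on the panel minus
#' that marker under shared fold assignments, quantifying how much each
#' member contributes to test performance.
#'
#' @param table A cohort tibble.
#' @param panel Feature columns forming the panel (at least 2).
#' @param config A [cv_config()].
#' @param model An [svm_model()].
#' @return A named list (removed marker -> `cv_outcome`).
#' @export
leave_one_marker_out <- function(table, panel, config = cv_config(),
                                 model = svm_model()) {
  table <- check_cohort(table)
  missing <- setdiff(panel, names(table))
  if (length(missing) > 0) {
    abort(paste0("Panel markers absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(panel) < 2) {
    abort("Cannot leave a marker out of a one-marker panel.")
  }
  splits <- stratified_splits(table, config)
  out <- lapply(panel, function(mk) {
    repeated_cv(table, model = model, config = config,
                features = setdiff(panel, mk), splits = splits)
  })
  setNames(out, panel)
}
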
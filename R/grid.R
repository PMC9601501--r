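grid_config_names <- c("serum_only", "plasma_only", "combined", "combined_rfe",
                       "serum_rfe", "plasma_rfe", "combined_pca",
                       "combined_rfe_age")

#' Run the configuration comparison grid
#'
#' Evaluates a set of panel configurations on one cohort under *identical*
#' fold assignments, so test-set differences can be compared pairwise with
#' paired t-tests:
#'
#' * `serum_only` / `plasma_only` — all markers of one fraction;
#' * `combined` — both fractions together;
#' * `combined_rfe`, `serum_rfe`, `plasma_rfe` — the feature universe first
#'   reduced by [rfe()] on the full table (one selection per universe,
#'   shared by every `*_rfe` configuration on it);
#' * `combined_pca` — the combined features projected onto `n_pca`
#'   training-fold principal components inside each split;
#' * `combined_rfe_age` — the RFE-selected panel plus the age covariate
#'   (z-scored with the panel inside each training fold).
#'
#' Selecting the panel on the full table before cross-validation mirrors the
#' published workflow but leaks test information into the selection; see
#' `rfe_in_folds` for the honest alternative and the package vignette for
#' the caveat.
#'
#' @param table A cohort tibble.
#' @param configurations Subset of
#'   `r paste0('c("', paste(grid_config_names, collapse = '", "'), '")')`.
#' @param config A [cv_config()].
#' @param model An [svm_model()].
#' @param n_pca Components for `combined_pca`.
#' @param rfe_args Extra arguments passed to [rfe()].
#' @param rfe_in_folds If `TRUE`, `*_rfe` configurations rerun the
#'   elimination inside every training fold (slow, unbiased) instead of once
#'   on the full table.
#' @return An object of class `experiment_grid`: named list `outcomes`
#'   (configuration -> `cv_outcome`), `rfe` (feature universe ->
#'   `rfe_result`), `comparisons` (pairwise paired t-tests on per-split test
#'   accuracies) and `manifest` (config hash, split hash, seed, version).
#' @export
run_grid <- function(table,
                     configurations = c("serum_only", "plasma_only",
                                        "combined", "combined_rfe"),
                     config = cv_config(), model = svm_model(), n_pca = 10,
                     rfe_args = list(), rfe_in_folds = FALSE) {
  table <- check_cohort(table)
  bad <- setdiff(configurations, grid_config_names)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration(s): ", paste(bad, collapse = ", ")))
  }
  if (length(configurations) < 1) abort("Need at least one configuration.")
  serum <- marker_columns(table, "serum")
  plasma <- marker_columns(table, "plasma")
  all_mk <- marker_columns(table)
  needs_serum <- grepl("^serum", configurations)
  needs_plasma <- grepl("^plasma", configurations)
  if (any(needs_serum) && length(serum) == 0) {
    abort("Configuration needs Serum_ columns but the table has none.")
  }
  if (any(needs_plasma) && length(plasma) == 0) {
    abort("Configuration needs Plasma_ columns but the table has none.")
  }
  if ("combined_rfe_age" %in% configurations && !"age" %in% names(table)) {
    abort("combined_rfe_age needs an `age` column in the table.")
  }
  splits <- stratified_splits(table, config)

  universes <- list(combined = all_mk, serum = serum, plasma = plasma)
  rfe_results <- list()
  select_on <- function(universe) {
    if (is.null(rfe_results[[universe]])) {
      rfe_results[[universe]] <<- do.call(
        rfe, c(list(table, model = model, features = universes[[universe]]),
               rfe_args))
    }
    rfe_results[[universe]]$selected_features
  }
  fold_selector <- function(universe) {
    function(train_tbl) {
      do.call(rfe, c(list(train_tbl, model = model,
                          features = universes[[universe]]),
                     rfe_args))$selected_features
    }
  }

  run_one <- function(cfg) {
    switch(cfg,
      serum_only = repeated_cv(table, model, config, serum, splits),
      plasma_only = repeated_cv(table, model, config, plasma, splits),
      combined = repeated_cv(table, model, config, all_mk, splits),
      combined_pca = repeated_cv(table, model, config, all_mk, splits,
                                 n_pca = n_pca),
      serum_rfe = if (rfe_in_folds) {
        repeated_cv(table, model, config, serum, splits,
                    select_fun = fold_selector("serum"))
      } else repeated_cv(table, model, config, select_on("serum"), splits),
      plasma_rfe = if (rfe_in_folds) {
        repeated_cv(table, model, config, plasma, splits,
                    select_fun = fold_selector("plasma"))
      } else repeated_cv(table, model, config, select_on("plasma"), splits),
      combined_rfe = if (rfe_in_folds) {
        repeated_cv(table, model, config, all_mk, splits,
                    select_fun = fold_selector("combined"))
      } else repeated_cv(table, model, config, select_on("combined"), splits),
      combined_rfe_age = repeated_cv(
        table, model, config, c(select_on("combined"), "age"), splits))
  }
  outcomes <- setNames(lapply(configurations, run_one), configurations)

  comparisons <- tibble()
  if (length(configurations) > 1) {
    pairs <- utils::combn(configurations, 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      cmp <- compare_outcomes(outcomes[[pairs[1, j]]], outcomes[[pairs[2, j]]])
      mutate(cmp, config_a = pairs[1, j], config_b = pairs[2, j],
             .before = 1)
    })
  }
  manifest <- list(
    configurations = configurations,
    seed = config$seed, k = config$k, repeats = config$repeats,
    n_samples = nrow(table), n_features = length(all_mk),
    split_hash = attr(splits, "split_hash"),
    config_hash = rlang::hash(list(configurations, config, model, n_pca,
                                   rfe_args, rfe_in_folds)),
    version = as.character(utils::packageVersion("panelselect")))
  structure(list(outcomes = outcomes, rfe = rfe_results,
                 comparisons = comparisons, manifest = manifest),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("<experiment_grid> ", length(x$outcomes), " configurations, split hash ",
      substr(x$manifest$split_hash, 1, 8), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' One row per configuration of an experiment grid
#'
#' @param x An `experiment_grid`.
#' @param ... Unused.
#' @return The per-configuration [glance.cv_outcome()] rows, with a
#'   `configuration` column.
#' @export
glance.experiment_grid <- function(x, ...) {
  purrr::map_dfr(names(x$outcomes),
                 function(cfg) mutate(glance(x$outcomes[[cfg]]),
                                      configuration = cfg, .before = 1))
}

#' Overfitting report for an experiment grid
#'
#' The train-test accuracy gap (from the rounded averaged confusion
#' matrices) and the test-set MSE diagnostic per configuration, ordered from
#' most to least overfit. Combining correlated feature sets typically
#' inflates the training accuracy without helping the test set; elimination
#' shrinks both the gap and the MSE.
#'
#' @param grid An `experiment_grid`.
#' @return A tibble with `configuration`, `train_accuracy`, `test_accuracy`,
#'   `gap`, `mse_mean`, `mse_sd`.
#' @export
overfitting_report <- function(grid) {
  glance(grid) %>%
    mutate(gap = .data$train_accuracy - .data$test_accuracy) %>%
    select("configuration", "train_accuracy", "test_accuracy", "gap",
           "mse_mean", "mse_sd") %>%
    arrange(desc(.data$gap))
}

#' Write grid reports to an output directory
#'
#' Per configuration: the [cv_report()] table as CSV and the per-split
#' records as JSON. Plus `comparisons.csv`, `overfitting.csv`, the
#' elimination traces, and `manifest.json`.
#'
#' @param grid An `experiment_grid`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_reports <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cfg in names(grid$outcomes)) {
    out <- grid$outcomes[[cfg]]
    readr::write_csv(cv_report(out), file.path(dir, paste0(cfg, "_report.csv")))
    jsonlite::write_json(out$folds, file.path(dir, paste0(cfg, "_folds.json")),
                         digits = NA)
  }
  if (nrow(grid$comparisons) > 0) {
    readr::write_csv(grid$comparisons, file.path(dir, "comparisons.csv"))
  }
  readr::write_csv(overfitting_report(grid), file.path(dir, "overfitting.csv"))
  for (u in names(grid$rfe)) {
    readr::write_csv(tidy(grid$rfe[[u]]),
                     file.path(dir, paste0("rfe_trace_", u, ".csv")))
  }
  jsonlite::write_json(grid$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
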
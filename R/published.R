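#' Published reference performance tables
#'
#' The rounded fold-averaged confusion matrices and the printed performance
#' metrics of the dual-fraction AD study this package emulates, for the four
#' reported configurations (serum only, plasma only, combined, combined
#' after feature elimination) on training and testing sets. These ship as
#' plain text and serve to regression-lock the metric formulas: applying
#' [metric_report()] to the `tp/fp/fn/tn` cells must reproduce every
#' `*_pct` ratio column to two decimals, and `1 - accuracy` of the rounded
#' test matrices approximates the printed `mse` column. The printed AUCs
#' derive from restricted raw data and are informational only.
#'
#' @return A tibble with one row per (set, configuration): cells `tp`,
#'   `fp`, `fn`, `tn`, metric columns in percent, and the test-set `mse`.
#' @examples
#' perf <- published_performance()
#' with(perf[5, ], metric_report(confusion_counts(tp, fp, fn, tn)))
#' @export
published_performance <- function() {
  path <- system.file("extdata", "published_performance.csv",
                      package = "panelselect")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
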
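#' Biomarker cohort tables
#'
#' A cohort is an ordinary tibble with one row per participant: a `sample_id`
#' column, a `group` column with levels `"AD"` (cases, the positive class
#' throughout) and `"NC"` (controls), optional covariates (`age` in years,
#' `education` in years, `sex` in `{"M","F"}`), and one numeric column per
#' measured marker. Marker columns are prefixed by blood fraction,
#' `Serum_<name>` or `Plasma_<name>`; covariate columns carry no prefix.
#' All user-facing functions in the package take such a table as their first
#' argument and return tibbles, so analyses compose with the pipe.
#'
#' `marker_columns()` lists the feature columns of a cohort, optionally
#' restricted to one fraction; `fraction_columns()` is a convenience wrapper.
#'
#' @param table A cohort tibble.
#' @param fraction `"serum"`, `"plasma"`, or `NULL` for all marker columns.
#' @return A character vector of column names.
#' @examples
#' cohort <- generate_cohort(demo_cohort_spec(seed = 1))
#' head(marker_columns(cohort))
#' @export
marker_columns <- function(table, fraction = NULL) {
  reserved <- c("sample_id", "group", "age", "education", "sex")
  cols <- setdiff(names(table), reserved)
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  if (!is.null(fraction)) {
    fraction <- match.arg(tolower(fraction), c("serum", "plasma"))
    prefix <- if (fraction == "serum") "^Serum_" else "^Plasma_"
    cols <- grep(prefix, cols, value = TRUE)
  }
  cols
}

#' @rdname marker_columns
#' @export
fraction_columns <- function(table, fraction) marker_columns(table, fraction)

check_cohort <- function(table, require_group = TRUE) {
  if (!is.data.frame(table)) {
    abort("`table` must be a data frame of one row per participant.")
  }
  table <- as_tibble(table)
  if (require_group) {
    if (!"group" %in% names(table)) {
      abort("Cohort table has no `group` column.")
    }
    bad <- setdiff(unique(as.character(table$group)), c("AD", "NC"))
    if (length(bad) > 0) {
      abort(paste0("`group` labels must be 'AD' or 'NC'; found: ",
                   paste(bad, collapse = ", ")))
    }
    if (anyNA(table$group)) abort("`group` contains missing labels.")
  }
  table
}

group_factor <- function(x) factor(as.character(x), levels = c("AD", "NC"))

#' Read and write cohort tables
#'
#' Cohorts are exchanged as comma-separated text with a header row:
#' `sample_id`, `group`, covariates, then marker columns.
#'
#' @param table A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  table <- check_cohort(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cohort(table)
}

feature_matrix <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    abort(paste0("Features absent from table: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(x) <- "double"
  x
}
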
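#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided t-test directly from per-group mean, sd and n —
#' the form needed to check published demographic tables, where only
#' summaries are printed. The pooled variant uses the Student statistic with
#' `n_a + n_b - 2` degrees of freedom; the Welch variant uses the
#' Satterthwaite approximation. On summaries computed from raw data the
#' pooled variant reproduces `t.test(var.equal = TRUE)` exactly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries; both `n >= 2`.
#' @param variant `"pooled"` or `"welch"`.
#' @return A tibble with `statistic` (t), `df`, `p_value` and `flag`
#'   (`TRUE` for the degenerate both-sds-zero case, where `p = 1` by
#'   convention when the means are equal).
#' @examples
#' ttest_from_summary(76.14, 8.79, 79, 71.57, 8.91, 65)  # p rounds to 0.002
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n_a < 2 || n_b < 2) abort("Both groups need n >= 2.")
  if (sd_a < 0 || sd_b < 0) abort("Standard deviations must be nonnegative.")
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(tibble(statistic = 0, df = n_a + n_b - 2, p_value = 1, flag = TRUE))
    }
    return(tibble(statistic = Inf * sign(mean_a - mean_b), df = n_a + n_b - 2,
                  p_value = 0, flag = TRUE))
  }
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df), flag = FALSE)
}

#' Two-proportion comparison
#'
#' Chi-square test on the 2x2 success table without continuity correction
#' (so exactly equal proportions give p = 1).
#'
#' @param x_a,n_a,x_b,n_b Successes and totals per group.
#' @return A tibble with `p_value` and `flag` (`TRUE` when a zero table
#'   margin makes the test degenerate, reported as p = 1).
#' @examples
#' two_proportion_test(24, 79, 21, 65)
#' @export
two_proportion_test <- function(x_a, n_a, x_b, n_b) {
  if (x_a < 0 || x_b < 0 || x_a > n_a || x_b > n_b) {
    abort("Need 0 <= x <= n in both groups.")
  }
  tab <- rbind(c(x_a, n_a - x_a), c(x_b, n_b - x_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    return(tibble(p_value = 1, flag = TRUE))
  }
  p <- suppressWarnings(prop.test(c(x_a, x_b), c(n_a, n_b),
                                  correct = FALSE)$p.value)
  tibble(p_value = p, flag = FALSE)
}

#' Per-marker group-difference table
#'
#' One row per marker: per-group n/mean/sd, the direction of change in AD
#' relative to NC, and a Welch t-test p-value. Raw p-values are reported
#' (matching the published single-variable analyses); set `adjust = TRUE`
#' for an additional Benjamini-Hochberg column.
#'
#' @param table A cohort tibble with both groups present.
#' @param features Marker columns; defaults to all.
#' @param adjust Add a BH-adjusted `p_adj` column?
#' @return A tibble with columns `feature`, `n_nc`, `nc_mean`, `nc_sd`,
#'   `n_ad`, `ad_mean`, `ad_sd`, `direction` (`"up"` when the AD mean
#'   exceeds the NC mean), `p_value`, `flag` (constant marker, p undefined)
#'   and optionally `p_adj`.
#' @export
marker_group_tests <- function(table, features = NULL, adjust = FALSE) {
  table <- check_cohort(table)
  if (!all(c("AD", "NC") %in% table$group)) {
    abort("Both AD and NC groups must be present.")
  }
  features <- features %||% marker_columns(table)
  out <- purrr::map_dfr(features, function(f) {
    ad <- table[[f]][table$group == "AD"]
    nc <- table[[f]][table$group == "NC"]
    constant <- sd(ad) == 0 && sd(nc) == 0
    p <- if (constant) NA_real_ else t.test(ad, nc)$p.value
    tibble(feature = f,
           n_nc = length(nc), nc_mean = mean(nc), nc_sd = sd(nc),
           n_ad = length(ad), ad_mean = mean(ad), ad_sd = sd(ad),
           direction = ifelse(mean(ad) > mean(nc), "up", "down"),
           p_value = p, flag = constant)
  })
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Classify rank-correlation strength
#'
#' Strong if `|rho|` is in \[0.8, 1\], moderate in \[0.6, 0.8), weak below
#' 0.6 — exhaustive and mutually exclusive over \[-1, 1\].
#'
#' @param rho Spearman coefficients in \[-1, 1\].
#' @return Character vector in `{"strong", "moderate", "weak"}` (`NA` for
#'   `NA` input).
#' @examples
#' classify_correlation_strength(c(0.9252, 0.763290732, -0.1))
#' @export
classify_correlation_strength <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) abort("|rho| cannot exceed 1.")
  dplyr::case_when(
    is.na(rho) ~ NA_character_,
    abs(rho) >= 0.8 ~ "strong",
    abs(rho) >= 0.6 ~ "moderate",
    TRUE ~ "weak")
}

#' Spearman correlation of paired serum/plasma markers
#'
#' Computes the rank correlation (average ranks on ties) for each requested
#' feature pair and classifies its strength. By default all same-named
#' markers present in both fractions are paired.
#'
#' @param table A cohort tibble.
#' @param pairs Optional two-column data frame (`feature_a`, `feature_b`);
#'   defaults to every same-marker serum/plasma pair.
#' @return A tibble with `feature_a`, `feature_b`, `rho`, `strength` and
#'   `flag` (`TRUE` when a constant column makes rho undefined).
#' @export
spearman_pairs <- function(table, pairs = NULL) {
  table <- check_cohort(table)
  if (is.null(pairs)) {
    serum <- sub("^Serum_", "", marker_columns(table, "serum"))
    plasma <- sub("^Plasma_", "", marker_columns(table, "plasma"))
    shared <- intersect(serum, plasma)
    pairs <- tibble(feature_a = sprintf("Serum_%s", shared),
                    feature_b = sprintf("Plasma_%s", shared))
  }
  pairs <- as_tibble(pairs)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$feature_a[i]; b <- pairs$feature_b[i]
    missing <- setdiff(c(a, b), names(table))
    if (length(missing) > 0) {
      abort(paste0("Columns absent from table: ", paste(missing, collapse = ", ")))
    }
    constant <- sd(table[[a]]) == 0 || sd(table[[b]]) == 0
    rho <- if (constant) NA_real_ else
      cor(table[[a]], table[[b]], method = "spearman")
    tibble(feature_a = a, feature_b = b, rho = rho,
           strength = classify_correlation_strength(rho), flag = constant)
  })
}

#' Demographic summary table
#'
#' A cohort-characteristics report in the published layout: one row per
#' covariate with per-group `mean (sd)` and a p-value — pooled Student t for
#' the continuous covariates, uncorrected chi-square for sex.
#'
#' @param table A cohort tibble with `age` (and optionally `education`,
#'   `sex`) columns.
#' @return A tibble with columns `variable`, `ad`, `nc`, `p_value`.
#' @export
demographics_table <- function(table) {
  table <- check_cohort(table)
  rows <- list(tibble(variable = "N",
                      ad = as.character(sum(table$group == "AD")),
                      nc = as.character(sum(table$group == "NC")),
                      p_value = NA_real_))
  for (v in intersect(c("age", "education"), names(table))) {
    ad <- table[[v]][table$group == "AD"]
    nc <- table[[v]][table$group == "NC"]
    tt <- ttest_from_summary(mean(ad), sd(ad), length(ad),
                             mean(nc), sd(nc), length(nc), "pooled")
    rows[[length(rows) + 1]] <- tibble(
      variable = v,
      ad = sprintf("%.2f (%.2f)", mean(ad), sd(ad)),
      nc = sprintf("%.2f (%.2f)", mean(nc), sd(nc)),
      p_value = tt$p_value)
  }
  if ("sex" %in% names(table)) {
    ad_m <- sum(table$sex == "M" & table$group == "AD")
    nc_m <- sum(table$sex == "M" & table$group == "NC")
    n_ad <- sum(table$group == "AD"); n_nc <- sum(table$group == "NC")
    pt <- two_proportion_test(ad_m, n_ad, nc_m, n_nc)
    rows[[length(rows) + 1]] <- tibble(
      variable = "sex (% M)",
      ad = sprintf("%.1f", 100 * ad_m / n_ad),
      nc = sprintf("%.1f", 100 * nc_m / n_nc),
      p_value = pt$p_value)
  }
  bind_rows(rows)
}
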
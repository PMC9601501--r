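test_that("generation is deterministic and balanced, with positive markers", {
  spec <- demo_cohort_spec(seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(sum(a$group == "AD"), 79)
  expect_equal(sum(a$group == "NC"), 65)
  expect_equal(nrow(a), 144)
  mk <- marker_columns(a)
  expect_length(mk, 42)
  expect_true(all(vapply(a[mk], function(v) all(v > 0), logical(1))))
  expect_true(all(a$age >= 40 & a$age <= 110))
  # a different seed changes the draw
  expect_false(identical(a, generate_cohort(demo_cohort_spec(seed = 12))))
})

test_that("adding a marker does not perturb existing marker columns", {
  base <- planted_signal_spec(0, 3, 0, n_ad = 30, n_nc = 30, seed = 9)
  wider <- synthetic_spec(
    rbind(base$markers, marker_spec("ZZZ", "serum", 1, 1)),
    n_ad = 30, n_nc = 30, seed = 9)
  a <- generate_cohort(base)
  b <- generate_cohort(wider)
  for (col in paste0("Serum_M0", 1:3)) expect_identical(a[[col]], b[[col]])
})

test_that("copula hits target Spearman correlations at large n", {
  for (rho in c(-0.9, -0.4, 0.2, 0.7, 0.95)) {
    co <- generate_cohort(tiny_two_marker_spec(seed = 3, rho = rho,
                                               n_ad = 5000, n_nc = 5000))
    emp <- cor(co$Serum_X, co$Plasma_X, method = "spearman")
    expect_lt(abs(emp - rho), 0.02)
  }
})

test_that("log-normal marginals have the spec medians at large n", {
  markers <- rbind(marker_spec("A", "serum", nc_mean = 2.19, ad_mean = 4.40),
                   marker_spec("B", "plasma", nc_mean = 8345, ad_mean = 10110,
                               cv_within = 1.2))
  spec <- synthetic_spec(markers, n_ad = 5000, n_nc = 5000, seed = 21)
  co <- generate_cohort(spec)
  for (i in 1:2) {
    col <- marker_col(spec$markers$fraction[i], spec$markers$name[i])
    for (g in c("AD", "NC")) {
      target <- if (g == "AD") spec$markers$ad_mean[i] else spec$markers$nc_mean[i]
      expect_lt(abs(median(co[[col]][co$group == g]) / target - 1), 0.05)
    }
  }
})

test_that("zero planted effect yields no detectable group difference", {
  # with no effect the per-marker t-test should be non-significant at
  # alpha = 0.01 in the vast majority of seeds
  hits <- vapply(1:25, function(s) {
    co <- generate_cohort(planted_signal_spec(0, 2, 0, n_ad = 200, n_nc = 200,
                                              seed = s))
    p <- t.test(log(Serum_M01) ~ group, data = co)$p.value
    p < 0.01
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("planted AD shifts reproduce the expected direction at cohort scale", {
  # Serum_IL7-style shift (5.26 -> 10.15) should show AD > NC nearly always
  up <- vapply(1:20, function(s) {
    spec <- demo_cohort_spec(seed = s)
    co <- generate_cohort(spec)
    mean(co$Serum_IL7[co$group == "AD"]) > mean(co$Serum_IL7[co$group == "NC"])
  }, logical(1))
  expect_gte(mean(up), 0.95)
})

test_that("planted_signal_spec records the planted markers and validates input", {
  spec <- planted_signal_spec(2, 3, effect_size = 1.5, seed = 1)
  expect_identical(spec$planted, c("Serum_M01", "Serum_M02"))
  expect_equal(nrow(spec$markers), 5)
  expect_error(planted_signal_spec(0, 0, 0), "at least one marker")
  expect_error(planted_signal_spec(1, 1, -0.5), "effect_size")
  # rho != 0 doubles the markers into plasma twins
  spec2 <- planted_signal_spec(1, 1, 1, rho = 0.8)
  expect_equal(nrow(spec2$markers), 4)
  expect_equal(unname(spec2$cross_fraction_rho), rep(0.8, 2))
})

test_that("spec invariants are enforced", {
  m <- marker_spec("A", "serum", 1, 1)
  expect_error(synthetic_spec(rbind(m, m)), "unique")
  expect_error(marker_spec("A", "serum", -1, 1), "positive")
  expect_error(marker_spec("A", "serum", 1, 1, cv_within = 0), "positive")
  expect_error(synthetic_spec(m, n_ad = 1, n_nc = 5), "n_ad")
  both <- rbind(marker_spec("A", "serum", 1, 1), marker_spec("A", "plasma", 1, 1))
  expect_error(synthetic_spec(both, cross_fraction_rho = c(A = 0.999)), "0.99")
  expect_error(synthetic_spec(m, cross_fraction_rho = c(A = 0.5)),
               "absent from both fractions")
})

test_that("an inconsistent latent correlation matrix is rejected with names", {
  # three mutually high negative correlations cannot coexist
  markers <- rbind(marker_spec("A", "serum", 1, 1),
                   marker_spec("B", "serum", 1, 1),
                   marker_spec("C", "serum", 1, 1))
  extra <- tibble::tibble(
    feature_a = c("Serum_A", "Serum_A", "Serum_B"),
    feature_b = c("Serum_B", "Serum_C", "Serum_C"),
    rho = c(-0.9, -0.9, -0.9))
  spec <- synthetic_spec(markers, extra_rho = extra, n_ad = 10, n_nc = 10)
  expect_error(generate_cohort(spec), "positive definite.*Serum_A~Serum_B")
})

test_that("a mildly indefinite matrix is repaired with a warning", {
  markers <- rbind(marker_spec("A", "serum", 1, 1),
                   marker_spec("B", "serum", 1, 1),
                   marker_spec("C", "serum", 1, 1))
  extra <- tibble::tibble(
    feature_a = c("Serum_A", "Serum_A", "Serum_B"),
    feature_b = c("Serum_B", "Serum_C", "Serum_C"),
    rho = c(0.9, 0.9, 0.5))  # slightly below the PD boundary for the triple
  spec <- synthetic_spec(markers, extra_rho = extra, n_ad = 500, n_nc = 500)
  expect_warning(co <- generate_cohort(spec), "repaired")
  expect_equal(nrow(co), 1000)
})

test_that("verify_structure passes its own large-n cohort and flags shuffles", {
  spec <- tiny_two_marker_spec(seed = 5, rho = 0.9, n_ad = 4000, n_nc = 4000)
  co <- generate_cohort(spec)
  rep_ok <- verify_structure(co, spec, tol = 0.05)
  expect_false(any(rep_ok$flagged))
  shuffled <- co
  set.seed(1)
  shuffled$Plasma_X <- sample(shuffled$Plasma_X)
  rep_bad <- verify_structure(shuffled, spec, tol = 0.05)
  expect_true(any(rep_bad$flagged[rep_bad$check == "spearman"]))
  # tol = 0 flags sampling noise even on a faithful finite table
  small <- generate_cohort(tiny_two_marker_spec(seed = 5, n_ad = 40, n_nc = 40))
  expect_true(any(verify_structure(
    small, tiny_two_marker_spec(seed = 5, n_ad = 40, n_nc = 40), tol = 0)$flagged))
  # missing marker errors with its name
  expect_error(verify_structure(co[, setdiff(names(co), "Plasma_X")], spec),
               "Plasma_X")
})

test_that("spec and cohort round-trip through disk formats", {
  spec <- planted_signal_spec(1, 2, 1.2, rho = 0.6, n_ad = 12, n_nc = 12,
                              seed = 4)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_cohort_spec(spec, path)
    back <- read_cohort_spec(path)
    expect_equal(back$markers, spec$markers)
    expect_equal(back$cross_fraction_rho, spec$cross_fraction_rho)
    expect_identical(generate_cohort(back), generate_cohort(spec))
  }
  co <- generate_cohort(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, csv)
  expect_equal(as.data.frame(read_cohort(csv)), as.data.frame(co))
})
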
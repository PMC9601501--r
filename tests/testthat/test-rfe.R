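test_that("weight criterion finds the informative feature and zeroes constants", {
  hits <- vapply(1:10, function(s) {
    spec <- planted_signal_spec(1, 7, effect_size = 2, n_ad = 100, n_nc = 100,
                                seed = s)
    co <- generate_cohort(spec)
    rk <- rank_features(co)
    rk$feature[which.max(rk$value)] == "Serum_M01"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  co <- toy_cohort(n_per = 8)
  co$Serum_const <- 5
  rk <- rank_features(co)
  expect_equal(rk$value[rk$feature == "Serum_const"], 0)
  # order permutation of input columns does not change per-feature weights
  feats <- marker_columns(co)
  rk2 <- rank_features(co, features = rev(feats))
  expect_equal(rk$value[match(feats, rk$feature)],
               rk2$value[match(feats, rk2$feature)], tolerance = 1e-8)
})

test_that("a duplicated column shares weight mass with its twin", {
  co <- toy_cohort(n_per = 10, p_noise = 1)
  co$Serum_dup <- co$Serum_sig
  rk <- rank_features(co)
  w_pair <- sum(rk$value[rk$feature %in% c("Serum_sig", "Serum_dup")])
  expect_gte(w_pair + 1e-12, max(rk$value[rk$feature == "Serum_sig"]))
  expect_gte(w_pair + 1e-12, max(rk$value[rk$feature == "Serum_dup"]))
})

test_that("performance criterion flags the feature whose removal hurts", {
  co <- toy_cohort(n_per = 10, p_noise = 2, shift = 4)
  rk <- rank_features(co, criterion = "performance")
  expect_equal(rk$feature[which.max(rk$value)], "Serum_sig")
  expect_error(rank_features(co, model = svm_model(kernel = "radial")),
               "performance")
})

test_that("rfe eliminates a constant first and respects trace invariants", {
  co <- toy_cohort(n_per = 8, p_noise = 0)
  co$Serum_const <- 1
  res <- rfe(co)
  expect_equal(res$trace$feature[1], "Serum_const")
  expect_true(all(!duplicated(res$trace$feature)))
  expect_lte(nrow(res$trace), length(res$features) - 1)
  expect_equal(res$final_error,
               min(c(res$initial_error, res$trace$error_after)))
  expect_length(intersect(res$selected_features, res$trace$feature[
    res$trace$n_features_after < length(res$selected_features)]), 0)
  expect_setequal(res$ranking$rank, seq_along(res$features))
})

test_that("rfe with infinite patience matches the exhaustive nested-subset oracle", {
  # on small instances, enumerate the elimination-consistent nested chain
  # independently and pick the minimum manual LOOCV error with fewest features
  for (s in 1:3) {
    spec <- planted_signal_spec(2, 3, effect_size = 1.5, n_ad = 10, n_nc = 10,
                                seed = s)
    co <- generate_cohort(spec)
    res <- rfe(co, patience = Inf)
    # chain = full set, then the set after each elimination step
    chain <- list(res$features)
    remaining <- res$features
    for (st in unique(res$trace$step)) {
      remaining <- setdiff(remaining, res$trace$feature[res$trace$step == st])
      chain[[length(chain) + 1]] <- remaining
    }
    expect_equal(length(chain[[length(chain)]]), 1)  # full elimination
    errs <- vapply(chain, function(fs) manual_loocv_error(co, fs), numeric(1))
    # the scorer used inside rfe agrees with the manual oracle
    expect_equal(errs, c(res$initial_error, res$trace$error_after[
      !duplicated(res$trace$step)]), tolerance = 1e-12)
    best <- which(errs == min(errs))
    oracle_pick <- chain[[best[which.min(lengths(chain)[best])]]]
    expect_setequal(res$selected_features, oracle_pick)
  }
})

test_that("rfe recovers planted features and refuses degenerate input", {
  spec <- planted_signal_spec(3, 7, effect_size = 1.5, n_ad = 60, n_nc = 60,
                              seed = 31)
  co <- generate_cohort(spec)
  res <- rfe(co)
  expect_gte(length(intersect(res$selected_features, spec$planted)), 2)
  expect_error(rfe(co, features = "Serum_M01"), "at least 2")
  tiny <- co[c(1, 61, 62), ]
  expect_error(rfe(tiny), "repeated_cv")
})

test_that("pca_reduce preserves variance, ordering and labels", {
  co <- generate_cohort(planted_signal_spec(2, 6, 1, n_ad = 30, n_nc = 30,
                                            seed = 12))
  p <- length(marker_columns(co))
  red <- pca_reduce(co, p)
  expect_identical(red$group, co$group)
  vars <- vapply(paste0("PC", 1:p), function(c) var(red[[c]]), numeric(1))
  expect_true(all(diff(vars) <= 1e-10))  # non-increasing
  # orthogonal rotation preserves total variance of the standardized matrix
  expect_equal(sum(vars), p, tolerance = 1e-8)
  expect_error(pca_reduce(co, p + 1), "exceeds")
  red2 <- pca_reduce(co, 2)
  expect_setequal(marker_columns(red2), c("PC1", "PC2"))
})

test_that("PCA misses signal hidden in low-variance directions; RFE keeps it", {
  # one informative low-variance marker among high-variance noise
  set.seed(77)
  n_per <- 60
  co <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:(2 * n_per)),
    group = rep(c("AD", "NC"), each = n_per))
  for (j in 1:6) co[[sprintf("Serum_big%d", j)]] <- rnorm(2 * n_per, sd = 20)
  co$Serum_small <- 0.05 * (rnorm(2 * n_per) + rep(c(3, 0), each = n_per))
  cfg <- cv_config(k = 5, repeats = 3, seed = 77)
  splits <- stratified_splits(co, cfg)
  pca_out <- repeated_cv(co, config = cfg, splits = splits, n_pca = 2)
  sel <- rfe(co)
  expect_true("Serum_small" %in% sel$selected_features)
  rfe_out <- repeated_cv(co, config = cfg, splits = splits,
                         features = sel$selected_features)
  expect_gt(rfe_out$test_report$accuracy, pca_out$test_report$accuracy)
})

test_that("permutation importance ranks the dominant feature first, noise near zero", {
  spec <- planted_signal_spec(1, 5, effect_size = 2.5, n_ad = 80, n_nc = 80,
                              seed = 19)
  co <- generate_cohort(spec)
  fit <- fit_panel_svm(co)
  imp <- importance_scores(fit, co, m = 30, seed = 19)
  expect_equal(imp$feature[imp$rank == 1], "Serum_M01")
  expect_setequal(imp$rank, 1:6)
  noise_scores <- imp$score[imp$feature != "Serum_M01"]
  expect_lt(max(noise_scores), 2 / sqrt(30 * nrow(co)) + 0.02)
  # deterministic given the seed
  imp2 <- importance_scores(fit, co, m = 30, seed = 19)
  expect_identical(imp, imp2)
})

test_that("leave-one-marker-out quantifies marker contributions", {
  spec <- planted_signal_spec(1, 2, effect_size = 2.5, n_ad = 50, n_nc = 50,
                              seed = 23)
  co <- generate_cohort(spec)
  cfg <- cv_config(k = 5, repeats = 2, seed = 23)
  lomo <- leave_one_marker_out(co, marker_columns(co), config = cfg)
  expect_named(lomo, marker_columns(co))
  acc <- vapply(lomo, function(o) o$test_report$accuracy, numeric(1))
  # dropping the informative marker collapses accuracy toward chance;
  # dropping a noise marker leaves it high
  expect_lt(acc["Serum_M01"], 0.7)
  expect_gt(max(acc[c("Serum_M02", "Serum_M03")]), 0.8)
  expect_error(leave_one_marker_out(co, "Serum_M01"), "one-marker panel")
  expect_error(leave_one_marker_out(co, c("Serum_M01", "Serum_nope")), "nope")
})
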
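# Small fixture builders shared across test files.

tiny_two_marker_spec <- function(seed = 1, rho = 0.9, n_ad = 40, n_nc = 40) {
  markers <- rbind(
    marker_spec("X", "serum", nc_mean = 5, ad_mean = 5),
    marker_spec("X", "plasma", nc_mean = 50, ad_mean = 50))
  synthetic_spec(markers, cross_fraction_rho = c(X = rho),
                 n_ad = n_ad, n_nc = n_nc, seed = seed)
}

# deterministic separable toy cohort, no generator involved
toy_cohort <- function(n_per = 10, p_noise = 2, shift = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per
  out <- tibble::tibble(
    sample_id = sprintf("T%02d", seq_len(n)),
    group = rep(c("AD", "NC"), each = n_per),
    Serum_sig = rnorm(n) + rep(c(shift, 0), each = n_per))
  for (j in seq_len(p_noise)) out[[paste0("Serum_noise", j)]] <- rnorm(n)
  out
}

# independent manual LOOCV over a feature subset (oracle for rfe's scorer)
manual_loocv_error <- function(table, features, model = svm_model()) {
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  mu <- colMeans(x); s <- apply(x, 2, stats::sd); s[s < 1e-12] <- 1
  x <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  y <- factor(as.character(table$group), levels = c("AD", "NC"))
  wrong <- vapply(seq_len(nrow(x)), function(i) {
    fit <- e1071::svm(x = x[-i, , drop = FALSE], y = y[-i],
                      kernel = model$kernel, cost = model$cost, scale = FALSE)
    as.character(predict(fit, x[i, , drop = FALSE])) != as.character(y[i])
  }, logical(1))
  mean(wrong)
}
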
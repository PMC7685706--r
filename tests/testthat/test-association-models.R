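# labelled data with a planted logistic signal on the first k features
make_labelled_data <- function(n, k_signal = 0, n_noise = 3, seed = 1,
                               beta = 1.5) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (k_signal + n_noise)), nrow = n)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    eta <- -2 + if (k_signal > 0)
      x[, seq_len(k_signal), drop = FALSE] %*% rep(beta, k_signal) else 0
    y <- rbinom(n, 1, plogis(eta))
    d <- tibble::as_tibble(as.data.frame(x))
    d$label <- ifelse(y == 1, "causal", "non-causal")
    d$library <- sample(c(0, 1), n, replace = TRUE)
    d$expression <- rnorm(n)
    d$logFC <- abs(eta / 4 + rnorm(n, 0, 0.3))
    d
  })
}

test_that("a label-matching feature is overwhelmingly significant, a null one is not", {
  d <- make_labelled_data(800, k_signal = 0, seed = 2)
  d$strong <- as.integer(d$label == "causal") + rnorm(800, 0, 0.01)
  res <- single_feature_test(d, "strong")
  expect_lt(res$p, 1e-10)
  res_null <- single_feature_test(d, "f1")
  expect_gt(res_null$p, 0.001)
})

test_that("the likelihood-ratio p is invariant to affine feature rescaling", {
  d <- make_labelled_data(400, k_signal = 1, seed = 3)
  p1 <- single_feature_test(d, "f1")$p
  d$f1 <- 2 * d$f1 + 3
  p2 <- single_feature_test(d, "f1")$p
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("null single-feature tests keep nominal type-I error", {
  d <- make_labelled_data(2000, k_signal = 0, n_noise = 1, seed = 4)
  pvals <- vapply(1:120, function(i) {
    d$f1 <- withr::with_seed(5000 + i, rnorm(2000))
    single_feature_test(d, "f1")$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("the model registry enumerates 112 distinct resolvable specs", {
  reg <- build_model_registry()
  expect_equal(nrow(reg), 112)
  expect_equal(nrow(dplyr::distinct(reg[, -1])), 112)
  # every spec resolves to existing feature-matrix columns
  set.seed(5)
  pwms <- simulate_pwms(2, min_len = 4, max_len = 5)
  ref <- fixture_reference(len = 300, seed = 23)
  vv <- dplyr::bind_rows(fixture_snv(ref, 120, id = "v1"),
                         fixture_snv(ref, 160, id = "v2"))
  fm <- build_feature_matrix(vv, ref, pwms)
  sig <- attr(fm, "feature_groups")$per_tf
  for (i in seq_len(nrow(reg))) {
    cols <- spec_features(reg[i, ], fm, significant_features = sig)
    expect_true(all(cols %in% names(fm)))
    expect_gt(length(cols), 0)
  }
})

test_that("a perfectly predictive feature reaches AUC 1 and splits never leak", {
  d <- make_labelled_data(300, seed = 6)
  d$f1 <- as.numeric(d$label == "causal")
  fake_fm <- structure(d, feature_groups = list(nontf = "f1",
                                                per_tf = character(0),
                                                aggregated = character(0)))
  spec <- tibble::tibble(model_id = "M1", nontf = TRUE, strands = "plus",
                         strength = "both", aggregated = FALSE,
                         sig_only = FALSE)
  res <- fit_and_evaluate(spec, d, fake_fm, task = "classify",
                          split_seed = 1, cv_repeats = 1,
                          include_covariates = FALSE)
  expect_equal(res$auc, 1.0)
  expect_equal(res$n_train + res$n_test, 300)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(7)
  aucs <- vapply(1:20, function(s) {
    d <- make_labelled_data(500, k_signal = 2, n_noise = 2, seed = 100 + s)
    d$label <- sample(d$label)
    fake_fm <- structure(d, feature_groups = list(
      nontf = paste0("f", 1:4), per_tf = character(0),
      aggregated = character(0)))
    spec <- tibble::tibble(model_id = "M1", nontf = TRUE, strands = "plus",
                           strength = "both", aggregated = FALSE,
                           sig_only = FALSE)
    fit_and_evaluate(spec, d, fake_fm, task = "classify", split_seed = s,
                     cv_repeats = 1, include_covariates = FALSE)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("a planted logistic signal is learnable well above chance", {
  d <- make_labelled_data(2000, k_signal = 5, n_noise = 2, seed = 8)
  fake_fm <- structure(d, feature_groups = list(
    nontf = paste0("f", 1:7), per_tf = character(0),
    aggregated = character(0)))
  spec <- tibble::tibble(model_id = "M1", nontf = TRUE, strands = "plus",
                         strength = "both", aggregated = FALSE,
                         sig_only = FALSE)
  res <- fit_and_evaluate(spec, d, fake_fm, task = "classify",
                          split_seed = 2, cv_repeats = 2,
                          include_covariates = FALSE)
  expect_gt(res$auc, 0.7)
})

test_that("regression models report test rho and full-data r-squared", {
  d <- make_labelled_data(600, k_signal = 3, n_noise = 2, seed = 9)
  fake_fm <- structure(d, feature_groups = list(
    nontf = paste0("f", 1:5), per_tf = character(0),
    aggregated = character(0)))
  spec <- tibble::tibble(model_id = "M1", nontf = TRUE, strands = "plus",
                         strength = "both", aggregated = FALSE,
                         sig_only = FALSE)
  res <- fit_and_evaluate(spec, d, fake_fm, task = "regress",
                          split_seed = 3, cv_repeats = 1,
                          include_covariates = FALSE)
  expect_true(res$rho > 0 && res$rho <= 1)
  expect_true(res$r2_full > 0 && res$r2_full <= 1)
  # NA-bearing features are excluded up front
  d_na <- d
  d_na$f1[5] <- NA
  res_na <- fit_and_evaluate(spec, d_na, fake_fm, task = "regress",
                             split_seed = 3, cv_repeats = 1,
                             include_covariates = FALSE)
  expect_equal(res_na$n_features, res$n_features - 1)
})

test_that("Storey q-values scale BH by the null proportion", {
  set.seed(10)
  p <- c(runif(50) * 1e-5, runif(950))
  q <- storey_qvalues(p)
  bh <- p.adjust(p, method = "BH")
  pi0 <- estimate_pi1(p)$pi0
  expect_equal(q, pmin(pi0 * bh, 1), tolerance = 1e-12)
  expect_true(all(q <= bh + 1e-12))
})
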
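#' Storey q-values
#'
#' Adaptive false-discovery-rate q-values: the Benjamini-Hochberg
#' adjustment scaled by the estimated proportion of true nulls (pi0 from
#' [estimate_pi1()]).
#'
#' @param p Numeric vector of p-values.
#' @param lambda Lambda passed to [estimate_pi1()].
#' @return q-values in the order of `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  pi0 <- estimate_pi1(p, lambda = lambda)$pi0
  pmin(pi0 * p.adjust(p, method = "BH"), 1)
}

#' Single-feature logistic-regression test of causality
#'
#' Fits `label ~ covariates + feature` by maximum-likelihood logistic
#' regression and contrasts it against the covariate-only model with a
#' likelihood-ratio chi-square test (1 df). Covariates (the library a
#' variant was measured in and the baseline expression of its oligos) are
#' always included.
#'
#' @param data Tibble with the response and predictor columns; the
#'   response must be 0/1 or a two-level factor with `"causal"` as the
#'   positive level.
#' @param feature Name of the feature column (Z-scored upstream).
#' @param label_col Name of the response column (default `"label"`).
#' @param covariates Covariate column names present in `data`.
#' @return One-row tibble: `feature`, `estimate`, `p`, `separation` (TRUE
#'   when the fit showed signs of perfect separation).
#' @export
single_feature_test <- function(data, feature, label_col = "label",
                                covariates = c("library", "expression")) {
  covariates <- intersect(covariates, names(data))
  y <- data[[label_col]]
  if (!is.numeric(y)) y <- as.integer(y == "causal")
  df <- data.frame(y = y, data[, c(covariates, feature), drop = FALSE],
                   check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  rhs_cov <- if (length(covariates)) paste(sprintf("`%s`", covariates),
                                           collapse = " + ") else "1"
  f_full <- stats::as.formula(paste0("y ~ ", rhs_cov, " + `", feature, "`"))
  f_red <- stats::as.formula(paste0("y ~ ", rhs_cov))
  separation <- FALSE
  fit_full <- withCallingHandlers(
    glm(f_full, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  fit_red <- suppressWarnings(glm(f_red, data = df, family = binomial()))
  an <- anova(fit_red, fit_full, test = "Chisq")
  tibble(feature = feature,
         estimate = unname(coef(fit_full)[paste0("`", feature, "`")] %||%
                             coef(fit_full)[feature] %||%
                             utils::tail(coef(fit_full), 1)),
         p = an[["Pr(>Chi)"]][2],
         separation = separation)
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' Single-feature tests over a feature matrix
#'
#' Runs [single_feature_test()] for every feature column and attaches
#' Storey q-values over the feature set. Constant features (flagged by
#' [zscore_features()]) are skipped.
#'
#' @param data Tibble containing label, covariates, and feature columns.
#' @param features Character vector of feature column names.
#' @inheritParams single_feature_test
#' @return Tibble `feature`, `estimate`, `p`, `q`, `separation`.
#' @export
single_feature_tests <- function(data, features, label_col = "label",
                                 covariates = c("library", "expression")) {
  skip <- attr(data, "constant_features") %||% character(0)
  features <- setdiff(features, skip)
  out <- bind_rows(lapply(features, function(f) {
    single_feature_test(data, f, label_col, covariates)
  }))
  out$q <- storey_qvalues(out$p)
  out
}

#' Enumerate the multi-feature model registry
#'
#' Deterministically enumerates 112 feature-subset specifications from the
#' design axes: inclusion of the non-TF features (2), the non-empty
#' subsets of the three strand contexts (7), strong-only / weak-only /
#' both TF metrics (3), and restriction to features significant in the
#' single-feature analyses (2) - 84 base models - plus, for each model
#' using both strong and weak metrics, a variant that adds the 27
#' aggregated TF summary features (28 more). A user-supplied registry
#' tibble with the same columns overrides this enumeration.
#'
#' @return Tibble of 112 `ModelSpec` rows: `model_id`, `nontf`,
#'   `strands`, `strength`, `aggregated`, `sig_only`.
#' @export
build_model_registry <- function() {
  strand_sets <- c("plus", "minus", "agnostic", "plus+minus",
                   "plus+agnostic", "minus+agnostic", "plus+minus+agnostic")
  base <- tidyr::expand_grid(
    nontf = c(TRUE, FALSE), strands = strand_sets,
    strength = c("strong", "weak", "both"), sig_only = c(FALSE, TRUE)) %>%
    mutate(aggregated = FALSE)
  extra <- base %>% filter(.data$strength == "both") %>%
    mutate(aggregated = TRUE)
  out <- bind_rows(base, extra) %>%
    mutate(model_id = sprintf("M%03d", row_number())) %>%
    select("model_id", "nontf", "strands", "strength", "aggregated",
           "sig_only")
  out
}

#' Resolve the feature columns of a model specification
#'
#' @param spec One registry row (see [build_model_registry()]).
#' @param feature_matrix Feature tibble from [build_feature_matrix()]
#'   (uses its `"feature_groups"` attribute).
#' @param significant_features Features significant in the single-feature
#'   analyses (required when `spec$sig_only`).
#' @return Character vector of feature column names.
#' @export
spec_features <- function(spec, feature_matrix, significant_features = NULL) {
  groups <- attr(feature_matrix, "feature_groups")
  if (is.null(groups)) abort("feature_matrix lacks the feature_groups attribute")
  ctxs <- strsplit(spec$strands, "+", fixed = TRUE)[[1]]
  metrics <- switch(spec$strength,
                    strong = c("strong_best", "strong_mean", "strong_count"),
                    weak = c("weak_best", "weak_mean"),
                    both = tf_metrics)
  pat <- paste0("_(", paste(ctxs, collapse = "|"), ")_(",
                paste(metrics, collapse = "|"), ")$")
  cols <- grep(pat, groups$per_tf, value = TRUE)
  if (spec$aggregated) {
    agg_metrics <- c(if (spec$strength != "weak") "strong" else NULL,
                     if (spec$strength != "strong") "weak" else NULL)
    agg_pat <- paste0("^agg_(max|mean)_(", paste(ctxs, collapse = "|"), ")_(",
                      paste(agg_metrics, collapse = "|"), ")_")
    cols <- c(cols, grep(agg_pat, groups$aggregated, value = TRUE),
              grep(paste0("^agg_(", paste(ctxs, collapse = "|"),
                          ")_strong_count_total$"),
                   groups$aggregated, value = TRUE))
  }
  if (spec$nontf) {
    numeric_nontf <- groups$nontf[vapply(groups$nontf, function(cn) {
      is.numeric(feature_matrix[[cn]])
    }, logical(1))]
    cols <- c(numeric_nontf, cols)
  }
  if (isTRUE(spec$sig_only)) {
    if (is.null(significant_features)) {
      abort("sig_only spec requires significant_features")
    }
    cols <- intersect(cols, significant_features)
  }
  constant <- attr(feature_matrix, "constant_features") %||% character(0)
  setdiff(cols, constant)
}

#' Fit and evaluate one multi-feature prediction model
#'
#' Splits the labelled variants into a stratified 90% training / 10% test
#' partition, trains the model on the training set with five-times
#' repeated 10-fold cross-validation (selection metric: Cohen's Kappa at
#' the 0.5 probability threshold for classification, RMSE for
#' regression), refits on the full training set, and reports held-out
#' performance: the ROC AUC for classifiers, or the Spearman correlation
#' between predicted and observed values for regressions (plus the
#' full-data R^2). Features containing any `NA` are excluded before
#' fitting.
#'
#' @param spec One registry row.
#' @param data Tibble with `label` (`"causal"` / `"non-causal"`),
#'   optionally `logFC`, covariate columns, and the feature columns.
#' @param feature_matrix Feature tibble providing the column groups (see
#'   [spec_features()]); `data` must contain its columns.
#' @param task `"classify"` (predict causality) or `"regress"` (predict
#'   the absolute log fold-change).
#' @param split_seed Seed for the train/test split and fold assignment.
#' @param cv_repeats Repeats of the 10-fold cross-validation (default 5).
#' @param significant_features Passed to [spec_features()].
#' @param include_covariates Include `library` / `expression` covariate
#'   columns when present (default TRUE).
#' @return One-row tibble: `model_id`, `task`, `n_features`, `cv_metric`
#'   (best Kappa or RMSE), and `auc` or (`rho`, `r2_full`).
#' @export
fit_and_evaluate <- function(spec, data, feature_matrix,
                             task = c("classify", "regress"),
                             split_seed = 1L, cv_repeats = 5,
                             significant_features = NULL,
                             include_covariates = TRUE) {
  task <- match.arg(task)
  feats <- spec_features(spec, feature_matrix, significant_features)
  if (include_covariates) {
    feats <- c(intersect(c("library", "expression"), names(data)), feats)
  }
  feats <- feats[feats %in% names(data)]
  # exclude NA-bearing features
  feats <- feats[vapply(feats, function(f) !anyNA(data[[f]]), logical(1))]
  if (length(feats) == 0) abort("model specification selects no usable feature")
  keep <- data$label %in% c("causal", "non-causal")
  df <- data[keep, , drop = FALSE]
  y_class <- factor(ifelse(df$label == "causal", "causal", "noncausal"),
                    levels = c("noncausal", "causal"))
  y <- if (task == "classify") y_class else abs(df$logFC)
  x <- as.data.frame(df[, feats, drop = FALSE], check.names = TRUE)
  set.seed(split_seed)
  idx_train <- caret::createDataPartition(y_class, p = 0.9, list = FALSE)[, 1]
  stopifnot(length(intersect(idx_train, setdiff(seq_along(y), idx_train))) == 0)
  ctrl <- caret::trainControl(method = "repeatedcv", number = 10,
                              repeats = cv_repeats,
                              classProbs = task == "classify")
  if (task == "classify") {
    fit <- suppressWarnings(caret::train(
      x = x[idx_train, , drop = FALSE], y = y[idx_train], method = "glm",
      family = binomial(), metric = "Kappa", trControl = ctrl))
    prob <- predict(fit, newdata = x[-idx_train, , drop = FALSE],
                    type = "prob")[, "causal"]
    roc <- pROC::roc(response = y[-idx_train], predictor = prob,
                     levels = c("noncausal", "causal"), direction = "<",
                     quiet = TRUE)
    tibble(model_id = spec$model_id, task = task, n_features = length(feats),
           cv_metric = max(fit$results$Kappa, na.rm = TRUE),
           auc = as.numeric(pROC::auc(roc)),
           n_train = length(idx_train), n_test = length(y) - length(idx_train))
  } else {
    fit <- suppressWarnings(caret::train(
      x = x[idx_train, , drop = FALSE], y = y[idx_train], method = "lm",
      metric = "RMSE", trControl = ctrl))
    pred <- predict(fit, newdata = x[-idx_train, , drop = FALSE])
    rho <- suppressWarnings(cor(pred, y[-idx_train], method = "spearman"))
    full <- lm(y ~ ., data = cbind(y = y, x))
    tibble(model_id = spec$model_id, task = task, n_features = length(feats),
           cv_metric = min(fit$results$RMSE, na.rm = TRUE),
           rho = rho, r2_full = summary(full)$r.squared,
           n_train = length(idx_train), n_test = length(y) - length(idx_train))
  }
}
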
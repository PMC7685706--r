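#' Test variants for differential allelic activity
#'
#' For each variant, per-replicate activity differences between the oligo
#' carrying the RM allele and the matched BY oligo are tested with a
#' paired t-statistic. The log2 fold-change is the mean difference
#' (positive = RM allele drives higher expression). With `moderation =
#' TRUE` (default) the per-variant variance is shrunk toward a global
#' prior estimated across all variants by method of moments, and the test
#' uses the correspondingly augmented degrees of freedom; this stabilises
#' variances estimated from few replicates.
#'
#' @param expression Expression tibble (`oligo_id`, `replicate`,
#'   `activity`) from [compute_expression()].
#' @param pairs Variant-to-oligo map from [variant_pairs()]
#'   (`variant_id`, `by_oligo`, `rm_oligo`, plus `gene`/`library` carried
#'   through).
#' @param moderation Apply empirical-Bayes variance moderation.
#' @return A `promvar_tests` tibble: `variant_id`, `gene`, `library`,
#'   `logFC`, `t`, `df`, `p`, `q`, `n_replicates`. Pairs whose oligos lack
#'   the full replicate set are dropped. Requires at least 2 replicates
#'   (>= 3 recommended).
#' @export
test_variants <- function(expression, pairs, moderation = TRUE) {
  act <- expression %>%
    tidyr::pivot_wider(names_from = "replicate", values_from = "activity")
  mat <- as.matrix(act[, -1, drop = FALSE])
  rownames(mat) <- act$oligo_id
  ok <- pairs$by_oligo %in% rownames(mat) & pairs$rm_oligo %in% rownames(mat)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) abort("no testable variant pairs")
  d <- mat[pairs$rm_oligo, , drop = FALSE] - mat[pairs$by_oligo, , drop = FALSE]
  n <- rowSums(!is.na(d))
  if (any(n < 2)) abort("each variant needs at least 2 replicates")
  logfc <- rowMeans(d, na.rm = TRUE)
  s2 <- apply(d, 1, var, na.rm = TRUE)
  df_resid <- n - 1
  if (moderation && nrow(pairs) >= 3) {
    sq <- squeeze_variances(s2, df_resid)
    s2_used <- sq$var_post
    df_used <- df_resid + sq$df_prior
  } else {
    s2_used <- s2
    df_used <- df_resid
  }
  tstat <- logfc / sqrt(s2_used / n)
  p <- 2 * pt(abs(tstat), df = df_used, lower.tail = FALSE)
  # exact null: zero variance with zero effect
  degenerate <- s2_used == 0
  p[degenerate & logfc == 0] <- 1
  p[degenerate & logfc != 0] <- .Machine$double.xmin
  res <- tibble(
    variant_id = pairs$variant_id,
    gene = if ("gene" %in% names(pairs)) pairs$gene else NA_character_,
    library = if ("library" %in% names(pairs)) pairs$library else NA_character_,
    logFC = unname(logfc), t = unname(tstat), df = unname(df_used),
    p = unname(p), n_replicates = unname(n))
  res$q <- adjust_fdr(res$p)
  class(res) <- c("promvar_tests", class(res))
  res
}

# Method-of-moments empirical-Bayes variance shrinkage on the log scale.
# Marginally s2 ~ s0^2 * F(df, df0), so z = log(s2) has
#   Var(z) = trigamma(df/2) + trigamma(df0/2).
# Matching the observed variance of z recovers the prior df (df0); the
# prior scale (s0^2) comes from the mean of z with the corresponding
# digamma bias corrections. Posterior variance:
#   (df0*s0^2 + df*s2) / (df0 + df).
squeeze_variances <- function(s2, df) {
  d <- mean(df)
  pos <- s2 > 0
  if (sum(pos) < 3) {
    m <- mean(s2)
    return(list(var_post = rep(m, length(s2)), df_prior = Inf,
                var_prior = m))
  }
  z <- log(s2[pos])
  excess <- var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= trigamma(1e4 / 2)) {
    # observed variances no more dispersed than chi-square sampling noise:
    # effectively infinite prior df, fully pooled variance
    m <- mean(s2)
    return(list(var_post = rep(m, length(s2)), df_prior = Inf,
                var_prior = m))
  }
  df0 <- 2 * trigamma_inverse(excess)
  e_log_s0_2 <- mean(z) - digamma(d / 2) + log(d / 2) +
    digamma(df0 / 2) - log(df0 / 2)
  s0_2 <- exp(e_log_s0_2)
  list(var_post = (df0 * s0_2 + df * s2) / (df0 + df),
       df_prior = df0, var_prior = s0_2)
}

# Newton solve trigamma(y) = x for y > 0 (x > 0)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values (same order as `p`).
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  p.adjust(p, method = "BH")
}

#' Aggregate test results across libraries and strand contexts
#'
#' When a variant was assayed several times (both libraries, or both
#' orientations of a divergent promoter), the record with the smallest
#' p-value (ties broken by larger |logFC|) represents the variant
#' downstream.
#'
#' @param results A `promvar_tests` tibble.
#' @param by Grouping columns defining one aggregated record (default
#'   `"variant_id"`; use `c("variant_id", "strand")` to keep divergent
#'   orientations separate).
#' @return Tibble with one minimum-p record per group; `q` is recomputed
#'   over the aggregated records.
#' @export
aggregate_across_contexts <- function(results, by = "variant_id") {
  if (nrow(results) == 0) abort("empty result set")
  out <- results %>%
    group_by(across(all_of(by))) %>%
    arrange(.data$p, dplyr::desc(abs(.data$logFC)), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  out$q <- adjust_fdr(out$p)
  if (!inherits(out, "promvar_tests")) {
    class(out) <- c("promvar_tests", class(out))
  }
  out
}

#' Estimate the fraction of non-null tests (pi1)
#'
#' Storey's estimator: `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`
#' clipped to \[0, 1\], with `pi1 = 1 - pi0`. The default uses a fixed
#' `lambda = 0.5`; with `smooth = TRUE` a cubic smoother over the lambda
#' grid is extrapolated to `lambda -> 1`.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Single lambda (fixed estimator) or a grid for the
#'   smoother.
#' @param smooth Use the smoother over the grid.
#' @return List with `pi0`, `pi1`, `lambda`.
#' @export
estimate_pi1 <- function(p, lambda = 0.5, smooth = length(lambda) > 1) {
  if (length(p) == 0) abort("empty p-value vector")
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  if (smooth) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = min(3, length(lambda) - 1))
    pi0 <- predict(fit, x = max(lambda))$y
  } else {
    pi0 <- pi0_l[length(pi0_l)]
  }
  pi0 <- min(max(pi0, 0), 1)
  list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda)
}

#' Label variants as causal or non-causal
#'
#' Causal: FDR q-value at or below `causal_q` (default 5% FDR).
#' Non-causal: raw p-value above `noncausal_p` (default 0.2). Variants in
#' between are excluded from feature analyses.
#'
#' @param results Test results with `p` and `q` columns.
#' @param causal_q FDR threshold for the causal label.
#' @param noncausal_p Raw-p threshold for the non-causal label.
#' @return `results` with a `label` column in
#'   `c("causal", "non-causal", "excluded")`.
#' @export
classify_variants <- function(results, causal_q = 0.05, noncausal_p = 0.2) {
  out <- results %>%
    mutate(label = dplyr::case_when(
      .data$q <= causal_q ~ "causal",
      .data$p > noncausal_p ~ "non-causal",
      TRUE ~ "excluded"))
  if (inherits(results, "promvar_tests") &&
      !inherits(out, "promvar_tests")) {
    class(out) <- c("promvar_tests", class(out))
  }
  out
}
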
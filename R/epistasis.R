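#' Test a variant pair for a non-additive interaction
#'
#' Fits ordinary least squares `activity ~ x1 + x2 + x1:x2` on the
#' per-replicate activities of the four oligos carrying all combinations
#' of the two alleles (`x1`, `x2` indicate the RM allele at each variant).
#' The interaction p-value comes from the F-test contrasting the full
#' model against the additive model without the product term (equivalent
#' to the t-test on the interaction coefficient).
#'
#' @param pair_data Tibble with columns `x1`, `x2` (0/1 indicators),
#'   `replicate`, `activity`; all four allele combinations must be
#'   present.
#' @return A `promvar_interaction` object wrapping the fitted `lm`, with
#'   elements `beta` (named estimates b0, b1, b2, b3), `p_interaction`,
#'   and `fit`.
#' @export
test_interaction <- function(pair_data) {
  combos <- distinct(pair_data, .data$x1, .data$x2)
  if (nrow(combos) != 4) {
    abort("rank-deficient design: all four allele combinations are required")
  }
  fit <- lm(activity ~ x1 * x2, data = pair_data)
  red <- lm(activity ~ x1 + x2, data = pair_data)
  an <- anova(red, fit)
  p <- an[["Pr(>F)"]][2]
  beta <- coef(fit)
  names(beta) <- c("b0", "b1", "b2", "b3")
  structure(list(beta = beta, p_interaction = p, fit = fit),
            class = "promvar_interaction")
}

#' @exportS3Method generics::tidy
tidy.promvar_interaction <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("b0", "b1", "b2", "b3"),
         estimate = unname(x$beta),
         std_error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p_value = unname(s[, "Pr(>|t|)"]))
}

#' @exportS3Method generics::glance
glance.promvar_interaction <- function(x, ...) {
  tibble(b3 = unname(x$beta["b3"]), p_interaction = x$p_interaction,
         r_squared = summary(x$fit)$r.squared,
         df_residual = x$fit$df.residual)
}

#' Interaction tests for all four-oligo variant pairs
#'
#' Runs [test_interaction()] on every pair found by
#' [interaction_pairs()], reading per-replicate activities from an
#' expression table; pairs whose four oligos do not all pass the
#' expression filter are skipped. FDR over the tested pairs is
#' Benjamini-Hochberg.
#'
#' @param expression Expression tibble (`oligo_id`, `replicate`,
#'   `activity`).
#' @param pairs Pair table from [interaction_pairs()].
#' @return Tibble `block_id`, `gene`, `v1`, `v2`, `b0`..`b3`,
#'   `p_interaction`, `q`.
#' @export
test_interactions <- function(expression, pairs) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    oligos <- c(pairs$o_bb[i], pairs$o_rb[i], pairs$o_br[i], pairs$o_rr[i])
    if (!all(oligos %in% expression$oligo_id)) next
    dat <- bind_rows(
      expression %>% filter(.data$oligo_id == oligos[1]) %>%
        mutate(x1 = 0, x2 = 0),
      expression %>% filter(.data$oligo_id == oligos[2]) %>%
        mutate(x1 = 1, x2 = 0),
      expression %>% filter(.data$oligo_id == oligos[3]) %>%
        mutate(x1 = 0, x2 = 1),
      expression %>% filter(.data$oligo_id == oligos[4]) %>%
        mutate(x1 = 1, x2 = 1))
    res <- test_interaction(dat)
    rows[[length(rows) + 1]] <- tibble(
      block_id = pairs$block_id[i], gene = pairs$gene[i],
      v1 = pairs$v1[i], v2 = pairs$v2[i],
      b0 = res$beta[["b0"]], b1 = res$beta[["b1"]],
      b2 = res$beta[["b2"]], b3 = res$beta[["b3"]],
      p_interaction = res$p_interaction)
  }
  if (length(rows) == 0) {
    return(tibble(block_id = character(0), gene = character(0),
                  v1 = character(0), v2 = character(0), b0 = numeric(0),
                  b1 = numeric(0), b2 = numeric(0), b3 = numeric(0),
                  p_interaction = numeric(0), q = numeric(0)))
  }
  out <- bind_rows(rows)
  out$q <- adjust_fdr(out$p_interaction)
  out
}
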
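#' Aggregate per-variant effects to genes
#'
#' Sums or selects reporter-assay variant effects per gene: all assayed
#' variants, significant variants only (FDR at or below `causal_q`), the
#' most significant variant, or the second-most significant variant.
#'
#' @param results Variant test results (`variant_id`, `gene`, `logFC`,
#'   `p`, `q`).
#' @param selection One of `"all"`, `"significant"`, `"top1"`, `"top2"`.
#' @param causal_q FDR threshold defining significance (default 0.05).
#' @return Tibble `gene`, `effect`, `n_variants` (genes with no
#'   qualifying variant are absent).
#' @export
aggregate_gene_effects <- function(results,
                                   selection = c("all", "significant",
                                                 "top1", "top2"),
                                   causal_q = 0.05) {
  selection <- match.arg(selection)
  ranked <- results %>%
    filter(!is.na(.data$gene)) %>%
    group_by(.data$gene) %>%
    arrange(.data$p, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()
  sel <- switch(selection,
    all = ranked,
    significant = ranked %>% filter(.data$q <= causal_q),
    top1 = ranked %>% filter(.data$q <= causal_q, .data$rank == 1),
    top2 = ranked %>% filter(.data$q <= causal_q, .data$rank == 2))
  sel %>%
    group_by(.data$gene) %>%
    summarise(effect = sum(.data$logFC), n_variants = dplyr::n(),
              .groups = "drop")
}

# 95% CI for Spearman's rho via the Fisher z transform with the
# rank-correlation variance adjustment sqrt((1 + rho^2/2)/(n - 3))
spearman_ci <- function(rho, n, conf = 0.95) {
  if (n <= 3 || abs(rho) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  q <- qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Correlate aggregated variant effects with local eQTL effects
#'
#' Spearman rank correlation between per-gene aggregated reporter effects
#' and local eQTL effects, with a 95% confidence interval, optionally
#' restricted to strong eQTLs (`lod >= lod_min`) and stratified by a
#' per-gene flag (e.g. nucleosome occupancy of the variants).
#'
#' @param gene_effects Tibble from [aggregate_gene_effects()].
#' @param eqtl Tibble `gene`, `effect`, `lod`.
#' @param lod_min Minimum LOD score (default 0 = no filter).
#' @param strata Optional tibble `gene`, `stratum` for per-stratum
#'   correlations.
#' @return Tibble with one row per stratum (plus `"overall"`): `stratum`,
#'   `n`, `rho`, `p`, `ci_lo`, `ci_hi`.
#' @export
correlate_with_eqtl <- function(gene_effects, eqtl, lod_min = 0,
                                strata = NULL) {
  joined <- gene_effects %>%
    inner_join(eqtl, by = "gene", suffix = c("_mpra", "_eqtl")) %>%
    filter(.data$lod >= lod_min)
  if (nrow(joined) < 5) abort("fewer than 5 genes after filtering")
  one <- function(d, label) {
    ct <- suppressWarnings(cor.test(d$effect_mpra, d$effect_eqtl,
                                    method = "spearman"))
    ci <- spearman_ci(unname(ct$estimate), nrow(d))
    tibble(stratum = label, n = nrow(d), rho = unname(ct$estimate),
           p = ct$p.value, ci_lo = ci[1], ci_hi = ci[2])
  }
  out <- one(joined, "overall")
  if (!is.null(strata)) {
    js <- joined %>% inner_join(strata, by = "gene")
    for (s in unique(js$stratum)) {
      d <- js %>% filter(.data$stratum == s)
      if (nrow(d) >= 5) out <- bind_rows(out, one(d, as.character(s)))
    }
  }
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Wraps the exact hypergeometric test and reports both the conditional
#' maximum-likelihood odds ratio (the standard exact-test estimate) and
#' the sample odds ratio.
#'
#' @param tab 2x2 matrix or table of counts.
#' @return Tibble `odds_ratio` (conditional MLE), `sample_or`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
fet_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("fet_2x2 needs a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 table: a margin is zero")
  }
  ft <- fisher.test(tab)
  sample_or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble(odds_ratio = unname(ft$estimate), sample_or = sample_or,
         p = ft$p.value, ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2])
}

#' Directional agreement between variant and eQTL effects
#'
#' Cross-tabulates the sign of the per-gene top-variant reporter effect
#' against the sign of the local eQTL effect and tests for association
#' with a two-sided Fisher's exact test.
#'
#' @param mpra_effect,eqtl_effect Numeric vectors aligned by gene (zeros
#'   dropped).
#' @return List with `table` (2x2) and `test` (tibble from [fet_2x2()]).
#' @export
directional_agreement <- function(mpra_effect, eqtl_effect) {
  keep <- !is.na(mpra_effect) & !is.na(eqtl_effect) &
    mpra_effect != 0 & eqtl_effect != 0
  if (!any(keep)) abort("no genes with both effect signs available")
  tab <- table(mpra = mpra_effect[keep] > 0, eqtl = eqtl_effect[keep] > 0)
  if (!all(dim(tab) == c(2, 2))) {
    abort("degenerate sign table: one sign class is empty")
  }
  list(table = tab, test = fet_2x2(tab))
}

#' Enrichment of causal variants in genes with allele-specific expression
#'
#' Tests, by two-sided Fisher's exact test, whether genes with significant
#' allele-specific expression are more likely to harbor a causal reporter
#' variant.
#'
#' @param has_causal,has_ase Logical vectors aligned by gene.
#' @return List with `table` and `test` (see [fet_2x2()]).
#' @export
ase_enrichment <- function(has_causal, has_ase) {
  keep <- !is.na(has_causal) & !is.na(has_ase)
  if (!any(keep)) abort("empty input")
  tab <- table(causal = has_causal[keep], ase = has_ase[keep])
  if (!all(dim(tab) == c(2, 2))) {
    abort("degenerate table: a flag has a single level")
  }
  list(table = tab, test = fet_2x2(tab))
}
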
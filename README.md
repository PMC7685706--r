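# promvar

Design and analysis of massively parallel reporter assays (MPRAs) that
dissect *cis*-regulatory variants in yeast promoters.

In a cross between two yeast isolates (the laboratory strain BY and the
vineyard strain RM), thousands of promoter variants segregate, and linkage
collapses their effects into aggregated "local eQTL" signals, hiding which
individual variants are causal. An MPRA breaks this linkage: each promoter
fragment (oligo) carrying a defined allele configuration is cloned upstream
of a barcoded reporter, and the log2 ratio of summed barcode RNA counts to
DNA counts measures the regulatory activity driven by that exact sequence.
`promvar` implements the full computational pipeline for such a study, for
researchers analysing their own reporter data or building simulation-backed
method studies:

- **Library design** — TSS oligo blocks (all variants in the 144 bp
  upstream of the transcription start site: one all-BY oligo, one
  single-RM oligo per variant, one all-RM oligo) and Upstream blocks
  (allele pairs centered on a focal variant); restriction-site and
  synthesis-length filtering; A-rich reverse-complementation; constrained
  random 20-nt barcodes.
- **Barcode annotation** — building the barcode-to-oligo dictionary from
  merged amplicon reads via invariant anchor sequences, modal
  ("primary") oligo resolution, and perfect-match retention against the
  design.
- **Quantification** — index demultiplexing with one allowed mismatch,
  exact-match barcode counting, "sum" aggregation to oligos,
  missing-DNA-sample policies, counts-per-million normalisation, and the
  activity metric `log2(RNA/DNA)`.
- **Variant testing** — for each variant a paired test of the RM versus
  BY oligo activities across replicates with empirical-Bayes variance
  moderation; Benjamini–Hochberg FDR; smallest-p aggregation across
  libraries; Storey's π₁ (the estimated fraction of non-null tests);
  causal / non-causal labelling.
- **Epistasis and LD** — the interaction test
  `y = β₀ + β₁x₁ + β₂x₂ + β₃x₁x₂ + ε` on four-oligo variant pairs, and
  D′/r² linkage disequilibrium from isolate genotypes.
- **TFBS features** — allelic position-weight-matrix scanning in sliding
  windows over each variant (plus, minus, and strand-agnostic contexts;
  strong versus weak sites split at per-TF cutoffs), 15 features per TF
  and 27 aggregated summary features, plus non-TF sequence and annotation
  features.
- **Causality models** — single-feature logistic-regression tests
  (likelihood-ratio, with library and baseline-expression covariates) and
  a registry of 112 cross-validated multi-feature classifiers/regressors
  evaluated by held-out AUC or Spearman ρ.
- **eQTL comparison** — per-gene aggregation of variant effects and
  comparison against local eQTL effect tables (Spearman correlations with
  confidence intervals, directional-agreement and allele-specific
  expression Fisher tests).
- **Synthetic data** — a ground-truth-known generator (negative-binomial
  barcode counts, planted allelic effects and interactions, noisy
  gene-level eQTL effects) that powers the test suite and calibration
  studies.

## Worked example

Simulate a small study with planted |log2 FC| = 1 effects at 25% of
variants, quantify, and test:

```r
library(promvar)
library(dplyr)

cfg   <- sim_config(n_genes = 40, causal_fraction = 0.25, seed = 2026)
study <- simulate_mpra_study(cfg, effect_size = 1.0)
expr  <- compute_expression(aggregate_to_oligos(study$counts))
res   <- test_variants(expr, variant_pairs(study$manifest)) |>
  aggregate_across_contexts() |>
  classify_variants()

glance(res)
#> # A tibble: 1 × 4
#>   n_variants n_significant   pi1 median_abs_logFC
#>        <int>         <int> <dbl>            <dbl>
#> 1         74            26 0.216           0.0386

head(arrange(as_tibble(res), p), 4)
#> # A tibble: 4 × 10
#>   variant_id gene    library logFC     t    df         p n_replicates         q
#>   <chr>      <chr>   <chr>   <dbl> <dbl> <dbl>     <dbl>        <dbl>     <dbl>
#> 1 v0021      gene011 TSS      1.06  32.8   Inf 1.85e-235            6 1.37e-233
#> 2 v0061      gene034 TSS      1.04  32.1   Inf 2.14e-226            6 7.91e-225
#> 3 v0033      gene018 TSS      1.04  32.0   Inf 4.78e-224            6 1.18e-222
#> 4 v0025      gene014 TSS     -1.02 -31.4  Inf  4.66e-217            6 8.62e-216

table(res$label)
#>     causal   excluded non-causal
#>         26          9         39
```

74 variants survive design and filtering; 26 reach 5% FDR, with estimated
log2 fold-changes close to the planted ±1.0 (positive logFC means the RM
allele drives higher expression). π₁ ≈ 0.22 estimates the non-null
fraction among tested variants. `autoplot(res)` draws the volcano plot,
and `plot_allele_activity(expr, variant_pairs(study$manifest), "v0021")`
shows the per-replicate allele comparison for one variant.

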
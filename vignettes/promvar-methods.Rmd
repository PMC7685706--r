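---
title: "Models and methods behind promvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind promvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promvar)
```

`promvar` analyses massively parallel reporter assays (MPRAs) that measure
the *cis*-regulatory consequences of individual promoter variants
segregating between two yeast strains (BY, the reference-like laboratory
strain, and RM, a vineyard isolate). This vignette explains the models the
package implements, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The measurement model

Each designed promoter fragment ("oligo") is tagged by many random 20-nt
barcodes expressed in the 3' end of the reporter mRNA. For oligo $o$ in
replicate $r$, activity is quantified as

$$a_{or} = \log_2 \frac{\mathrm{RNA\ cpm}_{or} + c}{\mathrm{DNA\ cpm}_{or} + c},$$

where RNA and DNA counts are first summed over the oligo's barcodes
("sum" aggregation), each sample is scaled to counts per million, and $c$
is a pseudocount (default 0.5). Oligos are retained only if their summed
counts are positive in every replicate in both assays; with that filter
the plain ratio ($c = 0$) is well defined, and the pseudocount only guards
user data with extreme library-size imbalance. CPM was adopted as the
library-size normalisation; it makes the activity exactly invariant to
per-sample rescaling at $c = 0$ (a property the test suite asserts).

Counting is deliberately strict: sample indexes may mismatch by at most
one base (and must be unambiguous), barcode reads must match an annotated
barcode exactly, and a barcode's "primary" oligo — the modal oligo
sequence among its annotation reads — must match a designed sequence
exactly. Ties for the primary oligo discard the barcode (a conservative
choice affecting only low-count barcodes); barcodes are never
error-collapsed. When an RNA sample lacks its DNA partner, the default
policy copies the DNA counts of another sample from the same batch; sum-,
annotation- and drop-based policies are provided because the choice is a
judgement call that should stay visible to the analyst.

## The allelic test

For variant $v$ with matched oligo pair (BY allele, RM allele), the
per-replicate differences $d_r = a^{RM}_r - a^{BY}_r$ give
$\widehat{\mathrm{logFC}} = \bar d$ (positive = RM drives higher
expression, the sign convention used everywhere downstream) and a paired
t-statistic. With the default empirical-Bayes moderation, per-variant
variances are shrunk toward a global prior: sample variances are modelled
as $s^2 \sim s_0^2 F(d, d_0)$, the prior degrees of freedom $d_0$ are
estimated by matching the variance of $\log s^2$ (its theoretical value is
$\psi'(d/2) + \psi'(d_0/2)$), and the posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ is tested on $d + d_0$ degrees of freedom.
This estimator agrees numerically with limma's `squeezeVar` (asserted in
the tests against that independent implementation) and stabilises the
variance at the 6–12 replicates typical of these assays. Moderation can be
switched off, in which case the test reduces exactly to the paired t-test.
On planted-null count simulations the moderated test's type-I error at
$\alpha = 0.05$ averages 0.050 across seeds; single-seed estimates
fluctuate binomially.

FDR is Benjamini–Hochberg. When a variant is assayed in several contexts
(both libraries, or both orientations of a divergent promoter), the
smallest-p record represents it downstream, with p ties broken by larger
|logFC| (the tie-break is our choice; ties are measure-zero in practice).
The non-null fraction is estimated as
$\pi_1 = 1 - \pi_0$ with Storey's
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1 - \lambda))$, fixed
$\lambda = 0.5$ by default; an optional smoother over a $\lambda$ grid
extrapolates toward $\lambda \to 1$. Variants are labelled *causal* at
$q \le 0.05$, *non-causal* at raw $p > 0.2$, and excluded in between, so
the feature analyses contrast confident calls rather than borderline ones.

## Epistasis and linkage disequilibrium

TSS blocks with exactly two variants contain all four allele combinations,
allowing the interaction model
$y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_1 x_2 + \varepsilon$
on per-replicate activities ($x_i$ = RM indicator). The interaction
p-value is the F-test of the full versus additive model, equivalent to the
t-test on $\beta_3$; with balanced replicates $\hat\beta_3$ equals the
cell-mean contrast $(RR - RB) - (BR - BB)$, which the tests use as a
closed-form oracle. Replicate is not used as a blocking factor: the
activities are already per-replicate ratios, so replicate-wide scale
effects cancel within each observation, and plain OLS keeps the model
identical to the published form.

LD between two markers uses haploid/homozygous isolate calls and the two
most frequent alleles at each marker:
$D = p_{AB} - p_A p_B$, $D' = |D| / D_{\max}$, and
$r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, with
$D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D > 0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ otherwise. Heterozygous and missing calls
are dropped, monomorphic markers are flagged rather than silently zeroed,
and $D'$ is reported as an absolute value in $[0, 1]$.

## TFBS features

For each variant and each TF's position weight matrix (length $L$,
columns A/C/G/T, plus a per-TF "strong site" score cutoff), windows of
width $L$ slide over the variant in 1-bp steps; a window's score is the
sum of position weights for its bases, and every window overlapping the
variant span is scored. Windows at or above the cutoff are *strong*,
windows below it are *weak* — read as $\ge$ / $<$ so the two sets
partition all windows. Three strand contexts are scored: plus (the sense
sequence), minus (its reverse complement), and strand-agnostic (the union
of both strands' windows). Per context, five allelic metrics — |Δ best
strong score|, |Δ mean strong score|, |Δ strong-site count|, |Δ best weak
score|, |Δ mean weak score| — give 15 features per TF (2940 for 196 TFs).
Aggregation across TFs yields 27 summary features: the summed strong-count
change per context (3) and the max and mean of the best/mean differences
per strength and context (12 + 12).

Open corners were closed as follows. If either allele has no qualifying
window for a best/mean metric, that feature is 0 (keeping the matrix dense
rather than propagating NA); the count metric is always defined. Variant
spans for indels use the left-anchored allele plus one base of right
flank, so a deletion allele's windows are those overlapping the junction
and an insertion's windows cover the inserted bases and their flanking
bases; windows appearing on both strands in the agnostic context each
count once per strand. Non-TF features count TATA-box consensus matches
(`TATA(A/T)A(A/T)(A/G)`) and `ATG` occurrences per allele on its flanked
sequence, indel length, a nucleosome-bound flag (variant position within a
closed ±72 bp interval around a reported nucleosome center), and
derived-allele frequency (the outgroup isolate's call defines the
ancestral allele; heterozygous outgroup calls yield NA); conservation
scores, essentiality and similar annotations are joined as supplied, never
computed. Features are Z-scored with the population SD; zero-variance
columns are flagged and excluded from regressions.

## Causality models

Single-feature tests fit
$\mathrm{logit}\,P(\text{causal}) = \beta_0 + \beta_{lib} x_{lib} +
\beta_{expr} x_{expr} + \beta_f x_f$ and compare against the
covariate-only model with a likelihood-ratio $\chi^2_1$ test; the
covariates (library and baseline oligo expression) absorb the main
confounders of detection power. q-values over the feature set use the
Storey-scaled BH adjustment. Perfect separation is flagged rather than
hidden.

The multi-feature registry enumerates 112 specifications from the design
axes — non-TF features in/out (2) × non-empty strand-context subsets (7)
× strong-only/weak-only/both metrics (3) × significant-features-only
in/out (2), giving 84 base models, plus an aggregated-features variant for
each model that already uses both strong and weak metrics (28). The exact
composition of the published 112 subsets is not recoverable from text, so
this deterministic enumeration is our reconstruction of the stated axes;
a user-supplied registry table overrides it. Each model is evaluated with
a stratified 90/10 train/test split and five-times-repeated 10-fold
cross-validation on the training set (selection metric: Cohen's Kappa at
the 0.5 probability threshold for classifiers, RMSE for regressors, via
caret), refit on the full training set, and scored on the held-out 10% by
ROC AUC (classification) or Spearman ρ between predicted and observed
absolute log fold-changes (regression, plus the full-data $R^2$).
Features containing any NA are excluded before fitting; covariates are
included by default (the published description leaves this open) and can
be switched off. Elastic-net variants are deliberately omitted: the
unregularised models are the primary analysis, and regularisation was
reported not to improve them.

## Comparison with local eQTLs

Per-gene aggregates of variant effects (sum of all, sum of significant,
top or second-most-significant variant) are compared against local eQTL
effect tables by Spearman correlation, optionally restricted to strong
eQTLs (LOD threshold) and stratified (e.g. nucleosome-free versus bound).
Confidence intervals use the Fisher z transform with the rank-correlation
variance $\left(1 + \rho^2/2\right)/(n-3)$. Directional agreement between
top-variant and eQTL effect signs, and enrichment of causal variants in
genes with allele-specific expression, use two-sided Fisher's exact tests
reporting the conditional-MLE odds ratio (the sample odds ratio is also
emitted). Summed aggregation makes cancellation visible: two significant
variants of opposite sign sum to zero, reproducing promoters that carry
causal variants yet show no eQTL.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:
per-gene promoter contigs with 1-based variants (SNVs and left-anchored
1–20 bp indels, geometric length — the length law is our choice, as no
empirical distribution is published), oligo blocks built by the real
design code, a Poisson number of barcodes per oligo, and negative-binomial
DNA/RNA counts in which the RNA mean is the DNA mean times
$2^{\text{baseline} + \text{effect} + \text{interaction}}$ times a
log-normal per-sample library-size factor ($\sigma_{\log} = 0.3$; only
relative variation matters). Baseline activities are log-normal so the
expression covariate has variance; dispersion is shared across barcodes —
the simplest model consistent with replicate-correlation behaviour — and
is a free parameter, since the empirical barcode-count dispersion of such
assays is not published. Non-causal variants have planted effect exactly
0, and gene-level eQTL effects are the noisy sums of planted variant
effects.

The generator does **not** simulate read-level sequencing errors, barcode
synthesis artifacts, PCR jackpotting, chromatin context, or correlated
variant effects; annotation-module tests therefore use reads constructed
(and optionally corrupted) explicitly. Passing tests show the pipeline's
statistical operations are correct and calibrated under this model; they
do not certify performance on real data whose noise violates it.

## Problem sizes and numerical choices

The test suite and acceptance script scale simulations to what the checks
need, as the package's own choice of study size: 2000 variants × 6
replicates for null calibration, 200 planted variants at deep coverage
(≥ 80 barcodes/oligo, DNA mean ≥ 100) for effect recovery, 20 repeated
runs for empirical FDR, $10^4$ p-values for π₁ recovery, 1000 additive
pairs for interaction calibration, and an 80-gene end-to-end study. Seeds
fix every draw; `sim_config(seed = )` propagates to all downstream
randomness. Degenerate inputs are errors, not silent defaults: zero genes,
empty p-value vectors, rank-deficient interaction designs, monomorphic LD
markers, degenerate contingency margins, and insufficient PWM flanks all
abort with explicit messages. An A/T tie in the reverse-complementation
rule does not flip; the barcode generator errors when asked for more
barcodes than the constrained space ($2 \times 3^{11} \times 4^{8}$ at
length 20) contains.

## Known limitations

The per-variant test is a paired moderated t on oligo-level activities; it
does not weight barcodes by depth or model barcode-level counts (a
mixed-model route left out of scope). The 112-model registry is a
reconstruction of the stated design axes, not the published table. LD
handles biallelic, effectively-haploid genotypes only. Restriction-site
screening defaults to the three cloning enzymes (SfiI, AscI, SbfI) and is
configurable because the screened set is not enumerated in text. The
moderated test inherits the small, well-known anti-conservativeness of
empirical-Bayes pooling when true variances are heterogeneous; moderation
can be disabled where exactness matters more than power.
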
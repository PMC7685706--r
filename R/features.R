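tf_contexts <- c("plus", "minus", "agnostic")
tf_metrics <- c("strong_best", "strong_mean", "strong_count",
                "weak_best", "weak_mean")

#' Allelic TF-binding features for one variant and one PWM
#'
#' In each of the three strand contexts, windows at or above the TF's
#' cutoff are "strong" matches and windows below it are "weak" (the two
#' sets partition all windows). Five metrics are computed per context: the
#' absolute allelic difference in the best and in the mean score over
#' strong windows, the absolute difference in the number of strong
#' windows, and the absolute differences in best and mean score over weak
#' windows. Best/mean differences are set to 0 unless both alleles have at
#' least one qualifying window.
#'
#' @param alleles Output of [variant_alleles()].
#' @param pwm A `promvar_pwm`.
#' @return Named numeric vector of 15 features
#'   (`<tf>_<context>_<metric>`).
#' @export
tf_features <- function(alleles, pwm) {
  out <- numeric(0)
  for (ctx in tf_contexts) {
    s_by <- score_windows(alleles$by$seq, alleles$by$span_start,
                          alleles$by$span_end, pwm, ctx)
    s_rm <- score_windows(alleles$rm$seq, alleles$rm$span_start,
                          alleles$rm$span_end, pwm, ctx)
    strong_by <- s_by[s_by >= pwm$cutoff]
    strong_rm <- s_rm[s_rm >= pwm$cutoff]
    weak_by <- s_by[s_by < pwm$cutoff]
    weak_rm <- s_rm[s_rm < pwm$cutoff]
    both_diff <- function(a, b, f) {
      if (length(a) > 0 && length(b) > 0) abs(f(b) - f(a)) else 0
    }
    vals <- c(
      strong_best = both_diff(strong_by, strong_rm, max),
      strong_mean = both_diff(strong_by, strong_rm, mean),
      strong_count = abs(length(strong_rm) - length(strong_by)),
      weak_best = both_diff(weak_by, weak_rm, max),
      weak_mean = both_diff(weak_by, weak_rm, mean))
    names(vals) <- paste0(pwm$tf, "_", ctx, "_", names(vals))
    out <- c(out, vals)
  }
  out
}

#' Per-TF feature block for a set of variants
#'
#' Applies [tf_features()] over all variants and PWMs, yielding the
#' 15-features-per-TF block (with `n_tf` PWMs, `15 * n_tf` columns).
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference Named character vector of chromosome sequences.
#' @param pwms List of `promvar_pwm` objects.
#' @param flank Flank width for allele extraction; default one more than
#'   the longest PWM.
#' @return Tibble: `variant_id` plus one column per TF feature.
#' @export
tf_feature_matrix <- function(variants, reference, pwms, flank = NULL) {
  if (length(pwms) == 0) abort("at least one PWM is required")
  if (is.null(flank)) {
    flank <- max(vapply(pwms, function(p) nrow(p$mat), integer(1))) + 1L
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    al <- variant_alleles(variants[i, ], reference, flank)
    feats <- unlist(lapply(pwms, function(p) tf_features(al, p)))
    c(list(variant_id = variants$variant_id[i]), as.list(feats))
  })
  bind_rows(lapply(rows, as_tibble))
}

#' Aggregate per-TF features into 27 summary features
#'
#' Summarises the TF axis of a per-TF feature block for one variant: in
#' each strand context the total number of strong sites changed (3
#' features), and for every strength x best/mean x context combination
#' the maximum (12) and the average (12) allelic difference across TFs.
#'
#' @param tf_block One-variant per-TF feature tibble/row (columns named
#'   `<tf>_<context>_<metric>`), or the full matrix from
#'   [tf_feature_matrix()] (aggregated row-wise; keeps `variant_id`).
#' @return Tibble of 27 `agg_*` columns (plus `variant_id` if present).
#' @export
aggregate_tf_features <- function(tf_block) {
  tf_block <- as_tibble(tf_block)
  has_id <- "variant_id" %in% names(tf_block)
  feat_cols <- setdiff(names(tf_block), "variant_id")
  if (length(feat_cols) == 0) abort("no TF feature columns (zero TFs?)")
  agg_one <- function(row) {
    vals <- numeric(0)
    for (ctx in tf_contexts) {
      cols <- grep(paste0("_", ctx, "_strong_count$"), feat_cols, value = TRUE)
      v <- setNames(sum(unlist(row[cols])),
                    paste0("agg_", ctx, "_strong_count_total"))
      vals <- c(vals, v)
    }
    for (strength in c("strong", "weak")) {
      for (stat in c("best", "mean")) {
        for (ctx in tf_contexts) {
          cols <- grep(paste0("_", ctx, "_", strength, "_", stat, "$"),
                       feat_cols, value = TRUE)
          x <- unlist(row[cols])
          vals <- c(vals,
                    setNames(max(x), paste0("agg_max_", ctx, "_",
                                            strength, "_", stat)),
                    setNames(mean(x), paste0("agg_mean_", ctx, "_",
                                             strength, "_", stat)))
        }
      }
    }
    vals
  }
  out <- bind_rows(lapply(seq_len(nrow(tf_block)), function(i) {
    as_tibble(as.list(agg_one(tf_block[i, feat_cols])))
  }))
  if (has_id) out <- bind_cols(tf_block["variant_id"], out)
  out
}

#' Count TATA-box consensus matches
#'
#' Counts (possibly overlapping) occurrences of the consensus
#' `TATA(A/T)A(A/T)(A/G)` in a sequence.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Integer vector of match counts.
#' @export
count_tata <- function(sequence) {
  vapply(sequence, count_regex_overlapping, integer(1),
         pattern = "TATA[AT]A[AT][AG]", USE.NAMES = FALSE)
}

#' Count start codons
#'
#' Counts (possibly overlapping) occurrences of `ATG`.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Integer vector of match counts.
#' @export
count_atg <- function(sequence) {
  vapply(sequence, count_regex_overlapping, integer(1),
         pattern = "ATG", USE.NAMES = FALSE)
}

#' Nucleosome-bound flag for variant positions
#'
#' A variant is nucleosome-bound if its position falls within any
#' `[center - 72, center + 72]` interval (closed on both ends) around a
#' reported nucleosome center on its chromosome.
#'
#' @param variants Variant tibble (`chrom`, `pos`).
#' @param nucleosomes Tibble of nucleosome centers (`chrom`, `center`).
#' @param halfwidth Extension on each side of the center (default 72).
#' @return Logical vector along `variants`.
#' @export
nucleosome_bound <- function(variants, nucleosomes, halfwidth = 72) {
  vapply(seq_len(nrow(variants)), function(i) {
    nc <- nucleosomes$center[nucleosomes$chrom == variants$chrom[i]]
    any(abs(nc - variants$pos[i]) <= halfwidth)
  }, logical(1))
}

#' Derived-allele assignment and frequency
#'
#' The ancestral allele is the call carried by the outgroup isolate (the
#' early-diverged Taiwanese strain); the derived allele is the other one.
#' Variants where the outgroup is heterozygous or missing, or carries
#' neither allele, get `NA`. The derived-allele frequency is computed over
#' non-missing, non-heterozygous isolate calls.
#'
#' @param variants Variant tibble with `variant_id`, `ref`, `alt`.
#' @param genotypes Long tibble of isolate calls: `variant_id`, `isolate`,
#'   `allele` (heterozygous calls contain `"/"`).
#' @param outgroup Isolate name serving as outgroup.
#' @return Tibble `variant_id`, `derived_allele`, `derived_is_alt`,
#'   `derived_freq`.
#' @export
derived_allele_frequency <- function(variants, genotypes, outgroup) {
  clean <- genotypes %>%
    filter(!is.na(.data$allele), !grepl("/", .data$allele, fixed = TRUE))
  og <- clean %>% filter(.data$isolate == outgroup) %>%
    select("variant_id", ancestral = "allele")
  rest <- clean %>% filter(.data$isolate != outgroup)
  variants %>%
    select("variant_id", "ref", "alt") %>%
    left_join(og, by = "variant_id") %>%
    mutate(derived_allele = dplyr::case_when(
      is.na(.data$ancestral) ~ NA_character_,
      .data$ancestral == .data$ref ~ .data$alt,
      .data$ancestral == .data$alt ~ .data$ref,
      TRUE ~ NA_character_)) %>%
    mutate(derived_is_alt = .data$derived_allele == .data$alt) %>%
    left_join(
      rest %>% group_by(.data$variant_id) %>%
        summarise(calls = list(.data$allele), .groups = "drop"),
      by = "variant_id") %>%
    mutate(derived_freq = purrr::map2_dbl(
      .data$calls, .data$derived_allele,
      function(calls, da) {
        if (is.null(calls) || is.na(da) || length(calls) == 0) return(NA_real_)
        mean(calls == da)
      })) %>%
    select("variant_id", "derived_allele", "derived_is_alt", "derived_freq")
}

#' Non-TF sequence and annotation features
#'
#' Computes the sequence-derived non-TF features (per-allele TATA-box and
#' start-codon counts on the flanked allele sequence plus their absolute
#' allelic differences, indel length, SNV indicator) and joins the
#' externally supplied annotations: nucleosome binding, derived-allele
#' frequency, and any per-variant or per-gene pass-through columns
#' (conservation scores, essentiality, expression level, ...). External
#' annotations are consumed, never computed.
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, optionally `gene`).
#' @param reference Named character vector of chromosome sequences.
#' @param flank Flank width for the allele sequences (default 50).
#' @param nucleosomes Optional nucleosome-center tibble (see
#'   [nucleosome_bound()]).
#' @param genotypes,outgroup Optional isolate genotypes and outgroup name
#'   (see [derived_allele_frequency()]).
#' @param variant_annotations Optional tibble joined by `variant_id`.
#' @param gene_annotations Optional tibble joined by `gene`.
#' @return Tibble of non-TF features, one row per variant.
#' @export
nontf_features <- function(variants, reference, flank = 50,
                           nucleosomes = NULL, genotypes = NULL,
                           outgroup = NULL, variant_annotations = NULL,
                           gene_annotations = NULL) {
  seqs <- lapply(seq_len(nrow(variants)), function(i) {
    variant_alleles(variants[i, ], reference, flank)
  })
  by_seq <- vapply(seqs, function(s) s$by$seq, character(1))
  rm_seq <- vapply(seqs, function(s) s$rm$seq, character(1))
  out <- tibble(
    variant_id = variants$variant_id,
    tata_by = count_tata(by_seq), tata_rm = count_tata(rm_seq),
    atg_by = count_atg(by_seq), atg_rm = count_atg(rm_seq),
    indel_length = abs(nchar(variants$ref) - nchar(variants$alt)),
    is_snv = as.integer(nchar(variants$ref) == 1 & nchar(variants$alt) == 1)) %>%
    mutate(tata_diff = abs(.data$tata_rm - .data$tata_by),
           atg_diff = abs(.data$atg_rm - .data$atg_by))
  if (!is.null(nucleosomes)) {
    out$nucleosome_bound <- as.integer(nucleosome_bound(variants, nucleosomes))
  }
  if (!is.null(genotypes) && !is.null(outgroup)) {
    out <- out %>%
      left_join(derived_allele_frequency(variants, genotypes, outgroup) %>%
                  select("variant_id", "derived_freq"),
                by = "variant_id")
  }
  if (!is.null(variant_annotations)) {
    out <- out %>% left_join(variant_annotations, by = "variant_id")
  }
  if (!is.null(gene_annotations) && "gene" %in% names(variants)) {
    out <- out %>%
      left_join(variants %>% select("variant_id", "gene"), by = "variant_id") %>%
      left_join(gene_annotations, by = "gene") %>%
      select(-"gene")
  }
  out
}

#' Z-score feature columns
#'
#' Standardises each numeric column by its across-variant mean and
#' population standard deviation. Zero-variance columns are left
#' unscaled and flagged in the `"constant_features"` attribute so model
#' code can exclude them.
#'
#' @param features Feature tibble (non-numeric columns pass through).
#' @param exclude Column names never scaled (default `"variant_id"` and
#'   any label column).
#' @return The tibble with scaled columns.
#' @export
zscore_features <- function(features, exclude = c("variant_id", "label")) {
  constant <- character(0)
  for (col in setdiff(names(features), exclude)) {
    x <- features[[col]]
    if (!is.numeric(x)) next
    mu <- mean(x, na.rm = TRUE)
    sigma <- sqrt(mean((x - mu)^2, na.rm = TRUE))
    if (!is.finite(sigma) || sigma == 0) {
      constant <- c(constant, col)
      next
    }
    features[[col]] <- (x - mu) / sigma
  }
  attr(features, "constant_features") <- constant
  features
}

#' Assemble the full variant feature matrix
#'
#' Binds the non-TF block, the per-TF block (15 features per TF) and the
#' 27 aggregated TF summary features into one wide variant-by-feature
#' tibble. Column groups are recorded in the `"feature_groups"` attribute.
#'
#' @inheritParams tf_feature_matrix
#' @inheritParams nontf_features
#' @return Wide feature tibble keyed by `variant_id`.
#' @export
build_feature_matrix <- function(variants, reference, pwms, flank = NULL,
                                 nucleosomes = NULL, genotypes = NULL,
                                 outgroup = NULL, variant_annotations = NULL,
                                 gene_annotations = NULL) {
  tf_block <- tf_feature_matrix(variants, reference, pwms, flank)
  agg_block <- aggregate_tf_features(tf_block)
  nontf_block <- nontf_features(variants, reference,
                                flank = if (is.null(flank)) 50 else flank,
                                nucleosomes = nucleosomes,
                                genotypes = genotypes, outgroup = outgroup,
                                variant_annotations = variant_annotations,
                                gene_annotations = gene_annotations)
  out <- nontf_block %>%
    left_join(tf_block, by = "variant_id") %>%
    left_join(agg_block, by = "variant_id")
  attr(out, "feature_groups") <- list(
    nontf = setdiff(names(nontf_block), "variant_id"),
    per_tf = setdiff(names(tf_block), "variant_id"),
    aggregated = setdiff(names(agg_block), "variant_id"))
  out
}
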
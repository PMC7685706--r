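#' Demultiplex index reads with one allowed mismatch
#'
#' Assigns each observed index read to a sample iff exactly one expected
#' index lies within Hamming distance 1; reads matching zero or multiple
#' indexes stay unassigned. Expected indexes must be pairwise distance >= 3
#' so one mismatch cannot create ambiguity.
#'
#' @param observed Character vector of observed index reads.
#' @param expected Tibble with `sample` and `index` columns (equal-length
#'   indexes).
#' @param max_mismatch Allowed mismatches (default 1).
#' @return Character vector of sample assignments (`NA` = unassigned).
#' @export
demultiplex <- function(observed, expected, max_mismatch = 1) {
  idx_len <- unique(nchar(expected$index))
  if (length(idx_len) != 1) abort("expected indexes must share one length")
  if (any(nchar(observed) != idx_len)) {
    abort("observed index length does not match the expected indexes")
  }
  exp_mat <- do.call(rbind, strsplit(expected$index, "", fixed = TRUE))
  obs_mat <- do.call(rbind, strsplit(observed, "", fixed = TRUE))
  out <- rep(NA_character_, length(observed))
  # distance from each observed read to each expected index
  for (i in seq_along(observed)) {
    d <- rowSums(exp_mat != matrix(obs_mat[i, ], nrow = nrow(exp_mat),
                                   ncol = idx_len, byrow = TRUE))
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1) out[i] <- expected$sample[hit]
  }
  out
}

#' Count barcodes per sample against an annotation dictionary
#'
#' Exact-match counting: only barcodes present in the dictionary are
#' retained; reads whose barcode does not perfectly match an annotated
#' barcode are excluded. Technical replicates of the same culture are
#' summed.
#'
#' @param barcode_reads Tibble of barcode observations with columns
#'   `barcode`, `sample` and optionally `n` (pre-tallied counts, default
#'   1 per row).
#' @param dictionary Dictionary tibble with `barcode`, `oligo_id`.
#' @param sample_sheet Tibble mapping `sample` to `assay`, `replicate`,
#'   `batch` (technical replicates share assay/replicate/batch).
#' @return Barcode-level count tibble: `barcode`, `oligo_id`, `assay`,
#'   `replicate`, `batch`, `count` (zero rows omitted).
#' @export
count_barcodes <- function(barcode_reads, dictionary, sample_sheet) {
  if (!"n" %in% names(barcode_reads)) barcode_reads$n <- 1L
  barcode_reads %>%
    semi_join(dictionary, by = "barcode") %>%
    left_join(sample_sheet, by = "sample") %>%
    group_by(.data$barcode, .data$assay, .data$replicate, .data$batch) %>%
    summarise(count = sum(.data$n), .groups = "drop") %>%
    left_join(dictionary %>% select("barcode", "oligo_id"), by = "barcode") %>%
    select("barcode", "oligo_id", "assay", "replicate", "batch", "count")
}

#' Aggregate barcode-level counts to oligos
#'
#' Oligo counts are the sum over the oligo's barcodes, per sample and
#' assay ("sum" aggregation). Total reads are conserved.
#'
#' @param counts Barcode-level count tibble with `oligo_id` (e.g. from
#'   [count_barcodes()] or [simulate_counts()]).
#' @return Oligo-level count tibble: `oligo_id`, `assay`, `replicate`,
#'   `batch`, `count`.
#' @export
aggregate_to_oligos <- function(counts) {
  if (!"batch" %in% names(counts)) counts$batch <- 1L
  counts %>%
    group_by(.data$oligo_id, .data$assay, .data$replicate, .data$batch) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Fill in missing DNA samples
#'
#' When an RNA sample has no DNA partner, its DNA column is filled
#' according to `policy`: copy the DNA counts of another sample from the
#' same batch (`"same_batch"`), use the elementwise sum of all DNA samples
#' (`"sum_all"`), substitute externally supplied annotation-run counts
#' (`"annotation"`), or drop the RNA sample (`"drop"`).
#'
#' @param counts Oligo-level count tibble.
#' @param missing_replicates Integer vector of replicate ids lacking DNA.
#' @param policy One of `"same_batch"`, `"sum_all"`, `"annotation"`,
#'   `"drop"`.
#' @param annotation_counts Tibble `oligo_id`, `count` (for policy
#'   `"annotation"`).
#' @return Count tibble with DNA rows present for every retained RNA
#'   replicate; the fill provenance is recorded in the `"dna_fill"`
#'   attribute.
#' @export
handle_missing_dna <- function(counts, missing_replicates,
                               policy = c("same_batch", "sum_all",
                                          "annotation", "drop"),
                               annotation_counts = NULL) {
  policy <- match.arg(policy)
  if (length(missing_replicates) == 0) return(counts)
  counts <- counts %>%
    filter(!(.data$assay == "DNA" &
               .data$replicate %in% missing_replicates))
  if (policy == "drop") {
    out <- counts %>% filter(!.data$replicate %in% missing_replicates)
    attr(out, "dna_fill") <- tibble(replicate = missing_replicates,
                                    source = "dropped")
    return(out)
  }
  dna <- counts %>% filter(.data$assay == "DNA")
  fills <- list()
  prov <- list()
  for (r in missing_replicates) {
    batch_r <- counts$batch[counts$replicate == r][1]
    filled <- switch(policy,
      same_batch = {
        donor <- dna %>% filter(.data$batch == batch_r)
        if (nrow(donor) == 0) {
          abort(sprintf("no same-batch DNA donor for replicate %s", r))
        }
        donor_rep <- min(donor$replicate)
        src <- donor %>% filter(.data$replicate == donor_rep)
        prov[[length(prov) + 1]] <- tibble(
          replicate = r, source = paste0("replicate_", donor_rep))
        src
      },
      sum_all = {
        prov[[length(prov) + 1]] <- tibble(replicate = r,
                                           source = "sum_of_all_DNA")
        dna %>% group_by(.data$oligo_id) %>%
          summarise(count = sum(.data$count), .groups = "drop") %>%
          mutate(assay = "DNA", batch = batch_r)
      },
      annotation = {
        if (is.null(annotation_counts)) {
          abort("annotation policy requires annotation_counts")
        }
        prov[[length(prov) + 1]] <- tibble(replicate = r,
                                           source = "annotation_run")
        annotation_counts %>% mutate(assay = "DNA", batch = batch_r)
      })
    filled$replicate <- r
    fills[[length(fills) + 1]] <- filled %>%
      select("oligo_id", "assay", "replicate", "batch", "count")
  }
  out <- bind_rows(counts, bind_rows(fills))
  attr(out, "dna_fill") <- bind_rows(prov)
  out
}

#' Compute per-oligo, per-replicate log2 expression
#'
#' Retains oligos with summed barcode counts above zero in every replicate
#' in both DNA and RNA, normalises each sample to counts-per-million, and
#' reports `log2((RNA_cpm + pseudocount) / (DNA_cpm + pseudocount))`.
#'
#' @param oligo_counts Oligo-level count tibble (from
#'   [aggregate_to_oligos()]).
#' @param pseudocount Pseudocount added to both CPM values (default 0.5;
#'   0 reproduces the plain ratio).
#' @return Expression tibble `oligo_id`, `replicate`, `activity`, with
#'   library sizes in the `"library_sizes"` attribute and the retained
#'   oligo set in `"retained_oligos"`.
#' @export
compute_expression <- function(oligo_counts, pseudocount = 0.5) {
  n_rep <- length(unique(oligo_counts$replicate))
  keep <- oligo_counts %>%
    group_by(.data$oligo_id) %>%
    summarise(ok = sum(.data$count > 0) == 2L * n_rep &&
                dplyr::n() == 2L * n_rep, .groups = "drop") %>%
    filter(.data$ok) %>% pull(.data$oligo_id)
  if (length(keep) == 0) abort("no oligo passes the all-replicates-nonzero filter")
  libsize <- oligo_counts %>%
    group_by(.data$assay, .data$replicate) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  wide <- oligo_counts %>%
    filter(.data$oligo_id %in% keep) %>%
    left_join(libsize, by = c("assay", "replicate")) %>%
    mutate(cpm = .data$count / .data$total * 1e6) %>%
    select("oligo_id", "assay", "replicate", "cpm") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "cpm")
  out <- wide %>%
    mutate(activity = log2((.data$RNA + pseudocount) /
                             (.data$DNA + pseudocount))) %>%
    select("oligo_id", "replicate", "activity")
  attr(out, "library_sizes") <- libsize
  attr(out, "retained_oligos") <- keep
  out
}

#' Average promoter-driven expression per gene
#'
#' Mean activity over all oligos designed from a gene's promoter
#' (irrespective of allele), used to compare reporter activity with native
#' gene expression and as the baseline-expression covariate in feature
#' models.
#'
#' @param expression Expression tibble from [compute_expression()].
#' @param manifest Oligo manifest (maps `oligo_id` to `gene`).
#' @return Tibble `gene`, `mean_activity`.
#' @export
gene_level_expression <- function(expression, manifest) {
  expression %>%
    left_join(manifest %>% select("oligo_id", "gene"), by = "oligo_id") %>%
    group_by(.data$gene) %>%
    summarise(mean_activity = mean(.data$activity), .groups = "drop")
}
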
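#' Read a variant table
#'
#' TSV with columns `chrom`, `pos` (1-based), `ref` (BY allele), `alt`
#' (RM allele) and optionally `variant_id`, `gene`. Missing ids are
#' generated.
#'
#' @param path TSV path.
#' @return Variant tibble.
#' @export
read_variant_table <- function(path) {
  v <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v))) {
    abort(paste("variant table needs columns:", paste(need, collapse = ", ")))
  }
  if (!"variant_id" %in% names(v)) {
    v$variant_id <- sprintf("v%04d", seq_len(nrow(v)))
  }
  bad <- v$ref == v$alt
  if (any(bad)) abort(sprintf("%d variant(s) with ref == alt", sum(bad)))
  v
}

#' Read a directory of PWM files with a cutoff table
#'
#' @param dir Directory of whitespace-matrix PWM files (one per TF; file
#'   base name = TF name).
#' @param cutoffs Tibble or TSV path with columns `tf`, `cutoff`.
#' @return List of `promvar_pwm` objects.
#' @export
read_pwm_set <- function(dir, cutoffs) {
  if (is.character(cutoffs)) {
    cutoffs <- readr::read_tsv(cutoffs, show_col_types = FALSE)
  }
  files <- list.files(dir, full.names = TRUE)
  lapply(files, function(f) {
    tf <- sub("\\.[^.]*$", "", basename(f))
    cut <- cutoffs$cutoff[cutoffs$tf == tf]
    if (length(cut) != 1) abort(sprintf("no cutoff for TF '%s'", tf))
    read_pwm(f, tf = tf, cutoff = cut)
  })
}

#' Write the main tabular artefacts of a study
#'
#' Convenience TSV writers for the oligo manifest, barcode dictionary and
#' count tables.
#'
#' @param x Tibble to write.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_promvar_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
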
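#' Construct a position weight matrix object
#'
#' @param tf Transcription-factor name.
#' @param mat Numeric matrix, positions x bases, with columns
#'   `A`, `C`, `G`, `T`.
#' @param cutoff Score threshold at or above which a sequence window is a
#'   "strong" match.
#' @return A `promvar_pwm` object.
#' @export
new_pwm <- function(tf, mat, cutoff) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat)) || !setequal(colnames(mat), c("A", "C", "G", "T"))) {
    abort("pwm matrix needs columns A, C, G, T")
  }
  mat <- mat[, c("A", "C", "G", "T"), drop = FALSE]
  if (nrow(mat) < 1) abort("pwm must have at least one position")
  if (!is.finite(cutoff)) abort("pwm cutoff must be finite")
  structure(list(tf = tf, mat = mat, cutoff = cutoff), class = "promvar_pwm")
}

#' @export
print.promvar_pwm <- function(x, ...) {
  cat(sprintf("<promvar_pwm> %s: %d positions, cutoff %.3g\n",
              x$tf, nrow(x$mat), x$cutoff))
  invisible(x)
}

#' Read a whitespace-matrix PWM file
#'
#' Parses the base-per-row text format used by yeast TF motif databases:
#' four lines starting with `A`, `C`, `G`, `T` (an optional `|` separator
#' is ignored), each followed by one weight per motif position.
#'
#' @param path File path.
#' @param tf TF name (default: file base name).
#' @param cutoff Strong-match score cutoff for this TF.
#' @return A `promvar_pwm`.
#' @export
read_pwm <- function(path, tf = NULL, cutoff) {
  if (is.null(tf)) tf <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[grepl("^[ACGT]\\b", lines) | grepl("^[ACGT]\\s*\\|", lines)]
  if (length(lines) != 4) abort("expected four base rows (A, C, G, T)")
  base <- substr(lines, 1, 1)
  vals <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(sub("^[ACGT]\\s*\\|?", "", l)), "\\s+")[[1]])
  })
  if (length(unique(lengths(vals))) != 1) {
    abort("unequal row lengths in PWM file")
  }
  mat <- do.call(cbind, setNames(vals, base))
  new_pwm(tf, mat, cutoff)
}

#' Score sliding PWM windows over a variant
#'
#' Scores every window of width equal to the PWM length that overlaps at
#' least one base of the variant span, in one-base-pair increments. The
#' score of a window is the sum of the position weights for its bases.
#' `context = "plus"` scans the sequence as given; `"minus"` scans the
#' reverse complement; `"agnostic"` pools the windows of both strands.
#'
#' @param sequence Allele sequence with flanks (character scalar). Flanks
#'   must extend at least `nrow(pwm$mat) - 1` bases on both sides of the
#'   span.
#' @param span_start,span_end 1-based span of the variant allele within
#'   `sequence`.
#' @param pwm A `promvar_pwm`.
#' @param context `"plus"`, `"minus"`, or `"agnostic"`.
#' @return Numeric vector of window scores.
#' @export
score_windows <- function(sequence, span_start, span_end, pwm,
                          context = c("plus", "minus", "agnostic")) {
  context <- match.arg(context)
  L <- nrow(pwm$mat)
  n <- nchar(sequence)
  if (context == "minus") {
    return(score_windows(revcomp(sequence), n - span_end + 1L,
                         n - span_start + 1L, pwm, "plus"))
  }
  if (context == "agnostic") {
    return(c(score_windows(sequence, span_start, span_end, pwm, "plus"),
             score_windows(sequence, span_start, span_end, pwm, "minus")))
  }
  s_min <- span_start - L + 1L
  s_max <- span_end
  if (s_min < 1L || s_max > n - L + 1L) {
    abort("insufficient flank: extend the sequence by at least pwm length - 1")
  }
  idx <- match(str_bases(sequence), c("A", "C", "G", "T"))
  starts <- s_min:s_max
  scores <- numeric(length(starts))
  for (i in seq_len(L)) {
    w <- unname(pwm$mat[i, ])[idx[starts + i - 1L]]
    w[is.na(w)] <- 0
    scores <- scores + w
  }
  scores
}

#' Extract flanked allele sequences and spans for a variant
#'
#' Builds, for each allele, the allele string embedded in `flank` bases of
#' reference context, and the window-overlap span used by
#' [score_windows()]: for SNVs the substituted base; for indels the
#' left-anchored allele plus one base of right flank (for a deletion
#' allele this is the junction base).
#'
#' @param variant One-row tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param reference Named character vector of chromosome sequences.
#' @param flank Flank width (must be >= PWM length - 1 for scoring).
#' @return List with `by` and `rm`, each
#'   `list(seq, span_start, span_end)`.
#' @export
variant_alleles <- function(variant, reference, flank) {
  stopifnot(nrow(variant) == 1)
  chrom_seq <- reference[[variant$chrom]]
  if (is.null(chrom_seq)) abort(sprintf("unknown chromosome '%s'", variant$chrom))
  p <- variant$pos
  ref <- variant$ref
  alt <- variant$alt
  left <- substr(chrom_seq, max(1L, p - flank), p - 1L)
  right <- substr(chrom_seq, p + nchar(ref),
                  min(nchar(chrom_seq), p + nchar(ref) + flank - 1L))
  if (nchar(left) < flank || nchar(right) < flank) {
    abort("variant too close to the contig edge for the requested flank")
  }
  obs <- substr(chrom_seq, p, p + nchar(ref) - 1L)
  if (obs != ref) {
    abort(sprintf("reference mismatch at %s:%d", variant$chrom, p))
  }
  is_indel <- nchar(ref) != nchar(alt)
  mk <- function(allele) {
    span_start <- nchar(left) + 1L
    span_end <- span_start + nchar(allele) - 1L + if (is_indel) 1L else 0L
    list(seq = paste0(left, allele, right),
         span_start = span_start, span_end = span_end)
  }
  list(by = mk(ref), rm = mk(alt))
}

#' Simulate a random PWM set
#'
#' Draws PWMs with log-odds-like weights for testing and synthetic
#' studies; the cutoff is placed near the upper tail of achievable scores
#' so strong matches are sparse, as in curated motif collections.
#'
#' @param n_tf Number of TFs.
#' @param min_len,max_len Motif length range.
#' @param prefix Name prefix.
#' @return List of `promvar_pwm` objects.
#' @export
simulate_pwms <- function(n_tf, min_len = 5, max_len = 12, prefix = "TF") {
  lapply(seq_len(n_tf), function(i) {
    L <- sample(min_len:max_len, 1)
    mat <- matrix(rnorm(L * 4, 0, 1.5), nrow = L,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    best <- sum(apply(mat, 1, max))
    new_pwm(sprintf("%s%03d", prefix, i), mat, cutoff = 0.8 * best)
  })
}
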
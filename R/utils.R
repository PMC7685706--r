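#' Reverse-complement a DNA string
#'
#' Vectorised reverse complement for plain character DNA. IUPAC wildcard `N`
#' maps to itself.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive;
#'   returned upper-case).
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  x <- toupper(x)
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("hamming() requires equal-length strings")
  }
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# split a DNA string into a character vector of bases
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# count occurrences of a fixed substring (non-overlapping irrelevant here:
# anchors are searched as exact, possibly overlapping matches)
count_fixed <- function(string, pattern) {
  m <- gregexpr(pattern, string, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# count (possibly overlapping) regex matches via lookahead
count_regex_overlapping <- function(string, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), string, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Write sequences as FASTA
#'
#' Minimal plain-text FASTA writer for reference/oligo sequences.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("no FASTA headers found")
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1), collapse = "")
  setNames(toupper(unname(seqs)), id)
}
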
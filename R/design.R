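#' Default oligo adapters and screened restriction sites
#'
#' `default_adapters()` returns the constant priming/cloning sequences added
#' to each designed insert (5' and 3'). With a 144-bp insert they yield a
#' 195-bp oligo. Both are free of the screened restriction sites on either
#' strand. `default_restriction_sites()` returns the recognition motifs of
#' the three cloning enzymes screened during design (SfiI, AscI, SbfI);
#' `N` is a wildcard.
#'
#' @return A named character vector.
#' @export
default_adapters <- function() {
  c(adapter5 = "ACCTGTAGTCGACGCATTCGCCAAG",
    adapter3 = "CAAGGTCTACGAGCATACGACTTGTC")
}

#' @rdname default_adapters
#' @export
default_restriction_sites <- function() {
  c(SfiI = "GGCCNNNNNGGCC", AscI = "GGCGCGCC", SbfI = "CCTGCAGG")
}

# Splice RM alleles into a plus-strand reference window.
# window_seq: plus-strand sequence of [window_start, window_end]
# variants: tibble with pos, ref, alt (1-based genomic, left-anchored)
# use_rm: logical vector along variants
splice_alleles <- function(window_seq, window_start, variants, use_rm) {
  if (nrow(variants) == 0 || !any(use_rm)) {
    return(window_seq)
  }
  v <- variants[use_rm, , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  out <- character(0)
  cursor <- 1L # 1-based offset within window_seq
  for (i in seq_len(nrow(v))) {
    off <- v$pos[i] - window_start + 1L
    ref_len <- nchar(v$ref[i])
    if (off < cursor) abort("overlapping variants in one splice")
    obs <- substr(window_seq, off, off + ref_len - 1L)
    if (obs != v$ref[i]) {
      abort(sprintf("reference mismatch at pos %d: expected '%s', found '%s'",
                    v$pos[i], v$ref[i], obs))
    }
    out <- c(out, substr(window_seq, cursor, off - 1L), v$alt[i])
    cursor <- off + ref_len
  }
  paste0(paste(out, collapse = ""),
         substr(window_seq, cursor, nchar(window_seq)))
}

check_variants_in_window <- function(variants, win_start, win_end, what) {
  if (nrow(variants) == 0) return(invisible(NULL))
  bad <- variants$pos < win_start |
    (variants$pos + nchar(variants$ref) - 1L) > win_end
  if (any(bad)) {
    abort(sprintf("%d variant(s) outside the %s window [%d, %d]: %s",
                  sum(bad), what, win_start, win_end,
                  paste(variants$variant_id[bad], collapse = ", ")))
  }
  invisible(NULL)
}

new_oligo_row <- function(oligo_id, block_id, gene, library, variant_ids,
                          allele_config, insert) {
  tibble(oligo_id = oligo_id, block_id = block_id, gene = gene,
         library = library, variant_ids = variant_ids,
         allele_config = allele_config, insert = insert)
}

#' Design a TSS oligo block
#'
#' Builds the set of promoter-fragment sequences covering the 144 bp
#' immediately upstream of a gene's transcription start site. The block
#' holds one oligo carrying the BY (reference) allele at every variant, one
#' oligo per variant carrying the RM (alternative) allele at that variant
#' only, and one oligo carrying the RM allele at every variant. Oligos with
#' identical insert sequences are emitted once (so a one-variant block has
#' two oligos). Minus-strand genes are designed from the reverse complement
#' so inserts read 5'-to-3' toward the reporter.
#'
#' @param gene Gene identifier.
#' @param tss 1-based genomic position of the transcription start site.
#' @param strand `"+"` or `"-"`.
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` (1-based, left-anchored alleles; `ref` is the BY allele, `alt`
#'   the RM allele). All must lie in the 144-bp window upstream of the TSS;
#'   out-of-window variants raise an error.
#' @param reference Named character vector of chromosome sequences.
#' @param window_size Window width in bp (default 144). The window is the
#'   `window_size` positions strictly upstream of the TSS (the TSS base
#'   itself is excluded).
#' @return A tibble manifest with one row per unique oligo: `oligo_id`,
#'   `block_id`, `gene`, `library`, `variant_ids`, `allele_config`,
#'   `insert`. Zero variants yield a zero-row tibble.
#' @export
design_tss_block <- function(gene, tss, strand, variants, reference,
                             window_size = 144) {
  empty <- new_oligo_row(character(0), character(0), character(0),
                         character(0), character(0), character(0),
                         character(0))
  if (nrow(variants) == 0) return(empty)
  chrom <- unique(variants$chrom)
  if (length(chrom) != 1) abort("TSS block variants must share one chromosome")
  if (!chrom %in% names(reference)) abort(sprintf("unknown chromosome '%s'", chrom))
  if (strand == "+") {
    win_start <- tss - window_size
    win_end <- tss - 1L
  } else {
    win_start <- tss + 1L
    win_end <- tss + window_size
  }
  if (win_start < 1L || win_end > nchar(reference[[chrom]])) {
    abort("TSS window extends beyond the reference sequence")
  }
  check_variants_in_window(variants, win_start, win_end, "TSS")
  variants <- variants[order(variants$pos), , drop = FALSE]
  k <- nrow(variants)
  window_seq <- substr(reference[[chrom]], win_start, win_end)

  configs <- c(list(rep(FALSE, k)),
               lapply(seq_len(k), function(i) seq_len(k) == i),
               list(rep(TRUE, k)))
  labels <- c("BYall",
              paste0("RM@", variants$variant_id),
              "RMall")
  block_id <- paste0(gene, "_TSS")
  inserts <- vapply(configs, function(cfg) {
    ins <- splice_alleles(window_seq, win_start, variants, cfg)
    if (strand == "-") revcomp(ins) else ins
  }, character(1))
  cfg_str <- vapply(configs, function(cfg) {
    paste(ifelse(cfg, "RM", "BY"), collapse = ";")
  }, character(1))
  man <- new_oligo_row(
    oligo_id = paste0(block_id, "|", labels),
    block_id = block_id, gene = gene, library = "TSS",
    variant_ids = paste(variants$variant_id, collapse = ";"),
    allele_config = cfg_str, insert = inserts)
  # unique-sequence deduplication, keeping BY-all and single-RM labels first
  man[!duplicated(man$insert), , drop = FALSE]
}

#' Design an Upstream oligo block
#'
#' Builds the pair of sequences representing a window of genomic DNA
#' centered on one focal variant: one oligo carries the BY allele and one
#' the RM allele. Any other variant falling inside the window stays at the
#' BY (reference) allele in both oligos, so the block assays a single
#' variant. For minus-strand genes the inserts are reverse-complemented.
#'
#' @param variant One-row tibble (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param reference Named character vector of chromosome sequences.
#' @param gene Gene identifier (used for the block id).
#' @param strand `"+"` or `"-"`.
#' @param window_size Window width on the BY reference (default 144). The
#'   window starts `floor((window_size - 1) / 2)` bases left of `pos`; the
#'   RM oligo keeps the same flanks, so allele-length differences change
#'   the RM insert length.
#' @return A two-row oligo manifest tibble (see [design_tss_block()]).
#' @export
design_upstream_block <- function(variant, reference, gene, strand,
                                  window_size = 144) {
  stopifnot(nrow(variant) == 1)
  chrom <- variant$chrom
  if (!chrom %in% names(reference)) abort(sprintf("unknown chromosome '%s'", chrom))
  win_start <- variant$pos - (window_size - 1L) %/% 2L
  win_end <- win_start + window_size - 1L
  if (win_start < 1L || win_end > nchar(reference[[chrom]])) {
    abort("Upstream window extends beyond the reference sequence")
  }
  check_variants_in_window(variant, win_start, win_end, "Upstream")
  window_seq <- substr(reference[[chrom]], win_start, win_end)
  inserts <- c(BY = window_seq,
               RM = splice_alleles(window_seq, win_start, variant, TRUE))
  if (strand == "-") inserts <- setNames(revcomp(inserts), names(inserts))
  block_id <- paste0(gene, "_Up_", variant$variant_id)
  new_oligo_row(
    oligo_id = paste0(block_id, "|", names(inserts)),
    block_id = block_id, gene = gene, library = "Upstream",
    variant_ids = variant$variant_id,
    allele_config = names(inserts), insert = unname(inserts))
}

#' Assemble full oligo sequences from inserts
#'
#' Prepends/appends the constant adapter sequences to every insert and
#' applies the A-rich reverse-complementation rule: an oligo whose designed
#' full sequence carries strictly more adenines than thymines is stored as
#' its reverse complement (`strand_flipped = TRUE`).
#'
#' @param manifest Oligo manifest from the `design_*` functions.
#' @param adapters Named character vector with `adapter5` and `adapter3`.
#' @param flip_a_rich Apply the A-rich flip rule (default `TRUE`).
#' @return The manifest with `full_sequence` and `strand_flipped` columns.
#' @export
assemble_oligos <- function(manifest, adapters = default_adapters(),
                            flip_a_rich = TRUE) {
  manifest$full_sequence <- paste0(adapters[["adapter5"]], manifest$insert,
                                   adapters[["adapter3"]])
  manifest$strand_flipped <- FALSE
  if (flip_a_rich && nrow(manifest) > 0) {
    manifest <- maybe_reverse_complement(manifest)
  }
  manifest
}

#' A-rich reverse-complementation rule
#'
#' Flips each oligo's `full_sequence` to its reverse complement iff the
#' designed sequence counts strictly more A than T (an A/T tie is not
#' flipped). Sets the `strand_flipped` flag accordingly.
#'
#' @param manifest Oligo manifest with a `full_sequence` column.
#' @return The manifest with flipped sequences where the rule applies.
#' @export
maybe_reverse_complement <- function(manifest) {
  n_a <- stringr::str_count(manifest$full_sequence, "A")
  n_t <- stringr::str_count(manifest$full_sequence, "T")
  flip <- n_a > n_t
  manifest$strand_flipped <- flip
  manifest$full_sequence[flip] <- revcomp(manifest$full_sequence[flip])
  manifest
}

site_regex <- function(site) gsub("N", "[ACGT]", site, fixed = TRUE)

#' Filter oligo blocks for restriction sites and synthesis length
#'
#' Drops an entire block when any of its oligos contains any screened
#' restriction-site motif (searched on both strands) or exceeds the
#' synthesis length limit.
#'
#' @param manifest Assembled oligo manifest (with `full_sequence`).
#' @param restriction_sites Named character vector of recognition motifs
#'   (`N` = any base); default [default_restriction_sites()].
#' @param max_len Maximum oligo length (default 200).
#' @return List with `kept` (manifest subset) and `dropped` (tibble of
#'   `block_id`, `reason`).
#' @export
filter_blocks <- function(manifest,
                          restriction_sites = default_restriction_sites(),
                          max_len = 200) {
  if (nrow(manifest) == 0) {
    return(list(kept = manifest,
                dropped = tibble(block_id = character(0),
                                 reason = character(0))))
  }
  pats <- vapply(restriction_sites, site_regex, character(1))
  has_site <- rep(FALSE, nrow(manifest))
  site_name <- rep(NA_character_, nrow(manifest))
  rc <- revcomp(manifest$full_sequence)
  for (i in seq_along(pats)) {
    hit <- grepl(pats[i], manifest$full_sequence) | grepl(pats[i], rc)
    site_name[hit & !has_site] <- names(pats)[i]
    has_site <- has_site | hit
  }
  too_long <- nchar(manifest$full_sequence) > max_len
  reason <- dplyr::case_when(
    has_site ~ paste0("restriction_site:", site_name),
    too_long ~ "exceeds_max_len",
    TRUE ~ NA_character_)
  per_block <- tibble(block_id = manifest$block_id, reason = reason) %>%
    filter(!is.na(.data$reason)) %>%
    distinct(.data$block_id, .keep_all = TRUE)
  kept <- manifest[!manifest$block_id %in% per_block$block_id, , drop = FALSE]
  list(kept = kept, dropped = per_block)
}

#' Generate constrained random barcodes
#'
#' Draws distinct 3'-UTR barcodes under the composition rules that keep
#' reporter mRNA expression high and uniform: position 1 is C or T;
#' positions 2-4 and every later even position carry A, C, or T (no
#' guanine) at equal frequency; the remaining odd positions (5, 7, ...)
#' carry all four bases at equal frequency.
#'
#' @param n Number of distinct barcodes to return.
#' @param length Barcode length (default 20).
#' @return Character vector of `n` distinct barcodes.
#' @export
#' @examples
#' set.seed(1)
#' generate_barcodes(3)
generate_barcodes <- function(n, length = 20) {
  if (n < 0) abort("n must be non-negative")
  if (n == 0) return(character(0))
  class_of <- barcode_position_classes(length)
  n_ct <- sum(class_of == "CT")
  n_nog <- sum(class_of == "noG")
  n_free <- sum(class_of == "free")
  space <- 2^n_ct * 3^n_nog * 4^n_free
  if (n > space) {
    abort(sprintf("n = %d exceeds the legal barcode space (%.0f)", n, space))
  }
  draw <- function(m) {
    cols <- lapply(class_of, function(cl) {
      alphabet <- switch(cl, CT = c("C", "T"), noG = c("A", "C", "T"),
                         free = c("A", "C", "G", "T"))
      sample(alphabet, m, replace = TRUE)
    })
    do.call(paste0, cols)
  }
  out <- unique(draw(n))
  while (length(out) < n) {
    out <- unique(c(out, draw(n - length(out) + 16L)))
  }
  out[seq_len(n)]
}

# position classes for the barcode composition rules
barcode_position_classes <- function(length) {
  vapply(seq_len(length), function(p) {
    if (p == 1) "CT"
    else if (p %in% 2:4) "noG"
    else if (p %% 2 == 0) "noG"
    else "free"
  }, character(1))
}

#' Size of the legal barcode sequence space
#'
#' @param length Barcode length.
#' @return Number of distinct barcodes satisfying the composition rules.
#' @export
barcode_space_size <- function(length = 20) {
  class_of <- barcode_position_classes(length)
  2^sum(class_of == "CT") * 3^sum(class_of == "noG") *
    4^sum(class_of == "free")
}

#' Enumerate BY/RM test pairs from an oligo manifest
#'
#' For each variant, the allelic comparison contrasts the oligo carrying
#' the RM allele at that variant only against the block's all-BY oligo
#' (TSS blocks) or the RM against the BY oligo (Upstream blocks).
#'
#' @param manifest Oligo manifest.
#' @return Tibble with `variant_id`, `gene`, `library`, `block_id`,
#'   `by_oligo`, `rm_oligo`.
#' @export
variant_pairs <- function(manifest) {
  out <- list()
  for (bid in unique(manifest$block_id)) {
    blk <- manifest[manifest$block_id == bid, , drop = FALSE]
    vids <- strsplit(blk$variant_ids[1], ";", fixed = TRUE)[[1]]
    if (blk$library[1] == "TSS") {
      by_oligo <- blk$oligo_id[blk$allele_config ==
                                 paste(rep("BY", length(vids)), collapse = ";")]
      if (length(by_oligo) != 1) next
      for (j in seq_along(vids)) {
        cfg <- rep("BY", length(vids))
        cfg[j] <- "RM"
        rm_oligo <- blk$oligo_id[blk$allele_config == paste(cfg, collapse = ";")]
        if (length(rm_oligo) != 1) next
        out[[length(out) + 1]] <- tibble(
          variant_id = vids[j], gene = blk$gene[1], library = "TSS",
          block_id = bid, by_oligo = by_oligo, rm_oligo = rm_oligo)
      }
    } else {
      by_oligo <- blk$oligo_id[blk$allele_config == "BY"]
      rm_oligo <- blk$oligo_id[blk$allele_config == "RM"]
      if (length(by_oligo) == 1 && length(rm_oligo) == 1) {
        out[[length(out) + 1]] <- tibble(
          variant_id = vids, gene = blk$gene[1], library = "Upstream",
          block_id = bid, by_oligo = by_oligo, rm_oligo = rm_oligo)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(variant_id = character(0), gene = character(0),
                  library = character(0), block_id = character(0),
                  by_oligo = character(0), rm_oligo = character(0)))
  }
  bind_rows(out)
}

#' Enumerate four-oligo variant pairs for interaction tests
#'
#' Finds TSS blocks with exactly two variants where all four allele
#' combinations (BY/BY, RM/BY, BY/RM, RM/RM) are present as distinct
#' oligos.
#'
#' @param manifest Oligo manifest.
#' @return Tibble with `block_id`, `gene`, `v1`, `v2` and the four oligo id
#'   columns `o_bb`, `o_rb`, `o_br`, `o_rr`.
#' @export
interaction_pairs <- function(manifest) {
  out <- list()
  tss <- manifest[manifest$library == "TSS", , drop = FALSE]
  for (bid in unique(tss$block_id)) {
    blk <- tss[tss$block_id == bid, , drop = FALSE]
    vids <- strsplit(blk$variant_ids[1], ";", fixed = TRUE)[[1]]
    if (length(vids) != 2) next
    grab <- function(cfg) blk$oligo_id[blk$allele_config == cfg]
    ids <- lapply(c("BY;BY", "RM;BY", "BY;RM", "RM;RM"), grab)
    if (any(lengths(ids) != 1)) next
    out[[length(out) + 1]] <- tibble(
      block_id = bid, gene = blk$gene[1], v1 = vids[1], v2 = vids[2],
      o_bb = ids[[1]], o_rb = ids[[2]], o_br = ids[[3]], o_rr = ids[[4]])
  }
  if (length(out) == 0) {
    return(tibble(block_id = character(0), gene = character(0),
                  v1 = character(0), v2 = character(0), o_bb = character(0),
                  o_rb = character(0), o_br = character(0),
                  o_rr = character(0)))
  }
  bind_rows(out)
}
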
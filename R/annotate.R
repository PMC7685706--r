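#' Default anchor sequences
#'
#' The two invariant sequences expected in well-formed merged amplicon
#' reads: one between the oligo and the barcode (library-specific, spanning
#' the SbfI/p2/AscI junction) and one upstream of the oligo (the SfiI-A
#' site, shared by both libraries).
#'
#' @param library `"TSS"` or `"Upstream"`.
#' @return List with `upstream_anchor` and `between_anchor`.
#' @export
default_anchors <- function(library = c("TSS", "Upstream")) {
  library <- match.arg(library)
  list(upstream_anchor = "GGCCGTAATGGCC",
       between_anchor = if (library == "TSS") "CCTGCAGGGGTTTAGCCGGCGTG"
                        else "CCTGCAGGGTTCCGCAGCCACAC")
}

#' Parse merged amplicon reads into (barcode, oligo) pairs
#'
#' A read is retained only if both invariant anchors occur exactly once
#' (exact string match) and in the expected order. The observed oligo is
#' the substring between the upstream anchor and the between-anchor; the
#' barcode is the `barcode_len` bases immediately following the
#' between-anchor.
#'
#' @param reads Character vector of merged reads.
#' @param anchors List with `upstream_anchor` and `between_anchor` (see
#'   [default_anchors()]).
#' @param barcode_len Barcode length (default 20).
#' @return Tibble with one row per read: `read_index`, `barcode`, `oligo`,
#'   `status` (`"ok"` or a rejection reason code).
#' @export
parse_reads <- function(reads, anchors = default_anchors("TSS"),
                        barcode_len = 20) {
  up <- anchors$upstream_anchor
  bt <- anchors$between_anchor
  if (!nzchar(up) || !nzchar(bt)) abort("anchors must be non-empty")
  n_up <- stringr::str_count(reads, stringr::fixed(up))
  n_bt <- stringr::str_count(reads, stringr::fixed(bt))
  pos_up <- stringr::str_locate(reads, stringr::fixed(up))
  pos_bt <- stringr::str_locate(reads, stringr::fixed(bt))
  status <- rep("ok", length(reads))
  status[n_up == 0] <- "missing_upstream_anchor"
  status[n_up > 1] <- "duplicated_upstream_anchor"
  status[status == "ok" & n_bt == 0] <- "missing_between_anchor"
  status[status == "ok" & n_bt > 1] <- "duplicated_between_anchor"
  ok <- status == "ok"
  bad_order <- ok & pos_bt[, "start"] <= pos_up[, "end"]
  status[bad_order] <- "anchor_order"
  ok <- status == "ok"
  oligo <- rep(NA_character_, length(reads))
  barcode <- rep(NA_character_, length(reads))
  oligo[ok] <- substr(reads[ok], pos_up[ok, "end"] + 1L,
                      pos_bt[ok, "start"] - 1L)
  bc_start <- pos_bt[, "end"] + 1L
  barcode[ok] <- substr(reads[ok], bc_start[ok],
                        bc_start[ok] + barcode_len - 1L)
  short <- ok & nchar(barcode) < barcode_len
  status[short] <- "truncated_barcode"
  barcode[short] <- NA_character_
  oligo[short] <- NA_character_
  tibble(read_index = seq_along(reads), barcode = barcode, oligo = oligo,
         status = status)
}

#' Resolve the primary oligo for each barcode
#'
#' The primary oligo of a barcode is the modal observed oligo sequence
#' among its reads; barcodes whose top two oligos tie are discarded. The
#' primary fraction (share of reads supporting the primary oligo) is
#' recorded.
#'
#' @param pairs Tibble with `barcode` and `oligo` columns (e.g. the `"ok"`
#'   rows of [parse_reads()]).
#' @return Tibble `barcode`, `oligo`, `reads` (reads supporting the
#'   primary), `total_reads`, `primary_fraction`.
#' @export
resolve_primary <- function(pairs) {
  pairs <- pairs %>% filter(!is.na(.data$barcode), !is.na(.data$oligo))
  if (nrow(pairs) == 0) {
    return(tibble(barcode = character(0), oligo = character(0),
                  reads = integer(0), total_reads = integer(0),
                  primary_fraction = numeric(0)))
  }
  pairs %>%
    count(.data$barcode, .data$oligo, name = "reads") %>%
    group_by(.data$barcode) %>%
    summarise(total_reads = sum(.data$reads),
              tied = sum(.data$reads == max(.data$reads)) > 1,
              oligo = .data$oligo[which.max(.data$reads)],
              reads = max(.data$reads), .groups = "drop") %>%
    filter(!.data$tied) %>%
    mutate(primary_fraction = .data$reads / .data$total_reads) %>%
    select("barcode", "oligo", "reads", "total_reads", "primary_fraction")
}

#' Match primary oligos to the design manifest
#'
#' Retains only barcodes whose primary oligo sequence perfectly matches a
#' designed oligo (exact full-length string equality); any mismatch,
#' including a single skipped base, rejects the barcode.
#'
#' @param primaries Output of [resolve_primary()].
#' @param manifest Design manifest with `oligo_id` and a sequence column.
#' @param sequence_col Manifest column holding the designed sequence read
#'   out by the amplicon (default `"full_sequence"`).
#' @return List with `dictionary` (tibble `barcode`, `oligo_id`, `reads`,
#'   `primary_fraction`) and `rejected` (tibble `barcode`, `reason`).
#' @export
match_to_design <- function(primaries, manifest,
                            sequence_col = "full_sequence") {
  design <- tibble(oligo_id = manifest$oligo_id,
                   oligo = manifest[[sequence_col]])
  hit <- primaries %>% inner_join(design, by = "oligo")
  miss <- primaries %>% anti_join(design, by = "oligo")
  list(dictionary = hit %>%
         select("barcode", "oligo_id", "reads", "primary_fraction"),
       rejected = tibble(barcode = miss$barcode,
                         reason = "no_perfect_design_match"))
}

#' Build a barcode-to-oligo dictionary from merged reads
#'
#' Chains [parse_reads()], [resolve_primary()] and [match_to_design()],
#' optionally applying a minimum read-support floor and a minimum primary
#' fraction.
#'
#' @inheritParams parse_reads
#' @inheritParams match_to_design
#' @param min_reads Minimum reads supporting the primary oligo (default 1).
#' @param min_primary_fraction Optional minimum primary fraction; the
#'   default (`0`) applies the modal rule only.
#' @return List with `dictionary` and `rejected_reads` /
#'   `rejected_barcodes` report tibbles.
#' @export
build_barcode_dictionary <- function(reads, manifest,
                                     anchors = default_anchors("TSS"),
                                     barcode_len = 20,
                                     sequence_col = "full_sequence",
                                     min_reads = 1,
                                     min_primary_fraction = 0) {
  parsed <- parse_reads(reads, anchors, barcode_len)
  primaries <- resolve_primary(parsed[parsed$status == "ok", ])
  primaries <- primaries %>%
    filter(.data$reads >= min_reads,
           .data$primary_fraction >= min_primary_fraction)
  matched <- match_to_design(primaries, manifest, sequence_col)
  list(dictionary = matched$dictionary,
       rejected_reads = parsed %>% filter(.data$status != "ok") %>%
         count(.data$status, name = "n_reads"),
       rejected_barcodes = matched$rejected)
}

#' Construct synthetic amplicon reads from a design and dictionary
#'
#' Builds error-free merged reads (`upstream_anchor + oligo +
#' between_anchor + barcode`) for testing the annotation path.
#'
#' @param dictionary Tibble `barcode`, `oligo_id`.
#' @param manifest Design manifest.
#' @param anchors Anchor list (see [default_anchors()]).
#' @param sequence_col Manifest sequence column.
#' @param reads_per_barcode Copies of each read to emit.
#' @return Character vector of reads.
#' @export
construct_reads <- function(dictionary, manifest,
                            anchors = default_anchors("TSS"),
                            sequence_col = "full_sequence",
                            reads_per_barcode = 1) {
  seqs <- setNames(manifest[[sequence_col]], manifest$oligo_id)
  reads <- paste0(anchors$upstream_anchor, seqs[dictionary$oligo_id],
                  anchors$between_anchor, dictionary$barcode)
  rep(reads, each = reads_per_barcode)
}
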
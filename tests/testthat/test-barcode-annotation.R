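anchors <- default_anchors("TSS")

make_reads <- function(oligos, barcodes) {
  paste0(anchors$upstream_anchor, oligos, anchors$between_anchor, barcodes)
}

test_that("constructed reads are parsed back exactly", {
  oligos <- c("ACGTACGTACGT", "TTTTCCCCAAAA")
  bcs <- c(strrep("CA", 10), strrep("TA", 10))
  parsed <- parse_reads(make_reads(oligos, bcs), anchors)
  expect_true(all(parsed$status == "ok"))
  expect_identical(parsed$oligo, oligos)
  expect_identical(parsed$barcode, bcs)
})

test_that("reads with missing, duplicated, or misordered anchors are rejected", {
  good <- make_reads("ACGT", strrep("C", 20))
  no_between <- paste0(anchors$upstream_anchor, "ACGT", strrep("C", 20))
  dup_between <- paste0(good, anchors$between_anchor)
  no_up <- paste0("ACGT", anchors$between_anchor, strrep("C", 20))
  wrong_order <- paste0(anchors$between_anchor, strrep("C", 20),
                        anchors$upstream_anchor, "ACGT")
  short_bc <- paste0(anchors$upstream_anchor, "ACGT",
                     anchors$between_anchor, "CCC")
  parsed <- parse_reads(c(good, no_between, dup_between, no_up, wrong_order,
                          short_bc), anchors)
  expect_equal(parsed$status,
               c("ok", "missing_between_anchor", "duplicated_between_anchor",
                 "missing_upstream_anchor", "anchor_order",
                 "truncated_barcode"))
})

test_that("the modal oligo is the primary; ties discard the barcode", {
  pairs <- tibble::tibble(
    barcode = c(rep("b1", 10), rep("b2", 1), rep("b3", 10)),
    oligo = c(rep("X", 9), "Y", "X", rep(c("X", "Y"), 5)))
  prim <- resolve_primary(pairs)
  expect_setequal(prim$barcode, c("b1", "b2"))
  expect_equal(prim$primary_fraction[prim$barcode == "b1"], 0.9)
  expect_equal(prim$primary_fraction[prim$barcode == "b2"], 1.0)
  expect_false("b3" %in% prim$barcode) # 5:5 tie
})

test_that("only perfect matches to the design are retained", {
  man <- tibble::tibble(oligo_id = "o1", full_sequence = "ACGTACGTACGT")
  prim <- tibble::tibble(
    barcode = c("b1", "b2", "b3"),
    oligo = c("ACGTACGTACGT", "ACGTCGTACGT", ""), # exact, 1-bp skip, empty
    reads = c(3L, 3L, 3L), total_reads = c(3L, 3L, 3L),
    primary_fraction = 1)
  m <- match_to_design(prim, man)
  expect_equal(m$dictionary$barcode, "b1")
  expect_equal(m$dictionary$oligo_id, "o1")
  expect_setequal(m$rejected$barcode, c("b2", "b3"))
})

test_that("error-free reads recover the full dictionary with fraction 1", {
  cfg <- sim_config(n_genes = 6, barcodes_per_oligo = 15, seed = 3)
  study <- simulate_mpra_study(cfg, libraries = "TSS")
  reads <- construct_reads(study$dictionary, study$manifest, anchors,
                           reads_per_barcode = 2)
  dict <- build_barcode_dictionary(reads, study$manifest, anchors)
  expect_equal(nrow(dict$dictionary), nrow(study$dictionary))
  expect_true(all(dict$dictionary$primary_fraction == 1))
  got <- dict$dictionary[order(dict$dictionary$barcode), ]
  want <- study$dictionary[order(study$dictionary$barcode), ]
  expect_identical(got$oligo_id, want$oligo_id)
})

test_that("corrupted reads are handled identically to a brute-force reference", {
  cfg <- sim_config(n_genes = 4, barcodes_per_oligo = 8, seed = 13)
  study <- simulate_mpra_study(cfg, libraries = "TSS")
  reads <- construct_reads(study$dictionary, study$manifest, anchors,
                           reads_per_barcode = 3)
  set.seed(99)
  corrupt <- sample(length(reads), round(0.05 * length(reads)))
  for (i in corrupt) {
    # one random substitution inside the oligo region
    off <- nchar(anchors$upstream_anchor) +
      sample(nchar(reads[i]) - nchar(anchors$upstream_anchor) -
               nchar(anchors$between_anchor) - 20, 1)
    base <- substr(reads[i], off, off)
    substr(reads[i], off, off) <- setdiff(c("A", "C", "G", "T"), base)[1]
  }
  dict <- build_barcode_dictionary(reads, study$manifest, anchors)

  # brute-force reference: tally (barcode, oligo) by direct string surgery
  ref_tally <- list()
  for (r in reads) {
    iu <- gregexpr(anchors$upstream_anchor, r, fixed = TRUE)[[1]]
    ib <- gregexpr(anchors$between_anchor, r, fixed = TRUE)[[1]]
    if (length(iu) != 1 || iu[1] == -1 || length(ib) != 1 || ib[1] == -1) next
    oligo <- substr(r, iu[1] + nchar(anchors$upstream_anchor), ib[1] - 1)
    bc <- substr(r, ib[1] + nchar(anchors$between_anchor),
                 ib[1] + nchar(anchors$between_anchor) + 19)
    key <- paste(bc, oligo, sep = "\r")
    prev <- ref_tally[[key]]
    ref_tally[[key]] <- (if (is.null(prev)) 0L else prev) + 1L
  }
  keys <- strsplit(names(ref_tally), "\r", fixed = TRUE)
  tall <- tibble::tibble(barcode = vapply(keys, `[`, "", 1),
                         oligo = vapply(keys, `[`, "", 2),
                         n = unlist(ref_tally))
  ref_dict <- list()
  for (bc in unique(tall$barcode)) {
    sub <- tall[tall$barcode == bc, ]
    top <- max(sub$n)
    if (sum(sub$n == top) > 1) next # tie
    oligo <- sub$oligo[which.max(sub$n)]
    hit <- study$manifest$oligo_id[study$manifest$full_sequence == oligo]
    if (length(hit) != 1) next
    ref_dict[[bc]] <- tibble::tibble(barcode = bc, oligo_id = hit,
                                     reads = top)
  }
  ref_dict <- dplyr::bind_rows(ref_dict)
  got <- dict$dictionary[order(dict$dictionary$barcode), ]
  want <- ref_dict[order(ref_dict$barcode), ]
  expect_identical(got$barcode, want$barcode)
  expect_identical(got$oligo_id, want$oligo_id)
  expect_identical(as.integer(got$reads), as.integer(want$reads))
  # entries never exceed the number of distinct observed barcodes
  expect_lte(nrow(dict$dictionary), length(unique(tall$barcode)))
})
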
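ref <- fixture_reference(len = 400)

test_that("TSS blocks enumerate BY-all, single-RM and RM-all oligos", {
  tss <- 300L
  v2 <- dplyr::bind_rows(fixture_snv(ref, 200, id = "a"),
                         fixture_snv(ref, 250, id = "b"))
  blk <- design_tss_block("g1", tss, "+", v2, ref)
  expect_equal(nrow(blk), 4)
  expect_setequal(blk$allele_config, c("BY;BY", "RM;BY", "BY;RM", "RM;RM"))
  expect_true(all(nchar(blk$insert) == 144))
  # one variant: the RM-all oligo duplicates the single-RM oligo
  blk1 <- design_tss_block("g1", tss, "+", v2[1, ], ref)
  expect_equal(nrow(blk1), 2)
  # zero variants: empty block
  expect_equal(nrow(design_tss_block("g1", tss, "+", v2[0, ], ref)), 0)
  # out-of-window variant rejected with reason
  expect_error(design_tss_block("g1", tss, "+", fixture_snv(ref, 100), ref),
               "outside")
})

test_that("inserts equal the BY window with RM alleles spliced at config positions", {
  tss <- 300L
  win <- substr(ref[[1]], tss - 144, tss - 1)
  set.seed(3)
  pos <- sort(sample(seq(tss - 140, tss - 5), 3))
  vv <- dplyr::bind_rows(lapply(seq_along(pos), function(i) {
    fixture_snv(ref, pos[i], id = paste0("v", i))
  }))
  blk <- design_tss_block("g1", tss, "+", vv, ref)
  # independent splice oracle: substr-replace each RM base
  for (i in seq_len(nrow(blk))) {
    cfg <- strsplit(blk$allele_config[i], ";")[[1]]
    expected <- win
    for (j in which(cfg == "RM")) {
      off <- pos[j] - (tss - 144) + 1
      substr(expected, off, off) <- vv$alt[j]
    }
    expect_identical(blk$insert[i], expected)
  }
})

test_that("minus-strand inserts reverse-complement back to the plus window", {
  tss <- 200L
  v <- fixture_snv(ref, 230, id = "m1")
  blk <- design_tss_block("g1", tss, "-", v, ref)
  plus_win <- substr(ref[[1]], tss + 1, tss + 144)
  by_insert <- blk$insert[blk$allele_config == "BY"]
  expect_identical(revcomp(by_insert), plus_win)
})

test_that("Upstream blocks assay one focal variant with shared flanks", {
  v <- fixture_snv(ref, 200)
  blk <- design_upstream_block(v, ref, "g1", "+")
  expect_equal(nrow(blk), 2)
  expect_true(all(nchar(blk$insert) == 144))
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              blk$insert[1], blk$insert[2])
  expect_equal(unname(d), 1)
  # a 3-bp insertion in RM lengthens the RM insert to 147
  vi <- v
  vi$alt <- paste0(v$ref, "ACG")
  blki <- design_upstream_block(vi, ref, "g1", "+")
  expect_equal(sort(nchar(blki$insert)), c(144, 147))
  # neighbouring variants each get their own block; the neighbour stays BY
  v2 <- fixture_snv(ref, 210, id = "v2")
  blk2 <- design_upstream_block(v2, ref, "g1", "+")
  expect_equal(nrow(blk2), 2)
  # focal window of blk contains position 210 with the reference base
  off <- 210 - (200 - 71) + 1
  expect_identical(substr(blk$insert[1], off, off), substr(ref[[1]], 210, 210))
  expect_identical(substr(blk$insert[2], off, off), substr(ref[[1]], 210, 210))
})

test_that("blocks with restriction sites or oversized oligos are dropped", {
  man <- tibble::tibble(
    oligo_id = c("b1|x", "b1|y", "b2|x", "b3|x"),
    block_id = c("b1", "b1", "b2", "b3"),
    gene = "g", library = "TSS", variant_ids = "v", allele_config = "BY",
    insert = "ACGT",
    full_sequence = c(paste0(strrep("ACT", 60), "GGCGCGCC"), # AscI
                      strrep("ACT", 60),
                      strrep("ACT", 65), # 195 bp, clean
                      strrep("ACTG", 51)), # 204 bp
    strand_flipped = FALSE)
  flt <- filter_blocks(man)
  expect_setequal(flt$dropped$block_id, c("b1", "b3"))
  expect_match(flt$dropped$reason[flt$dropped$block_id == "b1"], "AscI")
  expect_equal(unique(flt$kept$block_id), "b2")
  # sites are found on the reverse strand too
  man_rc <- man[3, ]
  man_rc$full_sequence <- paste0(strrep("ACT", 60), revcomp("GGCGCGCC"))
  expect_equal(nrow(filter_blocks(man_rc)$kept), 0)
})

test_that("A-rich oligos are reverse-complemented, ties are not", {
  man <- tibble::tibble(full_sequence = c("AAAAATTGGC", "AATTGC"),
                        oligo_id = c("o1", "o2"))
  out <- maybe_reverse_complement(man)
  expect_true(out$strand_flipped[1])
  expect_false(out$strand_flipped[2])
  expect_identical(out$full_sequence[1], revcomp("AAAAATTGGC"))
  expect_identical(out$full_sequence[2], "AATTGC")
  expect_identical(revcomp(revcomp("AAAAATTGGC")), "AAAAATTGGC")
})

test_that("barcodes obey the composition rules and fill the stated space", {
  expect_identical(generate_barcodes(0), character(0))
  set.seed(8)
  b <- generate_barcodes(1e5)
  expect_equal(length(unique(b)), 1e5)
  m <- do.call(rbind, strsplit(b, ""))
  expect_true(all(m[, 1] %in% c("C", "T")))
  no_g_positions <- c(2, 3, 4, seq(6, 20, by = 2))
  expect_false(any(m[, no_g_positions] == "G"))
  expect_equal(barcode_space_size(20), 2 * 3^11 * 4^8)
  expect_error(generate_barcodes(100, length = 3), "exceeds")
  # per-position composition is uniform over its alphabet (chi-square)
  for (j in seq_len(20)) {
    tab <- table(m[, j])
    expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  }
})

test_that("pair enumeration matches the block design", {
  tss <- 300L
  vv <- dplyr::bind_rows(fixture_snv(ref, 200, id = "a"),
                         fixture_snv(ref, 250, id = "b"))
  man <- dplyr::bind_rows(
    design_tss_block("g1", tss, "+", vv, ref),
    design_upstream_block(fixture_snv(ref, 180, id = "u"), ref, "g2", "+"))
  pairs <- variant_pairs(man)
  expect_setequal(pairs$variant_id, c("a", "b", "u"))
  expect_true(all(pairs$by_oligo %in% man$oligo_id))
  ip <- interaction_pairs(man)
  expect_equal(nrow(ip), 1)
  expect_equal(ip$v1, "a")
  expect_equal(ip$v2, "b")
})
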
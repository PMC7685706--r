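ref <- fixture_reference(len = 300, seed = 23)

test_that("window sets have the expected size and match the brute-force oracle", {
  v <- fixture_snv(ref, 150)
  set.seed(1)
  for (i in 1:50) {
    pwm <- simulate_pwms(1, min_len = 3, max_len = 10)[[1]]
    L <- nrow(pwm$mat)
    al <- variant_alleles(v, ref, flank = 12)
    sc_plus <- score_windows(al$by$seq, al$by$span_start, al$by$span_end,
                             pwm, "plus")
    expect_length(sc_plus, L)
    expect_equal(sc_plus,
                 oracle_window_scores(al$by$seq, al$by$span_start,
                                      al$by$span_end, pwm),
                 tolerance = 1e-12)
    sc_ag <- score_windows(al$by$seq, al$by$span_start, al$by$span_end,
                           pwm, "agnostic")
    expect_length(sc_ag, 2 * L)
  }
})

test_that("plus-context scores on a sequence equal minus-context scores on its reverse complement", {
  set.seed(2)
  pwm <- simulate_pwms(1, min_len = 6, max_len = 6)[[1]]
  v <- fixture_snv(ref, 120)
  al <- variant_alleles(v, ref, flank = 10)
  n <- nchar(al$by$seq)
  plus_here <- score_windows(al$by$seq, al$by$span_start, al$by$span_end,
                             pwm, "plus")
  minus_rc <- score_windows(revcomp(al$by$seq), n - al$by$span_end + 1,
                            n - al$by$span_start + 1, pwm, "minus")
  expect_equal(sort(plus_here), sort(minus_rc), tolerance = 1e-12)
})

test_that("insufficient flank is an explicit error", {
  v <- fixture_snv(ref, 150)
  pwm <- simulate_pwms(1, min_len = 9, max_len = 9)[[1]]
  al <- variant_alleles(v, ref, flank = 4)
  expect_error(score_windows(al$by$seq, al$by$span_start, al$by$span_end,
                             pwm, "plus"), "flank")
})

test_that("an all-zero PWM yields all-zero allelic features", {
  mat <- matrix(0, nrow = 5, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm <- new_pwm("ZERO", mat, cutoff = 1)
  v <- fixture_snv(ref, 150)
  al <- variant_alleles(v, ref, flank = 8)
  feats <- tf_features(al, pwm)
  expect_length(feats, 15)
  expect_true(all(feats == 0))
})

test_that("strong and weak windows partition all windows", {
  set.seed(3)
  pwm <- simulate_pwms(1, min_len = 7, max_len = 7)[[1]]
  pwm$cutoff <- 0 # split somewhere in the middle
  v <- fixture_snv(ref, 140)
  al <- variant_alleles(v, ref, flank = 10)
  for (ctx in c("plus", "minus", "agnostic")) {
    sc <- score_windows(al$by$seq, al$by$span_start, al$by$span_end, pwm, ctx)
    expect_equal(sum(sc >= pwm$cutoff) + sum(sc < pwm$cutoff), length(sc))
  }
  # a cutoff above every score: weak metrics equal unrestricted metrics
  hi <- pwm
  hi$cutoff <- 1e6
  sc <- score_windows(al$by$seq, al$by$span_start, al$by$span_end, hi, "plus")
  feats <- tf_features(al, hi)
  expect_equal(feats[["TF001_plus_strong_best"]], 0)
  expect_equal(feats[["TF001_plus_strong_count"]], 0)
  sc_rm <- score_windows(al$rm$seq, al$rm$span_start, al$rm$span_end,
                         hi, "plus")
  expect_equal(feats[["TF001_plus_weak_best"]],
               abs(max(sc_rm) - max(sc)), tolerance = 1e-12)
})

test_that("an RM-only strong site gives a strong-count difference of one", {
  # PWM that exactly matches the RM allele context on the plus strand
  v <- fixture_snv(ref, 150)
  al <- variant_alleles(v, ref, flank = 10)
  target <- substr(al$rm$seq, al$rm$span_start - 2, al$rm$span_start + 2)
  mat <- matrix(-10, nrow = 5, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in 1:5) mat[i, substr(target, i, i)] <- 1
  pwm <- new_pwm("MATCH", mat, cutoff = 5)
  feats <- tf_features(al, pwm)
  expect_equal(feats[["MATCH_plus_strong_count"]], 1)
})

test_that("feature counts honour the 15-per-TF and 27-aggregate contracts", {
  set.seed(4)
  pwms <- simulate_pwms(3, min_len = 4, max_len = 6)
  v <- fixture_snv(ref, 150)
  fm <- tf_feature_matrix(v, ref, pwms)
  expect_equal(ncol(fm) - 1, 15 * 3)
  ag <- aggregate_tf_features(fm)
  expect_equal(ncol(ag) - 1, 27)
  # single TF: aggregated max equals mean equals the TF's own value
  fm1 <- tf_feature_matrix(v, ref, pwms[1])
  ag1 <- aggregate_tf_features(fm1)
  expect_equal(ag1$agg_max_plus_weak_best, fm1$TF001_plus_weak_best)
  expect_equal(ag1$agg_mean_plus_weak_best, fm1$TF001_plus_weak_best)
  # three TFs: max and mean verified against direct computation
  cols <- paste0(c("TF001", "TF002", "TF003"), "_minus_weak_mean")
  vals <- unlist(fm[1, cols])
  expect_equal(ag$agg_max_minus_weak_mean, max(vals))
  expect_equal(ag$agg_mean_minus_weak_mean, mean(vals))
  counts <- unlist(fm[1, paste0(c("TF001", "TF002", "TF003"),
                                "_agnostic_strong_count")])
  expect_equal(ag$agg_agnostic_strong_count_total, sum(counts))
  expect_error(aggregate_tf_features(fm[, "variant_id", drop = FALSE]),
               "zero TFs")
})

test_that("TATA and ATG counting follows the consensus definitions", {
  expect_equal(count_tata("TATATAAG"), 1)
  expect_equal(count_tata("GGGGGGGG"), 0)
  expect_equal(count_tata("TATAAAAAG"), 1)
  expect_equal(count_atg("ATGATG"), 2)
  expect_equal(count_atg("ATATG"), 1)
})

test_that("non-TF features cover indel length, nucleosomes, and derived alleles", {
  v_snv <- fixture_snv(ref, 150)
  v_del <- v_snv
  v_del$variant_id <- "v2"
  v_del$pos <- 180L
  v_del$ref <- substr(ref[[1]], 180, 183)
  v_del$alt <- substr(ref[[1]], 180, 180)
  vv <- dplyr::bind_rows(v_snv, v_del)
  nuc <- tibble::tibble(chrom = "chrX", center = 78L)
  out <- nontf_features(vv, ref, flank = 30, nucleosomes = nuc)
  expect_equal(out$indel_length, c(0, 3))
  expect_equal(out$is_snv, c(1L, 0L))
  expect_equal(out$nucleosome_bound, c(1L, 0L)) # 150 = 78 + 72 (closed end)
  v_out <- fixture_snv(ref, 151) # one past the closed boundary
  expect_equal(nontf_features(v_out, ref, flank = 30,
                              nucleosomes = nuc)$nucleosome_bound, 0L)
  geno <- tibble::tibble(
    variant_id = rep("v1", 5),
    isolate = c("outg", "i1", "i2", "i3", "i4"),
    allele = c(v_snv$ref, v_snv$alt, v_snv$alt, v_snv$alt, v_snv$ref))
  daf <- derived_allele_frequency(v_snv, geno, outgroup = "outg")
  expect_identical(daf$derived_allele, v_snv$alt)
  expect_equal(daf$derived_freq, 0.75)
})

test_that("Z-scoring uses the population SD and flags constant columns", {
  f <- tibble::tibble(variant_id = c("a", "b", "c"),
                      x = c(1, 2, 3), k = c(2, 2, 2))
  z <- zscore_features(f)
  expect_equal(z$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(attr(z, "constant_features"), "k")
  z2 <- zscore_features(z)
  expect_equal(z2$x, z$x, tolerance = 1e-12)
})

test_that("the assembled feature matrix records its column groups", {
  set.seed(6)
  pwms <- simulate_pwms(2, min_len = 4, max_len = 5)
  vv <- dplyr::bind_rows(fixture_snv(ref, 120, id = "v1"),
                         fixture_snv(ref, 160, id = "v2"))
  fm <- build_feature_matrix(vv, ref, pwms)
  groups <- attr(fm, "feature_groups")
  expect_equal(length(groups$per_tf), 30)
  expect_equal(length(groups$aggregated), 27)
  expect_true(all(unlist(groups) %in% names(fm)))
})
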
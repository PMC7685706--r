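# Small deterministic fixtures shared across test files.

# one-contig reference with a known sequence
fixture_reference <- function(len = 400, seed = 11) {
  withr::with_seed(seed, {
    c(chrX = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""))
  })
}

# a one-row SNV tibble at `pos` on fixture_reference()
fixture_snv <- function(reference, pos, alt = NULL, id = "v1") {
  ref <- substr(reference[[1]], pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  tibble::tibble(variant_id = id, chrom = names(reference)[1],
                 pos = as.integer(pos), ref = ref, alt = alt)
}

# per-replicate activity table for a set of oligos from a mean vector
fixture_expression <- function(means, n_rep = 6, noise_sd = 0.05, seed = 7) {
  withr::with_seed(seed, {
    tibble::tibble(
      oligo_id = rep(names(means), each = n_rep),
      replicate = rep(seq_len(n_rep), length(means)),
      activity = rep(unname(means), each = n_rep) +
        rnorm(n_rep * length(means), 0, noise_sd))
  })
}

# brute-force PWM window scorer used as the independent oracle
oracle_window_scores <- function(sequence, span_start, span_end, pwm) {
  L <- nrow(pwm$mat)
  starts <- (span_start - L + 1):span_end
  vapply(starts, function(s) {
    w <- substr(sequence, s, s + L - 1)
    sum(vapply(seq_len(L), function(i) {
      b <- substr(w, i, i)
      if (b %in% colnames(pwm$mat)) pwm$mat[i, b] else 0
    }, numeric(1)))
  }, numeric(1))
}
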
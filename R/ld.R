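#' Pairwise linkage disequilibrium (D, D', r^2)
#'
#' Computes linkage disequilibrium between two markers from
#' haploid/homozygous genotype calls, using the two most frequent alleles
#' at each marker. With haplotype frequency `p_AB` and allele frequencies
#' `p_A`, `p_B` (major alleles): `D = p_AB - p_A p_B`;
#' `D' = |D| / D_max` where `D_max = min(p_A (1 - p_B), (1 - p_A) p_B)`
#' for `D > 0` and `min(p_A p_B, (1 - p_A)(1 - p_B))` otherwise;
#' `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#'
#' @param genotypes Tibble or matrix of isolates x 2 markers (character
#'   allele codes). Calls containing `"/"` (heterozygous) or `NA` are
#'   dropped.
#' @return Tibble `D`, `Dprime`, `r2`, `p_A`, `p_B`, `n` (isolates used).
#'   A monomorphic marker yields `NA` statistics with a warning.
#' @export
compute_ld <- function(genotypes) {
  g <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (ncol(g) != 2) abort("genotypes must have exactly 2 marker columns")
  keep <- !is.na(g[[1]]) & !is.na(g[[2]]) &
    !grepl("/", g[[1]], fixed = TRUE) & !grepl("/", g[[2]], fixed = TRUE)
  g <- g[keep, , drop = FALSE]
  if (nrow(g) < 2) abort("need at least 2 isolates with calls at both markers")
  top2 <- function(x) names(sort(table(x), decreasing = TRUE))[1:2]
  a1 <- top2(g[[1]])
  a2 <- top2(g[[2]])
  if (anyNA(a1) || anyNA(a2)) {
    warn("monomorphic marker: LD undefined")
    return(tibble(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                  p_A = NA_real_, p_B = NA_real_, n = nrow(g)))
  }
  use <- g[[1]] %in% a1 & g[[2]] %in% a2
  g <- g[use, , drop = FALSE]
  n <- nrow(g)
  p_a <- mean(g[[1]] == a1[1])
  p_b <- mean(g[[2]] == a2[1])
  p_ab <- mean(g[[1]] == a1[1] & g[[2]] == a2[1])
  d <- p_ab - p_a * p_b
  d_max <- if (d > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  dprime <- if (d == 0) 0 else abs(d) / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  tibble(D = d, Dprime = dprime, r2 = r2, p_A = p_a, p_B = p_b, n = n)
}

#' LD from haplotype counts
#'
#' Convenience wrapper over [compute_ld()] for a 2x2 haplotype count
#' table.
#'
#' @param n_AB,n_Ab,n_aB,n_ab Haplotype counts.
#' @return As [compute_ld()].
#' @export
ld_from_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  m1 <- c(rep("A", n_AB + n_Ab), rep("a", n_aB + n_ab))
  m2 <- c(rep("B", n_AB), rep("b", n_Ab), rep("B", n_aB), rep("b", n_ab))
  compute_ld(tibble(m1 = m1, m2 = m2))
}
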
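#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic MPRA generator.
#' The defaults describe a study in the regime of the assay this package
#' analyses: a median of about two promoter variants per gene, mostly SNVs,
#' hundreds of barcodes per oligo, overdispersed sequencing counts, and
#' replicate library sizes varying by a log-normal factor.
#'
#' @param n_genes Number of genes (one promoter contig each).
#' @param variants_per_gene Mean of the shifted-Poisson number of variants
#'   per promoter (`1 + rpois(variants_per_gene - 1)`).
#' @param snv_fraction Probability a variant is a SNV (vs. a 1-20 bp
#'   indel with geometric length distribution).
#' @param upstream_fraction Probability a variant falls in the distal
#'   upstream interval instead of the 144-bp TSS window.
#' @param causal_fraction Probability a variant carries a planted non-zero
#'   allelic effect.
#' @param effect_sd Standard deviation of planted log2 fold-changes.
#' @param interaction_fraction Probability a two-variant promoter carries a
#'   planted pairwise interaction.
#' @param n_replicates Biological replicates per assay.
#' @param barcodes_per_oligo Mean of the Poisson number of barcodes per
#'   oligo.
#' @param dna_mean Expected DNA count per barcode (before the library-size
#'   factor).
#' @param nb_dispersion Negative-binomial dispersion shared by DNA and RNA
#'   counts (`0` gives Poisson counts).
#' @param baseline_sd SD of per-block baseline log2 activities (log-normal
#'   baseline activity).
#' @param libsize_sdlog sdlog of the log-normal per-sample library-size
#'   factors.
#' @param seed Integer seed fixing every downstream draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50, variants_per_gene = 2,
                       snv_fraction = 0.8, upstream_fraction = 0.3,
                       causal_fraction = 0.2, effect_sd = 0.5,
                       interaction_fraction = 0.1, n_replicates = 6,
                       barcodes_per_oligo = 100, dna_mean = 50,
                       nb_dispersion = 0.05, baseline_sd = 1,
                       libsize_sdlog = 0.3, seed = 1L) {
  probs <- c(snv_fraction = snv_fraction, upstream_fraction = upstream_fraction,
             causal_fraction = causal_fraction,
             interaction_fraction = interaction_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("all fractions must lie in [0, 1]")
  }
  if (n_genes < 1) abort("n_genes must be a positive integer")
  if (variants_per_gene < 1) abort("variants_per_gene must be >= 1")
  if (any(c(effect_sd, barcodes_per_oligo, dna_mean, baseline_sd) <= 0)) {
    abort("effect_sd, barcodes_per_oligo, dna_mean and baseline_sd must be > 0")
  }
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  structure(list(
    n_genes = as.integer(n_genes), variants_per_gene = variants_per_gene,
    snv_fraction = snv_fraction, upstream_fraction = upstream_fraction,
    causal_fraction = causal_fraction, effect_sd = effect_sd,
    interaction_fraction = interaction_fraction,
    n_replicates = as.integer(n_replicates),
    barcodes_per_oligo = barcodes_per_oligo, dna_mean = dna_mean,
    nb_dispersion = nb_dispersion, baseline_sd = baseline_sd,
    libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
    class = "sim_config")
}

random_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate promoter references, variants, and TSS annotations
#'
#' Each gene gets its own contig with a transcription start site; variants
#' are placed either in the 144-bp TSS window or in a distal upstream
#' interval, with non-overlapping footprints. SNVs replace a single base;
#' indels are 1-20 bp insertions or deletions with geometric length
#' distribution, left-anchored in the VCF convention (coordinates are
#' 1-based).
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named character vector of contig
#'   sequences), `variants` (tibble: `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `region`, `class`), and `tss` (tibble: `gene`,
#'   `chrom`, `tss`, `strand`).
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  contig_len <- 1500L
  tss_pos <- 1000L
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  reference <- setNames(
    vapply(genes, function(g) random_dna(contig_len), character(1)),
    paste0(genes, "_chr"))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE,
                   prob = c(0.8, 0.2))
  tss <- tibble(gene = genes, chrom = names(reference), tss = tss_pos,
                strand = strand)
  vrows <- list()
  vid <- 0L
  for (i in seq_len(config$n_genes)) {
    n_var <- 1L + rpois(1, config$variants_per_gene - 1)
    # footprint-safe candidate positions, 25 bp apart
    if (strand[i] == "+") {
      tss_slots <- seq(tss_pos - 144L, tss_pos - 22L, by = 25L)
      up_slots <- seq(tss_pos - 400L, tss_pos - 170L, by = 25L)
    } else {
      tss_slots <- seq(tss_pos + 1L, tss_pos + 122L, by = 25L)
      up_slots <- seq(tss_pos + 170L, tss_pos + 378L, by = 25L)
    }
    in_up <- runif(n_var) < config$upstream_fraction
    n_tss <- min(sum(!in_up), length(tss_slots))
    n_up <- min(sum(in_up), length(up_slots))
    pos <- c(sort(sample(tss_slots, n_tss)), sort(sample(up_slots, n_up)))
    region <- rep(c("tss_window", "upstream"), c(n_tss, n_up))
    for (j in seq_along(pos)) {
      vid <- vid + 1L
      p <- pos[j]
      chrom_seq <- reference[[i]]
      is_snv <- runif(1) < config$snv_fraction
      if (is_snv) {
        ref <- substr(chrom_seq, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        cls <- "SNV"
      } else {
        len <- min(rgeom_shifted(0.3), 20L)
        if (runif(1) < 0.5) { # insertion
          ref <- substr(chrom_seq, p, p)
          alt <- paste0(ref, random_dna(len))
        } else { # deletion
          ref <- substr(chrom_seq, p, p + len)
          alt <- substr(chrom_seq, p, p)
        }
        cls <- "indel"
      }
      vrows[[vid]] <- tibble(
        variant_id = sprintf("v%04d", vid), chrom = names(reference)[i],
        pos = p, ref = ref, alt = alt, gene = genes[i],
        region = region[j], class = cls)
    }
  }
  list(reference = reference, variants = bind_rows(vrows), tss = tss)
}

rgeom_shifted <- function(prob) 1L + stats::rgeom(1, prob)

#' Plant ground-truth effects on simulated variants
#'
#' A `causal_fraction` of variants receive a log2 allelic effect drawn from
#' `N(0, effect_sd)` (optionally a fixed magnitude); the rest have effect
#' exactly 0. Two-variant promoters receive a planted pairwise interaction
#' with probability `interaction_fraction`. The true per-gene cis effect is
#' the sum of its variants' effects.
#'
#' @param variants Variant tibble from [simulate_promoters()].
#' @param config A [sim_config()].
#' @param effect_size Optional fixed |log2 FC| for causal variants (sign
#'   random); default draws from `N(0, effect_sd)`.
#' @return List with `variant_effects`, `interactions`, and `gene_effects`
#'   tibbles (the `GroundTruth`).
#' @export
plant_truth <- function(variants, config, effect_size = NULL) {
  set.seed(config$seed + 104729L)
  n <- nrow(variants)
  causal <- runif(n) < config$causal_fraction
  eff <- numeric(n)
  if (is.null(effect_size)) {
    eff[causal] <- rnorm(sum(causal), 0, config$effect_sd)
  } else {
    eff[causal] <- effect_size * sample(c(-1, 1), sum(causal), replace = TRUE)
  }
  variant_effects <- tibble(variant_id = variants$variant_id,
                            gene = variants$gene, effect = eff,
                            causal = causal)
  two_var <- variants %>%
    filter(.data$region == "tss_window") %>%
    count(.data$gene) %>%
    filter(.data$n == 2) %>%
    pull(.data$gene)
  inter <- list()
  for (g in two_var) {
    if (runif(1) < config$interaction_fraction) {
      vv <- variants$variant_id[variants$gene == g &
                                  variants$region == "tss_window"]
      inter[[length(inter) + 1]] <- tibble(
        gene = g, v1 = vv[1], v2 = vv[2],
        effect = rnorm(1, 0, config$effect_sd))
    }
  }
  interactions <- if (length(inter)) bind_rows(inter) else
    tibble(gene = character(0), v1 = character(0), v2 = character(0),
           effect = numeric(0))
  gene_effects <- variant_effects %>%
    group_by(.data$gene) %>%
    summarise(true_effect = sum(.data$effect), .groups = "drop")
  list(variant_effects = variant_effects, interactions = interactions,
       gene_effects = gene_effects)
}

#' Assign barcodes to oligos (true dictionary)
#'
#' Draws a Poisson number of distinct barcodes per oligo (at least one)
#' using the constrained barcode generator.
#'
#' @param manifest Oligo manifest (needs `oligo_id`).
#' @param config A [sim_config()].
#' @return Tibble `barcode`, `oligo_id`.
#' @export
assign_barcodes <- function(manifest, config) {
  set.seed(config$seed + 15485863L)
  n_per <- pmax(1L, rpois(nrow(manifest), config$barcodes_per_oligo))
  bcs <- generate_barcodes(sum(n_per))
  tibble(barcode = bcs,
         oligo_id = rep(manifest$oligo_id, n_per))
}

# log2 activity of each oligo given planted truth
oligo_activities <- function(manifest, truth, baseline_sd, seed) {
  set.seed(seed)
  blocks <- unique(manifest$block_id)
  base <- setNames(rnorm(length(blocks), 0, baseline_sd), blocks)
  eff <- setNames(truth$variant_effects$effect,
                  truth$variant_effects$variant_id)
  act <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vids <- strsplit(manifest$variant_ids[i], ";", fixed = TRUE)[[1]]
    cfg <- strsplit(manifest$allele_config[i], ";", fixed = TRUE)[[1]]
    rm_v <- vids[cfg == "RM"]
    a <- base[[manifest$block_id[i]]] + sum(eff[rm_v])
    if (nrow(truth$interactions) > 0) {
      hit <- truth$interactions$v1 %in% rm_v & truth$interactions$v2 %in% rm_v
      a <- a + sum(truth$interactions$effect[hit])
    }
    act[i] <- a
  }
  tibble(oligo_id = manifest$oligo_id, activity = act)
}

#' Simulate barcode-level DNA and RNA counts
#'
#' For each barcode, replicate and assay, counts are drawn from a negative
#' binomial whose RNA mean is the DNA mean scaled by `2^activity` and a
#' per-sample library-size factor; the oligo activity is the planted
#' baseline plus planted allelic and interaction effects.
#'
#' @param manifest Oligo manifest (`oligo_id`, `block_id`, `variant_ids`,
#'   `allele_config`).
#' @param dictionary Tibble `barcode`, `oligo_id`; every barcode must map
#'   to a manifest oligo.
#' @param truth Ground truth from [plant_truth()].
#' @param config A [sim_config()].
#' @param seed Seed for the count draws (default derived from the config).
#' @return Long count tibble: `barcode`, `oligo_id`, `sample`, `assay`,
#'   `replicate`, `batch`, `count`, with the per-sample size factors as the
#'   `"size_factors"` attribute and oligo activities as `"activities"`.
#' @export
simulate_counts <- function(manifest, dictionary, truth, config,
                            seed = config$seed + 32452843L) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(dictionary$oligo_id %in% manifest$oligo_id)) {
    abort("every barcode must map to a manifest oligo")
  }
  act <- oligo_activities(manifest, truth, config$baseline_sd,
                          seed = seed + 1L)
  set.seed(seed)
  n_rep <- config$n_replicates
  sf <- tibble(
    assay = rep(c("DNA", "RNA"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    size_factor = exp(rnorm(2 * n_rep, 0, config$libsize_sdlog)))
  bc <- dictionary %>% left_join(act, by = "oligo_id")
  n_bc <- nrow(bc)
  draw <- function(mu) {
    if (config$nb_dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  rows <- vector("list", 2L * n_rep)
  k <- 0L
  for (r in seq_len(n_rep)) {
    for (assay in c("DNA", "RNA")) {
      k <- k + 1L
      s <- sf$size_factor[sf$assay == assay & sf$replicate == r]
      mu <- if (assay == "DNA") rep(config$dna_mean * s, n_bc)
            else config$dna_mean * 2^bc$activity * s
      rows[[k]] <- tibble(
        barcode = bc$barcode, oligo_id = bc$oligo_id,
        sample = paste0(assay, "_", r), assay = assay, replicate = r,
        batch = 1L, count = draw(mu))
    }
  }
  out <- bind_rows(rows)
  attr(out, "size_factors") <- sf
  attr(out, "activities") <- act
  out
}

#' Simulate a per-gene local eQTL effect table
#'
#' The eQTL effect for a gene equals its true summed cis effect plus
#' Gaussian noise; the LOD-score proxy is monotone in |effect| / noise.
#'
#' @param truth Ground truth from [plant_truth()].
#' @param noise_sd SD of the Gaussian noise added to the summed effect.
#' @param seed Random seed.
#' @return Tibble `gene`, `effect`, `lod`.
#' @export
simulate_eqtl_table <- function(truth, noise_sd, seed = 1L) {
  set.seed(seed)
  g <- truth$gene_effects
  eff <- g$true_effect + rnorm(nrow(g), 0, noise_sd)
  lod <- (abs(eff) / (noise_sd + 1e-8))^2
  tibble(gene = g$gene, effect = eff, lod = lod)
}

#' Simulate a complete synthetic MPRA study
#'
#' Chains the generator with the design module: simulates promoters and
#' variants, designs TSS blocks (and Upstream blocks for distal variants),
#' assembles and filters oligos, assigns barcodes, plants ground-truth
#' effects, and draws replicate DNA/RNA counts.
#'
#' @param config A [sim_config()].
#' @param effect_size Optional fixed |log2 FC| for causal variants (see
#'   [plant_truth()]).
#' @param libraries Which libraries to design (subset of
#'   `c("TSS", "Upstream")`).
#' @return List with `reference`, `variants`, `tss`, `manifest`,
#'   `dictionary`, `truth`, `counts`, and `dropped_blocks`.
#' @export
simulate_mpra_study <- function(config, effect_size = NULL,
                                libraries = c("TSS", "Upstream")) {
  sim <- simulate_promoters(config)
  man <- list()
  if ("TSS" %in% libraries) {
    for (i in seq_len(nrow(sim$tss))) {
      g <- sim$tss$gene[i]
      vv <- sim$variants %>%
        filter(.data$gene == g, .data$region == "tss_window")
      if (nrow(vv) == 0) next
      man[[length(man) + 1]] <- design_tss_block(
        g, sim$tss$tss[i], sim$tss$strand[i], vv, sim$reference)
    }
  }
  if ("Upstream" %in% libraries) {
    up <- sim$variants %>% filter(.data$region == "upstream")
    for (i in seq_len(nrow(up))) {
      g <- up$gene[i]
      st <- sim$tss$strand[sim$tss$gene == g]
      man[[length(man) + 1]] <- design_upstream_block(
        up[i, ], sim$reference, g, st)
    }
  }
  manifest <- assemble_oligos(bind_rows(man))
  flt <- filter_blocks(manifest)
  manifest <- flt$kept
  dictionary <- assign_barcodes(manifest, config)
  truth <- plant_truth(sim$variants, config, effect_size = effect_size)
  counts <- simulate_counts(manifest, dictionary, truth, config)
  list(reference = sim$reference, variants = sim$variants, tss = sim$tss,
       manifest = manifest, dictionary = dictionary, truth = truth,
       counts = counts, dropped_blocks = flt$dropped)
}

#' Simulate a minimal two-oligo-per-variant assay
#'
#' Fast generator for calibration studies: every variant gets its own
#' block with one BY and one RM oligo, a drawn set of barcodes, and
#' replicate DNA/RNA counts with the planted log2 effects. Skips sequence
#' design entirely.
#'
#' @param effects Numeric vector of planted log2 fold-changes (one per
#'   variant; 0 = null).
#' @param config A [sim_config()] (uses `n_replicates`,
#'   `barcodes_per_oligo`, `dna_mean`, `nb_dispersion`, `baseline_sd`,
#'   `libsize_sdlog`, `seed`).
#' @return List with `manifest`, `dictionary`, `truth`, `counts`, and
#'   `pairs` (ready for [test_variants()]).
#' @export
simulate_variant_assay <- function(effects, config) {
  n <- length(effects)
  vids <- sprintf("v%05d", seq_len(n))
  blocks <- paste0("blk_", vids)
  manifest <- tibble(
    oligo_id = c(paste0(blocks, "|BY"), paste0(blocks, "|RM")),
    block_id = rep(blocks, 2), gene = rep(paste0("g_", vids), 2),
    library = "Upstream", variant_ids = rep(vids, 2),
    allele_config = rep(c("BY", "RM"), each = n))
  dictionary <- assign_barcodes(manifest, config)
  truth <- list(
    variant_effects = tibble(variant_id = vids, gene = paste0("g_", vids),
                             effect = effects, causal = effects != 0),
    interactions = tibble(gene = character(0), v1 = character(0),
                          v2 = character(0), effect = numeric(0)),
    gene_effects = tibble(gene = paste0("g_", vids), true_effect = effects))
  counts <- simulate_counts(manifest, dictionary, truth, config)
  pairs <- tibble(variant_id = vids, gene = paste0("g_", vids),
                  library = "Upstream", block_id = blocks,
                  by_oligo = paste0(blocks, "|BY"),
                  rm_oligo = paste0(blocks, "|RM"))
  list(manifest = manifest, dictionary = dictionary, truth = truth,
       counts = counts, pairs = pairs)
}
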
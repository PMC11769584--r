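# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# genotype_data from a bare dosage matrix (one chromosome, evenly spaced
# positions unless given).
make_gd <- function(dosage, positions = NULL, chromosome = "chr01",
                    release_year = NULL, line_type = NULL,
                    haplotypes = NULL, phased = FALSE) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(positions)) positions <- seq_len(m) * 1000
  variants <- data.frame(chromosome = chromosome, position = positions,
                         ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    release_year = release_year %||% rep(2000L, n),
    line_type = line_type %||% rep("F1", n),
    stringsAsFactors = FALSE)
  genotype_data(variants, samples, dosage, haplotypes = haplotypes,
                phased = phased)
}

# genotype_data from a haplotype matrix (rows 2i-1, 2i are sample i).
make_gd_phased <- function(haps, positions = NULL, chromosome = "chr01",
                           release_year = NULL) {
  n <- nrow(haps) / 2
  dosage <- haps[seq(1, 2 * n, 2), , drop = FALSE] +
    haps[seq(2, 2 * n, 2), , drop = FALSE]
  make_gd(dosage, positions, chromosome, release_year,
          haplotypes = haps, phased = TRUE)
}

# random biallelic panel in approximate HWE
random_gd <- function(n, m, p = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- runif(m, 0.1, 0.5)
    dosage <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
    make_gd(dosage)
  })
}

# small but realistic simulated panel used by several modules
small_panel_config <- function(seed = 1, n_cultivars = 80,
                               n_chromosomes = 3, n_variants = 300,
                               introgressions = list(), year_trend = 1) {
  sim_config(
    n_founders = 20, n_cultivars = n_cultivars,
    n_pure_lines = 2,
    year_range = c(1940, 2020),
    n_chromosomes = n_chromosomes,
    chrom_lengths_bp = rep(2e7, n_chromosomes),
    n_variants_per_chrom = n_variants,
    selection_trait = trait_config(name = "selection", n_qtl = 50,
                                   year_trend = year_trend),
    introgressions = introgressions,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
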
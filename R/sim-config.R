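#' Configuration for a simulated breeding-program panel
#'
#' Describes a forward-in-time simulation of a decades-long hybrid breeding
#' program: a founder set of fully inbred lines, a breeding pool that is
#' advanced by recurrent selection (one generation every
#' `generation_interval` years), and a panel of mostly-F1 cultivars sampled
#' from the pool along the way.  The defaults describe the kind of panel the
#' downstream analyses target: 150 cultivars (three of them pure lines)
#' released over roughly 80 years on a 12-chromosome genome.
#'
#' @param n_founders Number of fully inbred founder lines (>= 4).  The
#'   breeding pool keeps this size in every generation.
#' @param n_cultivars Number of cultivars in the released panel (>= 2).
#' @param n_pure_lines How many panel members are pure (fully homozygous)
#'   lines rather than F1 hybrids.
#' @param year_range Integer vector `c(first, last)` of release years.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths_bp Integer vector of chromosome lengths in bp.
#' @param n_variants_per_chrom Baseline number of segregating sites placed
#'   uniformly at random on each chromosome (introgression regions receive
#'   extra sites, see [introgression_spec()]).
#' @param founder_maf_dist Lower and upper bound of the uniform distribution
#'   from which per-site ancestral ALT-allele frequencies are drawn.
#' @param n_ancestral_haplotypes Size of the ancestral haplotype pool the
#'   founders are mosaics of.  Founder chromosomes switch ancestor with
#'   probability `1 - exp(-d / founder_segment_bp)` between consecutive
#'   sites `d` bp apart, which gives the panel linkage disequilibrium that
#'   decays with physical distance, as in real cultivar collections derived
#'   from narrow germplasm.
#' @param founder_segment_bp Mean ancestral segment length in bp.
#' @param selection_trait A [trait_config()] used for directional truncation
#'   selection of breeding-pool parents.  Its `year_trend` field sets the
#'   direction of selection (positive selects high trait values, negative low,
#'   zero disables selection so the pool evolves by drift only).
#' @param introgressions List of [introgression_spec()] objects.
#' @param generation_interval Years between breeding-pool generations.
#' @param selected_fraction Fraction of the pool retained as parents under
#'   truncation selection.
#' @param seed Integer seed; two simulations from the same config are
#'   bit-identical.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_panel()]
#' @export
sim_config <- function(n_founders = 60,
                       n_cultivars = 150,
                       n_pure_lines = 3,
                       year_range = c(1940, 2020),
                       n_chromosomes = 12,
                       chrom_lengths_bp = rep(6e7, n_chromosomes),
                       n_variants_per_chrom = 1200,
                       founder_maf_dist = c(0.05, 0.5),
                       n_ancestral_haplotypes = 3,
                       founder_segment_bp = 1e6,
                       selection_trait = trait_config(name = "selection",
                                                      n_qtl = 100,
                                                      year_trend = 1),
                       introgressions = list(),
                       generation_interval = 10,
                       selected_fraction = 0.7,
                       seed = 1L) {
  if (n_founders < 4) stop("n_founders must be >= 4")
  if (n_cultivars < 2) stop("n_cultivars must be >= 2")
  if (n_pure_lines < 0 || n_pure_lines > n_cultivars)
    stop("n_pure_lines must lie in [0, n_cultivars]")
  if (length(year_range) != 2 || year_range[1] >= year_range[2])
    stop("year_range must be c(first, last) with first < last")
  if (length(chrom_lengths_bp) != n_chromosomes)
    stop("chrom_lengths_bp must have one entry per chromosome")
  if (any(chrom_lengths_bp <= 0)) stop("chrom_lengths_bp must all be > 0")
  if (n_variants_per_chrom < 1) stop("n_variants_per_chrom must be >= 1")
  if (length(founder_maf_dist) != 2 ||
      founder_maf_dist[1] <= 0 || founder_maf_dist[2] > 0.5 ||
      founder_maf_dist[1] > founder_maf_dist[2])
    stop("founder_maf_dist must be bounds within (0, 0.5]")
  if (n_ancestral_haplotypes < 2)
    stop("n_ancestral_haplotypes must be >= 2")
  if (founder_segment_bp <= 0) stop("founder_segment_bp must be > 0")
  if (!inherits(selection_trait, "trait_config"))
    stop("selection_trait must be a trait_config")
  if (generation_interval <= 0) stop("generation_interval must be > 0")
  if (selected_fraction <= 0 || selected_fraction > 1)
    stop("selected_fraction must lie in (0, 1]")
  for (ig in introgressions) {
    if (!inherits(ig, "introgression_spec"))
      stop("introgressions must be a list of introgression_spec objects")
    if (ig$chromosome < 1 || ig$chromosome > n_chromosomes)
      stop("introgression chromosome index out of range")
    if (ig$end_bp > chrom_lengths_bp[ig$chromosome])
      stop("introgression region extends beyond its chromosome length")
  }
  structure(list(
    n_founders = as.integer(n_founders),
    n_cultivars = as.integer(n_cultivars),
    n_pure_lines = as.integer(n_pure_lines),
    year_range = as.integer(year_range),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    founder_maf_dist = as.numeric(founder_maf_dist),
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    founder_segment_bp = as.numeric(founder_segment_bp),
    selection_trait = selection_trait,
    introgressions = introgressions,
    generation_interval = as.numeric(generation_interval),
    selected_fraction = as.numeric(selected_fraction),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specify an introgressed donor segment
#'
#' Models a chromosomal segment introgressed from a divergent donor (e.g. a
#' wild-relative resistance haplotype dragged into elite material).  From
#' `onset_year` on, a configurable fraction of newly released F1 cultivars
#' carry the donor haplotype over the region.  With `keep_heterozygous = TRUE`
#' exactly one of the carrier's two gametes is the donor haplotype, producing
#' the heterozygosity excess typical of resistance loci maintained in the
#' heterozygous state in hybrids; with `FALSE` both gametes carry it, so the
#' region sweeps towards homozygosity in recent cultivars.  Recombination is
#' suppressed inside the region (linkage drag), and the region's variant
#' density is inflated by a factor `1 + 10 * donor_divergence`.
#'
#' @param chromosome Chromosome index (1-based).
#' @param start_bp,end_bp Region bounds in bp, `start_bp < end_bp`.
#' @param donor_divergence Per-site probability that the donor haplotype
#'   carries an allele absent from the founder pool, in `[0, 1]`.
#' @param onset_year First release year in which carriers appear.
#' @param carrier_frequency_after_onset Probability that an F1 cultivar
#'   released in or after `onset_year` carries the donor segment.
#' @param keep_heterozygous Logical; keep the donor segment in exactly one
#'   parental gamete of each carrier.
#'
#' @return An object of class `introgression_spec`.
#' @export
introgression_spec <- function(chromosome, start_bp, end_bp,
                               donor_divergence = 0.3,
                               onset_year = 1990,
                               carrier_frequency_after_onset = 0.8,
                               keep_heterozygous = TRUE) {
  if (start_bp >= end_bp) stop("start_bp must be < end_bp")
  if (donor_divergence < 0 || donor_divergence > 1)
    stop("donor_divergence must lie in [0, 1]")
  if (carrier_frequency_after_onset < 0 || carrier_frequency_after_onset > 1)
    stop("carrier_frequency_after_onset must lie in [0, 1]")
  structure(list(
    chromosome = as.integer(chromosome),
    start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp),
    donor_divergence = as.numeric(donor_divergence),
    onset_year = as.integer(onset_year),
    carrier_frequency_after_onset = as.numeric(carrier_frequency_after_onset),
    keep_heterozygous = isTRUE(keep_heterozygous)
  ), class = "introgression_spec")
}

#' Configuration of a simulated quantitative trait
#'
#' Defines the genetic architecture and the nuisance structure of a trait:
#' additive and dominance QTL effects plus random season, season-by-year and
#' residual components, mirroring multi-season cultivar trials.
#'
#' When `qtl_placement = "random"` the requested number of QTL is drawn among
#' the simulated variants and effect sizes are rescaled so that the realised
#' sample variance of the additive (dominance) genetic values equals
#' `additive_var` (`dominance_var`) exactly.  Alternatively an explicit
#' data frame with columns `chromosome`, `position_bp` and optionally
#' `additive_effect` / `dominance_effect` pins QTL to named variants; explicit
#' effects are used verbatim, without rescaling.
#'
#' @param name Trait label.
#' @param n_qtl Number of QTL (ignored for explicit placement).
#' @param additive_var Target variance of additive genetic values.
#' @param dominance_var Target variance of dominance deviations (driven by
#'   the heterozygosity indicator, 1 iff dosage equals 1).
#' @param season_var,season_year_var,residual_var Variances of the random
#'   season effect, season-by-year interaction and residual.
#' @param qtl_placement `"random"` or a data frame as described above.
#' @param year_trend Direction of parent selection when this trait drives the
#'   breeding pool: positive selects for high values, negative for low, zero
#'   disables selection.
#' @param mu Grand mean added to every record.
#'
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(name = "trait",
                         n_qtl = 100,
                         additive_var = 1,
                         dominance_var = 0,
                         season_var = 1,
                         season_year_var = 0.5,
                         residual_var = 1,
                         qtl_placement = "random",
                         year_trend = 0,
                         mu = 0) {
  vars <- c(additive_var = additive_var, dominance_var = dominance_var,
            season_var = season_var, season_year_var = season_year_var,
            residual_var = residual_var)
  if (any(vars < 0))
    stop("negative variance component: ",
         paste(names(vars)[vars < 0], collapse = ", "))
  if (n_qtl < 0) stop("n_qtl must be >= 0")
  if (!identical(qtl_placement, "random") && !is.data.frame(qtl_placement))
    stop("qtl_placement must be \"random\" or a data frame")
  if (is.data.frame(qtl_placement) &&
      !all(c("chromosome", "position_bp") %in% names(qtl_placement)))
    stop("explicit qtl_placement needs columns chromosome, position_bp")
  structure(list(
    name = name,
    n_qtl = as.integer(n_qtl),
    additive_var = as.numeric(additive_var),
    dominance_var = as.numeric(dominance_var),
    season_var = as.numeric(season_var),
    season_year_var = as.numeric(season_year_var),
    residual_var = as.numeric(residual_var),
    qtl_placement = qtl_placement,
    year_trend = as.numeric(year_trend),
    mu = as.numeric(mu)
  ), class = "trait_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cultivars, "cultivars (", x$n_pure_lines,
      "pure lines),", x$n_founders, "founders,\n  ",
      x$n_chromosomes, "chromosomes x", x$n_variants_per_chrom,
      "baseline variants, years", x$year_range[1], "-", x$year_range[2],
      ",", length(x$introgressions), "introgression(s)\n")
  invisible(x)
}
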
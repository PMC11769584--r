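#' Simulate an F1-dominated cultivar panel
#'
#' Forward-in-time simulation of a breeding program.  A pool of fully inbred
#' lines is founded at the first year of `config$year_range` and advanced one
#' generation every `generation_interval` years by (optionally directional)
#' truncation selection followed by crossing and instant re-inbreeding
#' (doubled-haploid gametes), so allele frequencies drift and/or move
#' directionally with calendar time.  Cultivars are released at years spread
#' evenly over the range: an F1 cultivar is the cross of two distinct inbred
#' lines from the pool of its release generation (its two haplotypes are
#' exactly the two parental lines), a pure-line cultivar is a single pool
#' line.  Introgression segments are overlaid on carriers afterwards (see
#' [introgression_spec()]).
#'
#' Meiosis places on average one crossover per chromosome (Poisson count,
#' uniform position); crossovers falling inside an introgression region are
#' discarded, mimicking the recombination suppression responsible for linkage
#' drag.
#'
#' @param config A [sim_config()].
#' @return A [genotype_data()] object with phased haplotypes.  Attributes
#'   carry simulation truth for validation: `parent_line_haplotypes` (the
#'   pre-introgression haplotypes, i.e. the recorded parents' genomes),
#'   `introgression_carriers` (per spec: carrier ids and region site
#'   indices), `founder_frequencies`, `selection_qtl` and `config`.
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  for (ig in config$introgressions) {
    if (ig$carrier_frequency_after_onset > 0 &&
        ig$onset_year > config$year_range[2])
      stop("introgression onset_year ", ig$onset_year,
           " is after the last release year; no cultivar can be a carrier")
  }
  withr::with_seed(config$seed, .simulate_panel_impl(config))
}

.simulate_panel_impl <- function(cfg) {
  nchr <- cfg$n_chromosomes
  intro <- cfg$introgressions

  ## --- variant positions (uniform, deduplicated, density spike in
  ## introgression regions proportional to 1 + 10 * donor_divergence) ---
  pos_list <- vector("list", nchr)
  for (ch in seq_len(nchr)) {
    L <- cfg$chrom_lengths_bp[ch]
    pos <- sample.int(L, cfg$n_variants_per_chrom, replace = TRUE)
    for (ig in intro) {
      if (ig$chromosome != ch) next
      base_density <- cfg$n_variants_per_chrom / L
      n_extra <- stats::rpois(1, base_density * (ig$end_bp - ig$start_bp) *
                                ig$donor_divergence * 10)
      if (n_extra > 0)
        pos <- c(pos, ig$start_bp - 1 +
                   sample.int(ig$end_bp - ig$start_bp + 1, n_extra,
                              replace = TRUE))
    }
    pos_list[[ch]] <- sort(unique(pos))
  }
  m_chr <- lengths(pos_list)
  m <- sum(m_chr)
  chrom_idx <- rep(seq_len(nchr), m_chr)
  pos <- unlist(pos_list, use.names = FALSE)

  ## --- founder allele frequencies; donor-specific sites are absent from the
  ## founder pool (frequency 0) and fixed on the donor haplotype ---
  p <- stats::runif(m, cfg$founder_maf_dist[1], cfg$founder_maf_dist[2])
  donor_haps <- vector("list", length(intro))
  region_sites <- vector("list", length(intro))
  for (k in seq_along(intro)) {
    ig <- intro[[k]]
    sites <- which(chrom_idx == ig$chromosome &
                     pos >= ig$start_bp & pos <= ig$end_bp)
    region_sites[[k]] <- sites
    dspec <- stats::runif(length(sites)) < ig$donor_divergence
    p[sites[dspec]] <- 0
    hap <- stats::rbinom(length(sites), 1, p[sites])
    hap[dspec] <- 1L
    donor_haps[[k]] <- hap
  }

  ## --- founder pool: n_founders fully inbred lines, one haplotype each.
  ## Founders are mosaics of a small ancestral haplotype pool (segment
  ## lengths ~ Exp(founder_segment_bp)), so linkage disequilibrium decays
  ## with physical distance as in real cultivar collections.
  chr_sites <- split(seq_len(m), chrom_idx)
  n_anc <- cfg$n_ancestral_haplotypes
  anc <- matrix(stats::rbinom(n_anc * m, 1, rep(p, each = n_anc)),
                nrow = n_anc)
  founders <- matrix(0L, cfg$n_founders, m)
  for (ch in seq_len(nchr)) {
    sel <- chr_sites[[ch]]
    d <- diff(pos[sel])
    p_switch <- 1 - exp(-d / cfg$founder_segment_bp)
    for (f in seq_len(cfg$n_founders)) {
      switches <- stats::rbinom(length(d), 1, p_switch)
      seg_id <- cumsum(c(1L, switches))
      seg_anc <- sample.int(n_anc, max(seg_id), replace = TRUE)
      founders[f, sel] <- anc[cbind(seg_anc[seg_id], sel)]
    }
  }
  founder_freq <- colMeans(founders)

  ## selection-trait QTL (additive only; the pool is inbred)
  st <- cfg$selection_trait
  n_qtl <- min(st$n_qtl, m)
  qtl_idx <- if (n_qtl > 0) sort(sample.int(m, n_qtl)) else integer(0)
  qtl_eff <- if (n_qtl > 0) stats::rnorm(n_qtl) else numeric(0)

  suppress <- lapply(seq_len(nchr), function(ch) {
    regs <- Filter(function(ig) ig$chromosome == ch, intro)
    if (length(regs) == 0) NULL
    else cbind(vapply(regs, `[[`, 0, "start_bp"),
               vapply(regs, `[[`, 0, "end_bp"))
  })
  gamete <- function(hA, hB) {
    out <- integer(m)
    for (ch in seq_len(nchr)) {
      sel <- chr_sites[[ch]]
      n_xo <- stats::rpois(1, 1)
      bp <- sort(stats::runif(n_xo, 0, cfg$chrom_lengths_bp[ch]))
      if (!is.null(suppress[[ch]]) && length(bp)) {
        inside <- vapply(bp, function(b)
          any(b >= suppress[[ch]][, 1] & b <= suppress[[ch]][, 2]), TRUE)
        bp <- bp[!inside]
      }
      seg <- findInterval(pos[sel], bp)
      from_a <- (seg + sample(0:1, 1)) %% 2 == 0
      out[sel] <- ifelse(from_a, hA[sel], hB[sel])
    }
    out
  }

  ## --- advance the breeding pool one generation per interval ---
  gens <- seq(cfg$year_range[1], cfg$year_range[2],
              by = cfg$generation_interval)
  pools <- vector("list", length(gens))
  pools[[1]] <- founders
  directional <- st$year_trend != 0 && n_qtl > 0
  for (g in seq_along(gens)[-1]) {
    prev <- pools[[g - 1]]
    if (directional) {
      val <- as.vector(prev[, qtl_idx, drop = FALSE] %*% qtl_eff)
      keep <- order(val, decreasing = st$year_trend > 0)
      keep <- keep[seq_len(max(2, ceiling(cfg$selected_fraction * nrow(prev))))]
    } else keep <- seq_len(nrow(prev))
    nxt <- matrix(0L, cfg$n_founders, m)
    for (i in seq_len(cfg$n_founders)) {
      par <- sample(keep, 2, replace = FALSE)
      nxt[i, ] <- gamete(prev[par[1], ], prev[par[2], ])
    }
    pools[[g]] <- nxt
  }

  ## --- release the panel ---
  n <- cfg$n_cultivars
  years <- round(seq(cfg$year_range[1], cfg$year_range[2], length.out = n))
  pure_idx <- if (cfg$n_pure_lines > 0) sample.int(n, cfg$n_pure_lines)
              else integer(0)
  line_type <- rep("F1", n)
  line_type[pure_idx] <- "pure_line"
  haps <- matrix(0L, 2 * n, m)
  parent1 <- parent2 <- character(n)
  for (i in seq_len(n)) {
    g <- findInterval(years[i], gens)
    pool <- pools[[g]]
    if (line_type[i] == "pure_line") {
      pl <- sample.int(nrow(pool), 1)
      haps[2 * i - 1, ] <- pool[pl, ]
      haps[2 * i, ] <- pool[pl, ]
      parent1[i] <- parent2[i] <- sprintf("G%d_L%02d", g, pl)
    } else {
      pl <- sample.int(nrow(pool), 2, replace = FALSE)
      haps[2 * i - 1, ] <- pool[pl[1], ]
      haps[2 * i, ] <- pool[pl[2], ]
      parent1[i] <- sprintf("G%d_L%02d", g, pl[1])
      parent2[i] <- sprintf("G%d_L%02d", g, pl[2])
    }
  }
  parent_haps <- haps

  ## --- overlay introgression segments on carriers (F1s only, so pure lines
  ## stay fully homozygous) ---
  carriers <- vector("list", length(intro))
  for (k in seq_along(intro)) {
    ig <- intro[[k]]
    eligible <- which(years >= ig$onset_year & line_type == "F1")
    if (length(eligible) == 0 && ig$carrier_frequency_after_onset > 0)
      stop("no F1 cultivar released in or after onset_year ", ig$onset_year)
    is_car <- eligible[stats::runif(length(eligible)) <
                         ig$carrier_frequency_after_onset]
    sites <- region_sites[[k]]
    for (i in is_car) {
      if (ig$keep_heterozygous) {
        row <- 2 * i - 2 + sample(1:2, 1)
        haps[row, sites] <- donor_haps[[k]]
      } else {
        haps[2 * i - 1, sites] <- donor_haps[[k]]
        haps[2 * i, sites] <- donor_haps[[k]]
      }
    }
    carriers[[k]] <- list(spec = ig, carriers = sprintf("cv%03d", is_car),
                          sites = sites, donor_hap = donor_haps[[k]])
  }

  sample_ids <- sprintf("cv%03d", seq_len(n))
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  variants <- data.frame(
    chromosome = sprintf("chr%02d", chrom_idx),
    position = pos,
    ref = ref, alt = unname(alt),
    id = sprintf("chr%02d_%d", chrom_idx, pos),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sample_ids, release_year = years, line_type = line_type,
    parent1 = parent1, parent2 = parent2, stringsAsFactors = FALSE)

  dosage <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(dosage) <- sample_ids
  gd <- genotype_data(variants, samples, dosage,
                      haplotypes = haps, phased = TRUE)
  attr(gd, "parent_line_haplotypes") <- parent_haps
  attr(gd, "introgression_carriers") <- carriers
  attr(gd, "founder_frequencies") <- founder_freq
  attr(gd, "selection_qtl") <- data.frame(site = qtl_idx, effect = qtl_eff)
  attr(gd, "config") <- cfg
  gd
}

#' Simulate multi-season phenotype records for a panel
#'
#' Generates long-format records
#' `y = mu + additive + dominance + season + season:year + residual`,
#' where the additive term is a weighted sum of ALT dosages over the trait's
#' QTL and the dominance term a weighted sum of heterozygosity indicators
#' (1 iff dosage equals 1).  Every cultivar is recorded in every
#' season-by-year cell (a balanced trial).  True per-cultivar genetic values
#' are attached for recovery testing.
#'
#' @param genotypes A [genotype_data()] object.
#' @param trait A [trait_config()].
#' @param n_seasons,n_years Number of cropping seasons and years.
#' @param seed Integer seed.
#' @return A data frame of class `phenotype_records` with columns
#'   `sample_id, season, year, trait, value` and attributes `truth`
#'   (per-cultivar additive, dominance and total genetic values) and `qtl`.
#' @export
simulate_phenotypes <- function(genotypes, trait, n_seasons = 2, n_years = 2,
                                seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(trait, "trait_config"))
  if (n_seasons < 1 || n_years < 1) stop("n_seasons and n_years must be >= 1")
  withr::with_seed(seed, {
    dosage <- genotypes$dosage
    m <- ncol(dosage)
    n <- nrow(dosage)

    if (is.data.frame(trait$qtl_placement)) {
      qp <- trait$qtl_placement
      key <- paste(genotypes$variants$chromosome, genotypes$variants$position)
      idx <- match(paste(qp$chromosome, qp$position_bp), key)
      if (anyNA(idx))
        stop("qtl_placement refers to variants absent from the panel: ",
             paste(paste(qp$chromosome, qp$position_bp)[is.na(idx)],
                   collapse = ", "))
      a_eff <- if ("additive_effect" %in% names(qp)) qp$additive_effect
               else stats::rnorm(length(idx))
      d_eff <- if ("dominance_effect" %in% names(qp)) qp$dominance_effect
               else rep(0, length(idx))
      explicit <- "additive_effect" %in% names(qp) ||
        "dominance_effect" %in% names(qp)
    } else {
      n_qtl <- min(trait$n_qtl, m)
      idx <- if (n_qtl > 0) sort(sample.int(m, n_qtl)) else integer(0)
      a_eff <- stats::rnorm(length(idx))
      d_eff <- stats::rnorm(length(idx))
      explicit <- FALSE
    }

    g_add <- as.vector(dosage[, idx, drop = FALSE] %*% a_eff)
    het <- (dosage[, idx, drop = FALSE] == 1) + 0
    g_dom <- as.vector(het %*% d_eff)
    if (!explicit) {
      ## rescale so realised sample variances hit the configured targets
      g_add <- .scale_to_var(g_add, trait$additive_var)
      g_dom <- .scale_to_var(g_dom, trait$dominance_var)
    }
    g_tot <- g_add + g_dom

    seasons <- sprintf("S%d", seq_len(n_seasons))
    yrs <- sprintf("Y%d", seq_len(n_years))
    s_eff <- stats::rnorm(n_seasons, 0, sqrt(trait$season_var))
    sy_eff <- matrix(stats::rnorm(n_seasons * n_years, 0,
                                  sqrt(trait$season_year_var)),
                     n_seasons, n_years,
                     dimnames = list(seasons, yrs))
    grid <- expand.grid(sample_id = genotypes$samples$sample_id,
                        season = seasons, year = yrs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(grid$sample_id, genotypes$samples$sample_id)
    grid$trait <- trait$name
    grid$value <- trait$mu + g_tot[gi] + s_eff[match(grid$season, seasons)] +
      sy_eff[cbind(grid$season, grid$year)] +
      stats::rnorm(nrow(grid), 0, sqrt(trait$residual_var))
    truth <- data.frame(sample_id = genotypes$samples$sample_id,
                        additive = g_add, dominance = g_dom,
                        genetic = g_tot, stringsAsFactors = FALSE)
    structure(grid[, c("sample_id", "season", "year", "trait", "value")],
              truth = truth,
              qtl = data.frame(site = idx, additive_effect = a_eff,
                               dominance_effect = d_eff),
              class = c("phenotype_records", "data.frame"))
  })
}

.scale_to_var <- function(x, target) {
  if (target == 0) return(rep(0, length(x)))
  v <- stats::var(x)
  if (v == 0) stop("cannot scale a constant genetic value to variance ",
                   target, " (no segregating QTL)")
  x * sqrt(target / v)
}

#' Write a simulated panel to standard file formats
#'
#' Writes a VCF 4.2 file (phased `GT` when haplotypes are present), a sample
#' metadata TSV (`sample_id, release_year, line_type`) and, when phenotype
#' records are supplied, a long-format phenotype TSV
#' (`sample_id, season, year, trait, value`).  The fixture round-trips
#' losslessly through [read_vcf()].
#'
#' @param genotypes A [genotype_data()].
#' @param phenotypes Optional `phenotype_records` data frame.
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix, default `"panel"`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(genotypes, phenotypes = NULL, out_dir,
                          prefix = "panel") {
  stopifnot(inherits(genotypes, "genotype_data"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  vcf <- file.path(out_dir, paste0(prefix, ".vcf"))
  meta <- file.path(out_dir, paste0(prefix, "_samples.tsv"))
  .write_panel_vcf(genotypes, vcf)
  utils::write.table(
    genotypes$samples[, c("sample_id", "release_year", "line_type")],
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf, metadata = meta)
  if (!is.null(phenotypes)) {
    ph <- file.path(out_dir, paste0(prefix, "_phenotypes.tsv"))
    utils::write.table(as.data.frame(phenotypes)[
      , c("sample_id", "season", "year", "trait", "value")],
      ph, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, phenotypes = ph)
  }
  invisible(paths)
}

.write_panel_vcf <- function(g, path) {
  v <- g$variants
  n <- nrow(g$samples)
  m <- nrow(v)
  if (g$phased && !is.null(g$haplotypes)) {
    h1 <- g$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- g$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
    gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = m)
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[t(g$dosage) + 1], nrow = m)
  }
  chroms <- unique(v$chromosome)
  cfg <- attr(g, "config")
  clen <- if (!is.null(cfg)) {
    stats::setNames(cfg$chrom_lengths_bp[seq_along(chroms)], chroms)
  } else {
    vapply(chroms, function(ch) max(v$position[v$chromosome == ch]), 0)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cultivarpopgen",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(clen[chroms])),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t"))
  body <- do.call(paste, c(
    list(v$chromosome, v$position, v$id, v$ref, v$alt, ".", "PASS", ".", "GT"),
    lapply(seq_len(n), function(j) gt[, j]),
    sep = "\t"))
  writeLines(c(header, body), path)
}

#' @export
print.phenotype_records <- function(x, ...) {
  cat("phenotype_records:", nrow(x), "records,",
      length(unique(x$sample_id)), "cultivars,",
      length(unique(x$season)), "season(s) x",
      length(unique(x$year)), "year(s), trait:",
      paste(unique(x$trait), collapse = ", "), "\n")
  invisible(x)
}
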
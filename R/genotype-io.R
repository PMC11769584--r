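#' Construct a genotype data container
#'
#' The common substrate of every analysis stage: a variant table, sample
#' metadata and an ALT-allele dosage matrix in `{0, 1, 2}`
#' (`{REF/REF, het, ALT/ALT}`), optionally with a phased binary haplotype
#' matrix whose rows `2i-1` and `2i` are the two gametes of sample `i`.
#'
#' @param variants Data frame with columns `chromosome`, `position`, `ref`,
#'   `alt` and optionally `id`; positions strictly increasing within each
#'   chromosome.
#' @param samples Data frame with at least a `sample_id` column (typically
#'   also `release_year` and `line_type`).
#' @param dosage Integer matrix, samples by variants, values in `{0, 1, 2}`.
#' @param haplotypes Optional binary matrix of dimension
#'   `2 * n_samples` by `n_variants`.
#' @param phased Logical; must come with `haplotypes`, whose paired rows must
#'   sum to `dosage`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(variants, samples, dosage, haplotypes = NULL,
                          phased = FALSE) {
  stopifnot(is.data.frame(variants), is.data.frame(samples),
            is.matrix(dosage))
  need <- c("chromosome", "position", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns ", paste(need, collapse = ", "))
  if (!"sample_id" %in% names(samples))
    stop("samples must have a sample_id column")
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants))
    stop("dosage must be n_samples x n_variants")
  if (!all(dosage %in% 0:2)) stop("dosage values must lie in {0, 1, 2}")
  bad <- tapply(variants$position, variants$chromosome,
                function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("variant positions must be strictly increasing within a chromosome")
  if (phased) {
    if (is.null(haplotypes)) stop("phased = TRUE requires haplotypes")
    if (nrow(haplotypes) != 2 * nrow(samples) ||
        ncol(haplotypes) != nrow(variants))
      stop("haplotypes must be 2*n_samples x n_variants")
    d2 <- haplotypes[seq(1, nrow(haplotypes), 2), , drop = FALSE] +
      haplotypes[seq(2, nrow(haplotypes), 2), , drop = FALSE]
    if (!all(d2 == dosage))
      stop("haplotypes are inconsistent with dosage")
  }
  if (is.null(variants$id))
    variants$id <- paste(variants$chromosome, variants$position, sep = "_")
  rownames(dosage) <- samples$sample_id
  structure(list(variants = variants, samples = samples, dosage = dosage,
                 haplotypes = haplotypes, phased = isTRUE(phased)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$samples), "samples x", nrow(x$variants),
      "variants on", length(unique(x$variants$chromosome)),
      "chromosome(s);", if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' Keep a subset of variants (internal index-based subset)
#' @noRd
.subset_variants <- function(g, keep) {
  g$variants <- g$variants[keep, , drop = FALSE]
  rownames(g$variants) <- NULL
  g$dosage <- g$dosage[, keep, drop = FALSE]
  if (!is.null(g$haplotypes))
    g$haplotypes <- g$haplotypes[, keep, drop = FALSE]
  g
}

#' Read a multi-sample VCF with sample metadata
#'
#' Ingests a finished (called, imputed) diploid VCF.  Multiallelic records
#' are dropped with a logged count; any missing genotype is an error naming
#' the first offending record, since imputation is assumed upstream.  The
#' phased flag is set iff every genotype uses the `|` separator, in which
#' case the haplotype matrix is populated.  Records with duplicated
#' (chromosome, position) are dropped with a logged count so positions are
#' strictly increasing.
#'
#' @param path Path to a VCF 4.x file.
#' @param metadata_path Path to a TSV with columns `sample_id`,
#'   `release_year`, `line_type`; every VCF sample must appear in it.
#' @return A [genotype_data()] object; samples in VCF column order.
#' @export
read_vcf <- function(path, metadata_path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("read_vcf: dropped ", sum(multi), " multiallelic record(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  dup <- duplicated(key)
  if (any(dup)) {
    message("read_vcf: dropped ", sum(dup),
            " record(s) at duplicated positions")
    fix <- fix[!dup, , drop = FALSE]
    gt <- gt[!dup, , drop = FALSE]
  }

  miss <- is.na(gt) | !grepl("^[01]([|/][01])?$", gt)
  if (any(miss)) {
    first <- which(miss, arr.ind = TRUE)[1, ]
    stop("missing or unparseable genotype at ",
         fix[first["row"], "CHROM"], ":", fix[first["row"], "POS"],
         " (sample ", colnames(gt)[first["col"]],
         "); impute genotypes upstream")
  }

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata must have a sample_id column")
  vcf_samples <- colnames(gt)
  missing_meta <- setdiff(vcf_samples, meta$sample_id)
  if (length(missing_meta))
    stop("VCF sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  samples <- meta[match(vcf_samples, meta$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  a2[is.na(a2)] <- a1[is.na(a2)]          # haploid-style single-allele GT
  dim(a1) <- dim(a2) <- dim(gt)
  phased <- all(grepl("|", gt, fixed = TRUE))

  m <- nrow(fix); n <- length(vcf_samples)
  dosage <- t(a1 + a2)
  haps <- NULL
  if (phased) {
    haps <- matrix(0L, 2 * n, m)
    haps[seq(1, 2 * n, 2), ] <- t(a1)
    haps[seq(2, 2 * n, 2), ] <- t(a2)
  }
  variants <- data.frame(
    chromosome = fix[, "CHROM"],
    position = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fix[, "ID"]),
    stringsAsFactors = FALSE)
  ord <- order(variants$chromosome, variants$position)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
    if (!is.null(haps)) haps <- haps[, ord, drop = FALSE]
  }
  genotype_data(variants, samples, dosage, haplotypes = haps, phased = phased)
}

#' Per-site ALT-allele frequencies
#' @noRd
.alt_freq <- function(g) colMeans(g$dosage) / 2

#' Filter variants by minor-allele frequency
#'
#' Keeps variants whose minor-allele frequency, computed from the `2n`
#' allele count of the dosage matrix, is at least `min_maf`.  A site with
#' MAF exactly at the threshold is retained.  Variant order is preserved.
#'
#' @param g A [genotype_data()].
#' @param min_maf Threshold in `[0, 0.5]`, default 0.05.
#' @return The filtered `genotype_data`.
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_data"))
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  p <- .alt_freq(g)
  maf <- pmin(p, 1 - p)
  .subset_variants(g, which(maf >= min_maf))
}

#' Greedy LD pruning of a variant set
#'
#' Left-to-right scan per chromosome: a variant is dropped when its
#' genotype-based r-squared (squared Pearson correlation of dosages) with any
#' retained variant among the previous `window` sites strictly exceeds
#' `r2_max`.  Deterministic; the retained set is an order-preserving subset
#' of the input.  `window` counts variant sites (the pruning tool's default
#' unit); set `window_unit = "bp"` to interpret it as a base-pair span
#' instead.
#'
#' @param g A [genotype_data()].
#' @param r2_max Drop threshold, default 0.99.
#' @param window Comparison window, default 1000 sites.
#' @param window_unit `"sites"` (default) or `"bp"`.
#' @return The pruned `genotype_data`.
#' @export
ld_prune <- function(g, r2_max = 0.99, window = 1000,
                     window_unit = c("sites", "bp")) {
  stopifnot(inherits(g, "genotype_data"))
  window_unit <- match.arg(window_unit)
  if (window < 1) stop("window must be >= 1")
  n <- nrow(g$dosage)
  ## standardized columns: crossprod gives Pearson r directly
  z <- scale(g$dosage)
  sdz <- attr(z, "scaled:scale")
  z <- z / sqrt(n - 1)
  keep <- logical(nrow(g$variants))
  for (ch in unique(g$variants$chromosome)) {
    idx <- which(g$variants$chromosome == ch)
    kept <- integer(0)
    for (j in idx) {
      if (is.na(sdz[j]) || sdz[j] == 0) { keep[j] <- TRUE; kept <- c(kept, j); next }
      if (window_unit == "sites") {
        cmp <- kept[j - kept <= window]
      } else {
        cmp <- kept[g$variants$position[j] - g$variants$position[kept] <= window]
      }
      cmp <- cmp[!is.na(sdz[cmp]) & sdz[cmp] > 0]
      drop <- FALSE
      if (length(cmp)) {
        r2 <- drop(crossprod(z[, cmp, drop = FALSE], z[, j]))^2
        drop <- any(r2 > r2_max)
      }
      if (!drop) { keep[j] <- TRUE; kept <- c(kept, j) }
    }
  }
  .subset_variants(g, which(keep))
}

#' Variant density in fixed-size blocks
#'
#' Counts variant records in non-overlapping blocks of `block_bp` base pairs
#' along each chromosome (block k covers `[(k-1)*block_bp + 1, k*block_bp]`).
#' Blocks with zero variants are reported as 0 up to the chromosome length
#' when one is supplied, otherwise up to the last variant.
#'
#' @param g A [genotype_data()].
#' @param block_bp Block size in bp, default 100 kb.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return A `windowed_stat` data frame (`chromosome, window_index, start_bp,
#'   end_bp, n_sites, value`) with `value` the per-block count.
#' @export
variant_density <- function(g, block_bp = 1e5, chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  if (block_bp <= 0) stop("block_bp must be > 0")
  chroms <- unique(g$variants$chromosome)
  if (!is.null(chrom_lengths)) chroms <- union(chroms, names(chrom_lengths))
  out <- lapply(chroms, function(ch) {
    p <- g$variants$position[g$variants$chromosome == ch]
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (length(p)) max(p) else block_bp
    nb <- ceiling(L / block_bp)
    counts <- tabulate(ceiling(p / block_bp), nbins = nb)
    data.frame(chromosome = ch, window_index = seq_len(nb),
               start_bp = (seq_len(nb) - 1) * block_bp + 1,
               end_bp = seq_len(nb) * block_bp,
               n_sites = counts, value = counts,
               partial = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  structure(out, statistic = "density",
            class = c("windowed_stat", "data.frame"))
}

#' @export
print.windowed_stat <- function(x, ...) {
  cat("windowed_stat (", attr(x, "statistic"), "): ", nrow(x),
      " windows on ", length(unique(x$chromosome)), " chromosome(s)\n",
      sep = "")
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}
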
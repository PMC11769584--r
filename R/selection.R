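## Windowed selection-signature statistics.  Windows slide in variant-site
## counts (not bp): window_sites per window, advancing by step_sites, per
## chromosome.  Trailing windows shorter than window_sites are reported with
## their true n_sites and marked partial; percentile ranking skips them.

.site_windows <- function(g, window_sites, step_sites) {
  if (window_sites < 1 || step_sites < 1)
    stop("window_sites and step_sites must be >= 1")
  chroms <- unique(g$variants$chromosome)
  out <- lapply(chroms, function(ch) {
    idx <- which(g$variants$chromosome == ch)
    m <- length(idx)
    starts <- seq(1, m, by = step_sites)
    ends <- pmin(starts + window_sites - 1, m)
    data.frame(chromosome = ch, window_index = seq_along(starts),
               start_site = idx[starts], end_site = idx[ends],
               start_bp = g$variants$position[idx[starts]],
               end_bp = g$variants$position[idx[ends]],
               n_sites = ends - starts + 1,
               partial = ends - starts + 1 < window_sites,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.window_mean <- function(frame, site_values) {
  vapply(seq_len(nrow(frame)), function(i)
    mean(site_values[frame$start_site[i]:frame$end_site[i]]), 0)
}

.resolve_subset <- function(g, samples) {
  if (is.null(samples)) return(seq_len(nrow(g$samples)))
  idx <- match(samples, g$samples$sample_id)
  if (anyNA(idx))
    stop("unknown sample id(s): ",
         paste(samples[is.na(idx)], collapse = ", "))
  idx
}

.as_windowed <- function(frame, value, statistic) {
  frame$value <- value
  frame <- frame[, c("chromosome", "window_index", "start_bp", "end_bp",
                     "n_sites", "value", "partial", "start_site",
                     "end_site")]
  structure(frame, statistic = statistic,
            class = c("windowed_stat", "data.frame"))
}

.check_same_frame <- function(a, b) {
  same <- identical(a$chromosome, b$chromosome) &&
    identical(a$start_bp, b$start_bp) &&
    identical(a$end_bp, b$end_bp) &&
    identical(a$n_sites, b$n_sites)
  if (!same) stop("window frames differ; build both tracks with the same ",
                  "window parameters on the same variant set")
}

#' Windowed nucleotide diversity
#'
#' Per site, the unbiased diversity estimate
#' `pi_site = (n / (n - 1)) * 2 p (1 - p)` with `n = 2 * n_samples` allele
#' copies and `p` the ALT frequency in the chosen sample subset; the window
#' value is the mean of `pi_site` over the window's sites.  This equals the
#' average pairwise difference per site among the `n` sampled allele copies.
#' Sites are those of the full variant table regardless of the subset, so
#' tracks for different subsets share one window frame.
#'
#' @param g A [genotype_data()].
#' @param samples Optional character vector of sample ids (default: all).
#' @param window_sites,step_sites Window and step size in variant sites
#'   (defaults 500 / 100).
#' @return A `windowed_stat` with statistic `"pi"`.
#' @export
nucleotide_diversity <- function(g, samples = NULL, window_sites = 500,
                                 step_sites = 100) {
  stopifnot(inherits(g, "genotype_data"))
  idx <- .resolve_subset(g, samples)
  if (length(idx) < 2) stop("need at least 2 samples")
  n <- 2 * length(idx)
  p <- colMeans(g$dosage[idx, , drop = FALSE]) / 2
  pi_site <- (n / (n - 1)) * 2 * p * (1 - p)
  frame <- .site_windows(g, window_sites, step_sites)
  .as_windowed(frame, .window_mean(frame, pi_site), "pi")
}

#' Reduction of diversity between a panel and a subpanel
#'
#' Per window, `ROD = pi_all / pi_sub`.  Windows where the subpanel
#' diversity is 0 are undefined (`NA`) and excluded from percentile ranking
#' — a division by zero carries no rank information.
#'
#' @param pi_all,pi_sub `windowed_stat` tracks of statistic `"pi"` built on
#'   identical window frames.
#' @return A `windowed_stat` with statistic `"ROD"`.
#' @export
rod <- function(pi_all, pi_sub) {
  .check_same_frame(pi_all, pi_sub)
  v <- ifelse(pi_sub$value > 0, pi_all$value / pi_sub$value, NA_real_)
  out <- pi_all
  out$value <- v
  attr(out, "statistic") <- "ROD"
  out
}

#' Windowed expected-minus-observed heterozygosity
#'
#' Per site, `H_site = H_exp - H_obs` with `H_exp = 2 p (1 - p)` (the
#' Hardy-Weinberg expectation at the subset allele frequency) and `H_obs`
#' the fraction of subset samples that are heterozygous; the window value is
#' the mean over sites.  Heterozygote excess therefore shows as negative
#' `H`.  Sites are the full panel's variant set for every subset, so tracks
#' are directly comparable.
#'
#' @inheritParams nucleotide_diversity
#' @return A `windowed_stat` with statistic `"H"`.
#' @export
heterozygosity_windows <- function(g, samples = NULL, window_sites = 500,
                                   step_sites = 100) {
  stopifnot(inherits(g, "genotype_data"))
  idx <- .resolve_subset(g, samples)
  if (length(idx) < 2) stop("need at least 2 samples")
  dos <- g$dosage[idx, , drop = FALSE]
  p <- colMeans(dos) / 2
  h_site <- 2 * p * (1 - p) - colMeans(dos == 1)
  frame <- .site_windows(g, window_sites, step_sites)
  .as_windowed(frame, .window_mean(frame, h_site), "H")
}

#' Heterozygosity-excess indicator between panel and subpanel
#'
#' Per window, `H_all - H_sub`.  Because heterozygote excess makes `H`
#' negative, large positive indicator values mark windows where the subpanel
#' shows excess heterozygosity relative to the full panel — the signature of
#' a donor segment kept heterozygous in recent hybrids.
#'
#' @param h_all,h_sub `windowed_stat` tracks of statistic `"H"` on identical
#'   frames.
#' @return A `windowed_stat` with statistic `"H_indicator"`.
#' @export
het_excess_indicator <- function(h_all, h_sub) {
  .check_same_frame(h_all, h_sub)
  out <- h_all
  out$value <- h_all$value - h_sub$value
  attr(out, "statistic") <- "H_indicator"
  out
}

#' Flag windows at or above an empirical percentile
#'
#' Computes the `q`-quantile of the window values (linear-interpolation
#' definition, `stats::quantile` type 7) over defined, full-size windows and
#' flags windows whose value is greater than or equal to it.  Ties at the
#' threshold are all flagged.  Partial trailing windows and undefined (`NA`)
#' windows never enter the quantile and are never flagged.
#'
#' @param stat A `windowed_stat`.
#' @param q Percentile in `[0, 1]`, default 0.95.
#' @return The input with a logical `flagged` column and a `threshold`
#'   attribute.
#' @export
percentile_flag <- function(stat, q = 0.95) {
  stopifnot(inherits(stat, "windowed_stat"))
  defined <- !is.na(stat$value) & !stat$partial
  if (sum(defined) < 20)
    stop("need at least 20 defined windows to rank (have ", sum(defined), ")")
  thr <- stats::quantile(stat$value[defined], probs = q, type = 7,
                         names = FALSE)
  stat$flagged <- defined & stat$value >= thr
  attr(stat, "threshold") <- thr
  stat
}

#' Linkage-disequilibrium decay curve
#'
#' Computes pairwise r-squared for all intra-chromosomal variant pairs up to
#' `max_dist_bp` apart, bins the pairs by distance and reports the mean
#' r-squared per bin.  `mode = "genotype"` uses the squared Pearson
#' correlation of ALT dosages; `mode = "haplotype"` uses
#' `r2 = D^2 / (p_A p_a p_B p_b)` from phased two-locus haplotype
#' frequencies (requires phased data).  Pairs with a monomorphic member are
#' skipped.  The half-decay distance is where the binned curve first drops
#' to half its maximum, linearly interpolated between bin midpoints.
#'
#' @param g A [genotype_data()]; apply [filter_maf()] first (LD summaries on
#'   rare variants are noise-dominated).
#' @param mode `"genotype"` or `"haplotype"`.
#' @param max_dist_bp Maximum pair distance, default 3 Mb.
#' @param bin_bp Distance bin width, default 10 kb.
#' @return An `ld_decay_curve`: `bins` data frame (`bin_start, bin_end,
#'   mean_r2, n_pairs`), `mode`, `max_r2`, `half_decay_bp`, `r2_at_half`.
#' @export
ld_decay <- function(g, mode = c("genotype", "haplotype"),
                     max_dist_bp = 3e6, bin_bp = 1e4) {
  stopifnot(inherits(g, "genotype_data"))
  mode <- match.arg(mode)
  if (mode == "haplotype" && (!g$phased || is.null(g$haplotypes)))
    stop("haplotype mode requires phased data")
  n_bins <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)

  if (mode == "genotype") {
    z <- scale(g$dosage)
    ok <- !is.na(attr(z, "scaled:scale")) & attr(z, "scaled:scale") > 0
    z <- z / sqrt(nrow(z) - 1)
  } else {
    hap <- g$haplotypes
    pa <- colMeans(hap)
    ok <- pa > 0 & pa < 1
  }

  for (ch in unique(g$variants$chromosome)) {
    idx <- which(g$variants$chromosome == ch & ok)
    if (length(idx) < 2) next
    pos <- g$variants$position[idx]
    for (i in seq_len(length(idx) - 1)) {
      j <- i + 1
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist_bp) j <- j + 1
      if (j == i + 1) next
      js <- (i + 1):(j - 1)
      if (mode == "genotype") {
        r2 <- drop(crossprod(z[, idx[js], drop = FALSE], z[, idx[i]]))^2
      } else {
        hi <- hap[, idx[i]]
        hj <- hap[, idx[js], drop = FALSE]
        p_i <- mean(hi)
        p_j <- colMeans(hj)
        p_ij <- colMeans(hj * hi)
        d <- p_ij - p_i * p_j
        r2 <- d^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
      }
      bins <- pmin(ceiling((pos[js] - pos[i]) / bin_bp), n_bins)
      bins[pos[js] - pos[i] <= 0] <- 1L
      for (bi in unique(bins)) {
        sel <- bins == bi
        sum_r2[bi] <- sum_r2[bi] + sum(r2[sel])
        n_pairs[bi] <- n_pairs[bi] + sum(sel)
      }
    }
  }
  mean_r2 <- ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_)
  bins <- data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_bp,
    bin_end = seq_len(n_bins) * bin_bp,
    mean_r2 = mean_r2, n_pairs = n_pairs)
  hd <- .half_decay(bins, bin_bp)
  structure(list(bins = bins, mode = mode,
                 max_r2 = hd$max_r2, half_decay_bp = hd$dist,
                 r2_at_half = hd$half),
            class = "ld_decay_curve")
}

.half_decay <- function(bins, bin_bp) {
  ok <- which(!is.na(bins$mean_r2))
  if (!length(ok)) return(list(max_r2 = NA_real_, dist = NA_real_,
                               half = NA_real_))
  r2 <- bins$mean_r2[ok]
  mid <- (bins$bin_start[ok] + bins$bin_end[ok]) / 2
  max_r2 <- max(r2)
  half <- max_r2 / 2
  below <- which(r2 <= half)
  below <- below[below > which.max(r2)]
  if (!length(below))
    return(list(max_r2 = max_r2, dist = NA_real_, half = half))
  k <- below[1]
  if (k == 1) return(list(max_r2 = max_r2, dist = mid[1], half = half))
  ## linear interpolation between the bracketing bin midpoints
  x0 <- mid[k - 1]; y0 <- r2[k - 1]
  x1 <- mid[k]; y1 <- r2[k]
  dist <- if (y0 == y1) x1 else x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
  list(max_r2 = max_r2, dist = dist, half = half)
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  cat("ld_decay_curve (", x$mode, "): max mean r2 = ",
      signif(x$max_r2, 3), ", half-decay at ",
      if (is.na(x$half_decay_bp)) "NA" else
        paste0(round(x$half_decay_bp / 1000, 1), " kb"),
      " (r2 = ", signif(x$r2_at_half, 3), ")\n", sep = "")
  invisible(x)
}
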
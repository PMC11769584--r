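#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' Centers ALT dosages by twice the panel allele frequency and scales by the
#' expected heterozygosity sum:
#' `A = W W' / (2 * sum(p * (1 - p)))` with `W[i,j] = x[i,j] - 2 p_j` and
#' `p_j` estimated from the panel itself.  Monomorphic sites are excluded
#' (they contribute nothing to `W` but would not inflate the denominator
#' either way); at least two polymorphic sites are required.
#'
#' @param g A [genotype_data()].
#' @param chromosome Optional chromosome label; default uses all variants.
#' @return A `kinship_matrix` object (fields `values`, `kind`, `sample_ids`,
#'   `chromosome`).
#' @export
additive_kinship <- function(g, chromosome = NULL) {
  x <- .kinship_dosage(g, chromosome)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("need at least 2 polymorphic sites",
         if (!is.null(chromosome)) paste0(" on ", chromosome))
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(x, 2, 2 * p)
  a <- tcrossprod(w) / (2 * sum(p * (1 - p)))
  .kinship_matrix(a, "additive", g$samples$sample_id, chromosome)
}

#' Dominance genomic relationship matrix (Vitezica parameterization)
#'
#' Codes genotypes `{0, 1, 2}` per site as
#' `{-2 p^2, 2 p q, -2 q^2}` (with `q = 1 - p`), the classical dominance
#' deviation coding, and scales the cross-product by `sum((2 p q)^2)`:
#' `D = H H' / sum((2 p q)^2)`.
#'
#' @inheritParams additive_kinship
#' @return A `kinship_matrix` of kind `"dominance"`.
#' @export
dominance_kinship <- function(g, chromosome = NULL) {
  x <- .kinship_dosage(g, chromosome)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("need at least 2 polymorphic sites",
         if (!is.null(chromosome)) paste0(" on ", chromosome))
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  h <- matrix(0, nrow(x), ncol(x))
  h[x == 0] <- (-2 * rep(p^2, each = nrow(x)))[x == 0]
  h[x == 1] <- (2 * rep(p * q, each = nrow(x)))[x == 1]
  h[x == 2] <- (-2 * rep(q^2, each = nrow(x)))[x == 2]
  d <- tcrossprod(h) / sum((2 * p * q)^2)
  .kinship_matrix(d, "dominance", g$samples$sample_id, chromosome)
}

.kinship_dosage <- function(g, chromosome) {
  stopifnot(inherits(g, "genotype_data"))
  if (is.null(chromosome)) return(g$dosage)
  sel <- g$variants$chromosome == chromosome
  if (!any(sel)) stop("no variants on chromosome ", chromosome)
  g$dosage[, sel, drop = FALSE]
}

.kinship_matrix <- function(values, kind, sample_ids, chromosome = NULL) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, kind = kind, sample_ids = sample_ids,
                 chromosome = chromosome),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", x$kind, "): ", length(x$sample_ids), " samples",
      if (!is.null(x$chromosome)) paste0(", chromosome ", x$chromosome),
      "\n", sep = "")
  invisible(x)
}

#' Chromosome-length-weighted integration of per-chromosome kinships
#'
#' Combines per-chromosome relationship matrices into a single genome-wide
#' matrix weighted by chromosome length:
#' `K = sum_c K_c * l_c` (and, by default, divided by `sum_c l_c` so the
#' weights form a convex combination).  Normalization is a pure rescaling:
#' principal components and GBLUP fits are invariant to a global positive
#' scaling of the kinship (the variance component absorbs it), so the
#' normalized form only keeps the matrix on the usual kinship scale; pass
#' `normalize = FALSE` for the literal weighted sum.
#'
#' @param matrices List of `kinship_matrix` objects in matching sample order.
#' @param lengths Numeric vector of chromosome lengths `l_c` (bp), one per
#'   matrix; all positive.
#' @param normalize Divide by `sum(lengths)` (default `TRUE`).
#' @return A `kinship_matrix` of kind `"integrated-<kind>"`.
#' @export
integrate_kinship <- function(matrices, lengths, normalize = TRUE) {
  if (!length(matrices)) stop("no matrices to integrate")
  if (length(lengths) != length(matrices))
    stop("need one length per matrix")
  if (any(lengths <= 0)) stop("chromosome lengths must all be > 0")
  ids <- matrices[[1]]$sample_ids
  for (k in matrices) {
    if (!inherits(k, "kinship_matrix")) stop("inputs must be kinship_matrix")
    if (!identical(k$sample_ids, ids))
      stop("sample order mismatch between kinship matrices")
  }
  w <- if (normalize) lengths / sum(lengths) else lengths
  acc <- matrix(0, length(ids), length(ids))
  for (i in seq_along(matrices)) acc <- acc + w[i] * matrices[[i]]$values
  kind <- paste0("integrated-", matrices[[1]]$kind)
  .kinship_matrix(acc, kind, ids)
}

#' Principal-component analysis of a kinship matrix
#'
#' Column-centers the kinship matrix and takes the top-`k` left singular
#' vectors scaled by their singular values — i.e. exactly what
#' `prcomp(K)` computes when the matrix itself is handed to a PCA, which is
#' the convention this analysis replicates (as opposed to an uncentered
#' eigendecomposition of `K`; the two differ and the choice is deliberate).
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so results are reproducible across BLAS backends.
#'
#' @param K A `kinship_matrix`.
#' @param k Number of components, `k <= n - 1`.
#' @return A `structure_scores` object: `scores` (n x k, rownames = sample
#'   ids) and `explained` (the k leading proportions of total variance,
#'   non-increasing).
#' @export
pca_structure <- function(K, k = 2) {
  stopifnot(inherits(K, "kinship_matrix"))
  n <- length(K$sample_ids)
  if (k >= n) stop("k must be <= n - 1")
  pc <- stats::prcomp(K$values, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  x <- pc$x
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; x[, j] <- -x[, j] }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- x[, seq_len(k), drop = FALSE]
  rownames(scores) <- K$sample_ids
  structure(list(scores = scores, explained = expl[seq_len(k)],
                 sample_ids = K$sample_ids),
            class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  cat("structure_scores:", nrow(x$scores), "samples x", ncol(x$scores),
      "components; explained:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
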
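## Mixed-model association scan:
##   y = S tau + X beta + a + e,  a ~ N(0, K sigma2_g),  e ~ N(0, I sigma2_e)
## The kinship is eigendecomposed once; rotating y, X and each marker by the
## eigenvectors makes the covariance diagonal, so the ML likelihood profiled
## over the variance ratio is cheap to maximize per variant.  Significance is
## an exact likelihood-ratio test against chi-square(1): both the null and
## the per-variant full model re-optimize the variance ratio.

## ML log-likelihood on the rotated scale at log-ratio lg.
## yt, Xt: rotated response/design; lam: kinship eigenvalues (clipped >= 0).
.ml_eval <- function(lg, yt, Xt, lam, details = FALSE) {
  n <- length(yt)
  w <- exp(lg) * lam + 1
  sw <- 1 / w
  A <- crossprod(Xt, Xt * sw)
  b <- tryCatch(solve(A, crossprod(Xt, yt * sw)),
                error = function(e) NULL)
  if (is.null(b)) return(if (details) NULL else -Inf)
  r <- yt - Xt %*% b
  rss <- sum(r^2 * sw)
  sig2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sig2) + sum(log(w)) + n)
  if (!details) return(ll)
  list(ll = ll, beta = drop(b), sigma2 = sig2, gamma = exp(lg))
}

.ml_profile <- function(yt, Xt, lam, grid = seq(-12, 12, length.out = 41)) {
  lls <- vapply(grid, function(g) .ml_eval(g, yt, Xt, lam), 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(g) .ml_eval(g, yt, Xt, lam),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (opt$objective < lls[i]) opt <- list(maximum = grid[i], objective = lls[i])
  .ml_eval(opt$maximum, yt, Xt, lam, details = TRUE)
}

#' Mixed-model GWAS with kinship and principal-component covariates
#'
#' Per-variant scan of `y = S tau + X beta + a + e` with
#' `a ~ N(0, K sigma2_g)`; `S` is the ALT-dosage column of the variant
#' (`{0, 1, 2} = {REF/REF, het, ALT/ALT}`), `X` an intercept plus optional
#' covariates (typically the first principal components of the integrated
#' additive kinship).  The variance ratio is re-optimized under each
#' per-variant full model as well as under the null, so the likelihood-ratio
#' statistic `2 (LL_full - LL_null)` is an exact ML LRT; p-values come from
#' chi-square with 1 degree of freedom.  Monomorphic variants are skipped
#' with a logged count; collinear covariates are an error.
#'
#' @param y Named numeric vector or `cultivar_values`.
#' @param g A [genotype_data()]; samples must cover `names(y)`.
#' @param covariates Optional `structure_scores` object or numeric matrix
#'   with rownames (sample ids); an intercept is always included.
#' @param K A `kinship_matrix` for the polygenic term.
#' @param reoptimize Re-estimate the variance ratio per variant (default
#'   `TRUE`, the exact test); `FALSE` holds it at the null optimum (faster,
#'   approximate).
#' @return An `association_result` data frame: one row per tested variant
#'   with `chromosome, position, ref, alt, beta, ll_full, ll_null, lrt, p,
#'   neglog10p`; attributes `n_skipped`, `covariates`, `kinship`.
#' @export
association_scan <- function(y, g, covariates = NULL, K, reoptimize = TRUE) {
  y <- .as_pheno_vector(y)
  stopifnot(inherits(g, "genotype_data"), inherits(K, "kinship_matrix"))
  ids <- names(y)
  if (!all(ids %in% g$samples$sample_id))
    stop("phenotyped sample(s) absent from genotypes")
  if (!all(ids %in% K$sample_ids))
    stop("phenotyped sample(s) absent from kinship")
  dos <- g$dosage[ids, , drop = FALSE]
  Kv <- K$values[ids, ids, drop = FALSE]

  X <- matrix(1, length(ids), 1)
  cov_label <- "intercept"
  if (!is.null(covariates)) {
    cm <- if (inherits(covariates, "structure_scores")) covariates$scores
          else covariates
    if (is.null(rownames(cm))) stop("covariates need sample rownames")
    if (!all(ids %in% rownames(cm)))
      stop("phenotyped sample(s) absent from covariates")
    X <- cbind(X, cm[ids, , drop = FALSE])
    cov_label <- paste("intercept +", ncol(cm), "covariate(s)")
  }
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")

  eg <- eigen(Kv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  St <- crossprod(U, dos)

  null <- .ml_profile(yt, Xt, lam)
  p_alt <- colMeans(dos) / 2
  test <- which(p_alt > 0 & p_alt < 1)
  n_skipped <- ncol(dos) - length(test)
  if (n_skipped > 0)
    message("association_scan: skipped ", n_skipped,
            " monomorphic variant(s)")

  res <- matrix(NA_real_, length(test), 3,
                dimnames = list(NULL, c("beta", "ll_full", "lrt")))
  for (i in seq_along(test)) {
    Xs <- cbind(Xt, St[, test[i]])
    full <- if (reoptimize) .ml_profile(yt, Xs, lam)
            else .ml_eval(log(null$gamma), yt, Xs, lam, details = TRUE)
    if (is.null(full)) next
    res[i, "beta"] <- full$beta[length(full$beta)]
    res[i, "ll_full"] <- full$ll
    res[i, "lrt"] <- max(0, 2 * (full$ll - null$ll))
  }
  pval <- stats::pchisq(res[, "lrt"], df = 1, lower.tail = FALSE)
  out <- data.frame(
    chromosome = g$variants$chromosome[test],
    position = g$variants$position[test],
    ref = g$variants$ref[test],
    alt = g$variants$alt[test],
    beta = res[, "beta"],
    ll_full = res[, "ll_full"],
    ll_null = null$ll,
    lrt = res[, "lrt"],
    p = pval,
    neglog10p = -log10(pval),
    stringsAsFactors = FALSE)
  structure(out, n_skipped = n_skipped, covariates = cov_label,
            kinship = K$kind, null_gamma = null$gamma,
            class = c("association_result", "data.frame"))
}

#' False-discovery-rate threshold for a p-value vector
#'
#' `method = "bh"` applies the Benjamini-Hochberg step-up rule: the
#' threshold is the largest sorted p-value satisfying
#' `p_(i) <= q * i / m`, and the significant set is `p <= threshold`.
#' `method = "storey"` computes q-values with the fixed-lambda estimate
#' `pi0 = min(1, mean(p > 0.5) / 0.5)` and flags q-values at or below `q`.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param q FDR level, default 0.05.
#' @param method `"bh"` (default) or `"storey"`.
#' @return An `fdr_decision`: `q`, `method`, `threshold` (p-value scale),
#'   `significant` (logical, aligned to input), and `pi0` for Storey.
#' @export
fdr_threshold <- function(pvalues, q = 0.05, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  pi0 <- NA_real_
  if (method == "bh") {
    adj <- stats::p.adjust(pvalues, method = "BH")
    sig <- adj <= q
  } else {
    lambda <- 0.5
    pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
    o <- order(pvalues)
    qv <- pi0 * m * pvalues[o] / seq_len(m)
    qv <- rev(cummin(rev(qv)))
    qvals <- numeric(m)
    qvals[o] <- pmin(qv, 1)
    sig <- qvals <= q
  }
  threshold <- if (any(sig)) max(pvalues[sig]) else 0
  structure(list(q = q, method = method, threshold = threshold,
                 significant = sig, n_significant = sum(sig), pi0 = pi0),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat("fdr_decision (", x$method, ", q = ", x$q, "): ",
      x$n_significant, " significant, p-threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Raw phenotype means by genotype class at one variant
#'
#' Reports the empirical effect of a variant as phenotype means of the
#' homozygote classes with the REF/REF class anchored to 0, i.e. the ALT/ALT
#' entry is the raw mean difference `mean(ALT/ALT) - mean(REF/REF)`.  A
#' class with no members is reported as `NA`.
#'
#' @param g A [genotype_data()].
#' @param y Named numeric vector or `cultivar_values`.
#' @param variant Variant index, or id matching `g$variants$id`.
#' @return Named numeric vector
#'   `c(effect_ref_ref = 0, effect_alt_alt = ...)` (NA when undefined).
#' @export
empirical_effect_summary <- function(g, y, variant) {
  y <- .as_pheno_vector(y)
  stopifnot(inherits(g, "genotype_data"))
  if (is.character(variant)) {
    variant <- match(variant, g$variants$id)
    if (is.na(variant)) stop("unknown variant id")
  }
  if (variant < 1 || variant > nrow(g$variants)) stop("variant out of range")
  dos <- g$dosage[names(y), variant]
  m0 <- if (any(dos == 0)) mean(y[dos == 0]) else NA_real_
  m2 <- if (any(dos == 2)) mean(y[dos == 2]) else NA_real_
  c(effect_ref_ref = if (is.na(m0)) NA_real_ else 0,
    effect_alt_alt = m2 - m0)
}
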
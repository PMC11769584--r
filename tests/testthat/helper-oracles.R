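# Independent oracles.  Each one recomputes a quantity by a route the
# implementation does not share: brute-force enumeration, dense unrotated
# likelihoods, or direct textbook arithmetic.

# Mean pairwise difference per site among all haplotype pairs, averaged over
# the sites of one window.  Direct enumeration over C(n_hap, 2) pairs.
pi_pairwise_oracle <- function(haps, sites) {
  nh <- nrow(haps)
  pairs <- utils::combn(nh, 2)
  diff_per_site <- vapply(seq_len(ncol(pairs)), function(k) {
    mean(haps[pairs[1, k], sites] != haps[pairs[2, k], sites])
  }, 0)
  mean(diff_per_site)
}

# SNP-BLUP (ridge regression on markers) via Henderson's marker-level mixed
# model equations: solve [[1'1, 1'W], [W'1, W'W + lambda I]].
snp_blup_fitted <- function(y, W, lambda) {
  n <- length(y); m <- ncol(W)
  C <- rbind(cbind(n, t(colSums(W))),
             cbind(colSums(W), crossprod(W) + lambda * diag(m)))
  rhs <- c(sum(y), crossprod(W, y))
  sol <- solve(C, rhs)
  drop(sol[1] + W %*% sol[-1])
}

# ML log-likelihood of y = X b + a + e, a ~ N(0, K g s2), e ~ N(0, I s2),
# computed densely on the unrotated scale (chol of V = g K + I per
# evaluation), maximized over log(g) by grid + local refinement.
ml_dense_oracle <- function(y, X, K) {
  n <- length(y)
  ll_at <- function(lg) {
    V <- exp(lg) * K + diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    b <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% b
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    s2 <- drop(crossprod(r, Vi_r)) / n
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(cV))) + n)
  }
  grid <- seq(-12, 12, length.out = 41)
  lls <- vapply(grid, ll_at, 0)
  i <- which.max(lls)
  opt <- stats::optimize(ll_at, c(grid[max(1, i - 1)],
                                  grid[min(length(grid), i + 1)]),
                         maximum = TRUE, tol = 1e-8)
  max(opt$objective, lls[i])
}

# -log10 p of the mixed-model LRT for one marker, everything dense/unrotated.
gwas_dense_oracle <- function(y, X, K, s) {
  ll0 <- ml_dense_oracle(y, X, K)
  ll1 <- ml_dense_oracle(y, cbind(X, s), K)
  lrt <- max(0, 2 * (ll1 - ll0))
  -log10(stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

# REML criterion for the phenotype LMM
#   value ~ cultivar (fixed) + (1|season) + (1|season:year),
# evaluated densely at given variance components; used to check that the
# fitted optimum beats a grid.  Constant terms dropped consistently.
lmm_reml_criterion <- function(value, cultivar, season, sy,
                               v_season, v_sy, v_resid) {
  X <- stats::model.matrix(~ 0 + factor(cultivar))
  Zs <- stats::model.matrix(~ 0 + factor(season))
  Zy <- stats::model.matrix(~ 0 + factor(sy))
  n <- length(value); p <- ncol(X)
  V <- v_resid * diag(n) + v_season * tcrossprod(Zs) + v_sy * tcrossprod(Zy)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), value))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(X, Vi_y))
  r <- value - X %*% b
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  -0.5 * (2 * sum(log(diag(cV))) +
            determinant(XtViX, logarithm = TRUE)$modulus +
            drop(crossprod(r, Vi_r)))
}

# haplotype-based r2 from first principles: two-locus haplotype frequencies
hap_r2_oracle <- function(hapA, hapB) {
  pA <- mean(hapA); pB <- mean(hapB)
  pAB <- mean(hapA * hapB)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
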
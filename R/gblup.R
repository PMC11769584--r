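## GBLUP genomic prediction: kernel mixed models
##   y = 1*mu + sum_k u_k + e,  u_k ~ N(0, K_k sigma2_k),  e ~ N(0, I sigma2_e)
## REML path profiles the residual variance out and optimizes the variance
## ratios gamma_k = sigma2_k / sigma2_e; the Gibbs path samples the same
## model with scaled-inverse-chi-square priors.

## REML log-likelihood (up to an additive constant) at given log-ratios.
## Returns the likelihood plus the GLS pieces needed for BLUP at the optimum.
.reml_eval <- function(loggam, y, X, Ks, details = FALSE) {
  n <- length(y)
  p <- ncol(X)
  H <- diag(n)
  for (k in seq_along(Ks)) H <- H + exp(loggam[k]) * Ks[[k]]
  cH <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(cH)) return(if (details) NULL else -Inf)
  logdetH <- 2 * sum(log(diag(cH)))
  HiX <- backsolve(cH, forwardsolve(t(cH), X))
  Hiy <- backsolve(cH, forwardsolve(t(cH), y))
  XtHiX <- crossprod(X, HiX)
  beta <- solve(XtHiX, crossprod(X, Hiy))
  r <- y - X %*% beta
  Hir <- backsolve(cH, forwardsolve(t(cH), r))
  quad <- drop(crossprod(r, Hir))
  if (quad <= 0) return(if (details) NULL else -Inf)
  s2 <- quad / (n - p)
  ll <- -0.5 * ((n - p) * log(s2) + logdetH +
                  determinant(XtHiX, logarithm = TRUE)$modulus + (n - p))
  if (!details) return(as.numeric(ll))
  list(ll = as.numeric(ll), beta = drop(beta), sigma2_e = s2,
       Hir = drop(Hir), gammas = exp(loggam))
}

## Maximize REML over log-ratio(s): coarse grid then local refinement.
.reml_optimize <- function(y, X, Ks) {
  nk <- length(Ks)
  if (nk == 1) {
    grid <- seq(-10, 10, by = 0.5)
    lls <- vapply(grid, function(g) .reml_eval(g, y, X, Ks), 0)
    best <- grid[which.max(lls)]
    opt <- stats::optimize(function(g) .reml_eval(g, y, X, Ks),
                           interval = c(best - 0.5, best + 0.5),
                           maximum = TRUE, tol = 1e-10)
    loggam <- opt$maximum
  } else {
    starts <- as.matrix(expand.grid(rep(list(c(-6, -2, 0, 2)), nk)))
    lls <- apply(starts, 1, function(g) .reml_eval(g, y, X, Ks))
    s0 <- starts[which.max(lls), ]
    opt <- stats::optim(s0, function(g) .reml_eval(g, y, X, Ks),
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = 1e-12,
                                       maxit = 2000))
    loggam <- opt$par
  }
  .reml_eval(loggam, y, X, Ks, details = TRUE)
}

#' Fit a GBLUP model with one or more kinship kernels
#'
#' Fits `y = mu + sum_k u_k + e` with `u_k ~ N(0, K_k sigma2_k)`.  The
#' phenotype may cover only a subset of the kernel samples; random effects
#' are predicted for every kernel sample, so unphenotyped cultivars get
#' genomic predictions through their kinship with the phenotyped block.
#'
#' The default REML path estimates variance components by profile REML over
#' the variance ratios (grid search plus local refinement) and predicts the
#' random effects from Henderson's mixed-model equations.  The Gibbs path
#' samples the same model with scaled-inverse-chi-square priors
#' (`df0 = 5`, prior R-squared 0.5 split equally across kernels) and reports
#' posterior means; both paths return the same result shape.
#'
#' @param y Named numeric vector of per-cultivar values, or a
#'   `cultivar_values` object.  Names must be kernel sample ids.
#' @param kernels A `kinship_matrix` or (optionally named) list of them, all
#'   in identical sample order.
#' @param method `"reml"` (default) or `"gibbs"`.
#' @param n_iter,burn_in,thin Gibbs sampler controls (defaults 15000 / 5000
#'   / 5).
#' @param check_psd Verify each kernel is PSD up to `-1e-6` before fitting.
#' @return A `gblup_model`: `mu`, `varcomp` (per kernel + `residual`),
#'   `u` (matrix of predicted random effects, all kernel samples by kernels),
#'   `fitted` (phenotyped samples), `obs_ids`, `sample_ids`, `loglik`,
#'   `method`.
#' @export
fit_gblup <- function(y, kernels, method = c("reml", "gibbs"),
                      n_iter = 15000, burn_in = 5000, thin = 5,
                      check_psd = TRUE) {
  method <- match.arg(method)
  y <- .as_pheno_vector(y)
  if (inherits(kernels, "kinship_matrix")) kernels <- list(kernels)
  if (!length(kernels)) stop("need at least one kernel")
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- vapply(kernels, function(k) k$kind, "")
  ids <- kernels[[1]]$sample_ids
  for (k in kernels) {
    if (!inherits(k, "kinship_matrix")) stop("kernels must be kinship_matrix")
    if (!identical(k$sample_ids, ids))
      stop("kernels must share one sample order")
  }
  if (check_psd) {
    for (nm in names(kernels)) {
      ev <- eigen(kernels[[nm]]$values, symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev) < -1e-6)
        stop("kernel '", nm, "' is not positive semi-definite (min eigenvalue ",
             signif(min(ev), 3), ")")
    }
  }
  obs <- intersect(ids, names(y))
  if (!length(obs)) stop("no phenotyped samples match the kernel samples")
  unknown <- setdiff(names(y), ids)
  if (length(unknown))
    stop("phenotyped sample(s) absent from kernels: ",
         paste(unknown, collapse = ", "))
  yv <- y[obs]
  oi <- match(obs, ids)
  Ks_obs <- lapply(kernels, function(k) k$values[oi, oi, drop = FALSE])
  X <- matrix(1, length(obs), 1)

  if (method == "reml") {
    fit <- .reml_optimize(yv, X, Ks_obs)
    if (is.null(fit)) stop("REML optimization failed")
    sigma2 <- fit$gammas * fit$sigma2_e
    u <- vapply(seq_along(kernels), function(k)
      fit$gammas[k] * drop(kernels[[k]]$values[, oi, drop = FALSE] %*% fit$Hir),
      numeric(length(ids)))
    mu <- fit$beta[1]
    loglik <- fit$ll
  } else {
    gb <- .gblup_gibbs(yv, Ks_obs, n_iter, burn_in, thin)
    sigma2 <- gb$sigma2_k
    ## plug-in BLUP at posterior-mean variances for all-sample predictions
    gammas <- sigma2 / gb$sigma2_e
    H <- diag(length(obs))
    for (k in seq_along(Ks_obs)) H <- H + gammas[k] * Ks_obs[[k]]
    Hir <- solve(H, yv - gb$mu)
    u <- vapply(seq_along(kernels), function(k)
      gammas[k] * drop(kernels[[k]]$values[, oi, drop = FALSE] %*% Hir),
      numeric(length(ids)))
    ## on phenotyped samples, keep the sampler's own posterior means
    u[oi, ] <- gb$u_obs
    mu <- gb$mu
    loglik <- NA_real_
  }
  dimnames(u) <- list(ids, names(kernels))
  varcomp <- c(stats::setNames(sigma2, names(kernels)),
               residual = if (method == "reml") fit$sigma2_e else gb$sigma2_e)
  fitted <- mu + rowSums(u[oi, , drop = FALSE])
  names(fitted) <- obs
  structure(list(mu = mu, varcomp = varcomp, u = u, fitted = fitted,
                 obs_ids = obs, sample_ids = ids, y = yv,
                 loglik = loglik, method = method),
            class = "gblup_model")
}

## Gibbs sampler on the eigenbasis of each kernel: u_k = U_k alpha_k with
## prior alpha_kj ~ N(0, lambda_kj sigma2_k); conditionals are diagonal.
.gblup_gibbs <- function(yv, Ks_obs, n_iter, burn_in, thin,
                         df0 = 5, R2 = 0.5) {
  n <- length(yv)
  nk <- length(Ks_obs)
  eig <- lapply(Ks_obs, function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > 1e-10 * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], lam = e$values[keep])
  })
  vy <- stats::var(yv)
  S_e <- vy * (1 - R2) * (df0 + 2)
  S_k <- vy * (R2 / nk) * (df0 + 2)
  mu <- mean(yv)
  alpha <- lapply(eig, function(e) numeric(length(e$lam)))
  u <- matrix(0, n, nk)
  sigma2_k <- rep(vy * R2 / nk, nk)
  sigma2_e <- vy * (1 - R2)
  keep_it <- seq(burn_in + 1, n_iter, by = thin)
  acc_mu <- 0; acc_u <- matrix(0, n, nk)
  acc_s2k <- numeric(nk); acc_s2e <- 0
  for (it in seq_len(n_iter)) {
    resid0 <- yv - rowSums(u)
    mu <- stats::rnorm(1, mean(resid0), sqrt(sigma2_e / n))
    for (k in seq_len(nk)) {
      ytil <- yv - mu - rowSums(u[, -k, drop = FALSE])
      z <- crossprod(eig[[k]]$U, ytil)
      prec <- 1 / sigma2_e + 1 / (eig[[k]]$lam * sigma2_k[k])
      mean_a <- drop(z) / (sigma2_e * prec)
      alpha[[k]] <- stats::rnorm(length(prec), mean_a, sqrt(1 / prec))
      u[, k] <- eig[[k]]$U %*% alpha[[k]]
      ss <- sum(alpha[[k]]^2 / eig[[k]]$lam)
      sigma2_k[k] <- (ss + df0 * S_k) /
        stats::rchisq(1, df0 + length(alpha[[k]]))
    }
    ee <- yv - mu - rowSums(u)
    sigma2_e <- (sum(ee^2) + df0 * S_e) / stats::rchisq(1, df0 + n)
    if (it %in% keep_it) {
      acc_mu <- acc_mu + mu
      acc_u <- acc_u + u
      acc_s2k <- acc_s2k + sigma2_k
      acc_s2e <- acc_s2e + sigma2_e
    }
  }
  nkeep <- length(keep_it)
  list(mu = acc_mu / nkeep, u_obs = acc_u / nkeep,
       sigma2_k = acc_s2k / nkeep, sigma2_e = acc_s2e / nkeep)
}

#' @export
print.gblup_model <- function(x, ...) {
  cat("gblup_model (", x$method, "): ", length(x$obs_ids), " phenotyped / ",
      length(x$sample_ids), " total samples\n  mu = ", signif(x$mu, 4),
      "; variance components: ",
      paste(sprintf("%s=%.4g", names(x$varcomp), x$varcomp),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Genomic estimated breeding values from a fitted GBLUP model
#'
#' `GEBV_i = mu + sum_k u_k[i]`, defined for every sample in the kernels,
#' including unphenotyped ones (their random effects are predicted through
#' the kinship with the phenotyped block).
#'
#' @param model A `gblup_model`.
#' @param target_samples Character vector of sample ids; default all kernel
#'   samples.  Unknown ids are an error.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, target_samples = NULL) {
  stopifnot(inherits(model, "gblup_model"))
  if (is.null(target_samples)) target_samples <- model$sample_ids
  unknown <- setdiff(target_samples, model$sample_ids)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  gebv <- model$mu + rowSums(model$u[target_samples, , drop = FALSE])
  names(gebv) <- target_samples
  gebv
}

#' Replicated k-fold cross-validation of GBLUP model accuracy
#'
#' For each replicate, samples are split into balanced random folds (seeded;
#' the identical fold assignment is reused for every model specification, so
#' model comparisons share folds).  Each fold is predicted from a model
#' fitted to the remaining folds; accuracy is the Pearson correlation between
#' predicted and observed values pooled over all held-out samples of the
#' replicate.  Replicates with constant predictions are recorded as
#' undefined and excluded with a logged count.
#'
#' @param y Named numeric vector or `cultivar_values`.
#' @param kernels Named list of `kinship_matrix` objects.
#' @param models Named list; each element a character vector of kernel names
#'   making up one model.  Default: nested models adding one kernel at a
#'   time (`additive`, then `additive + dominance`, ...).
#' @param n_folds Folds per replicate (default 2).
#' @param n_replicates Number of replicates (default 100).
#' @param seed Integer seed for the fold assignments.
#' @return A `cv_result`: `summary` data frame (`model, accuracy_mean,
#'   accuracy_sd, n_replicates, n_excluded`) plus the per-replicate accuracy
#'   matrix and fold assignments as attributes.
#' @export
cross_validate <- function(y, kernels, models = NULL, n_folds = 2,
                           n_replicates = 100, seed = 1L) {
  y <- .as_pheno_vector(y)
  if (inherits(kernels, "kinship_matrix")) kernels <- list(kernels)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- vapply(kernels, function(k) k$kind, "")
  if (is.null(models)) {
    models <- lapply(seq_along(kernels), function(k) names(kernels)[1:k])
    names(models) <- vapply(models, paste, "", collapse = "+")
  }
  ids <- kernels[[1]]$sample_ids
  obs <- intersect(ids, names(y))
  if (length(obs) < 2 * n_folds)
    stop("need at least ", 2 * n_folds, " phenotyped samples")
  for (nm in names(kernels)) {
    ev <- eigen(kernels[[nm]]$values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) stop("kernel '", nm, "' is not PSD")
  }
  yv <- y[obs]
  folds <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(r)
      sample(rep_len(seq_len(n_folds), length(obs))), integer(length(obs)))
  })
  acc <- matrix(NA_real_, n_replicates, length(models),
                dimnames = list(NULL, names(models)))
  for (r in seq_len(n_replicates)) {
    fold <- folds[, r]
    for (mi in seq_along(models)) {
      kern <- kernels[models[[mi]]]
      pred <- rep(NA_real_, length(obs))
      for (f in seq_len(n_folds)) {
        train <- fold != f
        fit <- fit_gblup(yv[train], kern, check_psd = FALSE)
        pred[!train] <- predict_gebv(fit, obs[!train])
      }
      if (stats::sd(pred) > 0)
        acc[r, mi] <- stats::cor(pred, yv)
    }
  }
  n_excl <- colSums(is.na(acc))
  if (any(n_excl > 0))
    message("cross_validate: ", sum(n_excl),
            " replicate(s) with undefined accuracy excluded")
  summary <- data.frame(
    model = names(models),
    accuracy_mean = colMeans(acc, na.rm = TRUE),
    accuracy_sd = apply(acc, 2, stats::sd, na.rm = TRUE),
    n_replicates = n_replicates,
    n_excluded = n_excl,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, accuracy = acc, folds = folds,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", nrow(x$accuracy), " replicates):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
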
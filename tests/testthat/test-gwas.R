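test_that("scan p-values match a brute-force dense ML oracle", {
  withr::with_seed(1, {
    n <- 40; m <- 12
    p <- runif(m, 0.2, 0.5)
    dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
    Kdos <- matrix(rbinom(n * 150, 2, 0.4), n)
    y <- setNames(0.6 * scale(dos[, 3])[, 1] + rnorm(n),
                  sprintf("s%03d", 1:n))
  })
  gd <- make_gd(dos)
  K <- additive_kinship(make_gd(Kdos))
  scan <- association_scan(y, gd, K = K)
  X <- matrix(1, n, 1)
  Kv <- K$values[names(y), names(y)]
  for (j in seq_len(nrow(scan))) {
    oracle <- gwas_dense_oracle(unname(y), X, Kv, dos[, j])
    expect_lt(abs(scan$neglog10p[j] - oracle), 1e-3)
  }
  expect_true(all(scan$lrt >= 0))
  expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("identity kinship reduces to ordinary regression LRT", {
  withr::with_seed(2, {
    n <- 60
    dos <- matrix(rbinom(n * 8, 2, 0.4), n)
    y <- setNames(rnorm(n), sprintf("s%03d", 1:n))
  })
  gd <- make_gd(dos)
  I_k <- structure(list(values = diag(n), kind = "identity",
                        sample_ids = names(y), chromosome = NULL),
                   class = "kinship_matrix")
  dimnames(I_k$values) <- list(names(y), names(y))
  scan <- association_scan(y, gd, K = I_k)
  for (j in seq_len(ncol(dos))) {
    rss0 <- sum(lm(y ~ 1)$residuals^2)
    rss1 <- sum(lm(y ~ dos[, j])$residuals^2)
    lrt <- n * log(rss0 / rss1)
    p_ols <- pchisq(lrt, 1, lower.tail = FALSE)
    expect_equal(scan$p[j], p_ols, tolerance = 1e-6)
  }
})

test_that("location shifts of the phenotype change no p-value", {
  withr::with_seed(3, {
    dos <- matrix(rbinom(50 * 10, 2, 0.4), 50)
    y <- setNames(rnorm(50), sprintf("s%03d", 1:50))
  })
  gd <- make_gd(dos)
  K <- additive_kinship(random_gd(50, 200, seed = 4))
  K$sample_ids <- names(y)
  dimnames(K$values) <- list(names(y), names(y))
  s1 <- association_scan(y, gd, K = K)
  s2 <- association_scan(y + 1000, gd, K = K)
  expect_equal(s1$p, s2$p, tolerance = 1e-6)
})

test_that("monomorphic variants are skipped and collinear covariates rejected", {
  withr::with_seed(5, {
    dos <- cbind(matrix(rbinom(30 * 5, 2, 0.4), 30), 0L)
    y <- setNames(rnorm(30), sprintf("s%03d", 1:30))
  })
  gd <- make_gd(dos)
  K <- additive_kinship(random_gd(30, 100, seed = 6))
  dimnames(K$values) <- list(names(y), names(y))
  K$sample_ids <- names(y)
  expect_message(scan <- association_scan(y, gd, K = K), "monomorphic")
  expect_equal(nrow(scan), 5)
  bad_cov <- matrix(1, 30, 1, dimnames = list(names(y), "const"))
  expect_error(association_scan(y, gd, covariates = bad_cov, K = K),
               "collinear")
})

test_that("a planted QTL tops the scan and permutation flattens it", {
  tops <- vapply(1:10, function(s) {
    gd <- simulate_panel(small_panel_config(seed = 400 + s,
                                            n_cultivars = 150,
                                            n_variants = 170))
    gdf <- filter_maf(gd, 0.05)
    m <- nrow(gdf$variants)
    qtl <- floor(m / 2)
    tc <- trait_config(qtl_placement = data.frame(
      chromosome = gdf$variants$chromosome[qtl],
      position_bp = gdf$variants$position[qtl],
      additive_effect = 1),
      season_var = 0, season_year_var = 0, residual_var = 0)
    ph <- simulate_phenotypes(gdf, tc, n_seasons = 1, n_years = 1,
                              seed = s)
    g_true <- attr(ph, "truth")$genetic
    # residual variance three times the genetic variance: ~25% explained
    y <- setNames(g_true + withr::with_seed(s, rnorm(length(g_true),
                                                     0, sqrt(3 * var(g_true)))),
                  ph$sample_id)
    chroms <- unique(gdf$variants$chromosome)
    lens <- vapply(chroms, function(ch)
      max(gdf$variants$position[gdf$variants$chromosome == ch]), 0)
    K <- integrate_kinship(lapply(chroms, function(ch)
      additive_kinship(gdf, ch)), lens)
    scan <- association_scan(y, gdf, K = K)
    hit <- which.min(scan$p)
    scan$position[hit] == gdf$variants$position[qtl] &&
      scan$chromosome[hit] == gdf$variants$chromosome[qtl]
  }, TRUE)
  expect_gte(sum(tops), 6)  # median over seeds: QTL is the top signal

  # permuting the phenotype destroys the signal: p-values uniform (KS)
  gd <- simulate_panel(small_panel_config(seed = 777, n_cultivars = 100,
                                          n_variants = 200))
  gdf <- filter_maf(gd, 0.05)
  K <- additive_kinship(gdf)
  y <- withr::with_seed(778,
    setNames(rnorm(100)[sample(100)], gdf$samples$sample_id))
  scan <- association_scan(y, gdf, K = K)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("PC covariates reduce genomic inflation on a structured panel", {
  gd <- simulate_panel(small_panel_config(seed = 31, n_cultivars = 120,
                                          n_variants = 250))
  gdf <- filter_maf(gd, 0.05)
  chroms <- unique(gdf$variants$chromosome)
  lens <- vapply(chroms, function(ch)
    max(gdf$variants$position[gdf$variants$chromosome == ch]), 0)
  K <- integrate_kinship(lapply(chroms, function(ch)
    additive_kinship(gdf, ch)), lens)
  pcs <- pca_structure(K, 2)
  # phenotype aligned with the panel's year structure (no single QTL)
  y <- setNames(scale(gdf$samples$release_year)[, 1] +
                  withr::with_seed(32, rnorm(120, 0, 0.5)),
                gdf$samples$sample_id)
  ident <- structure(list(values = diag(120), kind = "identity",
                          sample_ids = names(y), chromosome = NULL),
                     class = "kinship_matrix")
  dimnames(ident$values) <- list(names(y), names(y))
  lambda_gc <- function(scan)
    median(scan$lrt) / qchisq(0.5, 1)
  s_without <- association_scan(y, gdf, K = ident)
  s_with <- association_scan(y, gdf, covariates = pcs, K = ident)
  expect_lt(lambda_gc(s_with), lambda_gc(s_without))
})

test_that("FDR thresholds reproduce hand arithmetic and stay null-calibrated", {
  d <- fdr_threshold(c(0.001, 0.2, 0.9), q = 0.05, method = "bh")
  expect_equal(d$significant, c(TRUE, FALSE, FALSE))
  expect_equal(d$threshold, 0.001)
  # threshold reproduces the set
  expect_equal(d$significant, c(0.001, 0.2, 0.9) <= d$threshold)
  # determinism on a duplicated vector
  d2 <- fdr_threshold(c(0.001, 0.2, 0.9), q = 0.05, method = "bh")
  expect_identical(d$significant, d2$significant)
  # uniform null: essentially nothing significant
  exceed <- vapply(1:20, function(s) {
    p <- withr::with_seed(s, runif(1000))
    fdr_threshold(p, 0.05, "bh")$n_significant
  }, 0)
  expect_gte(sum(exceed <= 3), 19)
  # storey path: pi0 near 1 under the null, decisions sane
  p <- withr::with_seed(99, runif(500))
  ds <- fdr_threshold(p, 0.05, "storey")
  expect_gt(ds$pi0, 0.8)
  expect_lte(ds$n_significant, 3)
  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.1, 0)), "must lie")
})

test_that("empirical effect summaries anchor REF/REF at zero", {
  dos <- matrix(c(0, 0, 1, 1, 2, 2), 6, 1)
  gd <- make_gd(dos)
  ids <- gd$samples$sample_id
  expect_equal(empirical_effect_summary(gd, setNames(rep(5, 6), ids), 1),
               c(effect_ref_ref = 0, effect_alt_alt = 0))
  expect_equal(empirical_effect_summary(gd, setNames(dos[, 1], ids), 1),
               c(effect_ref_ref = 0, effect_alt_alt = 2))
  # random fixture vs direct group means
  y <- withr::with_seed(7, setNames(rnorm(6), ids))
  got <- empirical_effect_summary(gd, y, 1)
  expect_equal(got[["effect_alt_alt"]],
               mean(y[dos[, 1] == 2]) - mean(y[dos[, 1] == 0]))
  # empty class is undefined
  dos2 <- matrix(c(0, 0, 1, 1, 1, 1), 6, 1)
  got2 <- empirical_effect_summary(make_gd(dos2), y, 1)
  expect_true(is.na(got2[["effect_alt_alt"]]))
})
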
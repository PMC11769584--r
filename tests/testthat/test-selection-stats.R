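test_that("windowed pi equals brute-force mean pairwise haplotype difference", {
  withr::with_seed(1, {
    haps <- matrix(rbinom(8 * 600, 1, runif(600, 0.05, 0.95)),
                   nrow = 8, byrow = FALSE)
  })
  gd <- make_gd_phased(haps)
  pw <- nucleotide_diversity(gd, window_sites = 100, step_sites = 50)
  for (i in seq_len(nrow(pw))) {
    sites <- pw$start_site[i]:pw$end_site[i]
    expect_equal(pw$value[i], pi_pairwise_oracle(haps, sites),
                 tolerance = 1e-12)
  }
  # direct arithmetic: one site, p = 0.5, 20 allele copies
  dos10 <- matrix(c(rep(0, 5), rep(2, 5), rep(1, 10)), 10, 2)
  g10 <- make_gd(dos10)
  pi1 <- nucleotide_diversity(g10, window_sites = 1, step_sites = 1)
  expect_equal(pi1$value[1], (20 / 19) * 0.5)
  # monomorphic windows are exactly zero; theoretical per-site maximum
  gmono <- make_gd(matrix(0, 4, 30))
  expect_true(all(nucleotide_diversity(gmono, window_sites = 10,
                                       step_sites = 5)$value == 0))
  expect_true(all(pw$value <= 0.5 * 16 / 15 + 1e-12))
  expect_error(nucleotide_diversity(gd, samples = "s001"), "at least 2")
})

test_that("pi is invariant to REF/ALT label swaps", {
  g <- random_gd(20, 100, seed = 2)
  p1 <- nucleotide_diversity(g, window_sites = 20, step_sites = 20)
  g2 <- g
  g2$dosage[, 1:50] <- 2 - g2$dosage[, 1:50]
  p2 <- nucleotide_diversity(g2, window_sites = 20, step_sites = 20)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("ROD divides tracks windowwise and flags undefined windows", {
  g <- random_gd(30, 200, seed = 3)
  pa <- nucleotide_diversity(g, window_sites = 50, step_sites = 25)
  expect_true(all(rod(pa, pa)$value == 1))
  ps <- pa; ps$value <- pa$value / 4
  expect_equal(rod(pa, ps)$value, rep(4, nrow(pa)))
  pz <- pa; pz$value[2] <- 0
  r <- rod(pa, pz)
  expect_true(is.na(r$value[2]))
  # frame mismatch is an error
  pb <- nucleotide_diversity(g, window_sites = 40, step_sites = 25)
  expect_error(rod(pa, pb), "frames differ")
})

test_that("H windows measure expected-minus-observed heterozygosity", {
  # exact HWE at p = 0.5: counts 1/4, 1/2, 1/4 -> H = 0
  dhwe <- matrix(rep(c(0, 1, 1, 2), 3), 4, 3)
  ghwe <- make_gd(dhwe)
  h <- heterozygosity_windows(ghwe, window_sites = 3, step_sites = 3)
  expect_equal(h$value[1], 0)
  # all samples heterozygous: H = 0.5 - 1 = -0.5 per site
  dhet <- matrix(1, 6, 4)
  h2 <- heterozygosity_windows(make_gd(dhet), window_sites = 4,
                               step_sites = 4)
  expect_equal(h2$value[1], -0.5)
  # brute-force per-site oracle on a random fixture
  g <- random_gd(25, 60, seed = 4)
  h3 <- heterozygosity_windows(g, window_sites = 60, step_sites = 60)
  p <- colMeans(g$dosage) / 2
  oracle <- mean(2 * p * (1 - p) - colMeans(g$dosage == 1))
  expect_equal(h3$value[1], oracle, tolerance = 1e-12)
  # REF/ALT swap invariance
  g2 <- g; g2$dosage <- 2 - g2$dosage
  h4 <- heterozygosity_windows(g2, window_sites = 60, step_sites = 60)
  expect_equal(h4$value, h3$value, tolerance = 1e-12)
})

test_that("the heterozygosity-excess indicator subtracts tracks windowwise", {
  g <- random_gd(30, 100, seed = 5)
  ha <- heterozygosity_windows(g, window_sites = 25, step_sites = 25)
  expect_true(all(het_excess_indicator(ha, ha)$value == 0))
  hb <- ha; hb$value <- ha$value - 0.21
  expect_equal(het_excess_indicator(ha, hb)$value,
               rep(0.21, nrow(ha)), tolerance = 1e-12)
})

test_that("percentile flagging follows the interpolated quantile definition", {
  ws <- structure(
    data.frame(chromosome = "chr01", window_index = 1:100,
               start_bp = 1:100, end_bp = 2:101, n_sites = 10,
               value = as.numeric(1:100), partial = FALSE,
               start_site = 1:100, end_site = 1:100),
    statistic = "test", class = c("windowed_stat", "data.frame"))
  fl <- percentile_flag(ws, 0.95)
  expect_equal(attr(fl, "threshold"), 95.05)
  expect_equal(sum(fl$flagged), 5)
  expect_equal(which(fl$flagged), 96:100)
  # ties at the threshold: >= rule flags the whole constant track
  wc <- ws; wc$value <- rep(7, 100)
  expect_true(all(percentile_flag(wc, 0.95)$flagged))
  expect_true(all(percentile_flag(ws, 0)$flagged))
  # partial and NA windows never flagged, never ranked
  wp <- ws
  wp$partial[1:50] <- TRUE
  wp$value[51] <- NA
  fl2 <- percentile_flag(wp, 0.5)
  expect_true(all(!fl2$flagged[1:51]))
  expect_error(percentile_flag(ws[1:10, ], 0.95), "at least 20")
})

test_that("LD decay r2 matches hand-computed worked cases in both modes", {
  # perfect LD: duplicated column gives r2 = 1 in both modes
  withr::with_seed(6, {
    haps <- matrix(rbinom(20 * 2, 1, 0.5), 20, 2)
    haps[, 2] <- haps[, 1]
  })
  gdup <- make_gd_phased(haps, positions = c(1000, 21000))
  for (mode in c("genotype", "haplotype")) {
    cur <- ld_decay(gdup, mode, max_dist_bp = 1e5, bin_bp = 1e5)
    expect_equal(cur$bins$mean_r2[1], 1, tolerance = 1e-12)
  }
  # printed 4-haplotype case AB, AB, aB, ab: r2 = 1/3 exactly
  h4 <- rbind(c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  g4 <- make_gd_phased(h4, positions = c(100, 200))
  cur4 <- ld_decay(g4, "haplotype", max_dist_bp = 1000, bin_bp = 1000)
  expect_equal(cur4$bins$mean_r2[1], 1 / 3, tolerance = 1e-12)
  expect_equal(hap_r2_oracle(h4[, 1], h4[, 2]), 1 / 3)
  # haplotype mode refuses unphased data
  expect_error(ld_decay(make_gd(matrix(0:2, 3, 4)), "haplotype"),
               "phased")
})

test_that("independent sites decay to the 1/n sampling floor", {
  g <- random_gd(100, 150, seed = 7)
  g <- filter_maf(g, 0.05)
  cur <- ld_decay(g, "genotype", max_dist_bp = 2e5, bin_bp = 2e5)
  # all pairs independent: mean r2 ~ 1/n
  expect_lt(abs(cur$bins$mean_r2[1] - 0.01), 0.005)
})

test_that("genotype and haplotype r2 coincide on fully homozygous panels", {
  withr::with_seed(8, {
    hap_lines <- matrix(rbinom(15 * 40, 1, 0.5), 15, 40)
    haps <- hap_lines[rep(1:15, each = 2), ]   # doubled: fully homozygous
  })
  g <- make_gd_phased(haps)
  cg <- ld_decay(g, "genotype", max_dist_bp = 4e4, bin_bp = 1e3)
  ch <- ld_decay(g, "haplotype", max_dist_bp = 4e4, bin_bp = 1e3)
  expect_equal(cg$bins$mean_r2, ch$bins$mean_r2, tolerance = 1e-9)
})

test_that("half-decay distance interpolates the binned curve", {
  bins <- data.frame(bin_start = c(0, 1000, 2000),
                     bin_end = c(1000, 2000, 3000),
                     mean_r2 = c(0.8, 0.6, 0.2), n_pairs = 10)
  hd <- cultivarpopgen:::.half_decay(bins, 1000)
  # half of max 0.8 is 0.4, crossed between midpoints 1500 and 2500
  expect_equal(hd$half, 0.4)
  expect_equal(hd$dist, 1500 + (0.6 - 0.4) / (0.6 - 0.2) * 1000)
})

test_that("pi and H windows built from one parameter set share a frame", {
  g <- random_gd(20, 300, seed = 9)
  sub <- g$samples$sample_id[1:10]
  pa <- nucleotide_diversity(g, NULL, 50, 20)
  hs <- heterozygosity_windows(g, sub, 50, 20)
  expect_identical(pa[, c("chromosome", "start_bp", "end_bp", "n_sites")],
                   hs[, c("chromosome", "start_bp", "end_bp", "n_sites")])
})
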
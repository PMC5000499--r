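test_that("chromosome tiling follows the sliding-window rule", {
  sp <- window_spec(100000, 10000)
  t1 <- tile_windows(c(chrA = 250000), sp)
  expect_equal(sum(t1$end - t1$start == 100000), 16L)  # full windows
  expect_equal(t1$start, seq(0L, 150000L, by = 10000L))

  ## non-divisible remainder: one final truncated window
  t2 <- tile_windows(c(chrA = 255000), sp)
  expect_equal(nrow(t2), 17L)
  expect_equal(t2[nrow(t2), c(start, end)], c(160000L, 255000L))

  ## chromosome shorter than one window
  t3 <- tile_windows(c(chrA = 50000), sp)
  expect_equal(nrow(t3), 1L)
  expect_equal(c(t3$start, t3$end), c(0L, 50000L))

  ## step = size degenerates to a non-overlapping tiling
  sp2 <- window_spec(100000, 100000)
  for (len in c(250000, 300000, 100000, 99999)) {
    expect_equal(nrow(tile_windows(c(c1 = len), sp2)),
                 max(1, ceiling(len / 100000)))
  }
})

test_that("pooled heterozygosity matches its closed form", {
  expect_equal(hp_pooled(50, 50), 0.5)   # symmetric maximum
  expect_equal(hp_pooled(70, 0), 0)      # fixed window
  expect_equal(hp_pooled(60, 40), 0.48)
  expect_true(is.na(hp_pooled(0, 0)))
  ## always within [0, 0.5]
  set.seed(1)
  a <- rpois(200, 40); b <- rpois(200, 15)
  h <- hp_pooled(a + 1, b)
  expect_true(all(h >= 0 & h <= 0.5))

  st <- sites_from_counts(c(10L, 20L), cbind(c(40L, 20L), c(25L, 15L), 0L, 0L),
                          cbind(c(10L, 10L), c(0L, 0L), 0L, 0L))
  wh <- window_hp(st, "P1")
  expect_equal(wh$sum_nmaj, 60L)
  expect_equal(wh$sum_nmin, 40L)
  expect_equal(wh$hp, 0.48)
})

test_that("window FST reproduces hand-derived single-site cases", {
  ## identical pools: no differentiation under either denominator
  same <- sites_from_counts(c(10L, 20L, 30L),
                            cbind(c(10L, 6L, 3L), c(10L, 6L, 9L), 0L, 0L),
                            cbind(c(5L, 3L, 2L), c(5L, 3L, 6L), 0L, 0L))
  expect_equal(window_fst(same, "within"), 0)
  expect_equal(window_fst(same, "total"), 0)

  ## pop1 fixed A, pop2 half A half T:
  ## pi1 = 0, pi2 = 0.5, pi_within = 0.25, pi_total = 0.375
  ws <- sites_from_counts(100L, matrix(c(12L, 0L, 0L, 0L), 1),
                          matrix(c(6L, 0L, 0L, 6L), 1))
  expect_equal(window_fst(ws, "within"), 0.5)
  expect_equal(window_fst(ws, "total"), 1 / 3)

  ## fixed different alleles: pi_within = 0, excluded; window unevaluable
  fd <- sites_from_counts(100L, matrix(c(12L, 0L, 0L, 0L), 1),
                          matrix(c(0L, 0L, 0L, 6L), 1))
  expect_true(is.na(window_fst(fd, "within")))
  expect_equal(window_fst(fd, "total"), 1)  # total denominator is positive
})

test_that("the Z-transform standardises exactly and is affine-invariant", {
  zt <- ztransform(c(1, 2, 3))
  expect_equal(zt$z, c(-1, 0, 1) * sqrt(3 / 2))  # population sd
  expect_equal(zt$mean, 2)

  set.seed(42)
  for (i in 1:100) {
    x <- rnorm(sample(5:200, 1), mean = runif(1, -5, 5), sd = runif(1, .1, 9))
    z <- ztransform(x)$z
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
    a <- runif(1, 0.1, 4); b <- runif(1, -10, 10)
    expect_equal(ztransform(a * x + b)$z, z)
  }
  ## already standardised input is untouched
  x <- c(-1, 0, 1) / sqrt(2 / 3)
  expect_equal(ztransform(x)$z, x)
  expect_error(ztransform(rep(2, 10), name = "hp"), "hp.*constant")
  expect_error(ztransform(3), "at least 2")
})

test_that("a site joins every window containing it", {
  ## 0-based position 105000 with 100k/10k windows: starts 10k..100k
  ## (a second, different site far away keeps the statistics non-constant)
  st <- sites_from_counts(c(105001L, 500001L),
                          cbind(c(20L, 9L), c(5L, 9L), 0L, 0L),
                          cbind(c(15L, 2L), c(5L, 16L), 0L, 0L))
  sc <- scan_windows(st, window_spec(min_snps = 1),
                     chrom_lengths = c(chr1 = 1e6))
  expect_equal(sc$windows[start <= 110000, start],
               seq(10000L, 100000L, by = 10000L))
  expect_equal(sc$windows[start > 110000, start],
               seq(410000L, 500000L, by = 10000L))
  expect_true(all(sc$windows$n_snps == 1L))
})

test_that("streamed scan equals the naive per-window oracle", {
  cfg <- sim_config(seed = 31, n_chrom = 1L, chrom_length = 200000L,
                    n_sites = 800L, n_sweeps = 1L, sweep_length = 40000L)
  d <- withr::local_tempdir()
  paths <- write_simulation(simulate_sweep_data(cfg), d)
  pm <- read_population_map(paths[["popmap"]])
  sites <- apply_filters(stream_site_counts(paths[["vcf"]], pm))$sites
  lens <- c(chr1 = 200000)
  for (den in c("within", "total")) {
    sc <- scan_windows(sites, window_spec(20000, 4000, min_snps = 1),
                       denominator = den, chrom_lengths = lens)
    orc <- oracle_window_stats(sites, window_spec(20000, 4000, min_snps = 1),
                               1, den, lens)
    m <- merge(sc$windows, orc, by = c("chrom", "start", "end"),
               suffixes = c("", ".orc"))
    expect_equal(nrow(m), nrow(sc$windows))
    expect_equal(m$n_snps, m$n_snps.orc)
    expect_equal(m$hp, m$hp.orc, tolerance = 1e-12)
    expect_equal(m$fst, m$fst.orc, tolerance = 1e-12)
  }
})

test_that("Z-scores have mean 0 and sd 1 over evaluated windows", {
  st <- random_sites(2000, seed = 12, span = 300000)
  sc <- scan_windows(apply_filters(st)$sites, window_spec(30000, 10000, 10),
                     chrom_lengths = c(chr1 = 300000))
  z <- sc$windows$zhp[!is.na(sc$windows$zhp)]
  expect_gt(length(z), 2)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  zf <- sc$windows$zfst[!is.na(sc$windows$zfst)]
  expect_lt(abs(mean(zf)), 1e-9)
  ## windows below min_snps carry no Z-score
  expect_true(all(is.na(sc$windows[n_snps < 10, zhp])))
})

test_that("shrinking the step only adds windows, preserving shared ones", {
  st <- random_sites(1000, seed = 8, span = 250000)
  sites <- apply_filters(st)$sites
  lens <- c(chr1 = 250000)
  coarse <- scan_windows(sites, window_spec(50000, 50000, 5),
                         chrom_lengths = lens)$windows
  fine <- scan_windows(sites, window_spec(50000, 10000, 5),
                       chrom_lengths = lens)$windows
  m <- merge(coarse, fine, by = c("chrom", "start", "end"),
             suffixes = c(".c", ".f"))
  expect_equal(nrow(m), nrow(coarse))
  expect_gt(nrow(fine), nrow(coarse))
  expect_equal(m$hp.c, m$hp.f)
  expect_equal(m$fst.c, m$fst.f)
  expect_equal(m$n_snps.c, m$n_snps.f)
})

test_that("window tables round-trip with their metadata header", {
  st <- random_sites(500, seed = 4, span = 100000)
  sc <- scan_windows(apply_filters(st)$sites, window_spec(20000, 5000, 5),
                     chrom_lengths = c(chr1 = 100000))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_window_table(sc, f)
  back <- read_window_table(f)
  expect_equal(as.data.frame(back), as.data.frame(sc$windows),
               ignore_attr = "metadata")
  meta <- attr(back, "metadata")
  expect_equal(meta$fst_denominator, "within")
  expect_equal(as.numeric(meta$mean_hp), sc$summary$mean_hp)
})
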
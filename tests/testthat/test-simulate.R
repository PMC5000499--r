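test_that("the seed fully determines the simulation outputs", {
  cfg <- sim_config(seed = 19, n_chrom = 1L, chrom_length = 80000L,
                    n_sites = 120L, low_mq_rate = 0.05,
                    n_sweeps = 1L, sweep_length = 20000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_sweep_data(cfg), d1)
  p2 <- write_simulation(simulate_sweep_data(cfg), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file:", f))
  }
  ## a different seed changes the data
  p3 <- write_simulation(simulate_sweep_data(sim_config(seed = 20,
                                                        n_chrom = 1L,
                                                        chrom_length = 80000L,
                                                        n_sites = 120L,
                                                        n_sweeps = 1L,
                                                        sweep_length = 20000L)),
                         withr::local_tempdir())
  expect_false(identical(readLines(p1[["vcf"]]), readLines(p3[["vcf"]])))
})

test_that("sweep intervals show elevated population differentiation", {
  cfg <- sim_config(seed = 3, n_chrom = 1L, chrom_length = 500000L,
                    n_sites = 3000L, n_sweeps = 2L, sweep_length = 100000L)
  fr <- simulate_frequencies(cfg)
  gap_in <- fr[in_sweep == TRUE, mean(abs(p1 - p2))]
  gap_out <- fr[in_sweep == FALSE, mean(abs(p1 - p2))]
  expect_gt(gap_in, gap_out)
  pv <- wilcox.test(fr[in_sweep == TRUE, abs(p1 - p2)],
                    fr[in_sweep == FALSE, abs(p1 - p2)],
                    alternative = "greater")$p.value
  expect_lt(pv, 1e-6)
  ## swept sites sit at the residual-frequency boundary
  expect_true(all(fr[swept == TRUE, p1] %in%
                    c(cfg$residual_maf, 1 - cfg$residual_maf)))
  ## sweep_strength = 0 leaves every site untouched
  fr0 <- simulate_frequencies(sim_config(seed = 3, n_chrom = 1L,
                                         chrom_length = 500000L,
                                         n_sites = 3000L,
                                         sweep_strength = 0))
  expect_false(any(fr0$swept))
})

test_that("weak drift keeps both populations near the ancestral frequency", {
  cfg <- sim_config(seed = 8, n_chrom = 1L, chrom_length = 300000L,
                    n_sites = 2000L, drift_f = 0.001, n_sweeps = 0L,
                    sweep_intervals = data.table(chrom = character(0),
                                                 start = integer(0),
                                                 end = integer(0)))
  fr <- simulate_frequencies(cfg)
  expect_lt(mean(abs(fr$p1 - fr$p_anc)), 0.02)
  expect_lt(mean(abs(fr$p1 - fr$p2)), 0.03)
})

test_that("genotypes and reads follow the stated sampling model", {
  ## fixed site, no error: every genotype 1/1, every read alt
  cfg <- sim_config(seed = 4, n_chrom = 1L, chrom_length = 10000L,
                    n_sites = 50L, error_rate = 0, sweep_strength = 0,
                    n_sweeps = 1L, sweep_length = 2000L,
                    n_genes = 3L, gene_length = 2000L)
  fr <- simulate_frequencies(cfg)
  fr[, `:=`(p1 = 1, p2 = 1)]
  r <- simulate_genotypes_and_reads(fr, cfg)
  for (k in 1:2) {
    g <- r$pools[[k]]$geno
    expect_true(all(g[!is.na(g)] == 2L))
    expect_true(all(r$pools[[k]]$ad_ref == 0L))
    expect_true(all(r$pools[[k]]$ad_alt == r$pools[[k]]$dp))
  }

  ## zero depth means every call is missing
  cfg0 <- sim_config(seed = 4, n_chrom = 1L, chrom_length = 10000L,
                     n_sites = 20L, mean_depth = 0,
                     n_sweeps = 1L, sweep_length = 2000L,
                     n_genes = 3L, gene_length = 2000L)
  r0 <- simulate_genotypes_and_reads(simulate_frequencies(cfg0), cfg0)
  expect_true(all(is.na(r0$pools[[1]]$geno)))
  expect_true(all(r0$pools[[1]]$dp == 0L))
})

test_that("pooled read frequencies track the true allele frequencies", {
  cfg <- sim_config(seed = 13, n_chrom = 1L, chrom_length = 200000L,
                    n_sites = 1000L, sweep_strength = 0)
  fr <- simulate_frequencies(cfg)
  r <- simulate_genotypes_and_reads(fr, cfg)
  alt <- rowSums(r$pools[[1]]$ad_alt)
  tot <- alt + rowSums(r$pools[[1]]$ad_ref)
  ok <- tot > 0
  phat <- alt[ok] / tot[ok]
  p <- fr$p1[ok]
  ## analytic envelope: genotype sampling (2n chromosomes) plus read
  ## sampling at the pooled depth, plus the error-rate bias bound
  n_chrom_pool <- 2 * cfg$pool_sizes[1]
  sigma <- sqrt(p * (1 - p) * (1 / n_chrom_pool + 1 / tot[ok]))
  expect_lt(mean(abs(phat - p)), mean(sigma) + cfg$error_rate)
})

test_that("simulated VCFs round-trip through the variant reader", {
  cfg <- sim_config(seed = 23, n_chrom = 2L, chrom_length = 50000L,
                    n_sites = 80L, n_sweeps = 1L, sweep_length = 10000L)
  d <- withr::local_tempdir()
  paths <- write_simulation(simulate_sweep_data(cfg), d)
  pm <- read_population_map(paths[["popmap"]])
  st <- stream_site_counts(paths[["vcf"]], pm)
  expect_equal(nrow(st), 160L)  # zero record loss
  expect_identical(attr(st, "pool_labels"), cfg$pool_labels)

  ## genotype-mode pool counts equal a direct tally of the truth genotypes
  sim <- simulate_sweep_data(cfg)
  stg <- stream_site_counts(paths[["vcf"]], pm, count_source = "genotype")
  g1 <- sim$reads$pools[[1]]$geno
  called <- rowSums(!is.na(g1))
  alt_copies <- rowSums(g1, na.rm = TRUE)
  ref_copies <- 2L * called - alt_copies
  expect_equal(stg$nmaj_1, as.integer(pmax(ref_copies, alt_copies)))
  expect_equal(stg$nmin_1, as.integer(pmin(ref_copies, alt_copies)))

  ## an empty simulation still writes a parseable header-only VCF
  cfg0 <- sim_config(seed = 2, n_chrom = 1L, chrom_length = 5000L,
                     n_sites = 0L, n_sweeps = 1L, sweep_length = 1000L,
                     n_genes = 2L, gene_length = 1000L)
  d0 <- withr::local_tempdir()
  p0 <- write_simulation(simulate_sweep_data(cfg0), d0)
  expect_true(all(startsWith(readLines(p0[["vcf"]]), "#")))
})

test_that("stronger drift raises genome-wide window FST", {
  means <- vapply(c(0.02, 0.08, 0.25), function(F) {
    cfg <- sim_config(seed = 50, n_chrom = 1L, chrom_length = 200000L,
                      n_sites = 1200L, drift_f = F, sweep_strength = 0)
    d <- withr::local_tempdir()
    paths <- write_simulation(simulate_sweep_data(cfg), d)
    pm <- read_population_map(paths[["popmap"]])
    sites <- apply_filters(stream_site_counts(paths[["vcf"]], pm))$sites
    sc <- scan_windows(sites, window_spec(40000, 20000, 5),
                       chrom_lengths = c(chr1 = 200000))
    mean(sc$windows$fst, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the toy annotation always places a gene inside a sweep", {
  for (seed in c(1, 6, 14)) {
    cfg <- sim_config(seed = seed, n_chrom = 1L, chrom_length = 300000L,
                      n_sites = 10L, n_genes = 5L, n_sweeps = 1L,
                      sweep_length = 50000L, gene_length = 5000L)
    sim <- simulate_sweep_data(cfg)
    expect_gt(length(sim$truth$genes_in_sweeps), 0)
    sw <- sim$truth$sweep_intervals
    g <- sim$genes[name %in% sim$truth$genes_in_sweeps]
    hit <- any(vapply(seq_len(nrow(g)), function(i)
      any(sw$chrom == g$chrom[i] & sw$start < g$end[i] & sw$end > g$start[i]),
      logical(1)))
    expect_true(hit)
  }
})
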
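library(data.table)

## Build a site table from explicit per-pool nucleotide count matrices
## (columns A, C, G, T). Major/minor, depths and totals derive from them.
sites_from_counts <- function(pos, nuc1, nuc2, chrom = "chr1",
                              mq = 60, total_depth = NULL,
                              nmiss1 = 0L, nmiss2 = 0L,
                              pool_labels = c("P1", "P2"),
                              pool_sizes = c(8L, 6L),
                              count_source = "allele-depth") {
  nuc1 <- matrix(as.integer(nuc1), ncol = 4)
  nuc2 <- matrix(as.integer(nuc2), ncol = 4)
  n <- length(pos)
  top2 <- function(m) {
    t(apply(m, 1, function(r) {
      o <- order(-r, seq_along(r))
      r[o[1:2]]
    }))
  }
  mm1 <- top2(nuc1); mm2 <- top2(nuc2)
  if (is.null(total_depth)) total_depth <- rowSums(nuc1) + rowSums(nuc2)
  dt <- data.table(
    chrom = rep(chrom, length.out = n), pos = as.integer(pos),
    rms_mq = rep(mq, length.out = n),
    total_depth = as.integer(total_depth),
    nA_1 = nuc1[, 1], nC_1 = nuc1[, 2], nG_1 = nuc1[, 3], nT_1 = nuc1[, 4],
    nmaj_1 = as.integer(mm1[, 1]), nmin_1 = as.integer(mm1[, 2]),
    depth_1 = as.integer(rowSums(nuc1)),
    nmiss_1 = rep(as.integer(nmiss1), length.out = n),
    nA_2 = nuc2[, 1], nC_2 = nuc2[, 2], nG_2 = nuc2[, 3], nT_2 = nuc2[, 4],
    nmaj_2 = as.integer(mm2[, 1]), nmin_2 = as.integer(mm2[, 2]),
    depth_2 = as.integer(rowSums(nuc2)),
    nmiss_2 = rep(as.integer(nmiss2), length.out = n)
  )
  site_table(dt, pool_labels, pool_sizes, count_source)
}

## Random site table for property tests: biallelic A/C counts, occasional
## close position pairs, quality fields spanning the filter thresholds.
random_sites <- function(n, seed, chrom = "chr1", span = 50 * n) {
  set.seed(seed)
  pos <- sort(sample.int(span, n))
  nuc1 <- cbind(rpois(n, 20), rpois(n, 6), 0L, 0L)
  nuc2 <- cbind(rpois(n, 15), rpois(n, 5), 0L, 0L)
  sites_from_counts(
    pos, nuc1, nuc2, chrom = chrom,
    mq = sample(c(10, 19, 20, 60), n, replace = TRUE,
                prob = c(.05, .05, .1, .8)),
    total_depth = sample(c(2:5, 30:60, 1200), n, replace = TRUE),
    nmiss1 = sample(0:8, n, replace = TRUE, prob = c(.6, rep(.05, 8))),
    nmiss2 = sample(0:6, n, replace = TRUE, prob = c(.7, rep(.05, 6)))
  )
}

## Write a small VCF from parallel vectors; body rows given verbatim.
write_test_vcf <- function(path, samples, rows,
                           contigs = c(chr1 = 1e6),
                           format = "GT:AD:DP") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"rms mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

## ---- independent oracles -------------------------------------------------

## Exhaustive filter oracle: evaluates every predicate per site with plain
## base-R logic; adjacency from the full input map, per chromosome.
oracle_filter <- function(sites, cfg) {
  dt <- as.data.table(sites)
  sz <- attr(sites, "pool_sizes")
  n <- nrow(dt)
  too_close <- logical(n)
  for (cn in unique(dt$chrom)) {
    idx <- which(dt$chrom == cn)
    p <- dt$pos[idx]
    for (i in seq_along(idx)) {
      too_close[idx[i]] <- any(abs(p[-i] - p[i]) < cfg$min_adjacent_gap)
    }
  }
  keep <- !is.na(dt$rms_mq) & dt$rms_mq >= cfg$min_rms_mq &
    dt$total_depth >= cfg$min_depth & dt$total_depth <= cfg$max_depth &
    (dt$nmiss_1 / sz[1]) < cfg$max_missing_rate &
    (dt$nmiss_2 / sz[2]) < cfg$max_missing_rate &
    !too_close
  dt[keep]
}

## Naive per-window recomputation of hp and fst: per-site diversity terms
## from the raw count columns, then an explicit loop over windows that
## re-subsets the sites each time.
oracle_window_stats <- function(sites, spec, focal_idx, denominator,
                                chrom_lengths) {
  dt <- as.data.table(sites)
  tiles <- tile_windows(chrom_lengths, spec)
  c1 <- as.matrix(dt[, .(nA_1, nC_1, nG_1, nT_1)])
  c2 <- as.matrix(dt[, .(nA_2, nC_2, nG_2, nT_2)])
  t1 <- rowSums(c1); t2 <- rowSums(c2)
  f1 <- c1 / t1; f2 <- c2 / t2
  pw <- ((1 - rowSums(f1^2)) + (1 - rowSums(f2^2))) / 2
  pt <- 1 - rowSums(((f1 + f2) / 2)^2)
  pw[t1 == 0 | t2 == 0] <- NA_real_
  pt[t1 == 0 | t2 == 0] <- NA_real_
  nmaj <- dt[[paste0("nmaj_", focal_idx)]]
  nmin <- dt[[paste0("nmin_", focal_idx)]]
  out <- list()
  for (i in seq_len(nrow(tiles))) {
    w <- tiles[i]
    in_w <- which(dt$chrom == w$chrom & (dt$pos - 1L) >= w$start &
                    (dt$pos - 1L) < w$end)
    if (!length(in_w)) next
    smaj <- sum(nmaj[in_w]); smin <- sum(nmin[in_w])
    hp <- if (smaj + smin > 0) 2 * smaj * smin / (smaj + smin)^2 else NA_real_
    wpw <- pw[in_w]; wpt <- pt[in_w]
    dsite <- if (denominator == "within") wpw else wpt
    use <- !is.na(wpw) & !is.na(wpt) & dsite > 0
    fst <- if (any(use)) {
      md <- if (denominator == "within") mean(wpw[use]) else mean(wpt[use])
      (mean(wpt[use]) - mean(wpw[use])) / md
    } else NA_real_
    out[[length(out) + 1L]] <- data.table(
      chrom = w$chrom, start = w$start, end = w$end,
      n_snps = length(in_w), hp = hp, fst = fst
    )
  }
  rbindlist(out)
}

## Type-7 quantile computed from first principles (sort + interpolate).
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  h <- 1 + (length(xs) - 1) * p
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}
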
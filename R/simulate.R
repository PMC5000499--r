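#' Configuration of the synthetic two-population sweep experiment
#'
#' The simulator emulates the data a pooled-resequencing sweep scan
#' consumes: two populations drifted apart from shared ancestral allele
#' frequencies under the Balding-Nichols model, a subset of genomic
#' intervals carrying hard sweeps (near-fixation in population 1, giving
#' low Hp and high FST there), per-individual read counts at finite depth
#' with sequencing error, and a toy gene annotation overlapping some sweep
#' intervals. Every random draw flows from `seed`.
#'
#' Defaults mirror a desk-scale version of a two-breed resequencing
#' contrast: 8 + 6 diploid individuals, moderate drift (F = 0.05), three
#' planted 150-kb sweeps across two 1-Mb chromosomes, 10x mean individual
#' depth and a 1 percent per-read error rate.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_sites SNP sites per chromosome.
#' @param pool_sizes integer(2), diploid individuals per pool.
#' @param pool_labels character(2) pool labels (pool 1 is the selected,
#'   focal population).
#' @param drift_f Balding-Nichols differentiation parameter in (0,1).
#' @param sweep_intervals optional data.frame (chrom, start, end; 0-based
#'   half-open) of sweep intervals; when NULL, `n_sweeps` intervals of
#'   `sweep_length` bp are placed uniformly without overlap.
#' @param n_sweeps,sweep_length auto-placement parameters.
#' @param sweep_strength probability that a site inside a sweep interval is
#'   driven to near-fixation in population 1.
#' @param residual_maf allele-frequency floor at swept sites.
#' @param mean_depth mean reads per individual per site (Poisson).
#' @param error_rate per-read miscall probability.
#' @param n_genes,gene_length toy annotation parameters.
#' @param mq_value simulated RMS mapping quality written to INFO/MQ.
#' @param low_mq_rate fraction of sites given `low_mq_value` instead, so the
#'   mapping-quality filter is exercised.
#' @param low_mq_value the low mapping-quality value.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chrom = 2L, chrom_length = 1e6, n_sites = 5000L,
                       pool_sizes = c(8L, 6L),
                       pool_labels = c("YNLC", "RJF"),
                       drift_f = 0.05,
                       sweep_intervals = NULL,
                       n_sweeps = 3L, sweep_length = 150000L,
                       sweep_strength = 0.9, residual_maf = 0.02,
                       mean_depth = 10, error_rate = 0.01,
                       n_genes = 40L, gene_length = 20000L,
                       mq_value = 60, low_mq_rate = 0, low_mq_value = 10) {
  if (missing(seed) || is.null(seed)) stop("sim_config: 'seed' is mandatory")
  stopifnot(drift_f > 0, drift_f < 1,
            sweep_strength >= 0, sweep_strength <= 1,
            residual_maf > 0, residual_maf < 0.5,
            error_rate >= 0, error_rate < 0.5,
            mean_depth >= 0, length(pool_sizes) == 2L,
            length(pool_labels) == 2L, n_chrom >= 1, n_sites >= 0,
            gene_length < chrom_length)
  if (!is.null(sweep_intervals)) {
    sweep_intervals <- as.data.table(sweep_intervals)
    stopifnot(all(c("chrom", "start", "end") %in% names(sweep_intervals)),
              all(sweep_intervals$start >= 0),
              all(sweep_intervals$end <= chrom_length),
              all(sweep_intervals$end > sweep_intervals$start))
  } else {
    stopifnot(sweep_length < chrom_length)
  }
  structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length), n_sites = as.integer(n_sites),
    pool_sizes = as.integer(pool_sizes), pool_labels = pool_labels,
    drift_f = drift_f, sweep_intervals = sweep_intervals,
    n_sweeps = as.integer(n_sweeps), sweep_length = as.integer(sweep_length),
    sweep_strength = sweep_strength, residual_maf = residual_maf,
    mean_depth = mean_depth, error_rate = error_rate,
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    mq_value = mq_value, low_mq_rate = low_mq_rate,
    low_mq_value = low_mq_value
  ), class = "sim_config")
}

.sim_chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chrom))

## place n_sweeps non-overlapping intervals uniformly across the genome
.auto_sweeps <- function(cfg) {
  chroms <- .sim_chrom_names(cfg)
  placed <- data.table(chrom = character(0), start = integer(0),
                       end = integer(0))
  for (i in seq_len(cfg$n_sweeps)) {
    for (try in 1:100) {
      cn <- sample(chroms, 1L)
      s <- sample.int(cfg$chrom_length - cfg$sweep_length, 1L) - 1L
      e <- s + cfg$sweep_length
      clash <- placed[chrom == cn & start < e & end > s]
      if (nrow(clash) == 0L) {
        placed <- rbind(placed, data.table(chrom = cn, start = s, end = e))
        break
      }
    }
  }
  setorder(placed, chrom, start)
  placed[]
}

#' Simulate per-site population allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each population's
#' frequency is an independent Beta draw with shapes
#' `p(1-F)/F` and `(1-p)(1-F)/F` (the Balding-Nichols model, expectation
#' `p`, variance `F p (1-p)`). Inside a sweep interval each site is, with
#' probability `sweep_strength`, driven to near-fixation in population 1:
#' its frequency is replaced by `residual_maf` or `1 - residual_maf`,
#' whichever boundary the drawn value was already nearer.
#'
#' Seeds the RNG from `cfg$seed`; calling twice gives identical output.
#'
#' @param cfg a [sim_config()].
#' @return data.table: chrom, pos (1-based), p_anc, p1, p2, in_sweep,
#'   swept; sweep intervals in `attr(, "sweep_intervals")`.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sweeps <- if (is.null(cfg$sweep_intervals)) .auto_sweeps(cfg) else
    as.data.table(cfg$sweep_intervals)

  out <- rbindlist(lapply(.sim_chrom_names(cfg), function(cn) {
    pos <- sort(sample.int(cfg$chrom_length, cfg$n_sites))
    data.table(chrom = cn, pos = pos)
  }))
  n <- nrow(out)
  if (n == 0L) {
    out[, `:=`(p_anc = numeric(0), p1 = numeric(0), p2 = numeric(0),
               in_sweep = logical(0), swept = logical(0))]
    setattr(out, "sweep_intervals", sweeps)
    return(out[])
  }
  F <- cfg$drift_f
  out[, p_anc := runif(n, 0.05, 0.95)]
  out[, p1 := rbeta(n, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)]
  out[, p2 := rbeta(n, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)]
  out[, in_sweep := FALSE]
  for (i in seq_len(nrow(sweeps))) {
    out[chrom == sweeps$chrom[i] & pos > sweeps$start[i] &
          pos <= sweeps$end[i], in_sweep := TRUE]
  }
  out[, swept := in_sweep & runif(n) < cfg$sweep_strength]
  out[swept == TRUE,
      p1 := ifelse(p1 < 0.5, cfg$residual_maf, 1 - cfg$residual_maf)]
  setattr(out, "sweep_intervals", sweeps)
  out[]
}

#' Simulate genotypes and sequencing reads for both pools
#'
#' Each diploid genotype is Binomial(2, p) in its population's allele
#' frequency; each individual's site depth is Poisson(`mean_depth`) (zero
#' depth = missing call); reads are drawn from the genotype's allele ratio
#' with a per-read error flipping to the other allele. Two nucleotides per
#' site serve as ref/alt, drawn uniformly. RMS mapping quality is
#' `mq_value`, replaced by `low_mq_value` for a `low_mq_rate` fraction of
#' sites.
#'
#' Seeds the RNG from `cfg$seed + 1` so the draw is reproducible on its own
#' as well as inside [simulate_sweep_data()].
#'
#' @param freqs output of [simulate_frequencies()].
#' @param cfg a [sim_config()].
#' @return list with `ref`/`alt` (site nucleotides), `mq`, sample names per
#'   pool, and per-pool matrices `geno` (alt-allele copies, NA = missing),
#'   `dp`, `ad_ref`, `ad_alt` (sites x individuals).
#' @export
simulate_genotypes_and_reads <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(freqs)
  nucpair <- t(vapply(seq_len(max(n, 0L)), function(i)
    sample(c("A", "C", "G", "T"), 2L), character(2)))
  if (n == 0L) nucpair <- matrix(character(0), 0, 2)
  mq <- rep(cfg$mq_value, n)
  if (cfg$low_mq_rate > 0 && n > 0) {
    mq[runif(n) < cfg$low_mq_rate] <- cfg$low_mq_value
  }
  samples <- list(
    sprintf("%s_%d", cfg$pool_labels[1], seq_len(cfg$pool_sizes[1])),
    sprintf("%s_%d", cfg$pool_labels[2], seq_len(cfg$pool_sizes[2]))
  )
  pools <- lapply(1:2, function(k) {
    ns <- cfg$pool_sizes[k]
    p <- if (k == 1) freqs$p1 else freqs$p2
    geno <- matrix(rbinom(n * ns, 2L, rep(p, ns)), n, ns,
                   dimnames = list(NULL, samples[[k]]))
    dp <- matrix(rpois(n * ns, cfg$mean_depth), n, ns,
                 dimnames = list(NULL, samples[[k]]))
    p_alt_read <- (geno / 2) * (1 - cfg$error_rate) +
      (1 - geno / 2) * cfg$error_rate
    ad_alt <- matrix(rbinom(n * ns, as.vector(dp), as.vector(p_alt_read)),
                     n, ns, dimnames = list(NULL, samples[[k]]))
    ad_ref <- dp - ad_alt
    geno[dp == 0L] <- NA_integer_  # no reads, no call
    list(geno = geno, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
  })
  list(ref = nucpair[, 1], alt = nucpair[, 2], mq = mq,
       samples = samples, pools = pools)
}

## toy annotation: genes placed uniformly; at least one gene is guaranteed
## to sit inside a sweep interval (the first gene is moved there if the
## uniform draw produced none).
.simulate_genes <- function(cfg, sweeps) {
  set.seed(cfg$seed + 2L)
  chroms <- .sim_chrom_names(cfg)
  genes <- data.table(
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    start = sample.int(cfg$chrom_length - cfg$gene_length,
                       cfg$n_genes, replace = TRUE) - 1L
  )
  genes[, end := start + cfg$gene_length]
  genes[, name := sprintf("gene%03d", seq_len(.N))]
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  overlaps_sweep <- function(g) {
    any(sweeps$chrom == g$chrom & sweeps$start < g$end & sweeps$end > g$start)
  }
  hit <- vapply(seq_len(nrow(genes)), function(i)
    overlaps_sweep(genes[i]), logical(1))
  if (!any(hit) && nrow(sweeps) > 0L) {
    mid <- (sweeps$start[1] + sweeps$end[1]) %/% 2L
    genes[1, `:=`(chrom = sweeps$chrom[1],
                  start = as.integer(mid),
                  end = as.integer(mid) + cfg$gene_length)]
  }
  setorder(genes, chrom, start, name)
  genes[]
}

#' Run the full synthetic experiment
#'
#' Chains [simulate_frequencies()], [simulate_genotypes_and_reads()] and
#' the toy gene annotation, and assembles the truth set (sweep intervals,
#' true per-site frequencies, genes inside sweeps).
#'
#' @param cfg a [sim_config()].
#' @return a `sweep_sim` list: `cfg`, `freqs`, `reads`, `genes`, `truth`.
#' @export
simulate_sweep_data <- function(cfg) {
  freqs <- simulate_frequencies(cfg)
  reads <- simulate_genotypes_and_reads(freqs, cfg)
  sweeps <- attr(freqs, "sweep_intervals")
  genes <- .simulate_genes(cfg, sweeps)
  genes_in_sweeps <- genes[
    sweeps, on = .(chrom), allow.cartesian = TRUE, nomatch = NULL
  ][start < i.end & end > i.start, sort(unique(name))]
  structure(list(
    cfg = cfg, freqs = freqs, reads = reads, genes = genes,
    truth = list(sweep_intervals = sweeps,
                 frequencies = freqs[, .(chrom, pos, p1, p2)],
                 genes_in_sweeps = genes_in_sweeps)
  ), class = "sweep_sim")
}

#' Write a simulated experiment to disk
#'
#' Emits `sim.vcf` (VCF 4.2 with GT:AD:DP per sample, INFO DP and MQ),
#' `popmap.tsv` (sample, pool), `genes.gff3` and `truth.json`. Output is a
#' pure function of the simulation object: the same seed gives
#' byte-identical files.
#'
#' @param sim a `sweep_sim` from [simulate_sweep_data()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sweep_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- sim$cfg
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))

  .write_sim_vcf(sim, paths[["vcf"]])

  popmap <- data.table(
    sample = unlist(sim$reads$samples),
    pool = rep(cfg$pool_labels, cfg$pool_sizes)
  )
  fwrite(popmap, paths[["popmap"]], sep = "\t", col.names = FALSE)

  g <- sim$genes
  gff <- c("##gff-version 3",
           sprintf("%s\tsweepscan_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   g$chrom, g$start + 1L, g$end, g$strand, g$name, g$name))
  writeLines(gff, paths[["genes"]])

  jsonlite::write_json(
    list(seed = cfg$seed,
         sweep_intervals = sim$truth$sweep_intervals,
         genes_in_sweeps = sim$truth$genes_in_sweeps,
         frequencies = sim$truth$frequencies),
    paths[["truth"]], digits = NA, auto_unbox = TRUE, dataframe = "columns"
  )
  invisible(paths)
}

.write_sim_vcf <- function(sim, path) {
  cfg <- sim$cfg
  freqs <- sim$freqs
  r <- sim$reads
  samples <- unlist(r$samples)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan_simulator",
    sprintf("##contig=<ID=%s,length=%d>", .sim_chrom_names(cfg),
            cfg$chrom_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- nrow(freqs)
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  geno <- cbind(r$pools[[1]]$geno, r$pools[[2]]$geno)
  dp <- cbind(r$pools[[1]]$dp, r$pools[[2]]$dp)
  ad_ref <- cbind(r$pools[[1]]$ad_ref, r$pools[[2]]$ad_ref)
  ad_alt <- cbind(r$pools[[1]]$ad_alt, r$pools[[2]]$ad_alt)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], n, ncol(geno))
  gt_str[is.na(geno)] <- "./."
  cells <- matrix(sprintf("%s:%d,%d:%d", gt_str, ad_ref, ad_alt, dp),
                  n, ncol(geno))
  sample_block <- do.call(paste, c(split(cells, col(cells)), sep = "\t"))
  total_dp <- rowSums(dp)
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MQ=%s\tGT:AD:DP\t%s",
                  freqs$chrom, freqs$pos, r$ref, r$alt,
                  as.integer(total_dp), formatC(r$mq, format = "fg"),
                  sample_block)
  writeLines(c(header, rows), path)
  invisible(path)
}
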
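#' Sliding-window specification
#'
#' Windows of `window_size` bp are laid along each chromosome every
#' `step_size` bp (0-based half-open internally). The final window is
#' truncated at the chromosome end; a chromosome shorter than one window
#' yields a single window covering it entirely. Windows with fewer than
#' `min_snps` SNPs are reported but excluded from the genome-wide
#' Z-standardisation, so near-empty windows cannot dominate the tails.
#'
#' @param window_size window width in bp.
#' @param step_size offset between successive window starts in bp;
#'   must not exceed `window_size`.
#' @param min_snps minimum SNPs for a window to enter the Z-transform.
#' @return a `window_spec` list.
#' @export
window_spec <- function(window_size = 100000L, step_size = 10000L,
                        min_snps = 10L) {
  stopifnot(window_size > 0, step_size > 0, step_size <= window_size,
            min_snps >= 1)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 min_snps = as.integer(min_snps)),
            class = "window_spec")
}

#' Tile chromosomes into sliding windows
#'
#' Window starts are `k * step_size` for `k = 0, 1, ..., K` with
#' `K = max(0, ceiling((length - window_size) / step_size))`, each window
#' ending at `min(start + window_size, length)`. Thus every base is covered,
#' only the final window can be truncated, and a chromosome shorter than
#' `window_size` produces exactly one window.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param spec a [window_spec()].
#' @return data.table with columns chrom, start, end (0-based half-open).
#' @export
tile_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"), all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)))
  rbindlist(lapply(names(chrom_lengths), function(cn) {
    len <- as.integer(chrom_lengths[[cn]])
    K <- max(0L, as.integer(ceiling((len - spec$window_size) /
                                      spec$step_size)))
    starts <- (0:K) * spec$step_size
    data.table(chrom = cn, start = starts,
               end = pmin(starts + spec$window_size, len))
  }))
}

#' Pooled heterozygosity of a window
#'
#' Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2, with the sums
#' taken over the SNPs of the window for the focal pool. Hp lies in
#' [0, 0.5]: 0 when the minor-allele count is zero everywhere (a swept,
#' near-fixed window) and 0.5 when major and minor counts balance.
#'
#' `hp_pooled` is the vectorised formula on pre-summed counts; `window_hp`
#' sums a site-table slice for one pool and applies it.
#'
#' @param sum_nmaj,sum_nmin summed major/minor allele counts.
#' @return `hp_pooled`: numeric vector (NA where both sums are zero).
#'   `window_hp`: list with `hp`, `sum_nmaj`, `sum_nmin`.
#' @export
hp_pooled <- function(sum_nmaj, sum_nmin) {
  tot <- sum_nmaj + sum_nmin
  ifelse(tot > 0, 2 * sum_nmaj * sum_nmin / tot^2, NA_real_)
}

#' @rdname hp_pooled
#' @param sites a [site_table()] slice holding the SNPs of one window.
#' @param focal_pool pool label (or index) of the selected population.
#' @export
window_hp <- function(sites, focal_pool) {
  k <- pool_index(sites, focal_pool)
  smaj <- sum(as.data.table(sites)[[paste0("nmaj_", k)]])
  smin <- sum(as.data.table(sites)[[paste0("nmin_", k)]])
  list(hp = hp_pooled(smaj, smin), sum_nmaj = smaj, sum_nmin = smin)
}

## per-site diversity terms from the two pools' nucleotide frequencies:
## pi = 1 - sum(f^2); pi_within averages the pools, pi_total uses the
## averaged frequencies. Rows where a pool has no counted allele are NA.
.site_pi_terms <- function(f1, f2) {
  pi1 <- 1 - rowSums(f1^2)
  pi2 <- 1 - rowSums(f2^2)
  fbar <- (f1 + f2) / 2
  list(pi_within = (pi1 + pi2) / 2,
       pi_total = 1 - rowSums(fbar^2))
}

#' Window fixation index from pooled nucleotide frequencies
#'
#' Per site, each pool's diversity term is pi = 1 - fA^2 - fT^2 - fC^2 -
#' fG^2 from its pooled nucleotide frequencies; pi_within is the average of
#' the two pools and pi_total is computed from the averaged frequencies.
#' The window statistic is the ratio of window means
#' (mean pi_total - mean pi_within) / mean pi_within for
#' `denominator = "within"`, or divided by mean pi_total for
#' `denominator = "total"` (the conventional normalisation, bounded by 1).
#' Ratio-of-averages is used rather than averaging per-site ratios, the
#' standard windowed estimator.
#'
#' A site contributes only when both pools have counted alleles and its
#' per-site denominator term is positive; a window with no contributing
#' site is unevaluated (NA).
#'
#' @param sites a [site_table()] slice holding the SNPs of one window.
#' @param denominator `"within"` or `"total"`.
#' @return window FST (possibly NA).
#' @export
window_fst <- function(sites, denominator = c("within", "total")) {
  denominator <- match.arg(denominator)
  f1 <- site_frequencies(sites, 1)
  f2 <- site_frequencies(sites, 2)
  terms <- .site_pi_terms(f1, f2)
  .fst_from_terms(terms$pi_within, terms$pi_total, denominator)
}

.fst_from_terms <- function(pi_within, pi_total, denominator) {
  denom_site <- if (denominator == "within") pi_within else pi_total
  use <- !is.na(pi_within) & !is.na(pi_total) & denom_site > 0
  if (!any(use)) return(NA_real_)
  mw <- mean(pi_within[use])
  mt <- mean(pi_total[use])
  md <- if (denominator == "within") mw else mt
  if (md <= 0) return(NA_real_)
  (mt - mw) / md
}

#' Genome-wide Z-transformation
#'
#' Standardises a window statistic to mean 0 and standard deviation 1 using
#' the population SD (divisor n) over all evaluated windows, so extreme
#' windows of different statistics are comparable on one scale.
#'
#' @param values numeric vector of per-window statistics (no NAs).
#' @param name statistic name used in error messages.
#' @return list with `z`, `mean`, `sd`.
#' @export
ztransform <- function(values, name = "statistic") {
  if (length(values) < 2L) {
    stop("ztransform(", name, "): need at least 2 evaluated windows")
  }
  if (anyNA(values)) stop("ztransform(", name, "): NA values not allowed")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    stop("ztransform(", name, "): constant input, Z-scores undefined")
  }
  list(z = (values - mu) / sigma, mean = mu, sd = sigma)
}

#' Sliding-window genome scan: Hp and FST per window, Z-transformed
#'
#' Assigns every SNP of the (filtered, sorted) site table to each window
#' containing it, computes pooled heterozygosity for the focal pool and the
#' fixation index between the two pools per window, then Z-transforms both
#' statistics across all evaluated windows genome-wide. Windows with at
#' least one SNP appear in the output; only windows with `min_snps` or more
#' SNPs receive Z-scores and enter the standardisation.
#'
#' @param sites a [site_table()] (typically after [apply_filters()]).
#' @param spec a [window_spec()].
#' @param focal_pool pool label whose heterozygosity is scanned for sweeps
#'   (defaults to the table's first pool).
#' @param denominator FST normalisation, see [window_fst()].
#' @param chrom_lengths named vector of chromosome lengths in bp; when NULL,
#'   each chromosome's largest SNP position is used.
#' @return list with `windows` (data.table: chrom, start, end, n_snps,
#'   sum_nmaj, sum_nmin, hp, fst, zhp, zfst) and `summary` (scan metadata:
#'   window counts, standardisation constants, formula choices).
#' @export
scan_windows <- function(sites, spec = window_spec(),
                         focal_pool = NULL,
                         denominator = c("within", "total"),
                         chrom_lengths = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(sites, "site_table"), inherits(spec, "window_spec"))
  labs <- attr(sites, "pool_labels")
  if (is.null(focal_pool)) focal_pool <- labs[1]
  k <- pool_index(sites, focal_pool)

  dt <- as.data.table(sites)
  .validate_site_order(dt)
  if (is.null(chrom_lengths)) {
    cl <- dt[, max(pos), by = chrom]
    chrom_lengths <- setNames(as.numeric(cl$V1), cl$chrom)
  }
  tiles <- tile_windows(chrom_lengths, spec)
  if (nrow(dt) == 0L) {
    return(.scan_result(tiles[0L], nrow(tiles), spec, focal_pool,
                        denominator, NULL, NULL))
  }

  ## per-site quantities reused by every window containing the site
  f1 <- site_frequencies(sites, 1)
  f2 <- site_frequencies(sites, 2)
  terms <- .site_pi_terms(f1, f2)
  per_site <- data.table(
    chrom = dt$chrom,
    pos0 = dt$pos - 1L,  # to 0-based
    nmaj = dt[[paste0("nmaj_", k)]],
    nmin = dt[[paste0("nmin_", k)]],
    pi_within = terms$pi_within,
    pi_total = terms$pi_total
  )

  w <- spec$window_size; s <- spec$step_size
  Kmax <- setNames(as.integer(ceiling(pmax(0, (chrom_lengths - w)) / s)),
                   names(chrom_lengths))
  per_site[, `:=`(
    kmin = pmax(0L, as.integer(ceiling((pos0 - w + 1L) / s))),
    kmax = pmin(Kmax[chrom], pos0 %/% s)
  )]
  per_site <- per_site[kmax >= kmin]
  n_rep <- per_site$kmax - per_site$kmin + 1L
  expanded <- per_site[rep(seq_len(.N), n_rep)]
  expanded[, win := rep(per_site$kmin, n_rep) + sequence(n_rep) - 1L]

  denom_col <- if (denominator == "within") "pi_within" else "pi_total"
  expanded[, evaluable := !is.na(pi_within) & !is.na(pi_total) &
             get(denom_col) > 0]
  stats <- expanded[, .(
    n_snps = .N,
    sum_nmaj = sum(nmaj),
    sum_nmin = sum(nmin),
    mean_pw = if (any(evaluable)) mean(pi_within[evaluable]) else NA_real_,
    mean_pt = if (any(evaluable)) mean(pi_total[evaluable]) else NA_real_
  ), by = .(chrom, win)]
  stats[, start := win * s]
  stats <- merge(stats, tiles, by = c("chrom", "start"), sort = FALSE)
  setorder(stats, chrom, start)

  stats[, hp := hp_pooled(sum_nmaj, sum_nmin)]
  md <- if (denominator == "within") stats$mean_pw else stats$mean_pt
  stats[, fst := ifelse(!is.na(md) & md > 0,
                        (mean_pt - mean_pw) / md, NA_real_)]

  windows <- stats[, .(chrom, start, end, n_snps, sum_nmaj, sum_nmin,
                       hp, fst)]
  windows[, `:=`(zhp = NA_real_, zfst = NA_real_)]

  eligible <- windows$n_snps >= spec$min_snps
  zh <- zf <- NULL
  idx_hp <- which(eligible & !is.na(windows$hp))
  if (length(idx_hp) >= 2L) {
    zh <- ztransform(windows$hp[idx_hp], name = "hp")
    set(windows, i = idx_hp, j = "zhp", value = zh$z)
  }
  idx_fst <- which(eligible & !is.na(windows$fst))
  if (length(idx_fst) >= 2L) {
    zf <- ztransform(windows$fst[idx_fst], name = "fst")
    set(windows, i = idx_fst, j = "zfst", value = zf$z)
  }
  .scan_result(windows, nrow(tiles), spec, focal_pool, denominator, zh, zf)
}

.scan_result <- function(windows, n_total, spec, focal_pool, denominator,
                         zh, zf) {
  summary <- list(
    n_windows_total = n_total,
    n_windows_reported = nrow(windows),
    n_windows_evaluated = sum(windows$n_snps >= spec$min_snps),
    mean_hp = if (is.null(zh)) NA_real_ else zh$mean,
    sd_hp = if (is.null(zh)) NA_real_ else zh$sd,
    mean_fst = if (is.null(zf)) NA_real_ else zf$mean,
    sd_fst = if (is.null(zf)) NA_real_ else zf$sd,
    focal_pool = focal_pool,
    fst_denominator = denominator,
    window_size = spec$window_size,
    step_size = spec$step_size,
    min_snps = spec$min_snps
  )
  list(windows = windows, summary = summary)
}

#' Write the window table with a run-metadata header
#'
#' Columns are BED-compatible (chrom, start, end first, 0-based half-open);
#' `#`-prefixed header lines record the formula variants and thresholds so a
#' result file is self-describing.
#'
#' @param scan result of [scan_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(scan, path) {
  s <- scan$summary
  hdr <- c("# sweepscan window table v1",
           paste0("# package_version=", as.character(packageVersion("sweepscan"))),
           paste0("# focal_pool=", s$focal_pool),
           paste0("# fst_denominator=", s$fst_denominator),
           paste0("# window_size=", s$window_size),
           paste0("# step_size=", s$step_size),
           paste0("# min_snps=", s$min_snps),
           paste0("# mean_hp=", s$mean_hp), paste0("# sd_hp=", s$sd_hp),
           paste0("# mean_fst=", s$mean_fst), paste0("# sd_fst=", s$sd_fst))
  writeLines(hdr, path)
  fwrite(scan$windows, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a window table written by [write_window_table()]
#' @param path path to the file.
#' @return data.table of windows with the header metadata in
#'   `attr(, "metadata")`.
#' @export
read_window_table <- function(path) {
  lines <- readLines(path, n = 40L)
  hdr <- lines[startsWith(lines, "#")]
  kv <- regmatches(hdr, regexec("^# ([a-z_]+)=(.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  meta <- setNames(lapply(kv, `[[`, 3), vapply(kv, `[[`, character(1), 2))
  dt <- fread(path, sep = "\t", skip = length(hdr), header = TRUE)
  setattr(dt, "metadata", meta)
  dt
}
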
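NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a site table
#'
#' The site table is the pipeline's central per-SNP container: one row per
#' variant position with, for each of the two population pools, the summed
#' nucleotide counts (reads or allele copies, depending on `count_source`),
#' the derived major/minor counts nMAJ and nMIN, the pool read depth and the
#' number of samples with no call. Site-level quality annotations
#' (RMS mapping quality, total depth across all samples) ride along for the
#' SNP filters.
#'
#' Positions are 1-based as in VCF; all window arithmetic downstream converts
#' to 0-based half-open intervals internally.
#'
#' @param dt a data.frame/data.table with columns `chrom`, `pos`, `rms_mq`,
#'   `total_depth` and, for pool k in 1:2, `nA_k`, `nC_k`, `nG_k`, `nT_k`,
#'   `nmaj_k`, `nmin_k`, `depth_k`, `nmiss_k`.
#' @param pool_labels character(2), pool labels in column order.
#' @param pool_sizes integer(2), number of samples per pool.
#' @param count_source `"allele-depth"` (counts are summed reads) or
#'   `"genotype"` (counts are called allele copies).
#' @return a `site_table` (a keyed data.table).
#' @export
site_table <- function(dt, pool_labels, pool_sizes,
                       count_source = c("allele-depth", "genotype")) {
  count_source <- match.arg(count_source)
  dt <- as.data.table(dt)
  req <- c("chrom", "pos", "rms_mq", "total_depth",
           paste0(rep(c("nA_", "nC_", "nG_", "nT_",
                        "nmaj_", "nmin_", "depth_", "nmiss_"), 2),
                  rep(1:2, each = 8)))
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(pool_labels) != 2L || length(pool_sizes) != 2L) {
    stop("pool_labels and pool_sizes must each have length 2")
  }
  setcolorder(dt, req)
  .validate_site_order(dt)
  for (k in 1:2) {
    nmaj <- dt[[paste0("nmaj_", k)]]
    nmin <- dt[[paste0("nmin_", k)]]
    if (any(nmin < 0) || any(nmaj < nmin)) {
      stop("pool ", k, ": nMAJ >= nMIN >= 0 violated")
    }
  }
  setattr(dt, "pool_labels", as.character(pool_labels))
  setattr(dt, "pool_sizes", as.integer(pool_sizes))
  setattr(dt, "count_source", count_source)
  setattr(dt, "class", c("site_table", class(dt)))
  dt
}

.validate_site_order <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(TRUE))
  if (anyDuplicated(rle(dt$chrom)$values)) {
    stop("site stream is not sorted: chromosome blocks are interleaved")
  }
  bad <- dt[, any(diff(pos) <= 0), by = chrom][V1 == TRUE]
  if (nrow(bad)) {
    stop("positions not strictly increasing within chromosome(s): ",
         paste(bad$chrom, collapse = ", "))
  }
  invisible(TRUE)
}

#' Pool index for a pool label
#' @param sites a `site_table`.
#' @param pool pool label (or 1/2).
#' @return 1 or 2.
#' @export
pool_index <- function(sites, pool) {
  labs <- attr(sites, "pool_labels")
  if (is.numeric(pool) && pool %in% 1:2) return(as.integer(pool))
  i <- match(pool, labs)
  if (is.na(i)) {
    stop("unknown pool '", pool, "'; site table has pools: ",
         paste(labs, collapse = ", "))
  }
  i
}

#' Per-site nucleotide counts or frequencies for one pool
#'
#' Frequencies are counts normalised by the pool's total counted
#' alleles/reads at the site; rows with zero total are all-NA.
#'
#' @param sites a `site_table`.
#' @param pool pool label or index.
#' @return numeric matrix with columns A, C, G, T.
#' @export
site_nucleotide_counts <- function(sites, pool) {
  k <- pool_index(sites, pool)
  m <- as.matrix(as.data.table(sites)[, paste0(c("nA_", "nC_", "nG_", "nT_"), k),
                                      with = FALSE])
  colnames(m) <- NUCLEOTIDES
  m
}

#' @rdname site_nucleotide_counts
#' @export
site_frequencies <- function(sites, pool) {
  m <- site_nucleotide_counts(sites, pool)
  tot <- rowSums(m)
  f <- m / tot
  f[tot == 0, ] <- NA_real_
  f
}

## major/minor = top-two nucleotide counts; ties broken by A < C < G < T
## (column order), so output is deterministic.
.major_minor <- function(counts) {
  i1 <- max.col(counts, ties.method = "first")
  nmaj <- counts[cbind(seq_len(nrow(counts)), i1)]
  tmp <- counts
  tmp[cbind(seq_len(nrow(counts)), i1)] <- -1L
  i2 <- max.col(tmp, ties.method = "first")
  nmin <- counts[cbind(seq_len(nrow(counts)), i2)]
  list(nmaj = as.integer(nmaj), nmin = as.integer(nmin))
}

#' Read per-site, per-pool allele counts from a VCF
#'
#' For every SNP record the samples of each pool are collapsed into a single
#' pooled count per nucleotide, from which the major/minor allele counts
#' nMAJ and nMIN and the pooled nucleotide frequencies derive. Two counting
#' modes are supported: `"allele-depth"` sums the per-sample allelic read
#' depths (the `AD` FORMAT field) into pool read counts — the natural choice
#' when pooled statistics are meant to weigh sites by sequencing evidence —
#' and `"genotype"` counts called allele copies (0/1/2 per diploid), the
#' fallback for VCFs without per-sample depths.
#'
#' Indel and other non-SNP records are skipped (a message reports how many).
#' Records where a pool has no called allele are emitted with zero counts and
#' `nmiss` equal to the pool size; the missingness filter removes them later.
#'
#' @param vcf path to a VCF 4.x file (plain or bgzipped), coordinate-sorted.
#' @param popmap a [population_map()]; every sample must exist in the VCF.
#' @param count_source `"allele-depth"` or `"genotype"`.
#' @return a [site_table()].
#' @export
stream_site_counts <- function(vcf, popmap,
                               count_source = c("allele-depth", "genotype")) {
  count_source <- match.arg(count_source)
  stopifnot(inherits(popmap, "population_map"))
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    return(.empty_site_table(popmap, count_source))
  }
  vcf_samples <- colnames(v@gt)[-1]
  absent <- setdiff(names(popmap$assignments), vcf_samples)
  if (length(absent)) {
    stop("sample(s) in population map absent from VCF: ",
         paste(absent, collapse = ", "))
  }

  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  alt[alt == "."] <- ""
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  is_snp <- ref %in% NUCLEOTIDES &
    vapply(alt_list, function(a) all(a %in% NUCLEOTIDES), logical(1))
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message("stream_site_counts: skipped ", n_skipped, " non-SNP record(s)")
  }
  keep <- which(is_snp)
  if (!length(keep)) {
    return(.empty_site_table(popmap, count_source))
  }

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  info <- fix[keep, "INFO"]
  rms_mq <- .info_number(info, "MQ")
  info_dp <- .info_number(info, "DP")

  ## allele slot -> nucleotide map, up to 3 ALT alleles for SNPs
  n <- length(keep)
  nucmat <- matrix(NA_character_, n, 4L)
  nucmat[, 1] <- ref[keep]
  for (j in 1:3) {
    has <- lengths(alt_list[keep]) >= j
    nucmat[has, j + 1L] <- vapply(alt_list[keep][has], `[[`, character(1), j)
  }

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- .format_field(v, "DP", keep)
  dp_num <- if (!is.null(dp)) {
    matrix(suppressWarnings(as.numeric(dp)), n, dimnames = dimnames(dp))
  } else NULL

  ## parse GT into two allele-index matrices (NA = uncalled)
  a1 <- matrix(suppressWarnings(as.integer(sub("[/|].*$", "", gt))),
               n, ncol(gt), dimnames = dimnames(gt))
  second <- sub("^[^/|]*[/|]", "", gt)
  second[second == gt] <- NA  # haploid call: no separator
  a2 <- matrix(suppressWarnings(as.integer(second)),
               n, ncol(gt), dimnames = dimnames(gt))
  called <- !(is.na(a1) & is.na(a2))

  ad_arr <- NULL
  if (count_source == "allele-depth") {
    ad <- .format_field(v, "AD", keep)
    if (is.null(ad)) {
      stop("count_source='allele-depth' but VCF has no AD FORMAT field; ",
           "use count_source='genotype'")
    }
    ad_arr <- .parse_ad(ad)  # n x samples x 4 allele slots
  }

  out <- data.table(chrom = chrom, pos = pos,
                    rms_mq = rms_mq, total_depth = NA_integer_)
  for (k in 1:2) {
    smp <- pool_samples(popmap, popmap$pool_labels[k])
    cols <- match(smp, colnames(gt))
    ## counts per allele slot (ref, alt1..alt3) summed over the pool
    slot_counts <- matrix(0, n, 4L)
    if (count_source == "genotype") {
      for (slot in 0:3) {
        slot_counts[, slot + 1L] <-
          rowSums(a1[, cols, drop = FALSE] == slot, na.rm = TRUE) +
          rowSums(a2[, cols, drop = FALSE] == slot, na.rm = TRUE)
      }
    } else {
      for (slot in 1:4) {
        slot_counts[, slot] <-
          rowSums(ad_arr[, cols, slot, drop = FALSE], na.rm = TRUE)
      }
    }
    ## fold allele slots onto nucleotides
    nuc_counts <- matrix(0L, n, 4L, dimnames = list(NULL, NUCLEOTIDES))
    for (slot in 1:4) {
      has <- !is.na(nucmat[, slot])
      if (!any(has)) next
      j <- match(nucmat[has, slot], NUCLEOTIDES)
      idx <- cbind(which(has), j)
      nuc_counts[idx] <- nuc_counts[idx] + as.integer(slot_counts[has, slot])
    }
    mm <- .major_minor(nuc_counts)
    depth_k <- if (!is.null(dp_num)) {
      as.integer(round(rowSums(dp_num[, cols, drop = FALSE], na.rm = TRUE)))
    } else if (!is.null(ad_arr)) {
      as.integer(rowSums(ad_arr[, cols, , drop = FALSE], na.rm = TRUE))
    } else {
      as.integer(rowSums(called[, cols, drop = FALSE]) * 2L)
    }
    set(out, j = paste0("nA_", k), value = nuc_counts[, "A"])
    set(out, j = paste0("nC_", k), value = nuc_counts[, "C"])
    set(out, j = paste0("nG_", k), value = nuc_counts[, "G"])
    set(out, j = paste0("nT_", k), value = nuc_counts[, "T"])
    set(out, j = paste0("nmaj_", k), value = mm$nmaj)
    set(out, j = paste0("nmin_", k), value = mm$nmin)
    set(out, j = paste0("depth_", k), value = depth_k)
    set(out, j = paste0("nmiss_", k),
        value = as.integer(length(cols) - rowSums(called[, cols, drop = FALSE])))
  }
  td <- info_dp
  no_info_dp <- is.na(td)
  td[no_info_dp] <- (out$depth_1 + out$depth_2)[no_info_dp]
  out[, total_depth := as.integer(round(td))]

  site_table(out, popmap$pool_labels, pool_sizes(popmap), count_source)
}

.empty_site_table <- function(popmap, count_source) {
  cols <- c("chrom", "pos", "rms_mq", "total_depth",
            paste0(rep(c("nA_", "nC_", "nG_", "nT_",
                         "nmaj_", "nmin_", "depth_", "nmiss_"), 2),
                   rep(1:2, each = 8)))
  dt <- as.data.table(c(list(character(0), integer(0), numeric(0), integer(0)),
                        rep(list(integer(0)), 16)))
  setnames(dt, cols)
  site_table(dt, popmap$pool_labels, pool_sizes(popmap), count_source)
}

.info_number <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_real_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\1",
                                              regmatches(info, regexpr(pat, info, perl = TRUE)),
                                              perl = TRUE)))
  out
}

.format_field <- function(v, element, keep) {
  fmt <- v@gt[keep, 1]
  if (!any(grepl(paste0("(^|:)", element, "(:|$)"), fmt))) return(NULL)
  vcfR::extract.gt(v, element = element)[keep, , drop = FALSE]
}

## AD strings ("ref,alt1[,alt2[,alt3]]") -> integer array n x samples x 4
.parse_ad <- function(ad) {
  n <- nrow(ad); ns <- ncol(ad)
  arr <- array(NA_integer_, c(n, ns, 4L),
               dimnames = list(NULL, colnames(ad), NULL))
  parts <- strsplit(as.vector(ad), ",", fixed = TRUE)
  for (slot in 1:4) {
    val <- vapply(parts, function(p) {
      if (length(p) >= slot) p[[slot]] else NA_character_
    }, character(1))
    arr[, , slot] <- matrix(suppressWarnings(as.integer(val)), n, ns)
  }
  arr
}

#' Write / read the site table as tab-separated text
#'
#' The on-disk format is a small number of `#`-prefixed header lines carrying
#' the pool labels, pool sizes and count source, followed by a tab-separated
#' table with a column header. Counts are stored as integers, so the
#' round-trip is lossless.
#'
#' @param sites a [site_table()].
#' @param path output path.
#' @return `write_site_table` returns `path` invisibly; `read_site_table`
#'   returns a [site_table()].
#' @export
write_site_table <- function(sites, path) {
  stopifnot(inherits(sites, "site_table"))
  hdr <- c(
    "# sweepscan site table v1",
    paste0("# pool1_label=", attr(sites, "pool_labels")[1]),
    paste0("# pool1_size=", attr(sites, "pool_sizes")[1]),
    paste0("# pool2_label=", attr(sites, "pool_labels")[2]),
    paste0("# pool2_size=", attr(sites, "pool_sizes")[2]),
    paste0("# count_source=", attr(sites, "count_source"))
  )
  writeLines(hdr, path)
  fwrite(as.data.table(sites), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- lines[startsWith(lines, "#")]
  n_hdr <- length(hdr)
  kv <- regmatches(hdr, regexec("^# ([a-z0-9_]+)=(.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  meta <- setNames(vapply(kv, `[[`, character(1), 3),
                   vapply(kv, `[[`, character(1), 2))
  for (key in c("pool1_label", "pool2_label", "pool1_size", "pool2_size",
                "count_source")) {
    if (!key %in% names(meta)) stop("site table header lacks '", key, "'")
  }
  dt <- fread(path, sep = "\t", skip = n_hdr, header = TRUE)
  if ("rms_mq" %in% names(dt)) dt[, rms_mq := as.numeric(rms_mq)]
  int_cols <- setdiff(names(dt), c("chrom", "rms_mq"))
  dt[, (int_cols) := lapply(.SD, as.integer), .SDcols = int_cols]
  bad <- which(Reduce(`|`, lapply(dt[, int_cols, with = FALSE],
                                  function(x) is.na(suppressWarnings(as.integer(x))))))
  if (length(bad)) {
    stop("malformed site table row at line ",
         bad[1] + n_hdr + 1L, " of ", path)
  }
  tryCatch(
    site_table(dt,
               pool_labels = c(meta[["pool1_label"]], meta[["pool2_label"]]),
               pool_sizes = as.integer(c(meta[["pool1_size"]],
                                         meta[["pool2_size"]])),
               count_source = meta[["count_source"]]),
    error = function(e) stop("invalid site table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}
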
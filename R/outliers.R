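#' Outlier-calling configuration
#'
#' Candidate sweep windows are called at empirical quantile thresholds of
#' the Z-transformed statistics: the lower `hp_quantile` tail of ZHp
#' (diversity loss) and the upper `fst_quantile` tail of ZFST
#' (differentiation). With `require_joint = TRUE` (the default) a window
#' must fall in both tails simultaneously; otherwise the union is taken.
#' Thresholds are always recomputed from the data at hand — published
#' threshold values are properties of a particular dataset, not constants.
#'
#' @param hp_quantile lower-tail mass for ZHp, in (0, 0.5].
#' @param fst_quantile upper-tail mass for ZFST, in (0, 0.5].
#' @param require_joint require both tails in the same window.
#' @return an `outlier_config` list.
#' @export
outlier_config <- function(hp_quantile = 0.05, fst_quantile = 0.05,
                           require_joint = TRUE) {
  stopifnot(hp_quantile > 0, hp_quantile <= 0.5,
            fst_quantile > 0, fst_quantile <= 0.5)
  structure(list(hp_quantile = hp_quantile, fst_quantile = fst_quantile,
                 require_joint = isTRUE(require_joint)),
            class = "outlier_config")
}

#' Call jointly extreme windows at empirical quantile thresholds
#'
#' The ZHp threshold is the empirical `hp_quantile` quantile (linear
#' interpolation between order statistics) of the evaluated windows' ZHp;
#' the ZFST threshold is the `1 - fst_quantile` quantile of ZFST. Windows
#' at or beyond a threshold are selected (`<=` / `>=`), jointly or as a
#' union depending on the configuration.
#'
#' @param windows window table from [scan_windows()] (needs `zhp`, `zfst`).
#' @param cfg an [outlier_config()].
#' @return list with `selected` (subset of `windows`), `zhp_threshold`,
#'   `zfst_threshold`, and `n_evaluated`.
#' @export
call_outliers <- function(windows, cfg = outlier_config()) {
  stopifnot(inherits(cfg, "outlier_config"))
  windows <- as.data.table(windows)
  if (!all(c("zhp", "zfst") %in% names(windows))) {
    stop("window table lacks zhp/zfst columns; run scan_windows() first")
  }
  ev <- windows[!is.na(zhp) & !is.na(zfst)]
  if (nrow(ev) == 0L) stop("no evaluated windows (all zhp/zfst are NA)")
  if (nrow(ev) < 20L) {
    warning("only ", nrow(ev),
            " evaluated windows; empirical quantiles are unstable")
  }
  thr_hp <- unname(quantile(ev$zhp, cfg$hp_quantile, type = 7))
  thr_fst <- unname(quantile(ev$zfst, 1 - cfg$fst_quantile, type = 7))
  low_hp <- ev$zhp <= thr_hp
  high_fst <- ev$zfst >= thr_fst
  sel <- if (cfg$require_joint) low_hp & high_fst else low_hp | high_fst
  list(selected = ev[sel],
       zhp_threshold = thr_hp,
       zfst_threshold = thr_fst,
       n_evaluated = nrow(ev))
}

.windows_to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}

#' Merge selected windows into sweep regions
#'
#' Overlapping or book-ended selected windows on the same chromosome are
#' collapsed into maximal regions; each region carries the number of member
#' windows and the extreme scores (minimum ZHp, maximum ZFST) among them.
#'
#' @param selected data.table of selected windows (from [call_outliers()]).
#' @return data.table: chrom, start, end (0-based half-open), n_windows,
#'   min_zhp, max_zfst, plus an empty `genes` list-column filled by
#'   [annotate_regions()].
#' @export
merge_regions <- function(selected) {
  selected <- as.data.table(selected)
  if (nrow(selected) == 0L) {
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      min_zhp = numeric(0), max_zfst = numeric(0),
                      genes = list()))
  }
  gr <- .windows_to_granges(selected)
  red <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
  hits <- GenomicRanges::findOverlaps(gr, red)
  member_of <- S4Vectors::subjectHits(hits)
  regions <- data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = as.integer(tabulate(member_of, nbins = length(red))),
    min_zhp = vapply(seq_along(red), function(i)
      min(selected$zhp[member_of == i]), numeric(1)),
    max_zfst = vapply(seq_along(red), function(i)
      max(selected$zfst[member_of == i]), numeric(1))
  )
  regions[, genes := rep(list(character(0)), .N)]
  setorder(regions, chrom, start)
  regions[]
}

#' Read a gene annotation in GFF3 or BED format
#'
#' GFF3 rows of type `gene` are used, named by their `Name` attribute when
#' present, else `ID`; BED needs at least 4 columns (chrom, start, end,
#' name). Coordinates are returned 0-based half-open (GFF3's 1-based closed
#' intervals are converted; BED already uses the convention).
#'
#' @param path annotation file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"gff3"` or `"bed"`.
#' @return data.table: chrom, start, end, name, strand.
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  format <- match.arg(format, c("gff3", "bed"))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("cannot parse ", format, " annotation '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (format == "gff3") {
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
               as.character(S4Vectors::mcols(gr)$type) == "gene"]
    nm <- as.character(S4Vectors::mcols(gr)$Name)
    id <- as.character(S4Vectors::mcols(gr)$ID)
    nm[is.na(nm) | nm == ""] <- id[is.na(nm) | nm == ""]
  } else {
    nm <- as.character(S4Vectors::mcols(gr)$name)
  }
  out <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr))
  )
  out[strand == "*", strand := "."]
  if (any(is.na(out$name) | out$name == "")) {
    stop("annotation '", path, "' contains gene(s) without a usable name")
  }
  if (any(out$end <= out$start)) {
    stop("annotation '", path, "' contains empty interval(s)")
  }
  setorder(out, chrom, start)
  out[]
}

#' Intersect sweep regions with a gene annotation
#'
#' A gene is assigned to every region its interval overlaps by at least
#' 1 bp (half-open convention on both sides, so a gene starting exactly at
#' a region's end is not assigned). Genes on chromosomes absent from the
#' region set are silently ignored (a message reports how many).
#'
#' @param regions region table from [merge_regions()].
#' @param genes annotation table from [read_gene_annotation()].
#' @return list with `regions` (the input with the `genes` list-column
#'   filled) and `candidate_genes` (deduplicated, sorted gene names across
#'   all regions).
#' @export
annotate_regions <- function(regions, genes) {
  regions <- as.data.table(regions)
  genes <- as.data.table(genes)
  if (nrow(regions) == 0L) {
    return(list(regions = regions, candidate_genes = character(0)))
  }
  known <- unique(regions$chrom)
  off <- genes[!chrom %in% known]
  if (nrow(off)) {
    message("annotate_regions: ", nrow(off),
            " gene(s) on chromosomes without regions ignored")
  }
  g <- genes[chrom %in% known]
  regions <- copy(regions)
  gene_lists <- rep(list(character(0)), nrow(regions))
  if (nrow(g)) {
    rgr <- .windows_to_granges(regions)
    ggr <- .windows_to_granges(g)
    hits <- GenomicRanges::findOverlaps(ggr, rgr, minoverlap = 1L)
    if (length(hits)) {
      by_region <- split(g$name[S4Vectors::queryHits(hits)],
                         S4Vectors::subjectHits(hits))
      for (i in names(by_region)) {
        gene_lists[[as.integer(i)]] <- sort(unique(by_region[[i]]))
      }
    }
  }
  regions[, genes := gene_lists]
  list(regions = regions[],
       candidate_genes = sort(unique(unlist(regions$genes))))
}

#' Write sweep regions as BED with score columns
#'
#' Standard BED6 columns (name = region id, score = max ZFST rescaled is
#' avoided — raw statistics are kept in extra columns documented in the
#' header): chrom, start, end, name, n_windows, strand, then min_zhp,
#' max_zfst and the semicolon-joined gene list.
#'
#' @param regions annotated region table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  hdr <- c("# sweepscan regions v1",
           "# columns: chrom start end name n_windows strand min_zhp max_zfst genes")
  out <- data.table(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = sprintf("sweep_region_%d", seq_len(nrow(regions))),
    n_windows = regions$n_windows, strand = ".",
    min_zhp = regions$min_zhp, max_zfst = regions$max_zfst,
    genes = vapply(regions$genes, function(g)
      if (length(g)) paste(g, collapse = ";") else ".", character(1))
  )
  writeLines(hdr, path)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}
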
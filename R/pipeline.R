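#' Run the full sweep-scan pipeline end to end
#'
#' Either simulates a complete experiment (when `sim` is given) or consumes
#' existing files, then chains the stages: pooled allele counting from the
#' VCF, SNP quality filtering, the sliding-window Hp/FST scan with
#' genome-wide Z-transformation, joint-outlier calling, region merging and
#' gene annotation. All intermediates and a run summary are written under
#' `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()]; when given, the input files are simulated
#'   into `out_dir` first.
#' @param vcf,popmap,genes input paths (ignored when `sim` is given).
#' @param count_source counting mode, see [stream_site_counts()].
#' @param filter a [filter_config()].
#' @param windows a [window_spec()].
#' @param outliers an [outlier_config()].
#' @param focal_pool pool scanned for diversity loss; defaults to pool 1.
#' @param denominator FST normalisation, see [window_fst()].
#' @param plots write the genome-wide scatter and per-region track images.
#' @return (invisibly) a list: `sites`, `filter_report`, `scan`,
#'   `outliers`, `regions`, `candidate_genes`, `paths`, and (simulated
#'   runs) `truth`.
#' @export
run_pipeline <- function(out_dir,
                         sim = NULL, vcf = NULL, popmap = NULL, genes = NULL,
                         count_source = c("allele-depth", "genotype"),
                         filter = filter_config(),
                         windows = window_spec(),
                         outliers = outlier_config(),
                         focal_pool = NULL,
                         denominator = c("within", "total"),
                         plots = TRUE) {
  count_source <- match.arg(count_source)
  denominator <- match.arg(denominator)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  truth <- NULL
  chrom_lengths <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    simdata <- simulate_sweep_data(sim)
    paths <- write_simulation(simdata, out_dir)
    vcf <- paths[["vcf"]]; popmap <- paths[["popmap"]]
    genes <- paths[["genes"]]
    truth <- simdata$truth
    chrom_lengths <- setNames(rep(as.numeric(sim$chrom_length), sim$n_chrom),
                              .sim_chrom_names(sim))
  }
  for (p in c(vcf, popmap)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }

  pm <- read_population_map(popmap)
  sites <- stream_site_counts(vcf, pm, count_source = count_source)
  site_path <- file.path(out_dir, "sites.tsv")
  write_site_table(sites, site_path)

  filt <- apply_filters(sites, filter)
  writeLines(summarize_report(filt$report),
             file.path(out_dir, "filter_report.txt"))

  scan <- scan_windows(filt$sites, windows, focal_pool = focal_pool,
                       denominator = denominator,
                       chrom_lengths = chrom_lengths)
  write_window_table(scan, file.path(out_dir, "windows.tsv"))

  out <- call_outliers(scan$windows, outliers)
  regions <- merge_regions(out$selected)
  gene_tab <- if (!is.null(genes) && file.exists(genes)) {
    read_gene_annotation(genes)
  } else NULL
  ann <- if (!is.null(gene_tab)) annotate_regions(regions, gene_tab) else
    list(regions = regions, candidate_genes = character(0))

  write_regions_bed(ann$regions, file.path(out_dir, "regions.bed"))
  writeLines(ann$candidate_genes, file.path(out_dir, "candidate_genes.txt"))
  writeLines(c(
    sprintf("sweepscan %s", as.character(packageVersion("sweepscan"))),
    sprintf("focal_pool: %s", scan$summary$focal_pool),
    sprintf("fst_denominator: %s", scan$summary$fst_denominator),
    sprintf("sites input/retained: %d/%d",
            filt$report$input_sites, filt$report$retained_sites),
    sprintf("windows evaluated: %d", scan$summary$n_windows_evaluated),
    sprintf("zhp_threshold: %.6g", out$zhp_threshold),
    sprintf("zfst_threshold: %.6g", out$zfst_threshold),
    sprintf("outlier windows: %d", nrow(out$selected)),
    sprintf("sweep regions: %d", nrow(ann$regions)),
    sprintf("candidate genes: %d", length(ann$candidate_genes))
  ), file.path(out_dir, "run_summary.txt"))

  if (isTRUE(plots) && nrow(scan$windows) > 0L) {
    plot_scan(scan$windows, ann$regions,
              file.path(out_dir, "zhp_zfst_scatter.png"))
    if (nrow(ann$regions) > 0L) {
      plot_region_track(scan$windows, ann$regions[1],
                        file.path(out_dir, "region1_track.png"))
    }
  }

  invisible(list(sites = sites, filter_report = filt$report, scan = scan,
                 outliers = out, regions = ann$regions,
                 candidate_genes = ann$candidate_genes, truth = truth,
                 paths = list(out_dir = out_dir, vcf = vcf, popmap = popmap,
                              genes = genes)))
}

#' Genome-wide ZHp versus ZFST scatter plot
#'
#' Each evaluated window is a point; windows inside reported sweep regions
#' are highlighted. The joint-outlier corner (low ZHp, high ZFST) is where
#' putatively selected windows concentrate.
#'
#' @param windows window table with `zhp`/`zfst` columns.
#' @param regions region table (may be empty) used to highlight members.
#' @param path output image path (png).
#' @return `path`, invisibly.
#' @export
plot_scan <- function(windows, regions, path) {
  windows <- as.data.table(windows)
  if (!all(c("zhp", "zfst") %in% names(windows))) {
    stop("plot_scan: window table lacks column(s): ",
         paste(setdiff(c("zhp", "zfst"), names(windows)), collapse = ", "))
  }
  ev <- windows[!is.na(zhp) & !is.na(zfst)]
  if (nrow(ev) == 0L) stop("plot_scan: no evaluated windows to plot")
  ev[, joint := FALSE]
  regions <- as.data.table(regions)
  for (i in seq_len(nrow(regions))) {
    ev[chrom == regions$chrom[i] & start < regions$end[i] &
         end > regions$start[i], joint := TRUE]
  }
  p <- ggplot2::ggplot(ev, ggplot2::aes(x = zhp, y = zfst, colour = joint)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "dodgerblue3"),
                                 guide = "none") +
    ggplot2::labs(x = "ZHp", y = "ZFST",
                  title = "Genome-wide window statistics") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
  invisible(path)
}

#' Per-region track of ZHp and ZFST along position
#'
#' Plots both Z-statistics against window midpoints in a margin around one
#' sweep region, with the region span shaded — the per-locus view of a
#' selection signal.
#'
#' @param windows window table with `zhp`/`zfst`.
#' @param region single-row region table.
#' @param path output image path (png).
#' @param margin bp of context either side of the region.
#' @return `path`, invisibly.
#' @export
plot_region_track <- function(windows, region, path, margin = 2e5) {
  windows <- as.data.table(windows)
  region <- as.data.table(region)
  stopifnot(nrow(region) == 1L)
  if (!all(c("zhp", "zfst") %in% names(windows))) {
    stop("plot_region_track: window table lacks column(s): ",
         paste(setdiff(c("zhp", "zfst"), names(windows)), collapse = ", "))
  }
  tr <- windows[chrom == region$chrom & end > region$start - margin &
                  start < region$end + margin & !is.na(zhp) & !is.na(zfst)]
  if (nrow(tr) == 0L) stop("plot_region_track: no windows near the region")
  tr[, midpoint := (start + end) / 2]
  long <- melt(tr, id.vars = "midpoint", measure.vars = c("zhp", "zfst"),
               variable.name = "statistic", value.name = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(midpoint, value,
                                          colour = statistic)) +
    ggplot2::annotate("rect", xmin = region$start, xmax = region$end,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "dodgerblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = sprintf("%s position (bp)", region$chrom), y = "Z",
                  title = "Selection signal around a sweep region") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 3.5, dpi = 120)
  invisible(path)
}
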
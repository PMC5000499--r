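#' SNP filter configuration
#'
#' Post-calling quality filters applied to the site stream before the window
#' scan: minimum RMS mapping quality, total-depth bounds, a minimum spacing
#' between adjacent SNPs, and a per-pool missing-data bound (strict: a pool's
#' missing rate must be below `max_missing_rate`).
#'
#' Defaults correspond to common resequencing practice: RMS mapping quality
#' >= 20, total coverage between 4 and 1000, adjacent SNPs at least 5 bp
#' apart, and less than 50 percent missing samples within each pool.
#'
#' @param min_rms_mq minimum RMS mapping quality (Phred-like).
#' @param min_depth,max_depth total-depth bounds (across all samples).
#' @param min_adjacent_gap minimum distance in bp between adjacent SNPs on
#'   the same chromosome; both members of any closer pair are removed.
#' @param max_missing_rate strict upper bound on each pool's fraction of
#'   samples with no call.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_rms_mq = 20, min_depth = 4, max_depth = 1000,
                          min_adjacent_gap = 5, max_missing_rate = 0.5) {
  stopifnot(min_depth <= max_depth,
            max_missing_rate > 0, max_missing_rate <= 1,
            min_adjacent_gap >= 1)
  structure(list(min_rms_mq = min_rms_mq, min_depth = min_depth,
                 max_depth = max_depth, min_adjacent_gap = min_adjacent_gap,
                 max_missing_rate = max_missing_rate),
            class = "filter_config")
}

FILTER_RULES <- c("mapping_quality", "depth_low", "depth_high",
                  "missing_rate", "adjacent_gap")

#' Apply SNP quality filters to a site table
#'
#' A site is retained iff its RMS mapping quality is at least `min_rms_mq`,
#' its total depth lies in `[min_depth, max_depth]`, each pool's missing
#' rate is strictly below `max_missing_rate`, and no other SNP in the input
#' lies closer than `min_adjacent_gap` bp on the same chromosome. The
#' spacing rule is symmetric: both members of a too-close pair are removed.
#' It is evaluated on the full input site map (not on the survivors of the
#' other rules), which makes it independent of the quality thresholds and
#' keeps filtering monotone: relaxing any one threshold can only grow the
#' retained set.
#'
#' Each removed site is attributed to the first failing rule, in the order
#' mapping quality, low depth, high depth, missingness, adjacency.
#'
#' @param sites a [site_table()], sorted by (chrom, pos).
#' @param cfg a [filter_config()].
#' @return list with `sites` (retained [site_table()]) and `report`
#'   (a `filter_report`: input/retained counts and per-rule removals).
#' @export
apply_filters <- function(sites, cfg = filter_config()) {
  stopifnot(inherits(sites, "site_table"), inherits(cfg, "filter_config"))
  dt <- as.data.table(sites)
  .validate_site_order(dt)
  n <- nrow(dt)
  sizes <- attr(sites, "pool_sizes")

  if (n == 0L) {
    report <- .filter_report(0L, setNames(rep(0L, length(FILTER_RULES)),
                                          FILTER_RULES))
    return(list(sites = sites, report = report))
  }

  pass_mq <- !is.na(dt$rms_mq) & dt$rms_mq >= cfg$min_rms_mq
  pass_dlo <- dt$total_depth >= cfg$min_depth
  pass_dhi <- dt$total_depth <= cfg$max_depth
  pass_miss <- (dt$nmiss_1 / sizes[1] < cfg$max_missing_rate) &
    (dt$nmiss_2 / sizes[2] < cfg$max_missing_rate)

  ## adjacency on the full input site map, per chromosome
  pass_adj <- rep(TRUE, n)
  gaps <- dt[, {
    d <- diff(pos)
    list(prev_ok = c(TRUE, d >= cfg$min_adjacent_gap),
         next_ok = c(d >= cfg$min_adjacent_gap, TRUE))
  }, by = chrom]
  pass_adj <- gaps$prev_ok & gaps$next_ok

  retained <- pass_mq & pass_dlo & pass_dhi & pass_miss & pass_adj
  fail_first <- rep(NA_character_, n)
  fail_first[!pass_adj] <- "adjacent_gap"
  fail_first[!pass_miss] <- "missing_rate"
  fail_first[!pass_dhi] <- "depth_high"
  fail_first[!pass_dlo] <- "depth_low"
  fail_first[!pass_mq] <- "mapping_quality"

  removed <- vapply(FILTER_RULES,
                    function(r) sum(fail_first == r, na.rm = TRUE),
                    integer(1))
  out <- dt[retained]
  out <- site_table(out, attr(sites, "pool_labels"), sizes,
                    attr(sites, "count_source"))
  list(sites = out, report = .filter_report(n, removed))
}

.filter_report <- function(input_sites, removed_by_rule) {
  structure(list(input_sites = as.integer(input_sites),
                 removed_by_rule = removed_by_rule,
                 retained_sites = as.integer(input_sites - sum(removed_by_rule))),
            class = "filter_report")
}

#' Human-readable summary of a filter report
#' @param report a `filter_report` from [apply_filters()].
#' @return character vector of lines (also printed by the print method).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  c(sprintf("input sites:    %d", report$input_sites),
    sprintf("  removed by %-16s %d", paste0(names(report$removed_by_rule), ":"),
            report$removed_by_rule),
    sprintf("retained sites: %d", report$retained_sites))
}

#' @export
print.filter_report <- function(x, ...) {
  writeLines(summarize_report(x))
  invisible(x)
}
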
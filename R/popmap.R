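#' Population map: sample-to-pool assignments
#'
#' A population map assigns every sequenced sample to exactly one of two
#' population pools (for example a selected breed pool and a wild reference
#' pool). Pooled statistics (Hp, FST) are computed per pool after summing
#' counts over all samples of the pool.
#'
#' @param samples character vector of unique sample identifiers.
#' @param pools character vector, same length, giving the pool label of each
#'   sample. Exactly two distinct labels are required and every label must
#'   have at least one sample.
#'
#' @return An object of class `population_map`: a list with elements
#'   `assignments` (named character vector, sample -> pool label) and
#'   `pool_labels` (character(2), in order of first appearance).
#' @export
#' @examples
#' population_map(c("s1", "s2", "s3"), c("A", "A", "B"))
population_map <- function(samples, pools) {
  samples <- as.character(samples)
  pools <- as.character(pools)
  if (length(samples) != length(pools)) {
    stop("'samples' and 'pools' must have the same length")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  labs <- unique(pools)
  if (length(labs) != 2L) {
    stop("a population map requires exactly 2 pool labels, got ",
         length(labs), ": ", paste(labs, collapse = ", "))
  }
  structure(
    list(assignments = setNames(pools, samples), pool_labels = labs),
    class = "population_map"
  )
}

#' Read a population map from a two-column text file
#'
#' The file has one row per sample: sample identifier, then pool label,
#' separated by whitespace or tabs. No header.
#'
#' @param path path to the two-column file.
#' @return A [population_map()] object.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map file not found: ", path)
  dt <- fread(path, header = FALSE, colClasses = "character")
  if (ncol(dt) != 2L) {
    stop("population map must have exactly 2 columns (sample, pool), got ",
         ncol(dt))
  }
  population_map(dt[[1]], dt[[2]])
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = x$pool_labels))
  cat("population_map:", sum(tab), "samples in 2 pools\n")
  for (lab in x$pool_labels) {
    cat(sprintf("  %s: %d sample(s)\n", lab, tab[[lab]]))
  }
  invisible(x)
}

#' Samples belonging to one pool
#' @param popmap a [population_map()].
#' @param pool pool label.
#' @return character vector of sample identifiers.
#' @export
pool_samples <- function(popmap, pool) {
  stopifnot(inherits(popmap, "population_map"))
  if (!pool %in% popmap$pool_labels) {
    stop("unknown pool label '", pool, "'; map has: ",
         paste(popmap$pool_labels, collapse = ", "))
  }
  names(popmap$assignments)[popmap$assignments == pool]
}

#' Pool sizes (number of samples per pool)
#' @param popmap a [population_map()].
#' @return named integer vector, one entry per pool label.
#' @export
pool_sizes <- function(popmap) {
  stopifnot(inherits(popmap, "population_map"))
  setNames(
    vapply(popmap$pool_labels,
           function(p) sum(popmap$assignments == p), integer(1)),
    popmap$pool_labels
  )
}
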
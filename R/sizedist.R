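#' Binned size distribution of a starch granule sample
#'
#' One sample's binned diameter distribution, either as raw particle counts
#' (`number_counts`) or as per-bin volume relative to total granule volume
#' in percent (`relative_volume_pct`) -- the representation in which wheat
#' endosperm starch shows its characteristic bimodal A-type/B-type shape.
#'
#' @param grid A [diameter_grid()].
#' @param values Numeric vector, one nonnegative magnitude per bin.
#' @param weighting `"number_counts"` or `"relative_volume_pct"`.
#' @param sample_id,genotype,timepoint Character metadata labels.
#' @param replicate Integer biological replicate index.
#' @param mass_mg Optional starch mass analysed, in mg (needed for
#'   granule-number-per-mg metrics).
#' @param normalized Logical; `TRUE` asserts `relative_volume_pct` values
#'   sum to 100.
#' @return An object of class `size_distribution`.
#' @seealso [validate_distribution()], [normalize_percent()]
#' @export
size_distribution <- function(grid, values,
                              weighting = c("relative_volume_pct", "number_counts"),
                              sample_id = "sample", genotype = "unknown",
                              timepoint = "unknown", replicate = 1L,
                              mass_mg = NA_real_, normalized = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(grid, "diameter_grid"))
  values <- as.numeric(values)
  d <- structure(
    list(grid = grid, values = values, weighting = weighting,
         meta = list(sample_id = as.character(sample_id),
                     genotype = as.character(genotype),
                     timepoint = as.character(timepoint),
                     replicate = as.integer(replicate)),
         mass_mg = as.numeric(mass_mg),
         normalized = isTRUE(normalized)),
    class = "size_distribution"
  )
  viol <- validate_distribution(d)
  if (length(viol)) {
    stop("invalid size_distribution: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  d
}

#' Validate a size distribution against its invariants
#'
#' Checks bin-count agreement, nonnegativity, and (for distributions
#' flagged normalized) that relative volumes sum to 100. Reports rather
#' than raises, so it can be used to audit externally read tables.
#'
#' @param d A `size_distribution` (or structurally similar list).
#' @return Character vector of violations, empty when all invariants hold.
#'   Each entry names the invariant and, where relevant, the offending bin.
#' @export
validate_distribution <- function(d) {
  v <- character()
  if (!inherits(d$grid, "diameter_grid")) {
    return("grid: not a diameter_grid")
  }
  nb <- n_bins(d$grid)
  if (length(d$values) != nb) {
    v <- c(v, sprintf("length: %d values for %d bins", length(d$values), nb))
  }
  if (anyNA(d$values)) {
    v <- c(v, sprintf("missing: value NA at bin %d", which(is.na(d$values))[1L]))
  } else if (any(d$values < 0)) {
    v <- c(v, sprintf("nonnegativity: negative value at bin %d",
                      which(d$values < 0)[1L]))
  }
  if (!d$weighting %in% c("number_counts", "relative_volume_pct")) {
    v <- c(v, sprintf("weighting: unknown weighting '%s'", d$weighting))
  }
  if (identical(d$weighting, "relative_volume_pct") && isTRUE(d$normalized) &&
      !anyNA(d$values) && length(d$values) == nb) {
    s <- sum(d$values)
    if (abs(s - 100) > 1e-6) {
      v <- c(v, sprintf("normalization: values flagged normalized sum to %.8g, not 100", s))
    }
  }
  v
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %s | %s %s rep %d | %d bins, %s%s\n",
              x$meta$sample_id, x$meta$genotype, x$meta$timepoint,
              x$meta$replicate, n_bins(x$grid), x$weighting,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Bundle replicate distributions of one genotype and timepoint
#'
#' @param distributions List of [size_distribution()] objects sharing one
#'   grid, one weighting and one (genotype, timepoint); replicate indices
#'   must be unique.
#' @return Object of class `replicate_set`.
#' @export
replicate_set <- function(distributions) {
  if (!length(distributions) ||
      !all(vapply(distributions, inherits, logical(1), "size_distribution"))) {
    stop("replicate_set needs a non-empty list of size_distribution objects",
         call. = FALSE)
  }
  ref <- distributions[[1L]]
  for (d in distributions[-1L]) {
    if (!grids_identical(ref$grid, d$grid)) {
      stop("all replicates must share identical grid edges", call. = FALSE)
    }
    if (!identical(ref$weighting, d$weighting)) {
      stop("all replicates must share one weighting", call. = FALSE)
    }
    if (!identical(ref$meta$genotype, d$meta$genotype) ||
        !identical(ref$meta$timepoint, d$meta$timepoint)) {
      stop("all replicates must share one (genotype, timepoint)", call. = FALSE)
    }
  }
  reps <- vapply(distributions, function(d) d$meta$replicate, integer(1))
  if (anyDuplicated(reps)) {
    stop("replicate indices must be unique within a replicate_set", call. = FALSE)
  }
  structure(list(distributions = distributions), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  d <- x$distributions[[1L]]
  cat(sprintf("<replicate_set> %s %s: %d replicates, %d bins (%s)\n",
              d$meta$genotype, d$meta$timepoint, length(x$distributions),
              n_bins(d$grid), d$weighting))
  invisible(x)
}

#' @export
length.replicate_set <- function(x) length(x$distributions)
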
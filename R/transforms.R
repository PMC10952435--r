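#' Volume of a sphere of given diameter
#'
#' The Coulter principle reports an equivalent spherical diameter per
#' counted particle, so granule volumes are computed as spheres throughout;
#' the discoid geometry of A-type granules is deliberately not modelled.
#'
#' @param d Diameter (um), positive.
#' @return Volume in cubic micrometres, `pi * d^3 / 6`.
#' @examples
#' sphere_volume(2)  # 4.18879
#' @export
sphere_volume <- function(d) {
  if (anyNA(d) || any(d <= 0)) {
    stop("diameter must be positive", call. = FALSE)
  }
  pi * d^3 / 6
}

#' Convert a number-weighted distribution to relative volume percent
#'
#' Each bin's count is weighted by the sphere volume at the bin midpoint
#' and the result normalized to sum 100, giving the volume-at-each-diameter
#' relative to total granule volume representation in which A- and B-type
#' granule peaks are fitted.
#'
#' @param d A [size_distribution()] with weighting `number_counts` and at
#'   least one positive count.
#' @return A normalized `relative_volume_pct` [size_distribution()] with
#'   the same grid and metadata.
#' @export
number_to_volume <- function(d) {
  stopifnot(inherits(d, "size_distribution"))
  if (d$weighting != "number_counts") {
    stop("number_to_volume expects a number_counts distribution", call. = FALSE)
  }
  vol <- d$values * sphere_volume(d$grid$midpoints)
  s <- sum(vol)
  if (s <= 0) {
    stop("cannot convert an all-zero count distribution to volume percent", call. = FALSE)
  }
  size_distribution(d$grid, 100 * vol / s, "relative_volume_pct",
                    sample_id = d$meta$sample_id, genotype = d$meta$genotype,
                    timepoint = d$meta$timepoint, replicate = d$meta$replicate,
                    mass_mg = d$mass_mg, normalized = TRUE)
}

#' Convert a volume-weighted distribution to (real-valued) counts
#'
#' Inverse of [number_to_volume()]: per-bin counts are proportional to
#' per-bin volume divided by the midpoint sphere volume, scaled to a given
#' total. Counts are real-valued; rounding is the caller's choice.
#'
#' @param d A `relative_volume_pct` [size_distribution()].
#' @param total_count Positive total particle count to distribute.
#' @return A `number_counts` [size_distribution()].
#' @export
volume_to_number <- function(d, total_count) {
  stopifnot(inherits(d, "size_distribution"))
  if (d$weighting != "relative_volume_pct") {
    stop("volume_to_number expects a relative_volume_pct distribution", call. = FALSE)
  }
  if (!is.numeric(total_count) || length(total_count) != 1L || total_count <= 0) {
    stop("total_count must be a single positive number", call. = FALSE)
  }
  if (sum(d$values) <= 0) {
    stop("cannot convert a zero-sum volume distribution to counts", call. = FALSE)
  }
  w <- d$values / d$grid$midpoints^3
  size_distribution(d$grid, total_count * w / sum(w), "number_counts",
                    sample_id = d$meta$sample_id, genotype = d$meta$genotype,
                    timepoint = d$meta$timepoint, replicate = d$meta$replicate,
                    mass_mg = d$mass_mg)
}

#' Normalize a volume-weighted distribution to sum 100
#'
#' @param d A `relative_volume_pct` [size_distribution()] with positive sum.
#' @return The same distribution rescaled to sum exactly 100 and flagged
#'   normalized. Idempotent on already-normalized input.
#' @export
normalize_percent <- function(d) {
  stopifnot(inherits(d, "size_distribution"))
  if (d$weighting != "relative_volume_pct") {
    stop("normalize_percent expects a relative_volume_pct distribution", call. = FALSE)
  }
  s <- sum(d$values)
  if (s <= 0) {
    stop("cannot normalize a zero-sum distribution", call. = FALSE)
  }
  size_distribution(d$grid, 100 * d$values / s, "relative_volume_pct",
                    sample_id = d$meta$sample_id, genotype = d$meta$genotype,
                    timepoint = d$meta$timepoint, replicate = d$meta$replicate,
                    mass_mg = d$mass_mg, normalized = TRUE)
}

#' Granule number per milligram of starch
#'
#' @param d A `number_counts` [size_distribution()].
#' @param mass_mg Starch mass analysed in mg; defaults to the
#'   distribution's own `mass_mg` field.
#' @return Total counts divided by mass, particles per mg.
#' @export
granules_per_mg <- function(d, mass_mg = d$mass_mg) {
  stopifnot(inherits(d, "size_distribution"))
  if (d$weighting != "number_counts") {
    stop("granules_per_mg expects a number_counts distribution", call. = FALSE)
  }
  if (is.null(mass_mg) || is.na(mass_mg)) {
    stop("starch mass unknown: set mass_mg (mg) on the distribution or pass it explicitly",
         call. = FALSE)
  }
  if (mass_mg <= 0) {
    stop("mass_mg must be positive", call. = FALSE)
  }
  sum(d$values) / mass_mg
}

#' Mean and standard error curve across replicates
#'
#' Per-bin arithmetic mean and standard error (sd with `n - 1` denominator
#' over the square root of n, appropriate for the small replicate sets,
#' typically n = 3, of granule phenotyping experiments).
#'
#' @param rs A [replicate_set()] of at least 2 normalized
#'   `relative_volume_pct` distributions on a common grid.
#' @return Object of class `aggregate_curve` with fields `grid`, `mean`,
#'   `se`, `n`, `genotype`, `timepoint`.
#' @export
aggregate_replicates <- function(rs) {
  stopifnot(inherits(rs, "replicate_set"))
  dists <- rs$distributions
  if (length(dists) < 2L) {
    stop("aggregate_replicates needs at least 2 replicates", call. = FALSE)
  }
  if (dists[[1L]]$weighting != "relative_volume_pct" ||
      !all(vapply(dists, function(d) isTRUE(d$normalized), logical(1)))) {
    stop("all replicates must be normalized relative_volume_pct distributions",
         call. = FALSE)
  }
  m <- do.call(cbind, lapply(dists, function(d) d$values))
  structure(
    list(grid = dists[[1L]]$grid,
         mean = rowMeans(m),
         se = apply(m, 1L, stats::sd) / sqrt(ncol(m)),
         n = ncol(m),
         genotype = dists[[1L]]$meta$genotype,
         timepoint = dists[[1L]]$meta$timepoint),
    class = "aggregate_curve"
  )
}

#' @export
print.aggregate_curve <- function(x, ...) {
  cat(sprintf("<aggregate_curve> %s %s: mean +/- SE of %d replicates over %d bins\n",
              x$genotype, x$timepoint, x$n, n_bins(x$grid)))
  invisible(x)
}
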
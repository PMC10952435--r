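#' Diameter grid for binned size distributions
#'
#' A `diameter_grid` holds the bin boundary diameters of a Coulter-counter
#' style measurement. Bin midpoints are geometric means of adjacent edges,
#' matching the log-spaced grids such instruments report and the log-scale
#' axes on which granule size distributions are conventionally plotted.
#'
#' @param edges Numeric vector of bin boundary diameters in micrometres,
#'   strictly increasing, all positive. `n` edges define `n - 1` bins.
#' @return An object of class `diameter_grid` with fields `edges` and
#'   `midpoints` (geometric means, micrometres).
#' @examples
#' g <- diameter_grid(c(2, 4, 8, 16))
#' g$midpoints  # 2.83, 5.66, 11.3
#' @export
diameter_grid <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L) {
    stop("a diameter grid needs at least 2 bin edges", call. = FALSE)
  }
  if (anyNA(edges) || any(edges <= 0)) {
    stop("bin edges must be positive and non-missing", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    bad <- which(diff(edges) <= 0)[1L] + 1L
    stop(sprintf("bin edges must be strictly increasing; edge %d (%g) is not above edge %d (%g)",
                 bad, edges[bad], bad - 1L, edges[bad - 1L]), call. = FALSE)
  }
  structure(
    list(edges = edges,
         midpoints = sqrt(edges[-length(edges)] * edges[-1L])),
    class = "diameter_grid"
  )
}

#' Log-spaced diameter grid
#'
#' Convenience constructor for a geometrically spaced grid, the layout used
#' by the synthetic measurement presets (default 300 bins over 2-60 um).
#'
#' @param n_bins Number of bins.
#' @param d_min,d_max Smallest and largest edge diameter (um).
#' @return A [diameter_grid()].
#' @export
log_diameter_grid <- function(n_bins = 300L, d_min = 2, d_max = 60) {
  stopifnot(n_bins >= 1L, d_min > 0, d_max > d_min)
  diameter_grid(exp(seq(log(d_min), log(d_max), length.out = n_bins + 1L)))
}

#' @export
print.diameter_grid <- function(x, ...) {
  cat(sprintf("<diameter_grid> %d bins over %.3g-%.3g um\n",
              length(x$midpoints), x$edges[1L], x$edges[length(x$edges)]))
  invisible(x)
}

#' Number of bins of a diameter grid
#' @param grid A [diameter_grid()].
#' @return Integer bin count.
#' @export
n_bins <- function(grid) {
  stopifnot(inherits(grid, "diameter_grid"))
  length(grid$midpoints)
}

grids_identical <- function(a, b, tol = 1e-9) {
  length(a$edges) == length(b$edges) &&
    max(abs(a$edges - b$edges)) <= tol * max(a$edges)
}
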
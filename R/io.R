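# Long-format CSV/TSV dialect: one row per (sample, bin) with explicit
# bin_lower_um/bin_upper_um columns. Explicit edges avoid any ambiguity in
# the midpoint convention of log-spaced instrument grids. Units are fixed
# to micrometres; decimal separator is "." only.

.sizedist_cols <- c("sample_id", "genotype", "timepoint", "replicate",
                    "weighting", "bin_lower_um", "bin_upper_um", "value")

.num_re <- "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"

.parse_num <- function(x, col, path) {
  x <- trimws(x)
  bad <- which(!grepl(.num_re, x))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' row %d has non-numeric value '%s' (decimal separator must be '.')",
                 basename(path), col, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  as.numeric(x)
}

#' Read binned size distributions from a long-format CSV/TSV table
#'
#' The table must carry a header with columns `sample_id`, `genotype`,
#' `timepoint`, `replicate`, `weighting`, `bin_lower_um`, `bin_upper_um`,
#' `value`, and optionally `mass_mg`. Rows belonging to one `sample_id`
#' must form a contiguous, strictly increasing sequence of bins. Values in
#' percent-volume samples that sum to 100 (within 1e-6) are flagged
#' normalized on read.
#'
#' @param path File path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return List of [size_distribution()] objects, one per `sample_id`, in
#'   first-appearance order.
#' @export
read_sizedist_table <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", comment.char = "#")
  missing_cols <- setdiff(.sizedist_cols, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(raw)) {
    stop(sprintf("%s: table has a header but no rows", basename(path)), call. = FALSE)
  }
  raw$bin_lower_um <- .parse_num(raw$bin_lower_um, "bin_lower_um", path)
  raw$bin_upper_um <- .parse_num(raw$bin_upper_um, "bin_upper_um", path)
  raw$value <- .parse_num(raw$value, "value", path)
  has_mass <- "mass_mg" %in% names(raw)

  out <- list()
  for (sid in unique(raw$sample_id)) {
    rows <- raw[raw$sample_id == sid, , drop = FALSE]
    rowno <- which(raw$sample_id == sid)
    o <- order(rows$bin_lower_um)
    rows <- rows[o, , drop = FALSE]
    rowno <- rowno[o]
    lo <- rows$bin_lower_um
    hi <- rows$bin_upper_um
    if (any(hi <= lo)) {
      i <- which(hi <= lo)[1L]
      stop(sprintf("%s: sample '%s' row %d: bin_upper_um (%g) not above bin_lower_um (%g) — non-monotonic bin edges",
                   basename(path), sid, rowno[i], hi[i], lo[i]), call. = FALSE)
    }
    if (length(lo) > 1L && any(abs(lo[-1L] - hi[-length(hi)]) > 1e-9 * max(hi))) {
      i <- which(abs(lo[-1L] - hi[-length(hi)]) > 1e-9 * max(hi))[1L]
      stop(sprintf("%s: sample '%s' row %d: bins not contiguous/ordered (lower %g does not meet previous upper %g)",
                   basename(path), sid, rowno[i + 1L], lo[i + 1L], hi[i]), call. = FALSE)
    }
    if (any(rows$value < 0)) {
      i <- which(rows$value < 0)[1L]
      stop(sprintf("%s: sample '%s' row %d: negative value %g",
                   basename(path), sid, rowno[i], rows$value[i]), call. = FALSE)
    }
    weighting <- unique(rows$weighting)
    if (length(weighting) != 1L) {
      stop(sprintf("%s: sample '%s' mixes weightings (%s)",
                   basename(path), sid, paste(weighting, collapse = ", ")), call. = FALSE)
    }
    if (!weighting %in% c("number_counts", "relative_volume_pct")) {
      stop(sprintf("%s: sample '%s' has unknown weighting '%s'",
                   basename(path), sid, weighting), call. = FALSE)
    }
    mass <- if (has_mass && !is.na(rows$mass_mg[1L]) &&
                nzchar(trimws(rows$mass_mg[1L])) &&
                !identical(trimws(rows$mass_mg[1L]), "NA")) {
      .parse_num(rows$mass_mg[1L], "mass_mg", path)
    } else NA_real_
    normalized <- weighting == "relative_volume_pct" &&
      abs(sum(rows$value) - 100) <= 1e-6
    out[[length(out) + 1L]] <- size_distribution(
      grid = diameter_grid(c(lo, hi[length(hi)])),
      values = rows$value, weighting = weighting,
      sample_id = sid, genotype = rows$genotype[1L],
      timepoint = rows$timepoint[1L],
      replicate = as.integer(rows$replicate[1L]),
      mass_mg = mass, normalized = normalized)
  }
  out
}

#' Write size distributions to the long-format CSV/TSV dialect
#'
#' All distributions must share one grid (mixed grids in one file are an
#' error). The file round-trips through [read_sizedist_table()] with exact
#' metadata and values identical to full double precision.
#'
#' @param dists List of [size_distribution()] objects (a single one may be
#'   passed bare).
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_sizedist_table <- function(dists, path, sep = ",") {
  if (inherits(dists, "size_distribution")) dists <- list(dists)
  if (!length(dists)) {
    stop("refusing to write an empty table: no distributions given", call. = FALSE)
  }
  if (!all(vapply(dists, inherits, logical(1), "size_distribution"))) {
    stop("all elements must be size_distribution objects", call. = FALSE)
  }
  ref <- dists[[1L]]
  for (d in dists[-1L]) {
    if (!grids_identical(ref$grid, d$grid)) {
      stop("mixed diameter grids in one file are not supported", call. = FALSE)
    }
  }
  rows <- do.call(rbind, lapply(dists, function(d) {
    e <- d$grid$edges
    data.frame(sample_id = d$meta$sample_id, genotype = d$meta$genotype,
               timepoint = d$meta$timepoint, replicate = d$meta$replicate,
               weighting = d$weighting, mass_mg = d$mass_mg,
               bin_lower_um = e[-length(e)], bin_upper_um = e[-1L],
               value = d$values, stringsAsFactors = FALSE)
  }))
  utils::write.table(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
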
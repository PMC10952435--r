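#' Locate modes and the inter-peak valley of a size distribution
#'
#' Finds local maxima of the per-bin percent-volume curve whose topographic
#' prominence is at least `prominence_frac` times the global maximum, after
#' light boxcar smoothing (5 bins) to suppress counting noise. In wheat
#' endosperm starch the two retained modes are the B-type peak (c. 6 um in
#' the wild type) and the A-type peak (c. 19 um); the valley between them
#' (c. 10 um) separates the two granule classes.
#'
#' @param d A normalized `relative_volume_pct` [size_distribution()] with
#'   at least 10 bins.
#' @param prominence_frac Minimum prominence as a fraction of the global
#'   maximum (default 0.05).
#' @return List with `modes`, a data.frame of `diameter` (um), `height`
#'   (smoothed % per bin) and `prominence`, sorted by diameter; and
#'   `valley`, the diameter of the minimum between the two most prominent
#'   modes (`NA` if fewer than 2 modes).
#' @export
detect_modes <- function(d, prominence_frac = 0.05) {
  stopifnot(inherits(d, "size_distribution"))
  if (n_bins(d$grid) < 10L) {
    stop("detect_modes needs at least 10 bins", call. = FALSE)
  }
  if (d$weighting != "relative_volume_pct" || !isTRUE(d$normalized)) {
    stop("detect_modes expects a normalized relative_volume_pct distribution",
         call. = FALSE)
  }
  y <- smooth_boxcar(d$values, 5L)
  x <- d$grid$midpoints
  n <- length(y)
  # strict local maxima (plateaus take their first bin)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == n) -Inf else y[i + 1L]
    y[i] > left && y[i] >= right
  }, logical(1))
  idx <- which(is_max)
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= prominence_frac * max(y)
  idx <- idx[keep]
  prom <- prom[keep]
  modes <- data.frame(diameter = x[idx], height = y[idx], prominence = prom)
  modes <- modes[order(modes$diameter), , drop = FALSE]
  rownames(modes) <- NULL
  valley <- NA_real_
  if (nrow(modes) >= 2L) {
    top2 <- modes[order(-modes$prominence)[1:2], "diameter"]
    lo <- which.min(abs(x - min(top2)))
    hi <- which.min(abs(x - max(top2)))
    between <- seq.int(lo, hi)
    valley <- x[between[which.min(y[between])]]
  }
  list(modes = modes, valley = valley)
}

smooth_boxcar <- function(y, width = 5L) {
  if (width <= 1L) return(y)
  half <- width %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# topographic prominence of peak i: walk out each side until a higher
# value or the boundary; the key saddle is the higher of the two minima.
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) {
    left_min <- min(left_min, y[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(y[seq_len(i)])
  right_min <- y[i]
  j <- i + 1L
  while (j <= n && y[j] <= y[i]) {
    right_min <- min(right_min, y[j])
    j <- j + 1L
  }
  if (j > n) right_min <- min(y[i:n])
  y[i] - max(left_min, right_min)
}

new_fit_result <- function(n_components, params, rss, converged, n_bins_used,
                           fitted = NULL) {
  structure(
    list(n_components = as.integer(n_components), params = params,
         rss = rss, converged = isTRUE(converged),
         n_bins_used = as.integer(n_bins_used), fitted = fitted),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d component(s), rss = %.4g, converged = %s\n",
              x$n_components, x$rss, x$converged))
  print(x$params)
  invisible(x)
}

check_fit_input <- function(d) {
  stopifnot(inherits(d, "size_distribution"))
  if (d$weighting != "relative_volume_pct" || !isTRUE(d$normalized)) {
    stop("fitting expects a normalized relative_volume_pct distribution; see normalize_percent()",
         call. = FALSE)
  }
  if (n_bins(d$grid) < 10L) {
    stop("fitting needs at least 10 bins", call. = FALSE)
  }
}

# unconstrained parameterization of the constrained mixture:
# w_B = plogis(t1); mu_A = exp(t2); sigma_A = exp(t3);
# B mean = mu_A * plogis(t4) (ordering constraint holds by construction);
# slog_B = exp(t5); mlog_B = log(B mean) - slog_B^2/2.
theta_to_params <- function(theta) {
  w <- stats::plogis(theta[1L])
  mu <- exp(theta[2L])
  sig <- exp(theta[3L])
  r <- stats::plogis(theta[4L])
  slog <- exp(theta[5L])
  list(w_B = w, mu_A = mu, sigma_A = sig,
       mlog_B = log(mu * r) - slog^2 / 2, slog_B = slog)
}

params_to_theta <- function(p) {
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  r <- clamp(exp(p$mlog_B + p$slog_B^2 / 2) / p$mu_A, 1e-3, 1 - 1e-3)
  c(stats::qlogis(clamp(p$w_B, 1e-4, 1 - 1e-4)), log(p$mu_A), log(p$sigma_A),
    stats::qlogis(r), log(p$slog_B))
}

default_two_component_init <- function(d, prominence_frac = 0.05) {
  det <- detect_modes(d, prominence_frac)
  x <- d$grid$midpoints
  v <- d$values
  if (nrow(det$modes) >= 2L) {
    top2 <- det$modes[order(-det$modes$prominence)[1:2], "diameter"]
    mu_A <- max(top2)
    b_mode <- min(top2)
    w_B <- sum(v[x < det$valley]) / 100
    above <- x >= det$valley
    sigma_A <- sqrt(sum(v[above] * (x[above] - mu_A)^2) / sum(v[above]))
    below <- x < det$valley
    mlogbar <- sum(v[below] * log(x[below])) / sum(v[below])
    slog_B <- sqrt(sum(v[below] * (log(x[below]) - mlogbar)^2) / sum(v[below]))
  } else {
    # unimodal or near-unimodal input: nominal small B component below the mode
    mu_A <- det$modes$diameter[which.max(det$modes$height)]
    b_mode <- mu_A / 2.5
    w_B <- 0.2
    sigma_A <- sqrt(sum(v * (x - mu_A)^2) / sum(v))
    slog_B <- 0.35
  }
  sigma_A <- min(max(sigma_A, 0.3), mu_A / 2)
  slog_B <- min(max(slog_B, 0.1), 0.8)
  w_B <- min(max(w_B, 0.02), 0.95)
  mlog_B <- log(b_mode)   # location seeded at the log of the smaller mode
  if (exp(mlog_B + slog_B^2 / 2) >= 0.95 * mu_A) {
    mlog_B <- log(0.5 * mu_A) - slog_B^2 / 2
  }
  mixture_params(w_B, mu_A, sigma_A, mlog_B, slog_B)
}

fit_objective <- function(d) {
  obs <- d$values
  grid <- d$grid
  penalty <- sum(obs^2) * 1e3
  function(theta) {
    if (any(!is.finite(theta))) return(penalty)
    p <- theta_to_params(theta)
    m <- component_bin_masses(grid, p)
    tot <- (1 - p$w_B) * m$A + p$w_B * m$B
    s <- sum(tot)
    # a line-search step can push all mass off the grid; penalize, don't error
    if (!is.finite(s) || s <= 1e-12) return(penalty)
    sum((obs - 100 * tot / s)^2)
  }
}

#' Fit the two-component (A + B) granule size mixture
#'
#' Minimizes the sum of squared per-bin differences between the observed
#' percent-volume values and the bin-integrated mixture model (normal
#' A-type component plus log-normal B-type component; see
#' [mixture_model_values()]). The ordering constraint (B mean below A mean)
#' is enforced through the optimizer's parameterization, so component
#' labels can never switch. Up to three deterministic starts are tried
#' (the initial guess, then `w_B` shifted by +/- 0.15) before the fit is
#' reported as non-converged.
#'
#' @param d A normalized `relative_volume_pct` [size_distribution()].
#' @param init Optional [mixture_params()] initial guess; by default
#'   derived from [detect_modes()] (A mean from the larger mode, B location
#'   from the log of the smaller mode, `w_B` from the volume fraction below
#'   the valley, spreads from moment heuristics).
#' @param prominence_frac Passed to [detect_modes()] for the default init.
#' @return A `fit_result` with `n_components = 2`, the fitted
#'   [mixture_params()], residual sum of squares `rss`, a `converged`
#'   flag and the fitted per-bin values.
#' @export
fit_two_component <- function(d, init = NULL, prominence_frac = 0.05) {
  check_fit_input(d)
  if (!is.null(init)) {
    viol <- validate_mixture_params(init)
    if (length(viol)) {
      stop("invalid init: ", paste(viol, collapse = "; "), call. = FALSE)
    }
    if (is.na(init$mlog_B) || init$w_B <= 0) {
      stop("init for a two-component fit must have w_B > 0 and B parameters set",
           call. = FALSE)
    }
  } else {
    init <- default_two_component_init(d, prominence_frac)
  }
  obj <- fit_objective(d)
  shift_w <- function(p, dw) {
    p$w_B <- min(max(p$w_B + dw, 0.02), 0.98)
    p
  }
  starts <- list(init, shift_w(init, 0.15), shift_w(init, -0.15))
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(params_to_theta(s), obj, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0L) {
      converged <- TRUE
      best <- if (res$value <= best$value) res else best
      break
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every start", call. = FALSE)
  }
  p <- theta_to_params(best$par)
  params <- mixture_params(p$w_B, p$mu_A, p$sigma_A, p$mlog_B, p$slog_B)
  new_fit_result(2L, params, best$value, converged, n_bins(d$grid),
                 fitted = mixture_model_values(d$grid, params))
}

#' Fit the A-type component alone
#'
#' Same bin-integrated least-squares objective as [fit_two_component()]
#' but with a single normal component (`w_B = 0`, B-type fields `NA`), for
#' distributions measured before B-type granule initiation (12 days after
#' flowering), where only an A-type peak exists.
#'
#' @inheritParams fit_two_component
#' @return A `fit_result` with `n_components = 1`.
#' @export
fit_one_component <- function(d, init = NULL) {
  check_fit_input(d)
  x <- d$grid$midpoints
  v <- d$values
  if (is.null(init)) {
    mu0 <- x[which.max(smooth_boxcar(v, 5L))]
    sig0 <- sqrt(sum(v * (x - mu0)^2) / sum(v))
    sig0 <- min(max(sig0, 0.3), mu0 / 2)
  } else {
    viol <- validate_mixture_params(init)
    if (length(viol)) {
      stop("invalid init: ", paste(viol, collapse = "; "), call. = FALSE)
    }
    mu0 <- init$mu_A
    sig0 <- init$sigma_A
  }
  obs <- v
  grid <- d$grid
  obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 700)) return(sum(obs^2) * 1e3)
    a <- diff(stats::pnorm(grid$edges, exp(theta[1L]), exp(theta[2L])))
    s <- sum(a)
    if (!is.finite(s) || s <= 1e-12) return(sum(obs^2) * 1e3)
    sum((obs - 100 * a / s)^2)
  }
  res <- stats::optim(c(log(mu0), log(sig0)), obj, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  params <- mixture_params(0, exp(res$par[1L]), exp(res$par[2L]))
  new_fit_result(1L, params, res$value, res$convergence == 0L, n_bins(d$grid),
                 fitted = mixture_model_values(d$grid, params))
}

bic_gaussian <- function(rss, n, k) {
  n * log(max(rss, 1e-300) / n) + k * log(n)
}

#' Choose between the one- and two-component fits
#'
#' Returns the two-component fit only when (a) [detect_modes()] finds at
#' least two modes at the given prominence threshold and (b) the
#' two-component fit lowers the BIC (Gaussian-residual approximation, 5 vs
#' 2 parameters). Otherwise the A-only fit is returned. This reproduces,
#' without an eyeball rule, the situation at 12 days after flowering where
#' only A-type granule peaks can be fitted.
#'
#' @inheritParams fit_two_component
#' @return A `fit_result` (either 1 or 2 components).
#' @export
select_model <- function(d, prominence_frac = 0.05) {
  check_fit_input(d)
  det <- detect_modes(d, prominence_frac)
  f1 <- fit_one_component(d)
  if (nrow(det$modes) < 2L) {
    return(f1)
  }
  f2 <- fit_two_component(d, prominence_frac = prominence_frac)
  nb <- n_bins(d$grid)
  if (bic_gaussian(f2$rss, nb, 5L) < bic_gaussian(f1$rss, nb, 2L)) f2 else f1
}

#' Phenotype metrics from a converged fit
#'
#' The A-type mean diameter is the fitted normal mean `mu_A`; the B-type
#' mean diameter is the log-normal mean `exp(mlog_B + slog_B^2/2)`; the
#' B-type granule content is `100 * w_B`, the percentage of total starch
#' volume present as B-type granules. For one-component fits all B-type
#' fields are `NA` ("na" in serialized tables).
#'
#' @param f A converged `fit_result`.
#' @param counts_info Optional: either a single number already expressed as
#'   granules per mg, or a list with `total_count` and `mass_mg` from the
#'   counting measurement.
#' @return Object of class `granule_metrics` with fields
#'   `a_mean_diameter`, `b_mean_diameter`, `b_content_pct`,
#'   `granules_per_mg`.
#' @export
derive_metrics <- function(f, counts_info = NULL) {
  stopifnot(inherits(f, "fit_result"))
  if (!isTRUE(f$converged)) {
    stop("cannot derive metrics from a non-converged fit", call. = FALSE)
  }
  p <- f$params
  gpm <- NA_real_
  if (!is.null(counts_info)) {
    if (is.numeric(counts_info) && length(counts_info) == 1L) {
      gpm <- as.numeric(counts_info)
    } else if (is.list(counts_info)) {
      if (is.null(counts_info$total_count) || is.null(counts_info$mass_mg) ||
          is.na(counts_info$mass_mg) || counts_info$mass_mg <= 0) {
        stop("counts_info needs total_count and a positive mass_mg", call. = FALSE)
      }
      gpm <- counts_info$total_count / counts_info$mass_mg
    } else {
      stop("counts_info must be a number or list(total_count, mass_mg)", call. = FALSE)
    }
  }
  if (f$n_components == 2L) {
    m <- structure(
      list(a_mean_diameter = p$mu_A,
           b_mean_diameter = exp(p$mlog_B + p$slog_B^2 / 2),
           b_content_pct = 100 * p$w_B,
           granules_per_mg = gpm),
      class = "granule_metrics")
    if (m$b_mean_diameter >= m$a_mean_diameter) {
      stop("invariant violated: B mean diameter not below A mean diameter",
           call. = FALSE)
    }
  } else {
    m <- structure(
      list(a_mean_diameter = p$mu_A,
           b_mean_diameter = NA_real_,
           b_content_pct = NA_real_,
           granules_per_mg = gpm),
      class = "granule_metrics")
  }
  m
}

#' @export
print.granule_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "na" else sprintf("%.4g", v)
  cat(sprintf("<granule_metrics> A mean %s um | B mean %s um | B content %s%% | %s granules/mg\n",
              fmt(x$a_mean_diameter), fmt(x$b_mean_diameter),
              fmt(x$b_content_pct), fmt(x$granules_per_mg)))
  invisible(x)
}

#' Percent change of a mutant value relative to a reference
#'
#' @param mutant_value,wt_value Numeric values; `wt_value` must be nonzero.
#' @return `100 * (mutant_value - wt_value) / wt_value`.
#' @examples
#' percent_change(23, 19)  # +21.05
#' @export
percent_change <- function(mutant_value, wt_value) {
  if (any(wt_value == 0)) {
    stop("reference value must be nonzero", call. = FALSE)
  }
  100 * (mutant_value - wt_value) / wt_value
}

#' Flatten a fit and its metrics to one table row
#'
#' @param f A `fit_result`.
#' @param metrics A [derive_metrics()] result (optional; derived on the fly
#'   for converged fits).
#' @param meta Optional metadata list (`sample_id`, `genotype`,
#'   `timepoint`, `replicate`).
#' @return A one-row [tibble::tibble] with metadata, `n_components`, the
#'   five mixture parameters, `rss`, `converged` and the four phenotype
#'   metrics (`NA` where not applicable).
#' @export
fit_to_row <- function(f, metrics = NULL, meta = NULL) {
  stopifnot(inherits(f, "fit_result"))
  if (is.null(metrics) && isTRUE(f$converged)) metrics <- derive_metrics(f)
  p <- f$params
  tibble::tibble(
    sample_id = meta$sample_id %||% NA_character_,
    genotype = meta$genotype %||% NA_character_,
    timepoint = meta$timepoint %||% NA_character_,
    replicate = meta$replicate %||% NA_integer_,
    n_components = f$n_components,
    w_B = p$w_B, mu_A = p$mu_A, sigma_A = p$sigma_A,
    mlog_B = p$mlog_B, slog_B = p$slog_B,
    rss = f$rss, converged = f$converged,
    a_mean_diameter = metrics$a_mean_diameter %||% NA_real_,
    b_mean_diameter = metrics$b_mean_diameter %||% NA_real_,
    b_content_pct = metrics$b_content_pct %||% NA_real_,
    granules_per_mg = metrics$granules_per_mg %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
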
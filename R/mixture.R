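#' Parameters of the normal + log-normal granule size mixture
#'
#' The volume-weighted granule size density is modelled as a two-component
#' mixture: a normal component for the large A-type granule peak and a
#' log-normal component for the small B-type granule peak,
#' \deqn{f(x) = (1 - w_B)\, N(x;\, \mu_A, \sigma_A) + w_B\, LogN(x;\, m_B, s_B),}
#' with the identifiability constraint that the B-component mean diameter
#' `exp(mlog_B + slog_B^2/2)` lies below the A-component mean `mu_A`.
#' `w_B` is the B-type volume fraction (B-type granule content / 100).
#'
#' @param w_B B-type volume fraction in \[0, 1\].
#' @param mu_A A-component mean diameter (um), positive.
#' @param sigma_A A-component standard deviation (um), positive.
#' @param mlog_B Log-normal location (log um); `NA` allowed when `w_B = 0`.
#' @param slog_B Log-normal scale (log um), positive; `NA` allowed when
#'   `w_B = 0`.
#' @return Object of class `mixture_params`.
#' @export
mixture_params <- function(w_B, mu_A, sigma_A, mlog_B = NA_real_, slog_B = NA_real_) {
  p <- structure(
    list(w_B = as.numeric(w_B), mu_A = as.numeric(mu_A),
         sigma_A = as.numeric(sigma_A), mlog_B = as.numeric(mlog_B),
         slog_B = as.numeric(slog_B)),
    class = "mixture_params"
  )
  viol <- validate_mixture_params(p)
  if (length(viol)) {
    stop("invalid mixture_params: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  p
}

#' Check mixture parameters against their invariants
#'
#' @param p A `mixture_params`-like list.
#' @return Character vector of violations (empty when valid).
#' @export
validate_mixture_params <- function(p) {
  v <- character()
  if (is.na(p$w_B) || p$w_B < 0 || p$w_B > 1) v <- c(v, "w_B must lie in [0, 1]")
  if (is.na(p$mu_A) || p$mu_A <= 0) v <- c(v, "mu_A must be positive")
  if (is.na(p$sigma_A) || p$sigma_A <= 0) v <- c(v, "sigma_A must be positive")
  has_B <- !is.na(p$w_B) && p$w_B > 0
  if (has_B) {
    if (is.na(p$mlog_B)) v <- c(v, "mlog_B required when w_B > 0")
    if (is.na(p$slog_B) || p$slog_B <= 0) {
      v <- c(v, "slog_B must be positive when w_B > 0")
    }
    if (!is.na(p$mlog_B) && !is.na(p$slog_B) && p$slog_B > 0 &&
        !is.na(p$mu_A) && exp(p$mlog_B + p$slog_B^2 / 2) >= p$mu_A) {
      v <- c(v, sprintf("component ordering violated: B mean %.4g not below A mean %.4g",
                        exp(p$mlog_B + p$slog_B^2 / 2), p$mu_A))
    }
  }
  v
}

#' @export
print.mixture_params <- function(x, ...) {
  if (!is.na(x$w_B) && x$w_B > 0) {
    cat(sprintf("<mixture_params> A: N(%.3g, %.3g um); B: LogN(mean %.3g um, slog %.3g); w_B = %.3f\n",
                x$mu_A, x$sigma_A, exp(x$mlog_B + x$slog_B^2 / 2), x$slog_B, x$w_B))
  } else {
    cat(sprintf("<mixture_params> A only: N(%.3g, %.3g um)\n", x$mu_A, x$sigma_A))
  }
  invisible(x)
}

#' Convenience constructor from component mean diameters
#'
#' Parameterizes the B component by its mean diameter rather than the
#' log-normal location: `mlog_B = log(b_mean) - slog_B^2 / 2`.
#'
#' @param a_mean,b_mean Component mean diameters (um); `b_mean = NA` gives
#'   an A-only model (`w_B` forced 0).
#' @param w_B B-type volume fraction.
#' @param sigma_A,slog_B Component spreads.
#' @return A [mixture_params()].
#' @export
mixture_from_means <- function(a_mean, b_mean = NA_real_, w_B = 0,
                               sigma_A = 3.5, slog_B = 0.35) {
  if (is.na(b_mean) || w_B == 0) {
    mixture_params(0, a_mean, sigma_A)
  } else {
    mixture_params(w_B, a_mean, sigma_A, log(b_mean) - slog_B^2 / 2, slog_B)
  }
}

# Per-bin probability masses of each component between bin edges.
# Integrals are exact (distribution-function differences), never midpoint
# density evaluations.
component_bin_masses <- function(grid, p) {
  e <- grid$edges
  a <- diff(stats::pnorm(e, mean = p$mu_A, sd = p$sigma_A))
  if (!is.na(p$w_B) && p$w_B > 0) {
    b <- diff(stats::plnorm(e, meanlog = p$mlog_B, sdlog = p$slog_B))
  } else {
    b <- rep(0, length(a))
  }
  list(A = a, B = b)
}

#' Model curve of the mixture on a diameter grid
#'
#' Per-bin percent volume implied by mixture parameters: component masses
#' are integrated between bin edges, combined with weights `(1 - w_B, w_B)`
#' and rescaled to sum 100 over the grid (truncated-mixture convention, so
#' the model lives on the same scale as a normalized measurement; mass
#' outside the measured range, always well under 1% for realistic granule
#' parameters, is folded back proportionally).
#'
#' @param grid A [diameter_grid()].
#' @param p A [mixture_params()].
#' @return Numeric vector of per-bin percent values summing to 100.
#' @export
mixture_model_values <- function(grid, p) {
  m <- component_bin_masses(grid, p)
  tot <- (1 - p$w_B) * m$A + p$w_B * m$B
  s <- sum(tot)
  if (s <= 0) {
    stop("mixture has no mass on the grid: peaks lie outside the measured range",
         call. = FALSE)
  }
  100 * tot / s
}
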
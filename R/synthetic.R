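# Seeded synthetic granule populations emulating Coulter-counter
# measurements. Presets parameterize the volume-weighted mixture directly
# (the representation in which granule phenotypes are reported); the
# number-weighted view is derived from it, avoiding a non-closed-form
# d^3-weighting of the normal A component.

#' Names of the built-in population presets
#'
#' Wild-type and plastid-division-mutant granule populations at three
#' developmental stages: 12 days after flowering (A-type granules only,
#' before B-type initiation), 16 days after flowering (B-type granules
#' newly initiated) and mature grain.
#'
#' @return Character vector of valid preset names.
#' @export
preset_names <- function() {
  c("WT_mature", "parc6_mature", "WT_12DAF", "parc6_12DAF",
    "WT_16DAF", "parc6_16DAF")
}

#' Synthetic granule population specification
#'
#' @param params A [mixture_params()] describing the volume-weighted
#'   mixture.
#' @param total_granules Number of granules counted per measurement
#'   (>= 1000).
#' @param grid A [diameter_grid()] for the emulated instrument.
#' @param replicate_jitter_cv Coefficient of variation of the log-normal
#'   jitter applied to component location parameters across biological
#'   replicates (0-0.2).
#' @param density_g_cm3 Starch density used to link granule volume to
#'   starch mass (literature value 1.5 g cm^-3).
#' @param genotype,timepoint,name Metadata labels attached to generated
#'   samples.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(params, total_granules = 1e5L,
                            grid = log_diameter_grid(300L, 2, 60),
                            replicate_jitter_cv = 0.03,
                            density_g_cm3 = 1.5,
                            genotype = "unknown", timepoint = "unknown",
                            name = NA_character_) {
  viol <- validate_mixture_params(params)
  if (length(viol)) {
    stop("invalid mixture params: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  if (total_granules < 1e3) {
    stop("total_granules must be at least 1000", call. = FALSE)
  }
  if (replicate_jitter_cv < 0 || replicate_jitter_cv > 0.2) {
    stop("replicate_jitter_cv must lie in [0, 0.2]", call. = FALSE)
  }
  if (density_g_cm3 <= 0) {
    stop("density_g_cm3 must be positive", call. = FALSE)
  }
  structure(
    list(params = params, total_granules = as.integer(total_granules),
         grid = grid, replicate_jitter_cv = replicate_jitter_cv,
         density_g_cm3 = density_g_cm3, genotype = genotype,
         timepoint = timepoint, name = name),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s (%s, %s): %d granules, jitter cv %.3g\n",
              x$name, x$genotype, x$timepoint, x$total_granules,
              x$replicate_jitter_cv))
  print(x$params)
  invisible(x)
}

#' Built-in granule population presets
#'
#' Point values anchor the volume-weighted mixture at the mid-points of
#' reported phenotype ranges: wild-type mature grain has its A-type peak
#' near 19 um, B-type mean near 6 um and B-type content 40%; the
#' plastid-division mutant shifts these to 23 um, 8.75 um and 70%. At 12
#' days after flowering only A-type granules exist (mean 14.0 um wild
#' type, 14.4 um mutant). At 16 days after flowering the mutant's A mean
#' is 5% above wild type and its B content 98% above; the 16-DAF wild-type
#' anchors (A mean 16 um, B content 15%) and all spreads (`sigma_A` 3.5
#' um, `slog_B` 0.35) are package choices, not measured values.
#'
#' @param name One of [preset_names()].
#' @param ... Overrides passed to [population_spec()] (e.g.
#'   `total_granules`, `grid`, `replicate_jitter_cv`).
#' @return A [population_spec()].
#' @export
make_preset <- function(name, ...) {
  if (length(name) != 1L || !name %in% preset_names()) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 paste(name, collapse = ","),
                 paste(preset_names(), collapse = ", ")), call. = FALSE)
  }
  anchors <- list(
    WT_mature    = list(a = 19.0,  b = 6.0,  w = 0.40,  slog = 0.35),
    parc6_mature = list(a = 23.0,  b = 8.75, w = 0.70,  slog = 0.35),
    WT_12DAF     = list(a = 14.0,  b = NA,   w = 0,     slog = 0.35),
    parc6_12DAF  = list(a = 14.4,  b = NA,   w = 0,     slog = 0.35),
    # newly initiated B-type granules: smaller and more uniform than mature
    WT_16DAF     = list(a = 16.0,  b = 5.0,  w = 0.15,  slog = 0.25),
    parc6_16DAF  = list(a = 16.0 * 1.05, b = 5.5, w = 0.15 * 1.98, slog = 0.25)
  )[[name]]
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  population_spec(
    params = mixture_from_means(anchors$a, anchors$b, anchors$w,
                                slog_B = anchors$slog),
    genotype = parts[1L], timepoint = parts[2L], name = name, ...)
}

#' Noiseless expected volume-weighted density of a population
#'
#' Bin-integrated mixture volume density on the spec's grid, normalized to
#' sum 100. Errors when a component would lose more than 1% of its mass to
#' truncation (peak too far outside the measured diameter range).
#'
#' @param spec A [population_spec()].
#' @return A normalized `relative_volume_pct` [size_distribution()].
#' @export
expected_volume_density <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  m <- component_bin_masses(spec$grid, spec$params)
  if (sum(m$A) < 0.99) {
    stop(sprintf("A-type peak truncated: only %.1f%% of its mass lies on the grid",
                 100 * sum(m$A)), call. = FALSE)
  }
  if (spec$params$w_B > 0 && sum(m$B) < 0.99) {
    stop(sprintf("B-type peak truncated: only %.1f%% of its mass lies on the grid",
                 100 * sum(m$B)), call. = FALSE)
  }
  size_distribution(spec$grid, mixture_model_values(spec$grid, spec$params),
                    "relative_volume_pct",
                    sample_id = paste0(spec$genotype, "_", spec$timepoint, "_expected"),
                    genotype = spec$genotype, timepoint = spec$timepoint,
                    normalized = TRUE)
}

# evaluate code under a given RNG seed without disturbing the caller's
# random state
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    stop("an explicit seed is required: synthetic sampling has no implicit global randomness",
         call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# fixed sub-seed arithmetic: adding replicates never perturbs earlier ones
sub_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + r * 7919) %% 2147483647L
}

#' Draw one binned Coulter-counter measurement
#'
#' Converts the expected volume density to expected per-bin number
#' proportions (division by midpoint diameter cubed) and draws the spec's
#' total granule count as a single multinomial realization. Deterministic
#' per (spec, seed). The realized starch mass (mg) implied by the sampled
#' counts and the spec's starch density is attached as `mass_mg`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed (mandatory).
#' @return A `number_counts` [size_distribution()]; counts sum exactly to
#'   `spec$total_granules`.
#' @export
sample_binned_counts <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed)) {
    stop("an explicit seed is required: synthetic sampling has no implicit global randomness",
         call. = FALSE)
  }
  vol <- expected_volume_density(spec)
  w <- vol$values / spec$grid$midpoints^3
  p <- w / sum(w)
  counts <- with_seed(seed, as.numeric(stats::rmultinom(1L, spec$total_granules, p)))
  mass_mg <- sum(counts * sphere_volume(spec$grid$midpoints)) *
    spec$density_g_cm3 * 1e-9  # um^3 * g cm^-3 -> mg
  size_distribution(spec$grid, counts, "number_counts",
                    sample_id = paste0(spec$genotype, "_", spec$timepoint, "_counts"),
                    genotype = spec$genotype, timepoint = spec$timepoint,
                    mass_mg = mass_mg)
}

#' Simulate a biological replicate set
#'
#' Each replicate multiplies the component location parameters (`mu_A`,
#' and `exp(mlog_B)` when a B component exists) by independent log-normal
#' jitter factors with mean 1 and coefficient of variation
#' `replicate_jitter_cv` (plant-to-plant variation), then draws a
#' multinomial measurement and converts it to normalized percent volume.
#' Sub-seeds are derived from the master seed by fixed arithmetic, one per
#' replicate.
#'
#' @param spec A [population_spec()].
#' @param n_reps Number of biological replicates (>= 2).
#' @param seed Master integer seed (mandatory).
#' @return A [replicate_set()] of normalized `relative_volume_pct`
#'   distributions with `mass_mg` set from the sampled counts.
#' @export
simulate_replicate_set <- function(spec, n_reps = 3L, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed)) {
    stop("an explicit seed is required: synthetic sampling has no implicit global randomness",
         call. = FALSE)
  }
  if (n_reps < 2L) {
    stop("n_reps must be at least 2", call. = FALSE)
  }
  cv <- spec$replicate_jitter_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  dists <- lapply(seq_len(n_reps), function(r) {
    s <- sub_seed(seed, r)
    jit <- with_seed(s, {
      if (sdlog > 0) stats::rlnorm(2L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else c(1, 1)
    })
    p <- spec$params
    jp <- if (p$w_B > 0) {
      mixture_params(p$w_B, p$mu_A * jit[1L], p$sigma_A,
                     p$mlog_B + log(jit[2L]), p$slog_B)
    } else {
      mixture_params(0, p$mu_A * jit[1L], p$sigma_A)
    }
    rspec <- spec
    rspec$params <- jp
    counts <- sample_binned_counts(rspec, seed = sub_seed(s, 1L))
    v <- number_to_volume(counts)
    size_distribution(v$grid, v$values, "relative_volume_pct",
                      sample_id = sprintf("%s_%s_r%d", spec$genotype, spec$timepoint, r),
                      genotype = spec$genotype, timepoint = spec$timepoint,
                      replicate = r, mass_mg = counts$mass_mg, normalized = TRUE)
  })
  replicate_set(dists)
}
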
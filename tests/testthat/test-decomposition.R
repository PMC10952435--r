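wt_params <- function() {
  mixture_params(0.40, 19, 3.5, log(6) - 0.35^2 / 2, 0.35)
}

analytic_dist <- function(p, n = 300, d_min = 2, d_max = 60) {
  g <- log_diameter_grid(n, d_min, d_max)
  size_distribution(g, mixture_model_values(g, p), "relative_volume_pct",
                    normalized = TRUE)
}

test_that("mode detection finds the A- and B-type peaks of the wild-type mixture", {
  d <- analytic_dist(wt_params())
  det <- detect_modes(d)
  expect_equal(nrow(det$modes), 2)
  # larger-diameter mode within a few bins of 19 um (log bin width ~1.14%;
  # smoothing and the B-component tail shift the mixture argmax slightly)
  expect_lt(abs(log(det$modes$diameter[2] / 19)), 3 * log(60 / 2) / 300)
  expect_true(det$modes$diameter[1] < 10 && det$valley > det$modes$diameter[1] &&
                det$valley < det$modes$diameter[2])
})

test_that("mode detection: unimodal input gives one mode, faint peaks are filtered", {
  one <- analytic_dist(mixture_params(0, 14, 3.5))
  det <- detect_modes(one)
  expect_equal(nrow(det$modes), 1)
  expect_true(is.na(det$valley))

  faint <- analytic_dist(mixture_params(0.01, 19, 3.5, log(6), 0.35))
  expect_equal(nrow(detect_modes(faint, prominence_frac = 0.05)$modes), 1)

  expect_error(detect_modes(tiny_volume_dist(rep(1, 5))), "10 bins")
})

test_that("noiseless two-component fit recovers all five parameters within 0.1%", {
  p <- wt_params()
  f <- fit_two_component(analytic_dist(p))
  expect_true(f$converged)
  expect_lt(f$rss, 1e-8)
  expect_lt(abs(f$params$mu_A - p$mu_A) / p$mu_A, 1e-3)
  expect_lt(abs(f$params$sigma_A - p$sigma_A) / p$sigma_A, 1e-3)
  expect_lt(abs(f$params$mlog_B - p$mlog_B) / abs(p$mlog_B), 1e-3)
  expect_lt(abs(f$params$slog_B - p$slog_B) / p$slog_B, 1e-3)
  expect_lt(abs(f$params$w_B - p$w_B) / p$w_B, 1e-3)
})

test_that("noiseless recovery holds across random well-separated mixtures", {
  set.seed(5)
  for (i in 1:5) {
    mu <- runif(1, 16, 26)
    sig <- runif(1, 2.5, 4.5)
    b_mean <- runif(1, 5, 9)
    w <- runif(1, 0.2, 0.75)
    slog <- runif(1, 0.25, 0.45)
    p <- mixture_params(w, mu, sig, log(b_mean) - slog^2 / 2, slog)
    f <- fit_two_component(analytic_dist(p))
    expect_lt(abs(f$params$mu_A - mu) / mu, 1e-3)
    expect_lt(abs(f$params$w_B - w) / w, 1e-3)
    expect_lt(abs(exp(f$params$mlog_B + f$params$slog_B^2 / 2) - b_mean) / b_mean,
              1e-3)
  }
})

test_that("stochastic fit at 1e5 granules recovers mu_A within 2% and w_B within 0.03", {
  spec <- make_preset("WT_mature", replicate_jitter_cv = 0)
  d <- number_to_volume(sample_binned_counts(spec, seed = 77))
  f <- fit_two_component(d)
  expect_true(f$converged)
  expect_lt(abs(f$params$mu_A - 19) / 19, 0.02)
  expect_lt(abs(f$params$w_B - 0.40), 0.03)
})

test_that("an invalid init is rejected before optimization", {
  d <- analytic_dist(wt_params())
  bad <- unclass(wt_params())
  bad$sigma_A <- -1
  class(bad) <- "mixture_params"
  expect_error(fit_two_component(d, init = bad), "sigma_A")
  # ordering violation: B mean above A mean
  bad2 <- unclass(wt_params())
  bad2$mlog_B <- log(25)
  class(bad2) <- "mixture_params"
  expect_error(fit_two_component(d, init = bad2), "ordering")
})

test_that("one-component fit recovers a pure normal and loses to two on bimodal data", {
  one <- analytic_dist(mixture_params(0, 14, 3.5))
  f1 <- fit_one_component(one)
  expect_true(f1$converged)
  expect_lt(abs(f1$params$mu_A - 14), 0.01)
  # symmetric input: fitted mean matches the density-per-um mode bin within
  # one bin width (per-bin mass peaks above the mean on a log-spaced grid)
  dens <- one$values / diff(one$grid$edges)
  mode_mid <- one$grid$midpoints[which.max(dens)]
  bin_w <- diff(one$grid$edges)[which.max(dens)]
  expect_lt(abs(f1$params$mu_A - mode_mid), bin_w)

  bim <- analytic_dist(wt_params())
  fa <- fit_one_component(bim)
  fb <- fit_two_component(bim)
  expect_true(fa$converged && fb$converged)
  expect_gt(fa$rss, fb$rss)  # nested-model property
})

test_that("model selection: bimodal mature data get 2 components, A-only data get 1", {
  f2 <- select_model(analytic_dist(wt_params()))
  expect_equal(f2$n_components, 2)

  f1 <- select_model(analytic_dist(mixture_params(0, 14, 3.5)))
  expect_equal(f1$n_components, 1)
  expect_equal(f1$params$w_B, 0)
  expect_true(is.na(f1$params$mlog_B))

  # vanishing B component is folded into the A-only model by the prominence rule
  tiny_b <- analytic_dist(mixture_params(0.005, 19, 3.5, log(6), 0.35))
  expect_equal(select_model(tiny_b)$n_components, 1)
})

test_that("derived metrics follow the fitted parameters, with na for A-only fits", {
  f <- fit_two_component(analytic_dist(wt_params()))
  m <- derive_metrics(f)
  expect_equal(m$b_content_pct, 40, tolerance = 1e-3)
  expect_equal(m$b_mean_diameter, 6, tolerance = 1e-3)  # log-normal mean identity
  expect_equal(m$a_mean_diameter, f$params$mu_A)
  expect_lt(m$b_mean_diameter, m$a_mean_diameter)
  expect_true(is.na(m$granules_per_mg))
  m2 <- derive_metrics(f, counts_info = list(total_count = 1e5, mass_mg = 0.05))
  expect_equal(m2$granules_per_mg, 2e6)

  f1 <- fit_one_component(analytic_dist(mixture_params(0, 14, 3.5)))
  m1 <- derive_metrics(f1)
  expect_true(is.na(m1$b_mean_diameter) && is.na(m1$b_content_pct))
  expect_equal(m1$a_mean_diameter, f1$params$mu_A)

  bad <- f
  bad$converged <- FALSE
  expect_error(derive_metrics(bad), "non-converged")
})

test_that("percent change is the plain relative difference in percent", {
  expect_equal(percent_change(19, 19), 0)
  expect_equal(percent_change(23, 19), 100 * 4 / 19)
  expect_error(percent_change(5, 0), "nonzero")
})

test_that("mutant presets run end-to-end show larger A, B diameters and B content than wild type", {
  wt <- derive_metrics(fit_two_component(
    number_to_volume(sample_binned_counts(
      make_preset("WT_mature", replicate_jitter_cv = 0), seed = 31))))
  mut <- derive_metrics(fit_two_component(
    number_to_volume(sample_binned_counts(
      make_preset("parc6_mature", replicate_jitter_cv = 0), seed = 31))))
  expect_gt(percent_change(mut$a_mean_diameter, wt$a_mean_diameter), 0)
  expect_gt(percent_change(mut$b_mean_diameter, wt$b_mean_diameter), 0)
  expect_gt(percent_change(mut$b_content_pct, wt$b_content_pct), 0)
})

test_that("the optimizer beats a 5-point-per-parameter grid search on a coarse fixture", {
  p <- wt_params()
  d <- analytic_dist(p, n = 50)
  f <- fit_two_component(d)
  obs <- d$values
  grid_rss <- Inf
  for (w in seq(0.2, 0.6, length.out = 5))
    for (mu in seq(15, 25, length.out = 5))
      for (sig in seq(2, 5, length.out = 5))
        for (bm in seq(4, 9, length.out = 5))
          for (sl in seq(0.2, 0.5, length.out = 5)) {
            cand <- mixture_params(w, mu, sig, log(bm) - sl^2 / 2, sl)
            rss <- sum((obs - mixture_model_values(d$grid, cand))^2)
            grid_rss <- min(grid_rss, rss)
          }
  expect_lte(f$rss, grid_rss)
})

test_that("model values conserve mass and fits never swap component labels", {
  g <- log_diameter_grid(300, 2, 60)
  expect_lt(abs(sum(mixture_model_values(g, wt_params())) - 100), 1e-9)
  set.seed(9)
  for (i in 1:5) {
    spec <- make_preset(sample(c("WT_mature", "parc6_mature", "WT_16DAF"), 1))
    d <- number_to_volume(sample_binned_counts(spec, seed = i))
    f <- fit_two_component(d)
    expect_lt(exp(f$params$mlog_B + f$params$slog_B^2 / 2), f$params$mu_A)
  }
})
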
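test_that("sphere_volume follows pi d^3 / 6 with cubic scaling", {
  expect_equal(sphere_volume(2), pi * 8 / 6)
  expect_equal(sphere_volume(1), pi / 6)
  expect_equal(sphere_volume(10) / sphere_volume(5), 8)
  expect_error(sphere_volume(0), "positive")
  expect_error(sphere_volume(-3), "positive")
})

test_that("number-to-volume weighting: 8 small granules balance 1 at twice the diameter", {
  # geometric midpoints 1 and 2 um
  grid <- diameter_grid(c(2 / 3, 1.5, 8 / 3))
  expect_equal(grid$midpoints, c(1, 2))
  d <- size_distribution(grid, c(8, 1), "number_counts")
  v <- number_to_volume(d)
  expect_equal(v$values, c(50, 50))
  expect_true(v$normalized)

  single <- size_distribution(grid, c(0, 7), "number_counts")
  expect_equal(number_to_volume(single)$values, c(0, 100))
  expect_error(number_to_volume(size_distribution(grid, c(0, 0), "number_counts")),
               "all-zero")
})

test_that("volume_to_number inverts number_to_volume and preserves proportions", {
  grid <- diameter_grid(c(2 / 3, 1.5, 8 / 3))
  v <- size_distribution(grid, c(50, 50), "relative_volume_pct", normalized = TRUE)
  n <- volume_to_number(v, total_count = 9)
  expect_equal(n$values, c(8, 1))

  # round-trip property on random fixtures
  set.seed(11)
  g <- log_diameter_grid(40, 2, 60)
  for (i in 1:10) {
    counts <- rgamma(40, shape = 0.8) * 100
    d <- size_distribution(g, counts, "number_counts")
    back <- volume_to_number(number_to_volume(d), total_count = sum(counts))
    expect_lt(max(abs(back$values - counts)), 1e-9 * max(counts))
  }
  expect_error(volume_to_number(size_distribution(g, rep(0, 40),
                                                  "relative_volume_pct"), 10),
               "zero-sum")
})

test_that("normalize_percent scales to 100, idempotently", {
  g <- diameter_grid(c(2, 4, 8, 16))
  d <- size_distribution(g, c(1, 1, 2), "relative_volume_pct")
  nd <- normalize_percent(d)
  expect_equal(nd$values, c(25, 25, 50))
  expect_true(nd$normalized)
  expect_equal(normalize_percent(nd)$values, nd$values, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:10) {
    d <- size_distribution(g, runif(3, 0.01, 5), "relative_volume_pct")
    expect_lt(abs(sum(normalize_percent(d)$values) - 100), 1e-9)
  }
  expect_error(normalize_percent(size_distribution(g, c(0, 0, 0),
                                                   "relative_volume_pct")),
               "zero-sum")
})

test_that("weighting equivalence: binned counts of discrete diameters match direct d^3 accumulation", {
  g <- log_diameter_grid(30, 2, 60)
  set.seed(21)
  counts <- rpois(30, 40)
  # a discrete granule list sitting exactly at the bin midpoints
  diameters <- rep(g$midpoints, counts)
  direct <- vapply(seq_len(30), function(i) {
    sum(diameters[diameters == g$midpoints[i]]^3)
  }, numeric(1))
  direct <- 100 * direct / sum(direct)
  via_counts <- number_to_volume(size_distribution(g, counts, "number_counts"))
  expect_lt(max(abs(via_counts$values - direct)), 1e-9)
})

test_that("granules_per_mg is total counts over mass, linear in counts", {
  g <- diameter_grid(c(5, 20))
  d <- size_distribution(g, 5000, "number_counts", mass_mg = 0.01)
  expect_equal(granules_per_mg(d), 5e5)
  d2 <- size_distribution(g, 10000, "number_counts", mass_mg = 0.01)
  expect_equal(granules_per_mg(d2), 2 * granules_per_mg(d))
  expect_error(granules_per_mg(size_distribution(g, 5000, "number_counts")),
               "mass_mg")
})

test_that("a million 10-um granules at starch density 1.5 imply 0.785 mg and 1.273e6 per mg", {
  # hand arithmetic: V = pi*1000/6 um^3; mass = 1e6 V * 1.5 g/cm^3 = 0.7854 mg
  g <- diameter_grid(c(5, 20))  # geometric midpoint 10 um
  expect_equal(g$midpoints, 10)
  mass_mg <- 1e6 * sphere_volume(10) * 1.5 * 1e-9
  expect_equal(mass_mg, 0.7853982, tolerance = 1e-6)
  d <- size_distribution(g, 1e6, "number_counts", mass_mg = mass_mg)
  expect_equal(granules_per_mg(d), 1.2732395e6, tolerance = 1e-6)
})

test_that("replicate aggregation gives per-bin mean and n-1 standard error", {
  g <- diameter_grid(c(2, 6, 18))
  mk <- function(vals, r) size_distribution(g, vals, "relative_volume_pct",
                                            replicate = r, normalized = TRUE)
  same <- replicate_set(list(mk(c(40, 60), 1), mk(c(40, 60), 2)))
  agg <- aggregate_replicates(same)
  expect_equal(agg$se, c(0, 0))

  rs <- replicate_set(list(mk(c(10, 90), 1), mk(c(20, 80), 2)))
  agg <- aggregate_replicates(rs)
  expect_equal(agg$mean, c(15, 85))
  expect_equal(agg$se, c(5, 5))
  expect_equal(agg$n, 2)

  other <- size_distribution(diameter_grid(c(2, 7, 18)), c(10, 90),
                             "relative_volume_pct", replicate = 3,
                             normalized = TRUE)
  expect_error(replicate_set(list(mk(c(10, 90), 1), other)), "grid")
  expect_error(replicate_set(list(mk(c(10, 90), 1), mk(c(20, 80), 1))),
               "unique")
})

test_that("the mean curve of simulated wild-type replicates is bimodal near the generator peaks", {
  spec <- make_preset("WT_mature")
  rs <- simulate_replicate_set(spec, 3, seed = 101)
  agg <- aggregate_replicates(rs)
  expect_true(any(agg$se > 0))
  mean_dist <- normalize_percent(
    size_distribution(agg$grid, agg$mean, "relative_volume_pct"))
  det <- detect_modes(mean_dist)
  expect_gte(nrow(det$modes), 2)
  top2 <- det$modes[order(-det$modes$prominence)[1:2], "diameter"]
  expect_lt(abs(max(top2) - 19) / 19, 0.08)   # A-type peak near 19 um
  expect_gt(min(top2), 4.5)                   # B-type peak near its density mode
  expect_lt(min(top2), 7)
})
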
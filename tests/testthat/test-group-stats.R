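test_that("one-way ANOVA matches the textbook F computation and handles degeneracy", {
  expect_equal(one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))$statistic, 0)

  deg <- one_way_anova(list(a = c(0, 0), b = c(1, 1)))
  expect_true(deg$degenerate)
  expect_lt(deg$p.value, 1e-12)

  same <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_true(same$degenerate)
  expect_equal(same$p.value, 1)

  set.seed(8)
  g <- list(a = rnorm(4, 10), b = rnorm(5, 11), c = rnorm(3, 9))
  res <- one_way_anova(g)
  expect_equal(res$statistic, oracle_anova_f(g), tolerance = 1e-12)
  expect_equal(res$p.value,
               pf(oracle_anova_f(g), 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis H equals the hand formula and is rank-invariant", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, 3.857, tolerance = 5e-4)
  expect_equal(res$statistic, oracle_kw_h(g), tolerance = 1e-12)

  set.seed(14)
  g3 <- list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(4, 2))
  h0 <- kruskal_wallis(g3)$statistic
  # permuting labels of the same pooled data only reshuffles group sums
  perm <- list(a = g3$a[c(2, 1, 4, 3)], b = g3$b, c = g3$c)
  expect_equal(kruskal_wallis(perm)$statistic, h0)
  # monotone transforms leave ranks unchanged
  mono <- lapply(g3, function(v) exp(v) + 5)
  expect_equal(kruskal_wallis(mono)$statistic, h0)

  flat <- kruskal_wallis(list(a = c(3, 3), b = c(3, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
})

test_that("Tukey all-pairs: k = 2 reduces to the pooled t-test and matches ptukey by hand", {
  set.seed(31)
  a <- rnorm(5, 10)
  b <- rnorm(5, 11)
  pmat <- tukey_all_pairs(list(a = a, b = b))
  pooled <- t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(pmat["a", "b"], pooled, tolerance = 1e-9)

  same <- tukey_all_pairs(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same["a", "b"], 1)

  g <- list(a = rnorm(4, 10), b = rnorm(4, 12), c = rnorm(4, 10.5))
  pm <- tukey_all_pairs(g)
  expect_equal(pm, t(pm))
  expect_equal(diag(pm), c(a = 1, b = 1, c = 1))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(pm[i, j], oracle_tukey_pair(g, i, j), tolerance = 1e-9)
    # adjusted p never below the unadjusted pooled-MSE t p
    n <- length(unlist(g))
    mse <- sum(unlist(lapply(g, function(v) (v - mean(v))^2))) / (n - 3)
    tstat <- abs(mean(g[[i]]) - mean(g[[j]])) / sqrt(mse * (1 / 4 + 1 / 4))
    expect_gte(pm[i, j] + 1e-12, 2 * pt(-tstat, n - 3))
  }
})

test_that("rank-based all-pairs procedure is symmetric, unit-diagonal and sane", {
  set.seed(44)
  g <- list(a = rnorm(4), b = rnorm(4, 3), c = rnorm(4, 6))
  pm <- kw_all_pairs(g)
  expect_equal(pm, t(pm))
  expect_equal(unname(diag(pm)), rep(1, 3))
  # clearly separated extreme groups are the most significant pair
  expect_lt(pm["a", "c"], pm["a", "b"])
  expect_lt(pm["a", "c"], 0.05)
})

test_that("Welch t-test matches the hand formulas and is antisymmetric", {
  same <- pairwise_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  set.seed(6)
  a <- rnorm(4, 10, 1)
  b <- rnorm(6, 12, 3)
  res <- pairwise_t(a, b)
  o <- oracle_welch(a, b)
  expect_equal(res$statistic, o$t, tolerance = 1e-12)
  expect_equal(res$df, o$df, tolerance = 1e-12)
  expect_equal(res$p.value, o$p, tolerance = 1e-12)

  rev <- pairwise_t(b, a)
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p.value, res$p.value)

  expect_equal(pairwise_t(c(1, 1), c(1, 1))$p.value, 1)
  expect_equal(pairwise_t(c(1, 1), c(2, 2))$p.value, 0)
})

test_that("Brown-Forsythe gate agrees with the reference implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  g <- list(a = rnorm(6, 0, 1), b = rnorm(6, 0, 4), c = rnorm(6, 0, 1))
  mine <- brown_forsythe(g)
  df <- data.frame(value = unlist(g),
                   group = factor(rep(names(g), lengths(g))))
  ref <- car::leveneTest(value ~ group, data = df, center = median)
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(mine$p.value, ref[1, "Pr(>F)"], tolerance = 1e-9)
})

test_that("test selection: normal equal-variance data get ANOVA, gross outliers get ranks", {
  set.seed(2)
  clean <- list(a = rnorm(5, 10), b = rnorm(5, 10.5), c = rnorm(5, 11))
  expect_identical(choose_test(clean), "anova_tukey")

  dirty <- clean
  dirty$a[1] <- 1e4  # extreme outlier wrecks residual normality
  expect_identical(choose_test(dirty), "kw_ranks")

  # decision is a deterministic function of the data
  expect_identical(choose_test(dirty), choose_test(dirty))
  expect_warning(sel <- choose_test(list(a = c(1, 2), b = c(3, 4))),
                 "residual degrees")
  expect_identical(sel, "kw_ranks")
})

test_that("compact letters encode exactly the pairwise non-significances", {
  all_ns <- matrix(1, 3, 3)
  expect_identical(unname(compact_letters(all_ns, 0.05)), rep("a", 3))

  all_sig <- diag(1, 4)
  expect_identical(unname(compact_letters(all_sig, 0.05)), c("a", "b", "c", "d"))

  pm <- matrix(c(1, 0.001, 0.2,
                 0.001, 1, 0.04,
                 0.2, 0.04, 1), 3, 3)
  expect_identical(unname(compact_letters(pm, 0.05)), c("a", "b", "a"))

  bad <- matrix(c(1, 0.2, 0.5, 1), 2, 2)
  expect_error(compact_letters(bad, 0.05), "symmetric")
})

test_that("letter displays match exhaustive brute force on random matrices up to k = 5", {
  set.seed(77)
  for (i in 1:60) {
    k <- sample(3:5, 1)
    pm <- random_pmat(k)
    alpha <- sample(c(0.05, 0.2, 0.5), 1)
    lets <- compact_letters(pm, alpha)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      expect_identical(letters_share(lets, a, b), pm[a, b] > alpha,
                       label = sprintf("share relation, case %d pair %d-%d", i, a, b))
    }
    n_letters <- length(unique(unlist(strsplit(lets, ""))))
    expect_identical(n_letters, oracle_min_letters(pm, alpha),
                     label = sprintf("minimal letter count, case %d", i))
  }
})

test_that("compare_groups ties the scheme together with letters at the chosen alpha", {
  set.seed(123)
  g <- list(WT = rnorm(3, 40, 2), mut = rnorm(3, 70, 2))
  res <- compare_groups(g, alpha = 0.05)
  expect_true(res$test_used %in% c("anova_tukey", "kw_ranks"))
  expect_identical(dim(res$pairwise), c(2L, 2L))
  expect_length(res$letters, 2)
  expect_identical(res$group, c("WT", "mut"))
  forced <- compare_groups(g, method = "kw_ranks")
  expect_identical(forced$test_used, "kw_ranks")
})

test_that("rank and parametric schemes agree on well-separated groups", {
  set.seed(55)
  g <- list(a = rnorm(4, 0, 1), b = rnorm(4, 10, 1), c = rnorm(4, 20, 1))
  expect_lt(one_way_anova(g)$p.value, 0.05)
  expect_lt(kruskal_wallis(g)$p.value, 0.05)
})
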
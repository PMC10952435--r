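# Group comparison scheme used for granule phenotype metrics: one-way
# ANOVA with Tukey all-pairwise comparisons when residual normality and
# variance homogeneity are tenable, Kruskal-Wallis on ranks with a
# Tukey-type (Nemenyi) rank procedure otherwise, Welch t-tests for
# two-genotype time-course contrasts, and compact letter displays.

# accept a named list of numeric vectors or a data.frame(group, value)
as_group_data <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      stop("a data.frame of groups needs columns 'group' and 'value'", call. = FALSE)
    }
    values <- as.numeric(groups$value)
    labels <- as.character(groups$group)
  } else if (is.list(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      names(groups) <- paste0("group", seq_along(groups))
    }
    values <- unlist(groups, use.names = FALSE)
    labels <- rep(names(groups), lengths(groups))
  } else {
    stop("groups must be a named list of numeric vectors or a data.frame", call. = FALSE)
  }
  if (anyNA(values)) {
    keep <- !is.na(values)
    values <- values[keep]
    labels <- labels[keep]
  }
  lv <- unique(labels)
  g <- factor(labels, levels = lv)
  if (nlevels(g) < 2L) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  if (any(tabulate(g) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  list(values = values, g = g, levels = lv)
}

#' One-way analysis of variance
#'
#' Classical F statistic and p-value from the F distribution. Degenerate
#' inputs (zero within-group variance) are flagged: equal group means give
#' `p = 1` by convention, unequal means give `p = 0`.
#'
#' @param groups Named list of numeric vectors (one per group, >= 2
#'   observations each) or a data.frame with columns `group`, `value`.
#' @return List with `statistic` (F), `p.value`, `df` (numerator,
#'   denominator) and `degenerate` flag.
#' @export
one_way_anova <- function(groups) {
  gd <- as_group_data(groups)
  x <- gd$values
  g <- gd$g
  k <- nlevels(g)
  n <- length(x)
  mj <- tapply(x, g, mean)
  nj <- tabulate(g)
  ssb <- sum(nj * (mj - mean(x))^2)
  ssw <- sum((x - mj[as.integer(g)])^2)
  tol <- 1e-12 * max(ssb + ssw, 1)
  if (ssw <= tol) {
    if (ssb <= tol) {
      return(list(statistic = 0, p.value = 1, df = c(k - 1L, n - k),
                  degenerate = TRUE))
    }
    return(list(statistic = Inf, p.value = 0, df = c(k - 1L, n - k),
                degenerate = TRUE))
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f,
       p.value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       df = c(k - 1L, n - k), degenerate = FALSE)
}

#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' Tie-corrected H statistic with a chi-square (k - 1 df) p-value, via
#' [stats::kruskal.test()]. All-identical observations give `H = 0`,
#' `p = 1`.
#'
#' @inheritParams one_way_anova
#' @return List with `statistic` (H), `p.value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  gd <- as_group_data(groups)
  if (length(unique(gd$values)) == 1L) {
    return(list(statistic = 0, p.value = 1, df = nlevels(gd$g) - 1L))
  }
  kt <- stats::kruskal.test(gd$values, gd$g)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Tukey honestly-significant-difference all-pairwise comparisons
#'
#' Studentized-range-adjusted p-values for every pair of groups, from
#' [stats::TukeyHSD()] on the one-way fit.
#'
#' @inheritParams one_way_anova
#' @return Symmetric matrix of adjusted p-values with unit diagonal,
#'   dimnames = group names in input order.
#' @export
tukey_all_pairs <- function(groups) {
  gd <- as_group_data(groups)
  k <- nlevels(gd$g)
  # safe internal level names: group labels may themselves contain "-"
  gi <- factor(paste0("g", as.integer(gd$g)), levels = paste0("g", seq_len(k)))
  mj <- tapply(gd$values, gi, mean)
  ssw <- sum((gd$values - mj[as.integer(gi)])^2)
  pmat <- diag(1, k)
  dimnames(pmat) <- list(gd$levels, gd$levels)
  if (ssw <= 1e-12 * max(sum((gd$values - mean(gd$values))^2), 1)) {
    # no within-group variance: pairs with equal means share p = 1, others 0
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      pmat[i, j] <- pmat[j, i] <- if (abs(mj[i] - mj[j]) <= 1e-12) 1 else 0
    }
    return(pmat)
  }
  fit <- stats::aov(v ~ gi, data = data.frame(v = gd$values, gi = gi))
  tk <- stats::TukeyHSD(fit)$gi
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    i <- as.integer(sub("^g", "", pairs[[r]][1L]))
    j <- as.integer(sub("^g", "", pairs[[r]][2L]))
    pmat[i, j] <- pmat[j, i] <- tk[r, "p adj"]
  }
  pmat
}

#' Tukey-type (Nemenyi) all-pairwise comparisons on rank sums
#'
#' Post-hoc procedure following a Kruskal-Wallis test: mean-rank
#' differences are referred to the studentized range distribution
#' (`ptukey` with infinite degrees of freedom). No tie correction is
#' applied to the rank variance.
#'
#' @inheritParams one_way_anova
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
kw_all_pairs <- function(groups) {
  gd <- as_group_data(groups)
  k <- nlevels(gd$g)
  n <- length(gd$values)
  rk <- rank(gd$values)
  rbar <- tapply(rk, gd$g, mean)
  nj <- tabulate(gd$g)
  pmat <- diag(1, k)
  dimnames(pmat) <- list(gd$levels, gd$levels)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    se <- sqrt(n * (n + 1) / 12 * (1 / nj[i] + 1 / nj[j]))
    if (se == 0 || abs(rbar[i] - rbar[j]) == 0) {
      p <- 1
    } else {
      q <- sqrt(2) * abs(rbar[i] - rbar[j]) / se
      p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    }
    pmat[i, j] <- pmat[j, i] <- p
  }
  pmat
}

#' Two-sided Welch t-test between two groups
#'
#' Welch's unequal-variance t-test, the appropriate two-genotype contrast
#' for small replicate sets with no variance-homogeneity guarantee. Both
#' groups constant with equal means gives `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors (>= 2 observations each).
#' @return List with `statistic` (t), `p.value`, `df`
#'   (Welch-Satterthwaite).
#' @export
pairwise_t <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p.value = 1, df = NA_real_))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0,
                df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}

#' Brown-Forsythe test for equality of group variances
#'
#' One-way F test on absolute deviations from the group medians.
#'
#' @inheritParams one_way_anova
#' @return List with `statistic`, `p.value`.
#' @export
brown_forsythe <- function(groups) {
  gd <- as_group_data(groups)
  med <- tapply(gd$values, gd$g, stats::median)
  dev <- abs(gd$values - med[as.integer(gd$g)])
  res <- one_way_anova(split(dev, gd$g))
  if (res$degenerate && res$p.value == 1) {
    # all deviations equal: no evidence of heteroscedasticity
    return(list(statistic = 0, p.value = 1))
  }
  list(statistic = res$statistic, p.value = res$p.value)
}

#' Choose between the parametric and rank-based comparison scheme
#'
#' Returns `"anova_tukey"` when a Shapiro-Wilk test on the pooled
#' within-group residuals and a Brown-Forsythe equal-variance test both
#' exceed `alpha_assumption`; otherwise `"kw_ranks"`. With fewer than 3
#' residual degrees of freedom the Shapiro-Wilk test is uninformative and
#' the rank-based scheme is chosen with a warning. The decision is a
#' deterministic function of the data.
#'
#' @inheritParams one_way_anova
#' @param alpha_assumption Significance level for the assumption checks
#'   (default 0.05).
#' @return `"anova_tukey"` or `"kw_ranks"`.
#' @export
choose_test <- function(groups, alpha_assumption = 0.05) {
  gd <- as_group_data(groups)
  k <- nlevels(gd$g)
  n <- length(gd$values)
  if (n - k < 3L) {
    warning("fewer than 3 residual degrees of freedom: defaulting to the rank-based scheme")
    return("kw_ranks")
  }
  mj <- tapply(gd$values, gd$g, mean)
  resid <- gd$values - mj[as.integer(gd$g)]
  sw_p <- tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) 0)
  bf_p <- brown_forsythe(groups)$p.value
  if (sw_p > alpha_assumption && bf_p > alpha_assumption) "anova_tukey" else "kw_ranks"
}

# all cliques of an adjacency matrix, as a list of integer vectors
all_cliques <- function(adj) {
  k <- nrow(adj)
  out <- list()
  for (m in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    if (length(members) == 1L ||
        all(adj[members, members][upper.tri(diag(length(members)))])) {
      out[[length(out) + 1L]] <- members
    }
  }
  out
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters to groups such that two groups share at least one
#' letter exactly when their pairwise p-value exceeds `alpha`. Letters
#' correspond to cliques of the non-significance graph; the display uses a
#' minimum edge-clique cover (found exactly, with deterministic
#' tie-breaking by earliest group index), so the letter count is minimal.
#'
#' @param pmat Symmetric matrix of pairwise p-values with unit diagonal.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group, in the
#'   matrix's row order; letters start at "a" for the clique containing
#'   the earliest group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  if (!is.matrix(pmat) || nrow(pmat) != ncol(pmat)) {
    stop("pmat must be a square matrix", call. = FALSE)
  }
  if (max(abs(pmat - t(pmat))) > 1e-9) {
    stop("pmat must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(pmat) - 1) > 1e-9)) {
    stop("pmat must have unit diagonal", call. = FALSE)
  }
  k <- nrow(pmat)
  if (k > 12L) {
    stop("compact_letters supports up to 12 groups", call. = FALSE)
  }
  labels <- rownames(pmat)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  adj <- pmat > alpha
  diag(adj) <- TRUE
  cliques <- all_cliques(adj)
  # maximal cliques only, ordered deterministically
  is_maximal <- vapply(cliques, function(ci) {
    !any(vapply(cliques, function(cj) {
      length(cj) > length(ci) && all(ci %in% cj)
    }, logical(1)))
  }, logical(1))
  cand <- cliques[is_maximal]
  ord <- order(vapply(cand, min, integer(1)),
               -lengths(cand),
               vapply(cand, function(ci) paste(ci, collapse = ","), character(1)))
  cand <- cand[ord]
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  covers <- function(sel) {
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        i <- edges[r, 1L]; j <- edges[r, 2L]
        if (!any(vapply(sel, function(ci) i %in% ci && j %in% ci, logical(1)))) {
          return(FALSE)
        }
      }
    }
    all(seq_len(k) %in% unlist(sel))
  }
  chosen <- NULL
  for (m in seq_along(cand)) {
    combos <- utils::combn(length(cand), m, simplify = FALSE)
    for (cmb in combos) {
      if (covers(cand[cmb])) {
        chosen <- cand[cmb]
        break
      }
    }
    if (!is.null(chosen)) break
  }
  chosen <- chosen[order(vapply(chosen, min, integer(1)))]
  lets <- letters[seq_along(chosen)]
  out <- vapply(seq_len(k), function(i) {
    paste(lets[vapply(chosen, function(ci) i %in% ci, logical(1))], collapse = "")
  }, character(1))
  names(out) <- labels
  out
}

#' Full group comparison with compact letters
#'
#' Runs the comparison scheme end to end: test selection (unless forced),
#' omnibus test, all-pairwise comparisons and compact letter display.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the letter display (default 0.05).
#' @param alpha_assumption Level for the assumption gate in
#'   [choose_test()].
#' @param method `"auto"` (default, via [choose_test()]),
#'   `"anova_tukey"` or `"kw_ranks"`.
#' @return Object of class `comparison_result` with fields `test_used`,
#'   `statistic`, `p.value`, `pairwise` (p matrix), `letters`, `alpha`,
#'   and per-group summaries (`group`, `mean`, `se`, `n`).
#' @export
compare_groups <- function(groups, alpha = 0.05, alpha_assumption = 0.05,
                           method = c("auto", "anova_tukey", "kw_ranks")) {
  method <- match.arg(method)
  gd <- as_group_data(groups)
  test_used <- if (method == "auto") choose_test(groups, alpha_assumption) else method
  if (test_used == "anova_tukey") {
    omni <- one_way_anova(groups)
    pmat <- tukey_all_pairs(groups)
  } else {
    omni <- kruskal_wallis(groups)
    pmat <- kw_all_pairs(groups)
  }
  structure(
    list(test_used = test_used,
         statistic = omni$statistic, p.value = omni$p.value,
         pairwise = pmat,
         letters = compact_letters(pmat, alpha),
         alpha = alpha,
         group = gd$levels,
         mean = as.numeric(tapply(gd$values, gd$g, mean)),
         se = as.numeric(tapply(gd$values, gd$g, stats::sd) / sqrt(tabulate(gd$g))),
         n = tabulate(gd$g)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: omnibus statistic %.4g, p = %.4g (alpha %.3g)\n",
              x$test_used, x$statistic, x$p.value, x$alpha))
  print(data.frame(group = x$group, mean = x$mean, se = x$se, n = x$n,
                   letters = unname(x$letters)))
  invisible(x)
}
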
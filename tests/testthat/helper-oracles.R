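# Independent oracles used across the suite. These re-derive expectations
# by a different route than the package implementation.

# classical one-way ANOVA F from the two-line textbook computation
oracle_anova_f <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  grand <- mean(x)
  ss_between <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  ms_b <- ss_between / (length(groups) - 1)
  ms_w <- ss_within / (length(x) - length(groups))
  ms_b / ms_w
}

# Kruskal-Wallis H without ties: 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  rk <- rank(x)
  n <- length(x)
  rj <- tapply(rk, rep(seq_along(groups), lengths(groups)), sum)
  12 / (n * (n + 1)) * sum(rj^2 / lengths(groups)) - 3 * (n + 1)
}

# Welch statistic and Welch-Satterthwaite df from the formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Tukey adjusted p for one pair from the studentized range distribution
oracle_tukey_pair <- function(groups, i, j) {
  k <- length(groups)
  n <- length(unlist(groups))
  mse <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2))) / (n - k)
  se <- sqrt(mse / 2 * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
  unname(ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE))
}

# minimum number of letters needed for a compact letter display:
# exhaustive search over covers built from ALL cliques (not only maximal
# ones), enumerated with combn -- a different route than the package.
oracle_min_letters <- function(pmat, alpha) {
  k <- nrow(pmat)
  adj <- pmat > alpha
  diag(adj) <- TRUE
  cliques <- list()
  for (size in seq_len(k)) {
    for (members in utils::combn(k, size, simplify = FALSE)) {
      sub <- adj[members, members, drop = FALSE]
      if (all(sub)) cliques[[length(cliques) + 1L]] <- members
    }
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (m in seq_along(cliques)) {
    for (sel in utils::combn(length(cliques), m, simplify = FALSE)) {
      cover <- cliques[sel]
      edges_ok <- TRUE
      if (nrow(edges)) {
        for (r in seq_len(nrow(edges))) {
          if (!any(vapply(cover, function(ci) {
            edges[r, 1L] %in% ci && edges[r, 2L] %in% ci
          }, logical(1)))) {
            edges_ok <- FALSE
            break
          }
        }
      }
      if (edges_ok && all(seq_len(k) %in% unlist(cover))) {
        return(m)
      }
    }
  }
  k
}

# do two groups share at least one letter?
letters_share <- function(lets, i, j) {
  a <- strsplit(lets[i], "")[[1]]
  b <- strsplit(lets[j], "")[[1]]
  length(intersect(a, b)) > 0
}

# random symmetric p matrix with unit diagonal
random_pmat <- function(k) {
  m <- matrix(0, k, k)
  m[upper.tri(m)] <- runif(k * (k - 1) / 2)
  m <- m + t(m)
  diag(m) <- 1
  m
}

# quick valid normalized distribution on a small grid
tiny_volume_dist <- function(values, edges = NULL, normalized = TRUE) {
  if (is.null(edges)) edges <- exp(seq(log(2), log(60), length.out = length(values) + 1))
  v <- 100 * values / sum(values)
  size_distribution(diameter_grid(edges), v, "relative_volume_pct",
                    normalized = normalized)
}
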
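# Shared fixtures and independent oracle implementations used by the tests.
# The oracles deliberately use different code paths from the package
# (factorial-number-system unranking for permutations, direct statistic
# recomputation) so that agreement is informative.

# Tiny generator configuration for fast tests.
tiny_config <- function(seed = 1L, ...) {
  synth_config(n_genes_host = 24L, n_genes_symA = 12L, n_genes_symB = 12L,
               n_replicates = 4L, lib_size_mean = 5e4,
               n_de_genes = c(host = 4L, symA = 4L, symB = 4L),
               n_pathways = 4L, pathway_size = 3L, seed = seed, ...)
}

# Standardize each organism over the samples where it is present.
standardize_present <- function(ds, seed = 1L) {
  suppressWarnings(lapply(ds$counts, function(x)
    downsample_to_min(x[, colSums(x) > 0, drop = FALSE], seed = seed)))
}

# Unrank the k-th (0-based) permutation of 1..n in the factorial number
# system; enumerating k = 0..n!-1 yields every permutation exactly once.
oracle_permutation <- function(k, n) {
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    j <- k %/% f
    k <- k %% f
    out[i] <- avail[j + 1L]
    avail <- avail[-(j + 1L)]
  }
  out
}

# Exact two-sided permutation p for Spearman rho by exhaustive unranking.
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  hits <- 0L
  total <- factorial(n)
  for (k in 0:(total - 1L)) {
    perm <- oracle_permutation(k, n)
    if (abs(stats::cor(rx, ry[perm])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Independent ANOSIM R from a distance matrix and integer labels.
oracle_anosim_R <- function(Dm, g) {
  N <- nrow(Dm)
  rk <- matrix(0, N, N)
  rk[lower.tri(rk)] <- rank(Dm[lower.tri(Dm)])
  rk <- rk + t(rk)
  w <- b <- c()
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    if (g[i] == g[j]) w <- c(w, rk[i, j]) else b <- c(b, rk[i, j])
  }
  (mean(b) - mean(w)) / (N * (N - 1) / 4)
}

# Exact one-sided ANOSIM p by enumerating the group-1 index subsets.
oracle_anosim_exact_p <- function(Dm, g) {
  g <- as.integer(factor(g))
  N <- nrow(Dm)
  n1 <- sum(g == 1L)
  obs <- oracle_anosim_R(Dm, g)
  subsets <- utils::combn(N, n1)
  Rs <- apply(subsets, 2L, function(idx) {
    gg <- rep(2L, N); gg[idx] <- 1L
    oracle_anosim_R(Dm, gg)
  })
  mean(Rs >= obs - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumerating label assignments,
# two-sided via the doubled smaller tail of the rank sum.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  Wp <- apply(utils::combn(N, n1), 2L, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(Wp <= W + 1e-12), mean(Wp >= W - 1e-12)))
}
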
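# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Numerical fudge used when comparing permutation statistics to the observed
## value, so that exact ties survive floating-point round-off.
.EPS <- 1e-12

#' All permutations of 1..n
#'
#' Enumerates the full symmetric group; intended for exact permutation tests at
#' n <= 7 (5,040 rows).
#' @param n integer >= 1
#' @return integer matrix with factorial(n) rows and n columns
#' @keywords internal
#' @noRd
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  idx <- seq_len(n)
  for (i in idx) {
    rest <- idx[-i]
    out[[i]] <- cbind(rep.int(i, nrow(sub)),
                      matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Distinct permutations of a label multiset
#'
#' @param labels vector of group labels (factor or character)
#' @return matrix, one distinct arrangement per row (same element multiset as
#'   `labels`, as integer codes of `factor(labels)`)
#' @keywords internal
#' @noRd
multiset_permutations <- function(labels) {
  f <- as.integer(factor(labels))
  k <- max(f)
  counts <- tabulate(f, k)
  n <- length(f)
  rows <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      rows[[length(rows) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (g in seq_len(k)) {
      if (counts[g] > 0L) {
        counts[g] <- counts[g] - 1L
        rec(c(prefix, g), counts)
        counts[g] <- counts[g] + 1L
      }
    }
  }
  rec(integer(0), counts)
  do.call(rbind, rows)
}

#' Number of distinct arrangements of a label multiset
#' @keywords internal
#' @noRd
n_multiset_permutations <- function(labels) {
  f <- as.integer(factor(labels))
  counts <- tabulate(f, max(f))
  exp(lgamma(length(f) + 1) - sum(lgamma(counts + 1)))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert & Arabie chance-corrected agreement; 1 for identical partitions,
#' ~0 for independent ones.
#' @param a,b cluster label vectors of equal length
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Mann-Whitney U test (two groups)
#'
#' Rank-sum test with the U statistic reported by the symmetric (minimum)
#' convention. When both groups have at most `exact_max` observations the
#' two-sided p-value is computed by full enumeration of the
#' choose(n1 + n2, n1) label assignments, which remains valid under ties.
#' Otherwise the tie-corrected normal approximation is used. The normal
#' z statistic is reported in both cases.
#'
#' @param x,y numeric vectors for the two groups
#' @param exact_max largest per-group size for which the exact enumeration is
#'   used (default 8)
#' @return list with `U` (minimum-convention statistic), `z` (tie-corrected
#'   normal deviate), `p` (two-sided), `method` ("exact" or "normal"),
#'   `n` (group sizes)
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U_xy <- W - n1 * (n1 + 1) / 2
  U <- min(U_xy, n1 * n2 - U_xy)

  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 > 0) (U_xy - n1 * n2 / 2) / sqrt(sigma2) else 0

  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    Wperm <- colSums(matrix(r[idx], nrow = n1))
    p_le <- mean(Wperm <= W + .EPS)
    p_ge <- mean(Wperm >= W - .EPS)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(U = U, z = z, p = p, method = method, n = c(n1, n2))
}

#' Vectorized Mann-Whitney p-values over the rows of a matrix
#'
#' One test per gene (row); first `n1` columns form group 1. Exact enumeration
#' (tie-safe) when both group sizes are at most `exact_max`, otherwise the
#' tie-corrected normal approximation per row.
#' @keywords internal
#' @noRd
mw_pvalues_rows <- function(mat, n1, exact_max = 8L) {
  n2 <- ncol(mat) - n1
  N <- ncol(mat)
  R <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) R <- matrix(R, 1L, N)
  W <- rowSums(R[, seq_len(n1), drop = FALSE])
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    m <- ncol(idx)
    A <- matrix(0, N, m)
    A[cbind(as.vector(idx), rep(seq_len(m), each = n1))] <- 1
    Wperm <- R %*% A
    p_le <- rowMeans(Wperm <= W + .EPS)
    p_ge <- rowMeans(Wperm >= W - .EPS)
    p <- pmin(1, 2 * pmin(p_le, p_ge))
  } else {
    p <- apply(mat, 1L, function(v) {
      mann_whitney(v[seq_len(n1)], v[-seq_len(n1)], exact_max = 0L)$p
    })
  }
  unname(p)
}

## Column-center a matrix.
center_cols <- function(m) sweep(m, 2L, colMeans(m), "-")

## Expand a data.frame of predictors to a centered numeric model matrix
## (no intercept column).
predictor_matrix <- function(df) {
  df <- as.data.frame(df)
  mm <- stats::model.matrix(~ ., data = df)
  center_cols(mm[, -1L, drop = FALSE])
}

## Stage-scoped deterministic seed derivation: keeps derived seeds positive
## and below .Machine$integer.max for any small user seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483587) + 1L
}
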
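# Distance computation, principal coordinates analysis, distance-based
# redundancy analysis (dbRDA) with permutation tests and forward selection,
# ANOSIM with pairwise Bonferroni, and SIMPER decomposition.
#
# dbRDA follows the coordinate-regression construction: principal coordinates
# of the distance matrix (axes with positive eigenvalues) are regressed on
# the predictors, optionally after removing the effect of conditioning
# variables; explained variability R2 is constrained / total inertia and
# significance comes from permuting rows of the (residualized) coordinates.
# Negative PCoA eigenvalues are reported and their axes discarded; no
# Lingoes/Cailliez correction is applied by default.

#' Bray-Curtis dissimilarity between samples
#'
#' d(j,k) = sum_i |y_ij - y_ik| / sum_i (y_ij + y_ik).
#'
#' @param x samples-by-variables nonnegative matrix (rownames = sample ids)
#' @return `dist` object with attribute `metric = "bray_curtis"`
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative values")
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(rownames(x)[zero], collapse = ", "))
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Robust Aitchison distance between samples
#'
#' Each sample is transformed by the robust centered log-ratio: the log of
#' its positive counts minus the mean log over that sample's positive counts,
#' with zeros treated as missing. The distance between two samples is the
#' Euclidean distance over the features positive in both, scaled by
#' sqrt(n_features / n_shared) to keep sparser pairs comparable. On a
#' zero-free matrix this reduces to classical CLR + Euclidean distance.
#'
#' @param x samples-by-variables nonnegative count matrix
#' @return `dist` object with attribute `metric = "robust_aitchison"`
#' @export
robust_aitchison <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("robust Aitchison requires nonnegative counts")
  if (any(rowSums(x > 0) == 0))
    stop("sample(s) with no positive feature: ",
         paste(rownames(x)[rowSums(x > 0) == 0], collapse = ", "))
  lx <- log(x)
  lx[x == 0] <- NA
  r <- lx - rowMeans(lx, na.rm = TRUE)
  n <- nrow(x); p <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !is.na(r[i, ]) & !is.na(r[j, ])
      ns <- sum(shared)
      if (ns == 0L)
        stop("no shared positive feature between samples '",
             rownames(x)[i], "' and '", rownames(x)[j], "'")
      d[i, j] <- d[j, i] <-
        sqrt(sum((r[i, shared] - r[j, shared])^2)) * sqrt(p / ns)
    }
  }
  d <- stats::as.dist(d)
  attr(d, "metric") <- "robust_aitchison"
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition. Axes with
#' eigenvalues above 1e-10 are retained; negative eigenvalues are reported
#' and their axes discarded.
#'
#' @param D `dist` object or symmetric distance matrix
#' @return object of class `pcoa_fit`: list with `points` (samples x axes,
#'   scaled by sqrt(eigenvalue)), `eig` (all eigenvalues), `negative`
#'   (negative eigenvalues, if any) and `total_inertia` (sum of positive
#'   eigenvalues)
#' @export
pcoa <- function(D) {
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  A <- -0.5 * Dm^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-10
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(pts) <- rownames(Dm)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  structure(list(points = pts, eig = e$values,
                 negative = e$values[e$values < -1e-10],
                 total_inertia = sum(e$values[keep])),
            class = "pcoa_fit")
}

#' Distance-based redundancy analysis with a permutation test
#'
#' @param D `dist`/matrix of distances, or a precomputed [pcoa()] fit
#' @param X predictor table (data.frame; factors allowed) with rows in
#'   sample order
#' @param condition optional conditioning table whose effect is removed from
#'   both coordinates and predictors before fitting (partial dbRDA)
#' @param B number of row permutations for the pseudo-F test (default 999);
#'   residuals of the conditioning model are permuted for partial models
#' @param seed RNG seed
#' @return object of class `dbrda_fit`: eigenvalues of the constrained and
#'   unconstrained parts, inertia partition, `R2` (constrained/total),
#'   `adj_R2`, permutation `F` and `p`, `df` (number of constraint columns),
#'   `site_scores` and `biplot_scores`
#' @export
dbrda <- function(D, X, condition = NULL, B = 999L, seed = 1L) {
  pc <- if (inherits(D, "pcoa_fit")) D else pcoa(D)
  Y <- pc$points
  n <- nrow(Y)
  total <- pc$total_inertia
  Xm <- predictor_matrix(X)
  if (nrow(Xm) != n) stop("predictor rows must match the samples")

  cdf <- 0L
  cond_inertia <- 0
  Yc <- Y; Xr <- Xm
  if (!is.null(condition)) {
    Zm <- predictor_matrix(condition)
    qz <- qr(Zm)
    cdf <- qz$rank
    Yc <- qr.resid(qz, Y)
    Xr <- qr.resid(qz, Xm)
    cond_inertia <- total - sum(Yc^2)
  }
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr)) {
    drop_cols <- colnames(Xr)[qx$pivot[(qx$rank + 1L):ncol(Xr)]]
    stop("rank-deficient predictors; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  q <- qx$rank
  if (n < q + cdf + 1L)
    stop("too few samples (", n, ") for ", q, " predictors and ",
         cdf, " conditions")
  Q <- qr.Q(qx)[, seq_len(q), drop = FALSE]
  fit <- Q %*% crossprod(Q, Yc)
  constrained <- sum(fit^2)
  ss_yc <- sum(Yc^2)
  resid_ss <- ss_yc - constrained
  df_resid <- n - q - cdf - 1L

  Fobs <- if (df_resid > 0) (constrained / q) / (resid_ss / df_resid) else NA_real_
  p <- NA_real_
  if (df_resid > 0 && B > 0) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(B)) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      cb <- sum(crossprod(Q, Yp)^2)
      Fb <- (cb / q) / ((ss_yc - cb) / df_resid)
      if (Fb >= Fobs - .EPS) hits <- hits + 1L
    }
    p <- (1 + hits) / (B + 1)
  }

  sv <- svd(fit, nu = min(q, n), nv = 0)
  eig_c <- (sv$d^2)[seq_len(min(q, sum(sv$d^2 > 1e-12 * max(sv$d^2, 1))))]
  site <- sv$u[, seq_along(eig_c), drop = FALSE] %*%
    diag(sv$d[seq_along(eig_c)], length(eig_c))
  rownames(site) <- rownames(Y)
  colnames(site) <- paste0("CAP", seq_len(ncol(site)))
  eig_u <- svd(Yc - fit, nu = 0, nv = 0)$d^2
  eig_u <- eig_u[eig_u > 1e-10]
  biplot <- if (ncol(site) > 0 && nrow(site) > 2)
    suppressWarnings(stats::cor(Xr, site)) else NULL

  R2 <- constrained / total
  adj <- if (df_resid > 0)
    1 - (1 - R2) * (n - 1 - cdf) / df_resid else NA_real_

  structure(list(eig_constrained = eig_c, eig_unconstrained = eig_u,
                 total_inertia = total, constrained_inertia = constrained,
                 conditional_inertia = cond_inertia, residual_inertia = resid_ss,
                 R2 = R2, adj_R2 = adj, F = Fobs, p = p, df = q,
                 df_condition = cdf, df_resid = df_resid, n = n, B = B,
                 site_scores = site, biplot_scores = biplot),
            class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cat("dbRDA: df =", x$df, " F =", signif(x$F, 4), " R2 =", signif(x$R2, 4),
      " p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Forward selection of dbRDA predictors
#'
#' At each step every remaining candidate is tested as a marginal addition
#' (partial dbRDA conditioned on the already-selected set); the candidate
#' with the lowest permutation p enters (ties broken by larger marginal R2,
#' then column order). Selection stops when the best p >= alpha, or — after a
#' variable is accepted — when the cumulative adjusted R2 exceeds that of the
#' full model (the double-stopping rule used with ordistep-style selection).
#'
#' @param D distances or a [pcoa()] fit
#' @param candidates data.frame of candidate predictors
#' @param alpha entry threshold on the permutation p (default 0.05)
#' @param B permutations per candidate test
#' @param seed RNG seed
#' @param adjr2_guard disable with `FALSE` to select on alpha only
#' @return list with `selected` (names in order of entry), `steps`
#'   (data.frame of per-step p and marginal R2), and `model` (final
#'   [dbrda()] fit on the selected set, or NULL when nothing entered)
#' @export
forward_select <- function(D, candidates, alpha = 0.05, B = 199L, seed = 1L,
                           adjr2_guard = TRUE) {
  pc <- if (inherits(D, "pcoa_fit")) D else pcoa(D)
  candidates <- as.data.frame(candidates)
  if (!ncol(candidates)) stop("need at least one candidate")
  n <- nrow(pc$points)

  adj_full <- Inf
  if (adjr2_guard) {
    full <- tryCatch(dbrda(pc, candidates, B = 0L, seed = seed),
                     error = function(e) NULL)
    if (!is.null(full) && !is.na(full$adj_R2)) adj_full <- full$adj_R2
  }

  selected <- character(0)
  steps <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    step <- step + 1L
    res <- lapply(seq_along(remaining), function(i) {
      cand <- remaining[i]
      fit <- tryCatch(
        dbrda(pc, candidates[cand],
              condition = if (length(selected)) candidates[selected] else NULL,
              B = B, seed = derive_seed(seed, step * 1000L + i)),
        error = function(e) NULL)
      if (is.null(fit)) return(c(NA_real_, NA_real_))
      c(fit$p, fit$R2)
    })
    pvals <- vapply(res, `[`, numeric(1), 1L)
    r2s <- vapply(res, `[`, numeric(1), 2L)
    if (all(is.na(pvals))) break
    ord <- order(pvals, -r2s, seq_along(remaining), na.last = TRUE)
    best <- ord[1L]
    if (is.na(pvals[best]) || pvals[best] >= alpha) break
    selected <- c(selected, remaining[best])
    steps[[step]] <- data.frame(step = step, variable = remaining[best],
                                p = pvals[best], marginal_R2 = r2s[best],
                                stringsAsFactors = FALSE)
    if (adjr2_guard) {
      ## double-stopping rule: once the cumulative adjusted R2 reaches the
      ## full model's, further additions would only chase noise
      aug <- tryCatch(dbrda(pc, candidates[selected], B = 0L, seed = seed),
                      error = function(e) NULL)
      if (!is.null(aug) && !is.na(aug$adj_R2) && aug$adj_R2 > adj_full) break
    }
  }
  model <- if (length(selected))
    dbrda(pc, candidates[selected], B = max(B, 199L),
          seed = derive_seed(seed, 999999L)) else NULL
  list(selected = selected,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(step = integer(0), variable = character(0),
                    p = numeric(0), marginal_R2 = numeric(0)),
       model = model)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (N(N-1)/4) on the
#' ranked distances. The p-value permutes group labels: full enumeration of
#' the distinct label arrangements when there are at most `exact_limit` of
#' them, Monte-Carlo otherwise. With more than two groups, pairwise two-group
#' tests are run with Bonferroni adjustment.
#'
#' @param D `dist` object or distance matrix
#' @param groups grouping vector (each group n >= 2)
#' @param B Monte-Carlo permutations (default 999)
#' @param seed RNG seed
#' @param exact_limit largest number of distinct arrangements enumerated
#'   exactly (default 10000)
#' @return object of class `anosim_result`: `R`, `p`, `method`, and (for > 2
#'   groups) `pairwise` data.frame with Bonferroni-adjusted p
#' @export
anosim_test <- function(D, groups, B = 999L, seed = 1L, exact_limit = 10000) {
  Dm <- as.matrix(D)
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  N <- nrow(Dm)
  pair_i <- row(Dm)[lower.tri(Dm)]
  pair_j <- col(Dm)[lower.tri(Dm)]
  r <- rank(Dm[lower.tri(Dm)])
  denom <- N * (N - 1) / 4

  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  Robs <- stat(as.integer(groups))

  n_arr <- n_multiset_permutations(groups)
  if (n_arr <= exact_limit) {
    arr <- multiset_permutations(groups)
    Rperm <- apply(arr, 1L, stat)
    p <- mean(Rperm >= Robs - .EPS)
    method <- "exact"
  } else {
    set.seed(seed)
    g <- as.integer(groups)
    hits <- 0L
    for (b in seq_len(B)) {
      if (stat(g[sample.int(N)]) >= Robs - .EPS) hits <- hits + 1L
    }
    p <- (1 + hits) / (B + 1)
    method <- "permutation"
  }

  pairwise <- NULL
  if (nlevels(groups) > 2L) {
    combos <- utils::combn(levels(groups), 2L)
    npairs <- ncol(combos)
    pairwise <- do.call(rbind, lapply(seq_len(npairs), function(k) {
      keep <- groups %in% combos[, k]
      sub <- anosim_test(Dm[keep, keep], droplevels(groups[keep]), B = B,
                         seed = derive_seed(seed, k), exact_limit = exact_limit)
      data.frame(group1 = combos[1L, k], group2 = combos[2L, k],
                 R = sub$R, p = sub$p,
                 p_bonferroni = min(1, sub$p * npairs),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(R = Robs, p = p, method = method, pairwise = pairwise,
                 n = N, B = B),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", signif(x$R, 4), " p =", signif(x$p, 4),
      " (", x$method, ")\n")
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' SIMPER: per-variable contributions to between-group dissimilarity
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-variable contributions: for variable i, the mean over between-group
#' sample pairs (j, k) of |y_ij - y_ik| / sum_m (y_mj + y_mk). Contributions
#' sum exactly to the mean between-group dissimilarity.
#'
#' @param x samples-by-variables nonnegative matrix
#' @param groups two-group vector
#' @return object of class `simper_result`: data.frame sorted by decreasing
#'   contribution with `cumulative_pct`, plus attribute
#'   `overall_dissimilarity`
#' @export
simper <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("simper compares exactly two groups; iterate over pairs for more")
  if (any(x < 0)) stop("requires nonnegative values")
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  contrib <- numeric(ncol(x))
  npairs <- length(g1) * length(g2)
  for (j in g1) {
    for (k in g2) {
      denom <- sum(x[j, ] + x[k, ])
      contrib <- contrib + abs(x[j, ] - x[k, ]) / denom
    }
  }
  contrib <- contrib / npairs
  ord <- order(-contrib)
  out <- data.frame(variable = colnames(x)[ord], contribution = contrib[ord],
                    cumulative_pct = 100 * cumsum(contrib[ord]) / sum(contrib),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "overall_dissimilarity") <- sum(contrib)
  class(out) <- c("simper_result", class(out))
  out
}
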
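# Shannon diversity of gene expression: each sample's gene-count distribution
# is treated as a community profile and summarized by H = -sum p log p.
# Group comparisons are rank-based (Mann-Whitney / Kruskal-Wallis) and the
# symbiont-vs-host diversity relationship is an ordinary least-squares
# regression with confidence and prediction bands.

#' Shannon diversity of a count vector
#'
#' @param counts nonnegative vector with at least one positive entry
#' @param base logarithm base; default natural log (nats)
#' @return H = -sum p_i log p_i over the positive entries
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector has undefined diversity")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample Shannon diversity of a count matrix
#'
#' @param counts gene-by-sample count matrix (standardized counts by
#'   convention; pass raw counts explicitly if wanted)
#' @param base logarithm base
#' @return data.frame with columns `sample_id`, `H`, `organism`
#' @export
shannon_profile <- function(counts, base = exp(1)) {
  data.frame(sample_id = colnames(counts),
             H = apply(counts, 2L, shannon, base = base),
             organism = attr(counts, "organism") %||% NA_character_,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare Shannon diversity between groups
#'
#' Mann-Whitney for two groups (reporting both the U statistic and the
#' tie-corrected normal z, since published values may be either);
#' tie-corrected Kruskal-Wallis chi-square approximation for three or more.
#'
#' @param H numeric vector of diversity values
#' @param groups grouping vector
#' @return for 2 groups a [mann_whitney()] list; otherwise a list with
#'   `statistic` (Kruskal-Wallis H), `df`, `p`, `method = "kruskal_wallis"`
#' @export
compare_diversity <- function(H, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 observations")
  if (nlevels(groups) == 2L) {
    mann_whitney(H[groups == levels(groups)[1L]],
                 H[groups == levels(groups)[2L]])
  } else {
    kt <- stats::kruskal.test(H, groups)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, method = "kruskal_wallis")
  }
}

#' Regression between two sets of diversity values
#'
#' Ordinary least squares of y on x with slope F-test, plus 95% confidence and
#' prediction bands evaluated at the observed x.
#'
#' @param x,y paired numeric vectors (n >= 3)
#' @param level band coverage, default 0.95
#' @return list with `slope`, `intercept`, `r_squared`, `F`, `df`, `p`,
#'   `bands` (data.frame x, fit, ci_lo, ci_hi, pi_lo, pi_hi) and the `lm` fit
#' @export
regress_diversity <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ord <- order(x)
  nd <- data.frame(x = x[ord])
  ci <- stats::predict(fit, nd, interval = "confidence", level = level)
  pi <- stats::predict(fit, nd, interval = "prediction", level = level)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       F = unname(sm$fstatistic[1L]),
       df = unname(sm$fstatistic[2:3]),
       p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                     lower.tail = FALSE),
       bands = data.frame(x = nd$x, fit = ci[, "fit"],
                          ci_lo = ci[, "lwr"], ci_hi = ci[, "upr"],
                          pi_lo = pi[, "lwr"], pi_hi = pi[, "upr"]),
       fit = fit)
}
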
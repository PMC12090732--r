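# Library-size standardization by rarefaction (random subsampling without
# replacement to the minimum sample total) and symbiont/host read-proportion
# comparison. Rarefaction preserves integer counts, which the downstream
# rank-based statistics require; read proportions are always computed on
# UNstandardized counts.

#' Downsample every sample to the minimum library size
#'
#' Each sample's reads are subsampled without replacement (multivariate
#' hypergeometric) to the smallest sample total, so the expected downsampled
#' count of gene g in sample s is `count[g, s] * min_total / total[s]`. A
#' sample already at the minimum is returned unchanged. Deterministic for a
#' fixed seed.
#'
#' @param counts gene-by-sample count matrix
#' @param seed integer RNG seed
#' @return count matrix with all sample totals equal to the input minimum
#' @export
downsample_to_min <- function(counts, seed = 1L) {
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  target <- min(totals)
  set.seed(seed)
  if (nrow(counts) == 1L) {
    ## single-gene matrix: the subsample is fully determined
    out <- matrix(as.integer(target), 1L, ncol(counts))
  } else {
    ## rrarefy's advisory warning about count scales does not apply here:
    ## inputs are validated integer read counts
    out <- t(suppressWarnings(vegan::rrarefy(t(counts), target)))
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  attr(out, "organism") <- attr(counts, "organism")
  out
}

#' Per-sample symbiont-to-host read proportion
#'
#' Ratio of total symbiont reads to total host reads per sample, computed on
#' unstandardized counts.
#'
#' @param sym symbiont count matrix
#' @param host host count matrix with identical samples in identical order
#' @return named numeric vector of proportions
#' @export
symbiont_host_proportion <- function(sym, host) {
  if (!identical(colnames(sym), colnames(host)))
    stop("symbiont and host matrices must share aligned samples")
  host_tot <- colSums(host)
  if (any(host_tot == 0))
    stop("host total is zero for sample(s): ",
         paste(colnames(host)[host_tot == 0], collapse = ", "))
  colSums(sym) / host_tot
}

#' Compare read proportions (or any values) between two groups
#'
#' Mann-Whitney U test; exact enumeration of label assignments when both
#' groups have at most 8 observations, tie-corrected normal approximation
#' otherwise (see [mann_whitney()]).
#'
#' @param values numeric vector
#' @param groups two-level grouping vector of the same length
#' @return `mann_whitney` result list (U, z, p, method, n)
#' @export
compare_proportions <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("compare_proportions expects exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 observations")
  mann_whitney(values[groups == levels(groups)[1L]],
               values[groups == levels(groups)[2L]])
}
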
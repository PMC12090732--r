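# All-pairs Spearman correlation between two gene sets with permutation
# p-values, signed significant-edge summaries, outlier genes, profile
# clustering and quantile-cutoff edge lists.
#
# p-values use the standard Monte-Carlo construction (1 + #{|rho_b| >=
# |rho_obs|}) / (B + 1) with one shared permutation stream per network;
# pairs with n <= 7 samples are tested by full enumeration of the n!
# permutations instead. Multiple testing across the edge set is NOT corrected
# by default (edges are filtered at raw p < alpha); a BH option exists.

#' Spearman correlation with permutation p-value for one gene pair
#'
#' rho is Pearson correlation of average ranks (ties averaged). For n <= 7
#' the two-sided p is exact: the fraction of all n! permutations of y whose
#' |rho| reaches |rho_obs|. Otherwise p = (1 + #{b: |rho_b| >= |rho_obs|}) /
#' (B + 1) over B random permutations.
#'
#' @param x,y numeric vectors of equal length n >= 4, each with at least two
#'   distinct values
#' @param B permutation count for the Monte-Carlo branch (default 9999)
#' @param seed RNG seed for the Monte-Carlo branch
#' @return list with `rho`, `p`, `method` ("exact" or "permutation"), `B`
#' @export
correlate_pair <- function(x, y, B = 9999L, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 7L) {
    perms <- all_permutations(n)
    Y <- matrix(ry[perms], nrow(perms), n)
    rho_b <- as.vector(stats::cor(rx, t(Y)))
    p <- mean(abs(rho_b) >= abs(rho) - .EPS)
    list(rho = rho, p = p, method = "exact", B = nrow(perms))
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(B)) {
      rho_b <- stats::cor(rx, ry[sample.int(n)])
      if (abs(rho_b) >= abs(rho) - .EPS) hits <- hits + 1L
    }
    list(rho = rho, p = (1 + hits) / (B + 1), method = "permutation", B = B)
  }
}

#' All-pairs Spearman correlation network between two gene sets
#'
#' Computes rho and permutation p for every (row gene, column gene) pair
#' using one shared permutation stream: each permutation reshuffles the
#' samples of the second matrix and all pairs are re-evaluated jointly.
#' Genes constant across samples are excluded (with a message).
#'
#' @param mat1,mat2 gene-by-sample count matrices with identical, aligned
#'   samples (n >= 4)
#' @param B permutation count (default 999)
#' @param alpha significance threshold stored with the network
#' @param seed RNG seed
#' @param condition optional label ("single"/"mixed") stored with the network
#' @param adjust p-adjustment across all edges: "none" (default, mirroring
#'   raw-p edge filtering) or "BH"
#' @return object of class `corr_network`: list with `rho` and `p` matrices
#'   (rows = `mat1` genes, columns = `mat2` genes), `alpha`, `B`, `seed`,
#'   `condition`, `dropped` (constant genes)
#' @export
cross_network <- function(mat1, mat2, B = 999L, alpha = 0.05, seed = 1L,
                          condition = NA_character_,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(colnames(mat1), colnames(mat2)))
    stop("matrices must share aligned samples")
  n <- ncol(mat1)
  if (n < 4L) stop("need at least 4 shared samples")
  const1 <- apply(mat1, 1L, function(v) length(unique(v)) < 2L)
  const2 <- apply(mat2, 1L, function(v) length(unique(v)) < 2L)
  dropped <- c(rownames(mat1)[const1], rownames(mat2)[const2])
  if (length(dropped))
    message("excluding ", length(dropped), " constant gene(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  mat1 <- mat1[!const1, , drop = FALSE]
  mat2 <- mat2[!const2, , drop = FALSE]
  if (!nrow(mat1) || !nrow(mat2)) stop("no non-constant genes left")

  r1 <- t(apply(mat1, 1L, rank))
  r2 <- t(apply(mat2, 1L, rank))
  rho <- stats::cor(t(r1), t(r2))
  hits <- matrix(0L, nrow(rho), ncol(rho))
  athr <- abs(rho) - .EPS
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    rho_b <- stats::cor(t(r1), t(r2[, idx, drop = FALSE]))
    hits <- hits + (abs(rho_b) >= athr)
  }
  p <- (1 + hits) / (B + 1)
  if (adjust == "BH")
    p <- matrix(stats::p.adjust(p, "BH"), nrow(p), ncol(p))
  dimnames(p) <- dimnames(rho) <- list(rownames(mat1), rownames(mat2))
  structure(list(rho = rho, p = p, alpha = alpha, B = B, seed = seed,
                 condition = condition, dropped = dropped),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  sc <- signed_counts(x)
  cat("Spearman correlation network: ", nrow(x$rho), " x ", ncol(x$rho),
      " genes, B = ", x$B, "\n", sep = "")
  cat("significant edges at alpha = ", x$alpha, ": ",
      sc$total_pos, " positive, ", sc$total_neg, " negative\n", sep = "")
  invisible(x)
}

#' Signed significant-edge counts and per-gene correlation profiles
#'
#' Edges with p < alpha are counted by the sign of rho; rho = 0 edges count
#' in neither direction.
#'
#' @param net `corr_network` object
#' @param alpha override of the network's stored threshold
#' @return list with `total_pos`, `total_neg`, and `profiles`: a list of two
#'   data.frames (`rows`, `cols`) with per-gene `n_pos`, `n_neg`
#' @export
signed_counts <- function(net, alpha = net$alpha) {
  pos <- net$p < alpha & net$rho > 0
  neg <- net$p < alpha & net$rho < 0
  prof <- function(m_pos, m_neg, ids) {
    data.frame(gene_id = ids, n_pos = as.integer(rowSums(m_pos)),
               n_neg = as.integer(rowSums(m_neg)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(total_pos = sum(pos), total_neg = sum(neg),
       profiles = list(
         rows = prof(pos, neg, rownames(net$rho)),
         cols = prof(t(pos), t(neg), colnames(net$rho))))
}

#' Flag genes with outlying numbers of signed correlations
#'
#' A gene is an outlier if any of its connection counts exceeds the Tukey
#' upper fence (Q3 + 1.5 IQR) of that count's distribution. The rule and
#' fence multiplier are configurable.
#'
#' @param profiles data.frame with a `gene_id` column and one or more numeric
#'   count columns (e.g. n_pos/n_neg per condition); at least 5 rows
#' @param k fence multiplier (default 1.5)
#' @return data.frame with `gene_id`, logical `outlier`, and `triggered_by`
#'   (comma-separated column names that exceeded their fence)
#' @export
detect_outliers <- function(profiles, k = 1.5) {
  if (nrow(profiles) < 5L) stop("need at least 5 profiles")
  num <- vapply(profiles, is.numeric, logical(1)) & names(profiles) != "gene_id"
  cols <- names(profiles)[num]
  if (!length(cols)) stop("no numeric count columns in profiles")
  trig <- matrix(FALSE, nrow(profiles), length(cols),
                 dimnames = list(NULL, cols))
  for (cn in cols) {
    q <- stats::quantile(profiles[[cn]], c(0.25, 0.75), names = FALSE)
    fence <- q[2L] + k * (q[2L] - q[1L])
    trig[, cn] <- profiles[[cn]] > fence
  }
  data.frame(gene_id = profiles$gene_id,
             outlier = rowSums(trig) > 0,
             triggered_by = apply(trig, 1L, function(r)
               paste(cols[r], collapse = ",")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of correlation profiles
#'
#' Agglomerative clustering with Ward (ward.D2) or UPGMA (average) linkage on
#' Euclidean or Bray-Curtis distances.
#'
#' @param x numeric matrix, one profile per row (rownames = ids)
#' @param method linkage: "ward" or "upgma"
#' @param distance "euclidean" or "bray_curtis" (requires nonnegative rows)
#' @param k number of clusters
#' @return list with `labels` (named integer vector) and `tree` (hclust)
#' @export
cluster_profiles <- function(x, method = c("ward", "upgma"),
                             distance = c("euclidean", "bray_curtis"), k) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of profiles")
  d <- switch(distance,
              euclidean = stats::dist(x),
              bray_curtis = bray_curtis(x))
  tree <- stats::hclust(stats::as.dist(d),
                        method = switch(method, ward = "ward.D2",
                                        upgma = "average"))
  list(labels = stats::cutree(tree, k = k), tree = tree)
}

#' Significant-edge list above a |rho| quantile cutoff
#'
#' Retains edges with p < alpha whose |rho| is at or above the given quantile
#' of the significant |rho| values (cutoff 0.75 mirrors a "75% edge cutoff").
#'
#' @param net `corr_network` object
#' @param cutoff_quantile quantile of significant |rho| in `[0, 1]`
#' @return data.frame with `gene1`, `gene2`, `rho`, `p`, `sign`; zero rows if
#'   no significant edge exists
#' @export
edge_list <- function(net, cutoff_quantile = 0.75) {
  sig <- which(net$p < net$alpha & net$rho != 0, arr.ind = TRUE)
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      rho = numeric(0), p = numeric(0), sign = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  rho <- net$rho[sig]
  thr <- stats::quantile(abs(rho), cutoff_quantile, names = FALSE)
  keep <- abs(rho) >= thr - .EPS
  out <- data.frame(gene1 = rownames(net$rho)[sig[keep, 1L]],
                    gene2 = colnames(net$rho)[sig[keep, 2L]],
                    rho = rho[keep], p = net$p[sig][keep],
                    sign = as.integer(sign(rho[keep])),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$rho)), , drop = FALSE]
}
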
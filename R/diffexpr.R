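# Per-gene differential expression between single-infected and mixed
# cultures. The pipeline is nonparametric throughout, so the default
# per-gene test is Mann-Whitney on standardized counts (exact enumeration
# for group sizes up to 8, which handles ties correctly); a Welch t-test on
# log2 counts is available. P-values are Benjamini-Hochberg adjusted within
# the organism's gene set.

#' Pseudocount-stabilized log2 fold change
#'
#' @param mean_ref,mean_alt per-gene group means (reference and alternative,
#'   e.g. single and mixed)
#' @param pseudocount added to both means before the ratio (default 0.5)
#' @return log2((mean_alt + c) / (mean_ref + c))
#' @export
log2_fold_change <- function(mean_ref, mean_alt, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((mean_alt + pseudocount) / (mean_ref + pseudocount))
}

#' Per-gene differential expression test with FDR control
#'
#' @param counts gene-by-sample matrix of standardized counts
#' @param groups two-level grouping vector over samples; the FIRST level is
#'   the reference (single-infected), the second the alternative (mixed)
#' @param alpha FDR threshold for up/down classification (default 0.05)
#' @param method "mann_whitney" (default) or "welch_log"
#' @param pseudocount for the fold change (and the log transform under
#'   welch_log)
#' @return data.frame of class `de_result`: `gene_id`, `log2fc` (alt vs
#'   ref), raw `p`, BH-adjusted `q`, and `class` in up/down/ns
#' @export
de_test <- function(counts, groups, alpha = 0.05,
                    method = c("mann_whitney", "welch_log"),
                    pseudocount = 0.5) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  sizes <- table(groups)
  if (any(sizes < 3L)) stop("each group needs at least 3 samples")
  ref <- groups == levels(groups)[1L]
  m_ref <- rowMeans(counts[, ref, drop = FALSE])
  m_alt <- rowMeans(counts[, !ref, drop = FALSE])
  lfc <- log2_fold_change(m_ref, m_alt, pseudocount)

  if (method == "mann_whitney") {
    ordered <- counts[, c(which(ref), which(!ref)), drop = FALSE]
    p <- mw_pvalues_rows(ordered, n1 = sum(ref))
  } else {
    lg <- log2(counts + pseudocount)
    p <- apply(lg, 1L, function(v) {
      a <- v[ref]; b <- v[!ref]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
      stats::t.test(b, a)$p.value
    })
  }
  q <- stats::p.adjust(p, method = "BH")
  cls <- rep("ns", length(p))
  cls[q < alpha & lfc > 0] <- "up"
  cls[q < alpha & lfc < 0] <- "down"
  out <- data.frame(gene_id = rownames(counts), log2fc = lfc, p = p, q = q,
                    class = cls, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("de_result", class(out))
  out
}

#' Volcano-plot table
#'
#' Result table sorted by q with -log10(q); when written, the header comment
#' carries the up/down counts.
#'
#' @param res `de_result` from [de_test()]
#' @param path optional TSV path to write
#' @return data.frame with `gene_id`, `log2fc`, `neg_log10_q`, `class`
#' @export
volcano_table <- function(res, path = NULL) {
  out <- data.frame(gene_id = res$gene_id, log2fc = res$log2fc,
                    neg_log10_q = -log10(res$q), class = res$class,
                    stringsAsFactors = FALSE)
  out <- out[order(res$q), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# up: %d down: %d ns: %d",
                       sum(res$class == "up"), sum(res$class == "down"),
                       sum(res$class == "ns")), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
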
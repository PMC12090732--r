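# Pathway-level symbiont effect models: for each host pathway, a partial
# dbRDA of the pathway's gene expression on forward-selected symbiont genes
# under five model conditions (each symbiont in its single-infected cultures,
# each symbiont in mixed cultures, and both symbionts jointly in mixed
# cultures). The resulting pathways x conditions matrix of explained
# variability (R2) is clustered with K-means and summarized by within-group
# sum of squares, pseudo-F, percent variance explained and average
# silhouette.

#' Immune and regulatory pathway panel
#'
#' Default display names for the host immune/regulatory pathway panel used by
#' the synthetic annotation (41 signalling, immunity and protein-turnover
#' pathways).
#' @export
immune_regulatory_pathways <- c(
  "Sphingolipid", "JAK_STAT", "TOLL", "Notch", "TOLL_IMD", "Hedgehog",
  "NF_kappa", "NOD_like", "PI3K_Akt", "mTOR", "Wnt", "Oocyte meiosis",
  "Phospholipase D", "Mitophagy", "Autophagy", "Bacterial invasion of EC",
  "Peroxisome", "cAMP", "Endocytosis", "Hippo", "Ras", "ErbB",
  "Regulation of actin cytoskeleton", "Ubiquitin", "Apoptosis", "Proteasome",
  "Rap1", "Calcium", "MAPK", "Insulin", "p53", "Phosphatidylinositol",
  "Phagosome", "Lysozyme", "HIF_1", "TGF_beta", "AMPK", "Apelin",
  "cGMP_PKG", "FoxO", "TNF")

PATHWAY_CONDITIONS <- c("symB_single", "symA_single", "symB_mixed",
                        "symA_mixed", "both")

.condition_spec <- function(cond) {
  switch(cond,
         symA_single = list(status = "singleA", orgs = "symA"),
         symB_single = list(status = "singleB", orgs = "symB"),
         symA_mixed = list(status = "mixed", orgs = "symA"),
         symB_mixed = list(status = "mixed", orgs = "symB"),
         both = list(status = "mixed", orgs = c("symA", "symB")),
         stop("unknown condition: ", cond))
}

#' Per-pathway symbiont effect matrix (partial dbRDA)
#'
#' For every pathway and model condition, the response is the Bray-Curtis
#' distance over the pathway's host genes in the condition's samples; the
#' predictors are forward-selected symbiont genes (log2-transformed counts,
#' candidate pool capped by variance); the culture identity is partialled out
#' as a conditioning variable. The cell value is the explained variability
#' (R2) of the selected model, 0 when no predictor enters. Pathways mapping
#' to fewer than 2 host genes are skipped with a warning.
#'
#' @param host host gene-by-sample count matrix (standardized)
#' @param annotation [annotation_map()] for the host genes
#' @param sym named list of symbiont count matrices (`symA`, `symB`), samples
#'   aligned to `host`
#' @param meta sample table aligned to the matrices
#' @param pathways pathway ids to model; default all in the annotation
#' @param alpha forward-selection entry threshold
#' @param B permutations per selection test
#' @param seed RNG seed
#' @param max_candidates cap on the symbiont candidate-gene pool per model
#'   (most variable genes kept)
#' @param condition_on_culture partial out culture identity (default TRUE)
#' @return object of class `pathway_effects`: list with `R2` (pathways x
#'   conditions matrix), `df` (selected predictor counts), `skipped`
#' @export
pathway_effects <- function(host, annotation, sym, meta, pathways = NULL,
                            alpha = 0.05, B = 99L, seed = 1L,
                            max_candidates = 10L,
                            condition_on_culture = TRUE) {
  if (is.null(pathways))
    pathways <- unique(annotation$pathway_id[!is.na(annotation$pathway_id)])
  if (!length(pathways)) stop("empty pathway list")
  meta <- sample_table(meta)

  R2 <- matrix(NA_real_, length(pathways), length(PATHWAY_CONDITIONS),
               dimnames = list(pathways, PATHWAY_CONDITIONS))
  dfm <- R2
  skipped <- character(0)
  for (pw in pathways) {
    genes <- intersect(pathway_genes(annotation, pw), rownames(host))
    if (length(genes) < 2L) {
      warning("pathway '", pw, "' maps to fewer than 2 host genes; skipped")
      skipped <- c(skipped, pw)
      next
    }
    for (ci in seq_along(PATHWAY_CONDITIONS)) {
      cond <- PATHWAY_CONDITIONS[ci]
      spec <- .condition_spec(cond)
      samp <- meta$sample_id[meta$status == spec$status]
      samp <- intersect(samp, colnames(host))
      sub <- t(host[genes, samp, drop = FALSE])
      ok <- rowSums(sub) > 0
      sub <- sub[ok, , drop = FALSE]
      samp <- samp[ok]
      if (nrow(sub) < 5L) next
      D <- bray_curtis(sub)

      cand <- do.call(rbind, lapply(spec$orgs, function(o)
        sym[[o]][, samp, drop = FALSE]))
      cand <- cand[apply(cand, 1L, function(v) length(unique(v)) > 1L), ,
                   drop = FALSE]
      if (!nrow(cand)) next
      lcand <- log2(cand + 1)
      vs <- apply(lcand, 1L, stats::var)
      keep <- utils::head(order(-vs), max_candidates)
      cdf <- as.data.frame(t(lcand[keep, , drop = FALSE]))

      zc <- NULL
      if (condition_on_culture) {
        cu <- meta$culture[match(samp, meta$sample_id)]
        if (length(unique(cu)) > 1L)
          zc <- data.frame(culture = factor(cu))
      }
      pc <- pcoa(D)
      ## seed keyed to the pathway identity (not its list position) so the
      ## effect matrix is invariant to pathway order
      sel <- forward_select_conditioned(pc, cdf, zc, alpha = alpha, B = B,
                                        seed = derive_seed(seed, ci * 131L +
                                                             sum(utf8ToInt(pw))))
      R2[pw, cond] <- if (is.null(sel$model)) 0 else sel$model$R2
      dfm[pw, cond] <- length(sel$selected)
    }
  }
  structure(list(R2 = R2, df = dfm, skipped = skipped),
            class = "pathway_effects")
}

## Forward selection with a fixed conditioning table kept in every model.
## Used by pathway_effects so culture identity stays partialled out.
forward_select_conditioned <- function(pc, candidates, condition, alpha, B,
                                       seed) {
  if (is.null(condition))
    return(forward_select(pc, candidates, alpha = alpha, B = B, seed = seed))
  selected <- character(0)
  step <- 0L
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    step <- step + 1L
    res <- lapply(seq_along(remaining), function(i) {
      zt <- cbind(condition, candidates[selected])
      fit <- tryCatch(
        dbrda(pc, candidates[remaining[i]], condition = zt, B = B,
              seed = derive_seed(seed, step * 1000L + i)),
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
  }
  model <- if (length(selected))
    tryCatch(dbrda(pc, candidates[selected], condition = condition,
                   B = max(B, 199L), seed = derive_seed(seed, 999999L)),
             error = function(e) NULL) else NULL
  list(selected = selected, model = model)
}

#' K-means clustering of pathway effect profiles
#'
#' Clusters the rows of the R2 matrix; when `k` is NULL it is chosen to
#' maximize the average silhouette over `k_range`. Reports within-group sum
#' of squares, pseudo-F, percent variance explained and average silhouette.
#'
#' @param x pathways-by-conditions numeric matrix (e.g. `$R2` of
#'   [pathway_effects()]); rows with missing values are dropped
#' @param k number of clusters, or NULL to select by silhouette
#' @param k_range candidate k values when `k` is NULL (default 2:8)
#' @param seed RNG seed for the K-means restarts
#' @param nstart K-means restarts (default 25)
#' @return list with `labels` (named), `silhouette` (per pathway), `k` and
#'   `summary` (WGSS, pseudo_F, var_pct, avg_silhouette)
#' @export
cluster_pathways <- function(x, k = NULL, k_range = 2:8, seed = 1L,
                             nstart = 25L) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (!is.null(k) && (k < 2L || k > n))
    stop("k must be between 2 and the number of pathways (", n, ")")
  d <- stats::dist(x)
  fit_k <- function(kk) {
    set.seed(seed)
    km <- stats::kmeans(x, centers = kk, nstart = nstart)
    sil <- cluster::silhouette(km$cluster, d)
    list(km = km, sil = sil, avg = mean(sil[, "sil_width"]))
  }
  if (is.null(k)) {
    k_range <- k_range[k_range >= 2L & k_range < n]
    if (!length(k_range)) stop("no feasible k in k_range")
    fits <- lapply(k_range, fit_k)
    best <- which.max(vapply(fits, `[[`, numeric(1), "avg"))
    k <- k_range[best]
    chosen <- fits[[best]]
  } else {
    chosen <- fit_k(k)
  }
  km <- chosen$km
  wgss <- km$tot.withinss
  bgss <- km$betweenss
  pseudo_F <- (bgss / (k - 1)) / (wgss / (n - k))
  list(labels = stats::setNames(km$cluster, rownames(x)),
       silhouette = stats::setNames(chosen$sil[, "sil_width"], rownames(x)),
       k = k,
       summary = c(WGSS = wgss, pseudo_F = pseudo_F,
                   var_pct = 100 * bgss / km$totss,
                   avg_silhouette = chosen$avg))
}

#' Write a pathway-effect table (pathway, cluster, silhouette, R2 columns)
#'
#' @param eff [pathway_effects()] result
#' @param clust [cluster_pathways()] result on `eff$R2`
#' @param path optional TSV output path
#' @return the assembled data.frame
#' @export
pathway_effect_table <- function(eff, clust, path = NULL) {
  ids <- names(clust$labels)
  out <- data.frame(pathway = ids,
                    cluster = unname(clust$labels),
                    silhouette = unname(clust$silhouette),
                    eff$R2[ids, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$silhouette), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  out
}
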
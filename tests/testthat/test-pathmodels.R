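test_that("pathway effects separate responsive from unresponsive pathways", {
  ds <- generate_dataset(synth_config(seed = 3))
  m <- ds$meta
  std <- standardize_present(ds, seed = 11)
  eff <- suppressWarnings(pathway_effects(
    std$host, ds$annotation, list(symA = std$symA, symB = std$symB), m,
    B = 99, seed = 5))
  truth <- ds$truth$pathway_clusters
  expect_identical(rownames(eff$R2), names(truth))
  resp <- rowMeans(eff$R2[truth == 1L, , drop = FALSE])
  unresp <- rowMeans(eff$R2[truth == 2L, , drop = FALSE])
  expect_gt(min(resp), max(unresp))
  expect_true(all(eff$R2 >= 0 & eff$R2 <= 1, na.rm = TRUE))
  # clustering the profiles recovers the planted two groups
  cl <- cluster_pathways(eff$R2, k = 2, seed = 9)
  expect_gte(adjusted_rand_index(cl$labels[names(truth)], truth), 0.9)
})

test_that("pathways with fewer than two mapped genes are skipped with a warning", {
  ds <- generate_dataset(tiny_config(seed = 7))
  ann <- as.data.frame(ds$annotation)
  extra <- data.frame(gene_id = "hg0024", ko = "K99999",
                      pathway_id = "pw99", pathway_name = "Orphan")
  ann2 <- annotation_map(rbind(ann, extra))
  std <- standardize_present(ds, seed = 2)
  expect_warning(
    eff <- pathway_effects(std$host, ann2,
                           list(symA = std$symA, symB = std$symB), ds$meta,
                           pathways = c(unique(ann$pathway_id), "pw99"),
                           B = 29, seed = 1),
    "pw99")
  expect_true("pw99" %in% eff$skipped)
  expect_error(pathway_effects(std$host, ann2, list(), ds$meta,
                               pathways = character(0)),
               "empty pathway list")
})

test_that("K-means pathway clustering recovers planted profile groups", {
  set.seed(12)
  x <- rbind(matrix(runif(5 * 5, 0.8, 1.0), 5, 5),
             matrix(runif(5 * 5, 0.0, 0.2), 5, 5))
  rownames(x) <- paste0("pw", 1:10)
  colnames(x) <- paste0("c", 1:5)
  cl <- cluster_pathways(x, k = 2, seed = 4)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 5)), 1)
  expect_true(all(cl$silhouette >= -1 & cl$silhouette <= 1))
  # duplicated rows share a label
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2)[11] <- "pw11"
  cl2 <- cluster_pathways(x2, k = 2, seed = 4)
  expect_equal(cl2$labels[["pw1"]], cl2$labels[["pw11"]])
  expect_error(cluster_pathways(x, k = 1), "k must be")
  expect_error(cluster_pathways(x, k = 99), "k must be")
})

test_that("cluster summaries agree with direct recomputation", {
  set.seed(13)
  x <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(paste0("p", 1:8), NULL))
  cl <- cluster_pathways(x, k = 3, seed = 5)
  lab <- cl$labels
  centers <- do.call(rbind, lapply(split(seq_len(8), lab), function(idx)
    colMeans(x[idx, , drop = FALSE])))
  wgss <- sum((x - centers[as.character(lab), ])^2)
  expect_equal(unname(cl$summary["WGSS"]), wgss, tolerance = 1e-9)
  sil <- cluster::silhouette(lab, stats::dist(x))
  expect_equal(unname(cl$summary["avg_silhouette"]),
               mean(sil[, "sil_width"]), tolerance = 1e-9)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(unname(cl$summary["var_pct"]), 100 * (tss - wgss) / tss,
               tolerance = 1e-9)
})

test_that("silhouette-based selection picks a sensible k", {
  set.seed(14)
  x <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2), matrix(rnorm(12, 5, 0.1), 6, 2))
  rownames(x) <- paste0("p", 1:12)
  cl <- cluster_pathways(x, k = NULL, k_range = 2:6, seed = 6)
  expect_equal(cl$k, 2)
})

test_that("the effect matrix is invariant to pathway order", {
  ds <- generate_dataset(tiny_config(seed = 9))
  std <- standardize_present(ds, seed = 3)
  pws <- unique(ds$annotation$pathway_id)
  e1 <- suppressWarnings(pathway_effects(
    std$host, ds$annotation, list(symA = std$symA, symB = std$symB),
    ds$meta, pathways = pws, B = 29, seed = 2))
  e2 <- suppressWarnings(pathway_effects(
    std$host, ds$annotation, list(symA = std$symA, symB = std$symB),
    ds$meta, pathways = rev(pws), B = 29, seed = 2))
  expect_equal(e1$R2[pws, ], e2$R2[pws, ])
})
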
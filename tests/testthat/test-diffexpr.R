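test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(1, 4, pseudocount = 1e-9), 2,
               tolerance = 1e-6)
  # monotone in the alternative mean
  expect_true(all(diff(log2_fold_change(2, c(1, 2, 4, 8))) > 0))
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "pseudocount")
})

test_that("BH adjustment matches the step-up formula", {
  # classic fixed vector: all q equal min_j>=i (m/j) p_j = 0.04
  res <- stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH")
  expect_equal(res, rep(0.04, 4))
  # monotonicity in p-rank and q >= p inside de_test output
  ds <- generate_dataset(tiny_config(seed = 30))
  m <- ds$meta
  x <- ds$counts$host
  grp <- factor(ifelse(m$status == "mixed", "mixed", "single"),
                levels = c("single", "mixed"))
  de <- de_test(x, grp)
  expect_true(all(de$q >= de$p - 1e-12))
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-12))
})

test_that("classification is consistent with q, alpha and the fold-change sign", {
  ds <- generate_dataset(tiny_config(seed = 31))
  m <- ds$meta
  grp <- factor(ifelse(m$status == "mixed", "mixed", "single"),
                levels = c("single", "mixed"))
  de <- de_test(ds$counts$host, grp, alpha = 0.05)
  expect_true(all((de$class != "ns") == (de$q < 0.05 & de$log2fc != 0)))
  expect_true(all(de$log2fc[de$class == "up"] > 0))
  expect_true(all(de$log2fc[de$class == "down"] < 0))
})

test_that("identical groups produce no calls", {
  x <- matrix(rep(c(3L, 8L, 1L), each = 8), 3, 8, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  de <- de_test(x, rep(c("a", "b"), each = 4))
  expect_true(all(de$class == "ns"))
  expect_true(all(de$p == 1))
  expect_error(de_test(x, c("a", rep("b", 7))), "at least 3")
})

test_that("planted DE genes are recovered with controlled FDR", {
  sens <- fdr <- numeric(20)
  for (i in 1:20) {
    ds <- generate_dataset(synth_config(seed = 40 + i))
    m <- ds$meta
    x <- ds$counts$symA[, colSums(ds$counts$symA) > 0, drop = FALSE]
    std <- suppressWarnings(downsample_to_min(x, seed = i))
    s <- colnames(std)
    grp <- factor(ifelse(m$status[match(s, m$sample_id)] == "mixed",
                         "mixed", "single"), levels = c("single", "mixed"))
    de <- de_test(std, grp)
    truth <- ds$truth$de$symA$gene_id
    hits <- de$gene_id[de$class != "ns"]
    sens[i] <- mean(truth %in% hits)
    fdr[i] <- if (length(hits)) mean(!hits %in% truth) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.1)
})

test_that("recovered fold-change signs match the planted directions", {
  ds <- generate_dataset(synth_config(seed = 50))
  m <- ds$meta
  x <- ds$counts$symB[, colSums(ds$counts$symB) > 0, drop = FALSE]
  std <- suppressWarnings(downsample_to_min(x, seed = 1))
  s <- colnames(std)
  grp <- factor(ifelse(m$status[match(s, m$sample_id)] == "mixed",
                       "mixed", "single"), levels = c("single", "mixed"))
  de <- de_test(std, grp)
  tr <- ds$truth$de$symB
  got <- de$log2fc[match(tr$gene_id, de$gene_id)]
  expect_true(all(sign(got) == tr$sign))
})

test_that("volcano tables round-trip with conserved class counts", {
  ds <- generate_dataset(tiny_config(seed = 33))
  m <- ds$meta
  grp <- factor(ifelse(m$status == "mixed", "mixed", "single"),
                levels = c("single", "mixed"))
  de <- de_test(ds$counts$host, grp)
  path <- withr::local_tempfile(fileext = ".tsv")
  vt <- volcano_table(de, path)
  expect_true(all(diff(vt$neg_log10_q) <= 1e-12))  # sorted by ascending q
  expect_equal(table(vt$class), table(de$class))
  hdr <- readLines(path, n = 1)
  expect_match(hdr, sprintf("up: %d down: %d", sum(de$class == "up"),
                            sum(de$class == "down")))
  back <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(back), nrow(vt))
  expect_equal(back$log2fc, vt$log2fc)
})
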
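test_that("correlate_pair matches exhaustive enumeration for small n", {
  # monotone n = 4 pair: rho = 1, two-sided exact p = 2/24 (identity and
  # full reversal are the only permutations attaining |rho| = 1)
  r <- correlate_pair(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$rho, 1)
  expect_equal(r$p, 2 / 24)
  expect_identical(r$method, "exact")

  r2 <- correlate_pair(1:5, 5:1)
  expect_equal(r2$rho, -1)

  # random cases (with ties) agree with the unranking-based oracle
  set.seed(13)
  for (n in c(4, 5, 6)) {
    x <- sample(4, n, replace = TRUE)
    y <- sample(4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(correlate_pair(x, y)$p, oracle_spearman_exact_p(x, y))
  }

  # rho with ties equals Pearson on average ranks
  x <- c(1, 1, 2, 5, 3); y <- c(2, 4, 4, 1, 9)
  expect_equal(correlate_pair(x, y)$rho, stats::cor(rank(x), rank(y)))
  expect_error(correlate_pair(rep(1, 5), 1:5), "constant")
  expect_error(correlate_pair(1:3, 3:1), "at least 4")
})

test_that("Monte-Carlo permutation p never drops below 1/(B+1) and is seeded", {
  x <- 1:10; y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  r1 <- correlate_pair(x, y, B = 99, seed = 5)
  r2 <- correlate_pair(x, y, B = 99, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 100)
  r3 <- correlate_pair(x, x + 0.0, B = 99, seed = 5)
  expect_equal(r3$p, 1 / 100)
})

test_that("cross_network is rank-invariant and self-correlation is 1", {
  ds <- generate_dataset(tiny_config(seed = 21))
  m <- ds$counts$symA[1:6, 1:8]
  net <- suppressMessages(cross_network(m, m, B = 49, seed = 1))
  expect_equal(unname(diag(net$rho)), rep(1, 6))
  net10 <- suppressMessages(cross_network(m, m * 10L, B = 49, seed = 1))
  expect_equal(net10$rho, net$rho)
  expect_true(all(net$p >= 1 / 50))
  expect_error(suppressMessages(cross_network(m[, 1:3], m[, 1:3])),
               "at least 4")
})

test_that("constant genes are excluded from networks", {
  x <- matrix(c(rep(3L, 6), 1L, 5L, 2L, 8L, 4L, 6L), 2, 6, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("s", 1:6)))
  y <- matrix(sample(10L, 12L, TRUE), 2, 6,
              dimnames = list(c("y1", "y2"), paste0("s", 1:6)))
  expect_message(net <- cross_network(x, y, B = 19), "flat")
  expect_identical(rownames(net$rho), "var")
})

test_that("signed counts are conserved across per-gene profiles", {
  # hand-built network: fixed rho and p with known sign pattern
  rho <- matrix(c(0.9, -0.8, 0, 0.7, -0.6, 0.5, -0.4, 0.3, 0.2), 3, 3,
                dimnames = list(paste0("a", 1:3), paste0("b", 1:3)))
  p <- matrix(c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01, 0.01, 0.2, 0.2), 3, 3,
              dimnames = dimnames(rho))
  net <- structure(list(rho = rho, p = p, alpha = 0.05, B = 99),
                   class = "corr_network")
  sc <- signed_counts(net)
  # significant cells: (1,1)+, (2,1)-, (3,1) rho=0, (2,2)-, (3,2)+, (1,3)-
  expect_equal(sc$total_pos, 2)
  expect_equal(sc$total_neg, 3)
  expect_equal(sum(sc$profiles$rows$n_pos), sc$total_pos)
  expect_equal(sum(sc$profiles$rows$n_neg), sc$total_neg)
  expect_equal(sum(sc$profiles$cols$n_pos), sc$total_pos)
  expect_equal(sum(sc$profiles$cols$n_neg), sc$total_neg)
  # all p >= alpha gives zero counts
  net0 <- structure(list(rho = rho, p = p * 100, alpha = 0.05, B = 99),
                    class = "corr_network")
  expect_equal(signed_counts(net0)$total_pos + signed_counts(net0)$total_neg, 0)
})

test_that("outlier detection applies Tukey fences per count column", {
  prof <- data.frame(gene_id = paste0("g", 1:10),
                     n_pos = c(rep(2L, 9), 100L),
                     n_neg = rep(3L, 10))
  out <- detect_outliers(prof)
  expect_identical(out$gene_id[out$outlier], "g10")
  expect_identical(out$triggered_by[out$outlier], "n_pos")
  # equal counts: IQR 0, fence = Q3, nothing strictly above
  flat <- data.frame(gene_id = paste0("g", 1:6), n_pos = rep(4L, 6))
  expect_false(any(detect_outliers(flat)$outlier))
  # fence value agrees with a direct quantile computation
  set.seed(3)
  v <- c(rpois(19, 4), 40L)
  pr <- data.frame(gene_id = paste0("g", 1:20), n_pos = v)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  manual <- v > q[2] + 1.5 * (q[2] - q[1])
  expect_identical(detect_outliers(pr)$outlier, manual)
  expect_error(detect_outliers(prof[1:3, ]), "at least 5")
})

test_that("profile clustering recovers planted blobs and merges duplicates", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  rownames(x) <- paste0("g", 1:20)
  for (meth in c("ward", "upgma")) {
    cl <- cluster_profiles(x, method = meth, k = 2)
    expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 10)), 1)
  }
  # k = n gives singletons
  cl_n <- cluster_profiles(x, k = 20)
  expect_equal(length(unique(cl_n$labels)), 20)
  # duplicated rows merge first
  y <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  tr <- cluster_profiles(y, k = 2)
  expect_equal(tr$labels[["a"]], tr$labels[["b"]])
  expect_error(cluster_profiles(y, k = 5), "exceeds")
})

test_that("edge lists respect the |rho| quantile cutoff", {
  rho <- matrix(c(0.9, -0.5, 0.3, -0.7), 2, 2,
                dimnames = list(c("a1", "a2"), c("b1", "b2")))
  p <- matrix(0.01, 2, 2, dimnames = dimnames(rho))
  net <- structure(list(rho = rho, p = p, alpha = 0.05, B = 99),
                   class = "corr_network")
  expect_equal(nrow(edge_list(net, 0)), 4)          # all significant edges
  top <- edge_list(net, 1)                          # only the max-|rho| edge
  expect_identical(top$gene1, "a1")
  expect_equal(top$rho, 0.9)
  # quantile semantics: |rho| = (.3,.5,.7,.9), cutoff 0.5 -> threshold is the
  # median 0.6, so exactly the two strongest edges remain
  el <- edge_list(net, 0.5)
  expect_equal(sort(abs(el$rho)), c(0.7, 0.9))
  # no significant edges -> empty data.frame, not an error
  net0 <- structure(list(rho = rho, p = p + 0.99, alpha = 0.05, B = 99),
                    class = "corr_network")
  expect_equal(nrow(edge_list(net0)), 0)
})

test_that("network edge significance is calibrated under the null", {
  set.seed(99)
  n <- 12
  x <- matrix(rnorm(25 * n), 25, n, dimnames = list(paste0("a", 1:25),
                                                    paste0("s", 1:n)))
  y <- matrix(rnorm(25 * n), 25, n, dimnames = list(paste0("b", 1:25),
                                                    paste0("s", 1:n)))
  net <- cross_network(x, y, B = 199, seed = 4)
  expect_gte(length(net$p), 500)
  expect_lt(abs(mean(net$p < 0.05) - 0.05), 0.02)
})
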
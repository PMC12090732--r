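test_that("Bray-Curtis follows the defining formula", {
  x <- rbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  expect_equal(as.numeric(bray_curtis(x)), (2 + 0 + 2) / (4 + 4 + 4))
  same <- rbind(a = c(2, 5), b = c(2, 5))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- rbind(a = c(3, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("robust Aitchison reduces to CLR on dense data and is scale invariant", {
  set.seed(10)
  m <- matrix(rpois(7 * 9, 60) + 1L, 7, 9,
              dimnames = list(paste0("s", 1:7), NULL))
  clr <- log(m) - rowMeans(log(m))
  expect_equal(as.matrix(robust_aitchison(m)), as.matrix(stats::dist(clr)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # multiplying one sample leaves its distances unchanged (CLR invariance)
  m2 <- m; m2[3, ] <- m2[3, ] * 50L
  expect_equal(as.matrix(robust_aitchison(m2)), as.matrix(robust_aitchison(m)),
               tolerance = 1e-12)
  expect_equal(as.matrix(robust_aitchison(m))["s2", "s2"], 0)
  # disjoint supports are an error naming the pair
  bad <- rbind(s1 = c(2, 3, 0, 0), s2 = c(0, 0, 4, 5))
  expect_error(robust_aitchison(bad), "s1.*s2")
})

test_that("PCoA reconstructs planted geometry and conserves inertia", {
  set.seed(11)
  P <- matrix(rnorm(12 * 2), 12, 2)
  rownames(P) <- paste0("s", 1:12)
  pc <- pcoa(stats::dist(P))
  expect_lt(vegan::procrustes(P, pc$points[, 1:2])$ss, 1e-8)
  # inertia conservation: positive eigenvalue sum = sum of squared coords
  expect_equal(pc$total_inertia, sum(pc$points^2))
  # duplicated samples map to identical coordinates
  P2 <- rbind(P, P[1, , drop = FALSE])
  pc2 <- pcoa(stats::dist(P2))
  expect_equal(pc2$points[1, ], pc2$points[13, ], tolerance = 1e-8)
})

test_that("dbRDA matches classical RDA on Euclidean distances", {
  set.seed(12)
  for (i in 1:3) {
    Y <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(paste0("s", 1:10), NULL))
    X <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    fit <- dbrda(stats::dist(Y), X, B = 0)
    vf <- vegan::rda(Y ~ a + b + c, data = X)
    expect_equal(fit$eig_constrained / (10 - 1), unname(vf$CCA$eig),
                 tolerance = 1e-8)
    expect_equal(fit$R2, vegan::RsquareAdj(vf)$r.squared, tolerance = 1e-8)
  }
})

test_that("partial dbRDA matches vegan's conditioned model", {
  set.seed(14)
  Y <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(paste0("s", 1:12), NULL))
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  Z <- data.frame(cv = rnorm(12))
  fit <- dbrda(stats::dist(Y), X, condition = Z, B = 0)
  dat <- cbind(X, Z)
  D <- stats::dist(Y)
  vp <- eval(parse(text = "vegan::dbrda(D ~ a + b + Condition(cv), data = dat)"))
  expect_equal(fit$R2, vp$CCA$tot.chi / vp$tot.chi, tolerance = 1e-8)
  expect_equal(fit$F, stats::anova(vp, permutations = 99)$F[1],
               tolerance = 1e-8)
})

test_that("saturated dbRDA explains everything and collinearity errors", {
  set.seed(15)
  Y <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  pc <- pcoa(stats::dist(Y))
  fit <- dbrda(stats::dist(Y), as.data.frame(pc$points), B = 0)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  X <- data.frame(a = rnorm(8))
  X$b <- 2 * X$a
  expect_error(dbrda(stats::dist(Y), X), "collinear.*b")
})

test_that("dbRDA permutation p is uniform under a null predictor", {
  ps <- vapply(1:300, function(i) {
    set.seed(5000 + i)
    Y <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(paste0("s", 1:10), NULL))
    dbrda(stats::dist(Y), data.frame(x = rnorm(10)), B = 199, seed = i)$p
  }, numeric(1))
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("forward selection finds a planted informative predictor", {
  set.seed(17)
  hits <- 0L
  nseeds <- 10L
  for (i in seq_len(nseeds)) {
    z <- rnorm(16)
    Y <- matrix(rnorm(16 * 6), 16, 6) + z  # all genes track z
    rownames(Y) <- paste0("s", 1:16)
    cand <- data.frame(info = z + rnorm(16, 0, 0.2),
                       n1 = rnorm(16), n2 = rnorm(16),
                       n3 = rnorm(16), n4 = rnorm(16))
    fs <- forward_select(stats::dist(Y), cand, B = 99, seed = i)
    if (length(fs$selected) && fs$selected[1] == "info") hits <- hits + 1L
  }
  expect_gte(hits / nseeds, 0.9)
})

test_that("forward selection with alpha = 1 and no guard admits everything in p-order", {
  set.seed(18)
  Y <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(paste0("s", 1:12), NULL))
  cand <- data.frame(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  fs <- forward_select(stats::dist(Y), cand, alpha = 1.01, B = 49, seed = 2,
                       adjr2_guard = FALSE)
  expect_setequal(fs$selected, c("a", "b", "c"))
  expect_equal(fs$steps$variable, fs$selected)
})

test_that("ANOSIM matches its bounds, oracle, and enumeration", {
  # two groups, all between-distances larger than within: R = 1
  P <- rbind(matrix(rnorm(8, 0, 0.01), 4, 2), matrix(rnorm(8, 10, 0.01), 4, 2))
  rownames(P) <- paste0("s", 1:8)
  g <- rep(c("a", "b"), each = 4)
  res <- anosim_test(stats::dist(P), g)
  expect_equal(res$R, 1)
  expect_identical(res$method, "exact")
  expect_equal(res$p, 2 / choose(8, 4))  # the two perfect splits

  # random small cases agree with the brute-force oracle
  set.seed(19)
  for (i in 1:3) {
    Dm <- as.matrix(stats::dist(matrix(rnorm(8 * 3), 8, 3)))
    res2 <- anosim_test(Dm, g)
    expect_equal(res2$R, oracle_anosim_R(Dm, as.integer(factor(g))))
    expect_equal(res2$p, oracle_anosim_exact_p(Dm, g))
  }
  expect_error(anosim_test(stats::dist(P), c("a", rep("b", 7))), "singleton")
})

test_that("ANOSIM R is invariant under monotone distance transforms and null-centered", {
  set.seed(20)
  Dm <- as.matrix(stats::dist(matrix(rnorm(10 * 3), 10, 3)))
  g <- rep(c("a", "b"), each = 5)
  r1 <- anosim_test(Dm, g)$R
  r2 <- anosim_test(Dm^2, g)$R       # squaring preserves distance ranks
  expect_equal(r1, r2)
  Rs <- vapply(1:300, function(i) {
    set.seed(1000 + i)
    D <- stats::dist(matrix(rnorm(10 * 3), 10, 3))
    anosim_test(D, sample(g), B = 0, exact_limit = 1)$R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 0.05)
})

test_that("pairwise ANOSIM applies Bonferroni over the group pairs", {
  set.seed(21)
  P <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 5, 0.1), 5, 2),
             matrix(rnorm(10, 20, 0.1), 5, 2))
  rownames(P) <- paste0("s", 1:15)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- anosim_test(stats::dist(P), g, B = 99, seed = 3)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p * 3))
})

test_that("SIMPER contributions decompose the between-group dissimilarity", {
  set.seed(22)
  x <- matrix(abs(rnorm(8 * 6)) + 0.1, 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("v", 1:6)))
  g <- rep(c("a", "b"), each = 4)
  sp <- simper(x, g)
  bc <- as.matrix(bray_curtis(x))
  expect_equal(attr(sp, "overall_dissimilarity"), mean(bc[1:4, 5:8]),
               tolerance = 1e-9)
  expect_true(all(sp$contribution >= 0))
  expect_true(all(diff(sp$contribution) <= 0))
  expect_equal(sp$cumulative_pct[6], 100)
  # constant variable contributes 0
  x0 <- cbind(x, const = 1)
  expect_equal(simper(x0, g)$contribution[simper(x0, g)$variable == "const"], 0)
  expect_error(simper(x, rep(c("a", "b", "c"), c(3, 3, 2))), "two groups")
})

test_that("SIMPER matches a hand-enumerated two-variable toy", {
  x <- rbind(s1 = c(1, 3), s2 = c(2, 2), s3 = c(5, 1), s4 = c(4, 4))
  colnames(x) <- c("v1", "v2")
  g <- c("a", "a", "b", "b")
  # pairs (s1,s3), (s1,s4), (s2,s3), (s2,s4); denominators are the pair totals
  c1 <- mean(c(abs(1 - 5) / 10, abs(1 - 4) / 12, abs(2 - 5) / 10,
               abs(2 - 4) / 12))
  c2 <- mean(c(abs(3 - 1) / 10, abs(3 - 4) / 12, abs(2 - 1) / 10,
               abs(2 - 4) / 12))
  sp <- simper(x, g)
  expect_equal(sp$contribution[sp$variable == "v1"], c1, tolerance = 1e-12)
  expect_equal(sum(sp$contribution), c1 + c2, tolerance = 1e-12)
})
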
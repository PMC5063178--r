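# Rank statistics, FDR control, correlation matrices, clustering, newick.

test_that("Spearman's rho handles monotone data, ties and transforms", {
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 4, 9, 16))$rho, 1,
               tolerance = 1e-12)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(16, 9, 4, 1))$rho, -1,
               tolerance = 1e-12)

  # tied data against the midrank formula computed by hand
  x <- c(1, 2, 2, 3); y <- c(2, 1, 3, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(2, 1, 3, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y)$rho, oracle, tolerance = 1e-12)

  # invariance under strictly monotone transforms of either input
  set.seed(3)
  a <- rnorm(25); b <- rnorm(25)
  base <- spearman_cor(a, b)$rho
  expect_equal(spearman_cor(exp(a), b)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_cor(a, b^3 + 5 * b)$rho, base, tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("Spearman p-values: exact permutation for small n, t otherwise", {
  # perfect monotone sequence of 5: only the two extreme orderings of 120
  # reach |rho| = 1
  s <- spearman_cor(1:5, c(2, 3, 5, 8, 13))
  expect_equal(s$rho, 1, tolerance = 1e-12)
  expect_equal(s$p_value, 2 / 120, tolerance = 1e-12)

  # n > 8 uses the t approximation
  set.seed(11)
  x <- rnorm(20); y <- x + rnorm(20, sd = 2)
  s <- spearman_cor(x, y)
  tstat <- s$rho * sqrt((20 - 2) / (1 - s$rho^2))
  expect_equal(s$p_value, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the rank-sum formula and rejects degenerate input", {
  out <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  # ranks 1..6, no ties; rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(out$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(out$H, 3.857, tolerance = 1e-3)
  expect_equal(out$df, 1)

  # invariance under strictly monotone transforms of the values
  set.seed(7)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(exp(v), g)$H, kruskal_wallis(v, g)$H,
               tolerance = 1e-12)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)), "tied")
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= pmin(1, p * 40)))
  # monotone: adjusted values preserve the raw order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("correlation matrices use pairwise-complete observations with FDR", {
  set.seed(17)
  tb <- data.frame(A = rnorm(8), B = rnorm(8), C = rnorm(8))
  tb$B <- tb$A + rnorm(8, sd = 0.01)  # nearly identical ranks
  tb$A[6:8] <- NA                     # pair (A,B) shares 5 rows
  tb$C[c(1, 6:8)] <- NA               # pair (A,C) shares 4 rows
  cm <- corr_matrix(tb)
  expect_equal(cm$n["A", "B"], 5L)
  expect_equal(cm$n["A", "C"], 4L)
  expect_equal(cm$rho["A", "B"], 1, tolerance = 1e-12)
  # q matrix equals BH applied to the vectorized upper-triangle p-values
  up <- upper.tri(cm$p)
  expect_equal(cm$q[up], bh_adjust(cm$p[up]), tolerance = 1e-12)
  expect_true(isSymmetric(cm$rho))

  ident <- corr_matrix(data.frame(x = 1:6, y = 1:6))
  expect_equal(ident$rho["x", "y"], 1, tolerance = 1e-12)
})

test_that("correlation-distance clustering merges the closest pair first", {
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  hc <- hcluster(r)
  expect_equal(hc$height[1], 1 - 0.9, tolerance = 1e-12)
  # first merge joins the two original items t1, t2
  expect_true(all(hc$merge[1, ] < 0))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("t1", "t2"))
  # topology ((t1,t2),t3) survives the newick roundtrip
  phy <- ape::read.tree(text = to_newick(hc))
  pair <- ape::extract.clade(phy, ape::getMRCA(phy, c("t1", "t2")))
  expect_setequal(pair$tip.label, c("t1", "t2"))

  # identical items merge at height zero
  tb <- data.frame(a = 1:6, b = 1:6, c = 1:6)
  expect_true(all(abs(hcluster(tb)$height) < 1e-12))
})

test_that("complete linkage agrees with a brute-force agglomeration oracle", {
  set.seed(19)
  for (rep in 1:5) {
    tb <- as.data.frame(matrix(rnorm(8 * 6), 8, 6))
    names(tb) <- paste0("t", 1:6)
    r <- cor(tb, method = "spearman")
    hc <- hcluster(tb)
    expect_equal(sort(hc$height), bf_linkage_heights(1 - r, "complete"),
                 tolerance = 1e-12)
    # average linkage against the same oracle
    hca <- hcluster(tb, linkage = "average")
    expect_equal(sort(hca$height), bf_linkage_heights(1 - r, "average"),
                 tolerance = 1e-12)
  }
})

test_that("clustering is invariant to item order up to relabeling", {
  set.seed(23)
  tb <- as.data.frame(matrix(rnorm(10 * 5), 10, 5))
  names(tb) <- paste0("t", 1:5)
  hc1 <- hcluster(tb)
  perm <- sample(5)
  hc2 <- hcluster(tb[, perm])
  expect_equal(sort(hc1$height), sort(hc2$height), tolerance = 1e-12)
  c1 <- as.matrix(cophenetic(hc1))
  c2 <- as.matrix(cophenetic(hc2))
  expect_equal(c1[names(tb), names(tb)], c2[names(tb), names(tb)],
               tolerance = 1e-12)
})

test_that("newick export carries merge heights as branch lengths", {
  r <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  hc <- hcluster(r)
  s <- to_newick(hc)
  phy <- ape::read.tree(text = s)
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(unname(phy$edge.length), c(0.6, 0.6), tolerance = 1e-9)

  # roundtrip on a bigger tree: leaf-to-leaf path lengths equal twice the
  # cophenetic merge heights
  set.seed(29)
  tb <- as.data.frame(matrix(rnorm(12 * 6), 12, 6))
  names(tb) <- paste0("t", 1:6)
  hc <- hcluster(tb)
  path <- withr::local_tempfile(fileext = ".nwk")
  to_newick(hc, path)
  phy <- ape::read.tree(path)
  dist_tree <- ape::cophenetic.phylo(phy)
  dist_hc <- as.matrix(cophenetic(hc))
  nm <- rownames(dist_hc)
  expect_equal(dist_tree[nm, nm], 2 * dist_hc[nm, nm], tolerance = 1e-9)
})
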
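test_that("exact Wilcoxon p equals the all-positive-differences closed case", {
  w <- paired_wilcoxon(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w$statistic, 15)
  expect_equal(w$p_raw, 0.0625)  # 2 * P(W = 15) = 2/32
  expect_true(w$exact)
})

test_that("identical vectors are degenerate with p = 1", {
  w <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_true(w$degenerate)
  expect_equal(w$p_raw, 1)
  expect_equal(w$n, 0L)
})

test_that("exact branch agrees with full sign-pattern enumeration, ties included", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    x <- round(rexp(n, 1 / 50), -1)  # rounding creates ties and zeros
    y <- round(rexp(n, 1 / 50), -1)
    expect_equal(paired_wilcoxon(x, y)$p_raw, enum_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("p is invariant under common rescaling and node permutation", {
  set.seed(5)
  x <- rexp(12, 1 / 100); y <- rexp(12, 1 / 100)
  p0 <- paired_wilcoxon(x, y)$p_raw
  expect_equal(paired_wilcoxon(3.7 * x, 3.7 * y)$p_raw, p0)
  i <- sample(12)
  expect_equal(paired_wilcoxon(x[i], y[i])$p_raw, p0)
})

test_that("large-n branch matches the tie-corrected normal approximation of wilcox.test", {
  set.seed(17)
  x <- rexp(60, 1 / 100); y <- rexp(60, 1 / 120)
  mine <- paired_wilcoxon(x, y)
  expect_false(mine$exact)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_raw, unname(ref$p.value), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.003, 0.04, 0.6, 0.01, 1)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw-p rank
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("two points at dissimilarity 10 embed at ±5 on the first axis", {
  d <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  e <- mds_embed(d, dims = 1)
  expect_equal(unname(sort(abs(e$coordinates[, 1]))), c(5, 5))
  expect_equal(sum(e$coordinates[, 1]), 0)  # centroid at origin
})

test_that("Euclidean-embeddable dissimilarities are recovered exactly", {
  # equilateral triangle, side 1
  d <- matrix(1, 3, 3) - diag(3)
  e <- mds_embed(d, dims = 2)
  expect_equal(as.vector(dist(e$coordinates)), rep(1, 3), tolerance = 1e-9)
  # eigenvalue sum equals the trace of the centered Gram matrix (= sum of
  # squared centered coordinates for Euclidean input)
  expect_equal(sum(e$eigenvalues), sum(e$coordinates^2), tolerance = 1e-9)
})

test_that("a known 2D configuration is recovered up to rotation/reflection", {
  set.seed(23)
  conf <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(conf))
  e <- mds_embed(d, dims = 2)
  expect_lt(procrustes_rmsd(conf, e$coordinates), 1e-6)
})

test_that("invalid MDS input is rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(mds_embed(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(mds_embed(neg), "non-negative")
  diag_bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mds_embed(diag_bad), "diagonal")
})
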
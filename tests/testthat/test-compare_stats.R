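test_that("D matches the hand-computed two-source example and is zero for identical columns", {
  m <- cbind(x = c(100, 200), y = c(150, 300))
  d <- deviation_from_group_mean(m)
  expect_equal(unname(d$D), c(-20, 20))
  expect_equal(d$n_nodes, 2L)

  same <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(deviation_from_group_mean(same)$D), c(0, 0))
})

test_that("D sums to zero over any group (signed definition identity)", {
  for (seed in 1:10) {
    m <- random_age_matrix(50, sprintf("s%d", 1:6), seed)
    d <- deviation_from_group_mean(m)
    expect_lt(abs(sum(d$D)), 1e-9)
    # subgroup means are recomputed per group
    d3 <- deviation_from_group_mean(m, group = c("s2", "s4", "s5"))
    expect_lt(abs(sum(d3$D)), 1e-9)
  }
})

test_that("P matches hand values, is antisymmetric, and abs P bounds signed P", {
  m <- cbind(x = c(150, 300), y = c(100, 200))
  expect_equal(pairwise_mean_difference(m, "x", "y"), 75)
  expect_equal(pairwise_mean_difference(m, "y", "x"), -75)
  expect_equal(pairwise_mean_difference(m, "x", "y", signed = FALSE), 75)

  r <- random_age_matrix(40, c("a", "b"), 7)
  ps <- pairwise_mean_difference(r, "a", "b")
  expect_equal(pairwise_mean_difference(r, "b", "a"), -ps)
  expect_gte(pairwise_mean_difference(r, "a", "b", signed = FALSE), abs(ps))
  expect_error(pairwise_mean_difference(r, "a", "zz"), "unknown source")
})

test_that("P% follows its closed forms", {
  # y = 1.5 x at every node: per-node |difference| / mean = 0.5/1.25 -> 40%
  m <- cbind(x = c(100, 240, 17), y = 1.5 * c(100, 240, 17))
  expect_equal(pairwise_percent_difference(m, "x", "y", signed = FALSE), 40)
  expect_equal(pairwise_percent_difference(m, "x", "y", signed = TRUE), -40)
  # single node 300 vs 100 -> 100 * 200 / 200 = 100%
  one <- cbind(x = 300, y = 100)
  expect_equal(pairwise_percent_difference(one, "x", "y"), 100)
})

test_that("pure scale bias b gives |P%| = 200(b-1)/(b+1) and pair D = ±100(b-1)/(b+1)", {
  for (b in c(1.2, 1.5, 2, 3)) {
    m <- cbind(lo = c(50, 500, 1500), hi = b * c(50, 500, 1500))
    expect_equal(pairwise_percent_difference(m, "hi", "lo", signed = FALSE),
                 200 * (b - 1) / (b + 1))
    d <- deviation_from_group_mean(m)
    expect_equal(unname(d$D), c(-1, 1) * 100 * (b - 1) / (b + 1))
  }
})

test_that("statistics are invariant under node permutation", {
  m <- random_age_matrix(30, c("a", "b", "c"), 3)
  p <- sample(nrow(m))
  mp <- m[p, ]
  expect_equal(deviation_from_group_mean(mp)$D, deviation_from_group_mean(m)$D)
  expect_equal(pairwise_mean_difference(mp, "a", "c"),
               pairwise_mean_difference(m, "a", "c"))
  expect_equal(pairwise_percent_difference(mp, "b", "c"),
               pairwise_percent_difference(m, "b", "c"))
})

test_that("pairwise matrices have the right symmetry, diagonal, and entries", {
  m <- random_age_matrix(25, c("a", "b", "c"), 9)
  m <- cbind(m, d = 1.5 * m[, "a"])
  for (stat in c("P", "Ppct")) {
    s <- pairwise_matrix(m, stat, signed = TRUE)
    expect_equal(unname(diag(s)), rep(0, 4))
    expect_equal(unclass(s), -t(unclass(s)), ignore_attr = TRUE)
    a <- pairwise_matrix(m, stat, signed = FALSE)
    expect_equal(unclass(a), t(unclass(a)), ignore_attr = TRUE)
    expect_true(all(a >= 0))
  }
  pa <- pairwise_matrix(m, "Ppct", signed = FALSE)
  expect_equal(pa["a", "d"], 40)
  expect_true(all(abs(pa) <= 200))
})
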
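test_that("Yule simulation is ultrametric, correctly sized, and seed-deterministic", {
  t2 <- simulate_yule(2, 1, seed = 1)
  expect_equal(t2$phy$Nnode, 1L)
  expect_gt(t2$root_age, 0)

  for (n in c(5, 50)) {
    tr <- simulate_yule(n, 0.1, seed = n)
    expect_equal(tr$phy$Nnode, n - 1L)          # binary: L - 1 internal nodes
    expect_identical(sort(tr$phy$tip.label), sort(sprintf("t%d", 1:n)))
    expect_identical(unname(tr$age[1:n]), rep(0, n))
  }
  a <- simulate_yule(50, 0.1, seed = 7)
  b <- simulate_yule(50, 0.1, seed = 7)
  expect_identical(write_chronogram(a), write_chronogram(b))
  expect_false(identical(write_chronogram(a),
                         write_chronogram(simulate_yule(50, 0.1, seed = 8))))
})

test_that("perturbation with sigma = 0 is a pure bias rescale", {
  tr <- simulate_yule(30, 0.05, seed = 2)
  id <- perturb_ages(tr, "iid_lognormal", sigma = 0, bias = 1, seed = 1)
  expect_equal(id$age, tr$age, tolerance = 1e-12)
  for (b in c(0.5, 1.5)) {
    sc <- perturb_ages(tr, "iid_lognormal", sigma = 0, bias = b, seed = 1)
    expect_equal(sc$age, tr$age * b, tolerance = 1e-12)
    m <- build_age_matrix(list(orig = tr, scaled = sc))
    expect_equal(pairwise_percent_difference(m, "scaled", "orig", signed = FALSE),
                 200 * abs(b - 1) / (b + 1))
  }
})

test_that("perturbed trees keep all dated-tree invariants under both noise models", {
  tr <- simulate_yule(60, 0.05, seed = 9)
  for (model in c("iid_lognormal", "autocorrelated_lognormal")) {
    for (seed in 1:3) {
      p <- perturb_ages(tr, model, sigma = 0.3, bias = 1.1, seed = seed)
      e <- p$phy$edge
      expect_true(all(p$age[e[, 1]] > p$age[e[, 2]]))
      expect_identical(unname(p$age[1:60]), rep(0, 60))
      expect_identical(sort(p$phy$tip.label), sort(tr$phy$tip.label))
      # topology unchanged
      expect_identical(shared_clades(list(tr, p))$clade,
                       node_age_table(tr)$clade)
    }
  }
})

test_that("autocorrelated noise correlates parent/child log-age errors; iid does not", {
  tr <- simulate_yule(1200, 0.05, seed = 31)
  ntip <- 1200L
  log_err <- function(p, bias) {
    idx <- ntip + seq_len(p$phy$Nnode)
    log(p$age[idx] / (bias * tr$age[idx]))
  }
  pc_pairs <- function(p, bias) {
    e <- p$phy$edge
    keep <- e[, 2] > ntip
    err <- c(rep(NA_real_, ntip), log_err(p, bias))
    cbind(err[e[keep, 1]], err[e[keep, 2]])
  }
  ac <- perturb_ages(tr, "autocorrelated_lognormal", sigma = 0.1, seed = 3)
  pairs_ac <- pc_pairs(ac, 1)
  expect_gt(nrow(pairs_ac), 1000)
  expect_gt(cor(pairs_ac[, 1], pairs_ac[, 2]), 0.5)

  iid <- perturb_ages(tr, "iid_lognormal", sigma = 0.1, seed = 3)
  pairs_iid <- pc_pairs(iid, 1)
  expect_lt(abs(cor(pairs_iid[, 1], pairs_iid[, 2])), 0.1)
})

test_that("interchange moves change exactly the flanking clades", {
  t4 <- quartet()
  expect_identical(rearrange_clades(t4, 0), t4)
  moved <- rearrange_clades(t4, 1, seed = 3)
  expect_equal(shared_clades(list(t4, moved))$clade, "A|B|C|D")

  tr <- simulate_yule(40, 0.05, seed = 12)
  expect_error(rearrange_clades(tr, 40), "k too large")
  for (k in c(1, 3)) {
    mv <- rearrange_clades(tr, k, seed = k)
    lost <- 39L - nrow(shared_clades(list(tr, mv)))
    expect_gte(lost, k)       # each move breaks one or two clades
    expect_lte(lost, 2L * k)
    e <- mv$phy$edge
    expect_true(all(mv$age[e[, 1]] > mv$age[e[, 2]]))
  }
})

test_that("panels are reproducible byte-for-byte under a fixed config", {
  cfg <- panel_config(30, biases = c(0.9, 1, 1.1), sigma = 0.05, seed = 77,
                      broken_clades = 2, broken_sources = "CL3:C1")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_panel(generate_panel(cfg), d1)
  write_panel(generate_panel(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the panel does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_panel(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("panel biases surface as the closed-form pairwise statistics", {
  panel <- generate_panel(panel_config(40, biases = c(1, 1.5), seed = 13))
  m <- build_age_matrix(panel)
  expect_equal(pairwise_percent_difference(m, "CL2:C1", "CL1:C1", signed = FALSE), 40)
  d <- deviation_from_group_mean(m)
  expect_equal(unname(d$D), c(-20, 20))
  expect_equal(unname(pairwise_mean_difference(m, "CL2:C1", "CL1:C1")),
               mean(m[, 1]) * 0.5)
})
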
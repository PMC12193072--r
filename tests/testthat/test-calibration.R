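test_that("bundled calibration sets load with 17 constraints each and known bounds", {
  cal <- load_builtin_calibrations()
  expect_named(cal, c("C1", "C2", "C3"))
  for (s in cal) {
    expect_s3_class(s, "calibration_set")
    expect_equal(nrow(s$constraints), 17L)
    expect_true(all(s$constraints$min_ma <= s$constraints$max_ma))
  }
  rho3 <- cal$C3$constraints[cal$C3$constraints$node_no == 6, ]
  expect_equal(rho3$min_ma, 1560)
  expect_equal(rho3$max_ma, 2300)
  expect_equal(cal$C2$constraints$min_ma[cal$C2$constraints$node_no == 10], 948)
  goe <- cal$C1$constraints[cal$C1$constraints$node_no == 1, ]
  expect_equal(goe$node_name, "Great Oxidation Event")
  expect_equal(c(goe$min_ma, goe$max_ma), c(2320, 3000))
  # the three sets share every constraint except Rhodophyta/Ulvophyceae-style shifts
  expect_equal(cal$C1$constraints$node_name, cal$C3$constraints$node_name)
})

test_that("calibration checking flags ages outside closed [min, max] bounds", {
  tree <- read_chronogram("((A:1000,B:1000):500,(C:1200,D:1200):300);")
  cs <- calibration_set("T", data.frame(
    node_no = 1L, node_name = "AB split", min_ma = 948, max_ma = 2300))
  map <- list("1" = c("A", "B"))
  expect_equal(nrow(check_calibrations(tree, cs, map)), 0L)

  tight <- calibration_set("T", data.frame(
    node_no = 1L, node_name = "AB split", min_ma = 1048, max_ma = 2300))
  v <- check_calibrations(tree, tight, map)
  expect_equal(v$violation, "below_min")
  expect_equal(v$amount, 48)

  low <- calibration_set("T", data.frame(
    node_no = 1L, node_name = "AB split", min_ma = 100, max_ma = 900))
  v2 <- check_calibrations(tree, low, map)
  expect_equal(v2$violation, "above_max")
  expect_equal(v2$amount, 100)

  # closed interval: an age exactly at the bound is not a violation
  atmin <- calibration_set("T", data.frame(
    node_no = 1L, node_name = "AB split", min_ma = 1000, max_ma = 1000))
  expect_equal(nrow(check_calibrations(tree, atmin, map)), 0L)
})

test_that("missing leaves error; non-monophyletic groups warn but still check the MRCA", {
  tree <- read_chronogram("((A:1000,B:1000):500,(C:1200,D:1200):300);")
  cs <- calibration_set("T", data.frame(
    node_no = 1L, node_name = "x", min_ma = 10, max_ma = 3000))
  expect_error(check_calibrations(tree, cs, list("1" = c("A", "Z"))), "Z")
  # A and C span the root (age 1500), pulling in B and D
  expect_warning(v <- check_calibrations(tree, cs, list("1" = c("A", "C"))),
                 "not monophyletic")
  expect_equal(nrow(v), 0L)
})

test_that("relaxing any bound never adds violations (monotonicity)", {
  tree <- simulate_yule(30, 0.002, seed = 4)  # root age on the 100s-of-Myr scale
  tab <- node_age_table(tree)
  leaves <- attr(tab, "leaves")
  pick <- c(3, 8, 12)
  set.seed(99)
  cons <- data.frame(node_no = seq_along(pick), node_name = paste0("n", pick),
                     min_ma = tab$age[pick] * runif(3, 0.8, 1.2),
                     max_ma = tab$age[pick] * runif(3, 1.3, 1.6))
  map <- setNames(lapply(pick, function(i) leaves[[i]]), seq_along(pick))
  strict <- check_calibrations(tree, calibration_set("S", cons), map)
  relaxed_cons <- transform(cons, min_ma = min_ma * 0.5, max_ma = max_ma * 2)
  relaxed <- check_calibrations(tree, calibration_set("R", relaxed_cons), map)
  expect_lte(nrow(relaxed), nrow(strict))
  expect_true(all(relaxed$node_no %in% strict$node_no))

  empty <- calibration_set("E", data.frame(node_no = integer(),
                                           node_name = character(),
                                           min_ma = numeric(), max_ma = numeric()))
  expect_equal(nrow(check_calibrations(tree, empty, map)), 0L)
})

test_that("a panel generated to respect its bounds passes with zero violations", {
  panel <- generate_panel(panel_config(20, biases = c(1, 1.02), sigma = 0.01,
                                       seed = 2, root_scale = 2000))
  tab <- node_age_table(panel[[1]])
  leaves <- attr(tab, "leaves")
  cons <- data.frame(node_no = 1:2, node_name = c("a", "b"),
                     min_ma = tab$age[c(2, 5)] * 0.5,
                     max_ma = tab$age[c(2, 5)] * 2)
  map <- setNames(lapply(c(2, 5), function(i) leaves[[i]]), 1:2)
  cs <- calibration_set("S", cons)
  for (t in panel) expect_equal(nrow(check_calibrations(t, cs, map)), 0L)
})
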
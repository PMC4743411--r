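# Interpretation tools: bagging importance, threshold scans, the fixed
# selectivity rule, scaffold profiles, group mean comparisons.

test_that("a root-only split gives importance 1, unused features 0", {
  set.seed(2)
  n <- 200
  X <- data.frame(det = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),
                  noise = rnorm(n))
  y <- factor(as.integer(X$det > 0))
  bt <- fit_bagged_trees(X, y, n_trees = 1, seed = 3)
  imp <- bagging_importance(bt)
  expect_equal(imp$importance[imp$feature == "det"], 1)
  expect_equal(imp$importance[imp$feature == "noise"], 0)
  expect_error(bagging_importance(list()), "bagged_trees")
})

test_that("the class-determining feature ranks first in a stump ensemble", {
  set.seed(4)
  n <- 300
  X <- data.frame(det = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- factor(as.integer(X$det > 0))
  bt <- fit_bagged_trees(X, y, n_trees = 25, seed = 5,
                         control = rpart::rpart.control(maxdepth = 1, xval = 0,
                                                        minsplit = 5))
  imp <- bagging_importance(bt)
  expect_equal(imp$feature[1], "det")
  # depth-1 stumps bound importance by 1
  expect_true(all(imp$importance <= 1 + 1e-12))
})

test_that("importances are bounded below by zero and rankings non-increasing", {
  set.seed(6)
  X <- data.frame(a = rnorm(150), b = rnorm(150), c = rnorm(150))
  y <- factor(as.integer(X$a + 0.5 * X$b > 0))
  imp <- bagging_importance(fit_bagged_trees(X, y, n_trees = 10, seed = 7))
  expect_true(all(imp$importance >= 0))
  expect_true(all(diff(imp$importance) <= 1e-12))
})

test_that("threshold scan recovers a perfect separation at a midpoint", {
  values <- c(1, 2, 3, 10, 11, 12)
  classes <- c(1, 1, 1, 2, 2, 2)
  scan <- mcc_threshold_scan(values, classes)
  expect_equal(abs(scan$peak_mcc), 1)
  expect_equal(scan$peak_threshold, 6.5)
  # inverse orientation flips the sign of the peak
  scan2 <- mcc_threshold_scan(values, rev(classes))
  expect_equal(scan2$peak_mcc, -scan$peak_mcc)
  expect_error(mcc_threshold_scan(values, rep(1, 6)), "two classes")
})

test_that("threshold scan equals the exhaustive midpoint oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- 80
    cls <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(cls)) < 2) next
    vals <- rnorm(n) + (cls == "a") * runif(1, -2, 2)
    scan <- mcc_threshold_scan(vals, factor(cls))
    want <- scan_oracle(vals, factor(cls) == "a")
    expect_equal(scan$peak_mcc, unname(want["mcc"]), tolerance = 1e-12)
    expect_equal(scan$peak_threshold, unname(want["threshold"]))
    expect_true(all(abs(scan$scan$mcc) <= 1))
    expect_equal(nrow(scan$scan), length(unique(vals)) - 1)
  }
})

test_that("identical class distributions give a near-zero scan peak", {
  set.seed(10)
  n <- 10000
  vals <- rnorm(n)
  cls <- sample(rep_len(1:2, n))
  scan <- mcc_threshold_scan(vals, cls)
  expect_lt(abs(scan$peak_mcc), 0.06)
})

test_that("the selectivity rule reproduces the printed cascade", {
  expect_equal(selectivity_rule(21, 0), 2L)   # boundary: <= 21 hydrophobic
  expect_equal(selectivity_rule(22, 24), 2L)  # boundary: >= 24 aromatic
  expect_equal(selectivity_rule(22, 23), 1L)  # else branch
  expect_equal(selectivity_rule(c(10, 30, 25), c(5, 30, 10)), c(2L, 2L, 1L))
})

test_that("the rule partitions the integer lattice at exactly (21/22, 23/24)", {
  grid <- expand.grid(a_hyd = 0:40, a_aro = 0:40)
  cls <- selectivity_rule(grid$a_hyd, grid$a_aro)
  expect_setequal(unique(cls), c(1L, 2L))
  is2 <- grid$a_hyd <= 21 | grid$a_aro >= 24
  expect_equal(cls == 2L, is2)
})

test_that("scaffold profiles count clusters and label profiles correctly", {
  scafs <- setNames(c(rep("S1", 5)), paste0("K", 1:5))
  p1 <- scaffold_profile(scafs)
  expect_equal(unname(p1$summary["n_scaffolds"]), 1)
  expect_equal(unname(p1$summary["mean_per_scaffold"]), 5)
  scafs2 <- setNames(paste0("S", 1:5), paste0("K", 1:5))
  p2 <- scaffold_profile(scafs2)
  expect_equal(unname(p2$summary["n_singletons"]), 5)
  expect_equal(unname(p2$summary["mean_per_scaffold"]), 1)
  # label profiles and input-order invariance
  lab <- matrix(c(1L, 1L, 0L, NA, 1L, 0L, 1L, 1L, NA, 0L), ncol = 2,
                dimnames = list(paste0("K", 1:5), c("P-gp", "BCRP")))
  perm <- sample(5)
  pa <- scaffold_profile(scafs[perm], label_matrix(lab))
  expect_equal(unname(pa$summary), unname(p1$summary))
  counts <- pa$clusters[[1]]$label_counts[["P-gp"]]
  expect_equal(unname(counts["active"]), 3)
  expect_equal(unname(counts["inactive"]), 1)
  expect_equal(unname(counts["missing"]), 1)
})

test_that("group mean comparison recovers a planted shift", {
  expect_equal(unname(class_mean_compare(rep(2, 10), c(rep(TRUE, 4), rep(FALSE, 6)))),
               c(2, 2))
  expect_error(class_mean_compare(1:5, rep(TRUE, 5)), "non-empty")
  set.seed(12)
  n <- 1000
  grp <- rbinom(n, 1, 0.3) == 1
  vals <- rnorm(n, ifelse(grp, 78.2, 76.9), 2)
  m <- class_mean_compare(vals, grp)
  se <- 2 * sqrt(1 / sum(grp) + 1 / sum(!grp))
  expect_lt(abs((m["mean_in"] - m["mean_out"]) - 1.3), 3 * se)
})
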
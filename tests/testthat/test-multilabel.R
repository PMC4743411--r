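# Multi-label strategies: powerset encoding, binary relevance, classifiers
# chain, cross-validation harness.

make_Y <- function(p, b, keys = NULL) {
  Y <- cbind(`P-gp` = as.integer(p), BCRP = as.integer(b))
  rownames(Y) <- keys %||% paste0("K", seq_len(nrow(Y)))
  Y
}

test_that("powerset encoding follows the class table and round-trips", {
  Y <- make_Y(c(0, 1, 0, 1), c(0, 0, 1, 1))
  cls <- powerset_encode(Y)
  expect_equal(cls, c(0L, 1L, 2L, 3L))  # non/P-gp-sel/BCRP-sel/dual
  dec <- powerset_decode(cls, colnames(Y))
  expect_equal(unname(dec), unname(Y))
  # all tuples for three labels round-trip as well
  Y3 <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(Y3) <- c("a", "b", "c"); rownames(Y3) <- paste0("K", 1:8)
  expect_equal(sort(powerset_encode(Y3)), 0:7)
  expect_equal(unname(powerset_decode(powerset_encode(Y3), colnames(Y3))),
               unname(Y3))
  Yna <- make_Y(c(1, NA), c(0, 1))
  expect_error(powerset_encode(Yna), "missing")
})

test_that("class subsetting filters rows and keeps labels unchanged", {
  counts <- c(27, 48, 39, 47)
  classes <- rep(0:3, counts)
  X <- data.frame(x = seq_along(classes))
  sub <- subset_classes(X, classes, c(1, 2, 3))
  expect_equal(nrow(sub$X), 134)  # 48 + 39 + 47
  expect_setequal(unique(sub$classes), c(1, 2, 3))
  ident <- subset_classes(X, classes, 0:3)
  expect_equal(nrow(ident$X), length(classes))
  sel <- subset_classes(X, classes, c(1, 2))
  expect_setequal(unique(sel$classes), c(1, 2))
  expect_error(subset_classes(X, classes, 9), "no rows")
})

test_that("binary relevance trains one submodel per label on annotated rows", {
  sc <- generate_chain_scenario(150, seed = 2)
  m1 <- fit_binary_relevance(sc$X, sc$Y[, "A", drop = FALSE],
                             base_learner("logistic"), seed = 1)
  expect_length(m1$fits, 1)
  m2 <- fit_binary_relevance(sc$X, sc$Y, base_learner("logistic"), seed = 1)
  n_b <- sum(!is.na(sc$Y[, "B"]))
  expect_equal(length(m2$fits$B$fit$y), n_b)  # trained on annotated rows only
  # single-class label column errors with the label named
  Ybad <- sc$Y; Ybad[, "B"] <- 1L
  expect_error(fit_binary_relevance(sc$X, Ybad, base_learner("logistic")),
               "'B'")
})

test_that("separable data reaches perfect training accuracy per label", {
  set.seed(4)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Y <- make_Y(X$x1 > 0, X$x2 > 0)
  m <- fit_binary_relevance(X, Y, base_learner("random_forest"), seed = 2)
  pr <- predict(m, X)
  expect_equal(mean(pr$labels[, 1] == Y[, 1]), 1)
  expect_equal(mean(pr$labels[, 2] == Y[, 2]), 1)
})

test_that("a one-label chain reproduces binary relevance exactly", {
  sc <- generate_chain_scenario(150, seed = 5)
  Y1 <- sc$Y[, "A", drop = FALSE]
  for (bl in list(base_learner("logistic"), base_learner("random_forest"))) {
    br <- fit_binary_relevance(sc$X, Y1, bl, seed = 9)
    cc <- fit_classifiers_chain(sc$X, Y1, bl, seed = 9)
    pb <- predict(br, sc$X)
    pc <- predict(cc, sc$X)
    expect_equal(pb$scores, pc$scores, tolerance = 1e-12)
  }
})

test_that("chain submodels see the previous labels' scores as extra features", {
  sc <- generate_chain_scenario(150, seed = 6)
  cc <- fit_classifiers_chain(sc$X, sc$Y, base_learner("logistic"), seed = 1,
                              chain_order = c(1, 2))
  expect_length(cc$fits$B$features, ncol(sc$X) + 1)
  expect_true("cc_score_A" %in% cc$fits$B$features)
  expect_length(cc$fits$A$features, ncol(sc$X))
  # prediction is deterministic under a fixed seed
  p1 <- predict(cc, sc$X)
  p2 <- predict(cc, sc$X)
  expect_identical(p1$scores, p2$scores)
})

test_that("the chain outperforms binary relevance on the dependent label", {
  tr <- generate_chain_scenario(400, seed = 3)
  te <- generate_chain_scenario(400, seed = 1003)
  br <- fit_binary_relevance(tr$X, tr$Y, base_learner("random_forest"), seed = 3)
  cc <- fit_classifiers_chain(tr$X, tr$Y, base_learner("random_forest"),
                              seed = 3, chain_order = c(1, 2))
  auc_br <- auc_score(predict(br, te$X)$scores[, "B"], te$Y_full[, "B"])
  auc_cc <- auc_score(predict(cc, te$X)$scores[, "B"], te$Y_full[, "B"])
  expect_gt(auc_cc, auc_br)
})

test_that("label-powerset predictions decode to valid tuples", {
  set.seed(8)
  n <- 160
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Y <- make_Y(X$x1 > 0, X$x2 > 0.3)
  lp <- fit_label_powerset(X, Y, base_learner("random_forest"), seed = 1)
  pr <- predict(lp, X)
  expect_true(all(pr$classes %in% 0:3))
  expect_equal(unname(pr$labels),
               unname(powerset_decode(pr$classes, colnames(Y))))
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  # score 0.7 thresholds to 1
  expect_equal(predict(lp, X, threshold = 0.5)$labels,
               (pr$scores > 0.5) * 1L, ignore_attr = TRUE)
})

test_that("exact-match accuracy is at most the per-label macro accuracy", {
  set.seed(12)
  for (i in 1:20) {
    truth <- matrix(rbinom(60, 1, 0.5), ncol = 2)
    pred <- matrix(rbinom(60, 1, 0.5), ncol = 2)
    macro_acc <- mean(c(mean(truth[, 1] == pred[, 1]),
                        mean(truth[, 2] == pred[, 2])))
    expect_lte(subset_accuracy(truth, pred), macro_acc)
  }
})

test_that("cross-validation keeps compounds in single folds and stores seeds", {
  sc <- generate_chain_scenario(120, seed = 13)
  rep <- cross_validate(sc$X, sc$Y_full, "binary_relevance",
                        base_learner("logistic"), folds = 4, repeats = 2,
                        seed = 17)
  expect_length(rep$cv_spec$repeat_seeds, 2)
  expect_equal(rep$macro_accuracy,
               mean(rep$per_label[, "accuracy"]))
  expect_equal(rep$macro_auc, mean(rep$per_label[, "auc"]))
  # a perfect predictor scores 1 everywhere (wide margin around the boundary)
  X <- data.frame(x = c(runif(40, -3, -1), runif(40, 1, 3)))
  Yp <- make_Y(X$x > 0, X$x > 0)
  perfect <- cross_validate(X, Yp, "binary_relevance",
                            base_learner("logistic"), folds = 4, seed = 1)
  expect_equal(perfect$macro_accuracy, 1)
  expect_equal(perfect$macro_mcc, 1)
})

test_that("label-permutation null gives macro-MCC near zero", {
  set.seed(19)
  n <- 300
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Y <- make_Y(sample(rep_len(0:1, n)), sample(rep_len(0:1, n)))
  rep <- cross_validate(X, Y, "binary_relevance", base_learner("logistic"),
                        folds = 5, seed = 23)
  expect_lt(abs(rep$macro_mcc), 0.15)
  expect_lt(abs(rep$macro_auc - 0.5), 0.1)
})
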
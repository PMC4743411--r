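# Multi-label learning over label matrices with missing annotations:
# label-powerset encoding, binary relevance, classifiers chain, pluggable
# base learners and the cross-validation harness with macro-averaged
# metrics.

#' Specify a base learner
#'
#' Off-the-shelf estimators used inside the multi-label strategies:
#' `"logistic"` (stats::glm, nnet::multinom for >2 classes),
#' `"random_forest"` (randomForest, default 100 trees), `"svm_poly"`
#' (e1071::svm, polynomial kernel of degree 2, probability outputs) and
#' `"bagged_trees"` (bootstrap-aggregated rpart trees, default 50, the
#' interpretable ensemble used for feature importance).
#'
#' @param name Learner name.
#' @param ... Hyperparameters (`ntree` for random_forest, `degree` for
#'   svm_poly, `n_trees` for bagged_trees).
#' @return Object of class `base_learner`.
#' @export
base_learner <- function(name = c("logistic", "random_forest", "svm_poly",
                                  "bagged_trees"), ...) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...)), class = "base_learner")
}

.prep_X <- function(X) {
  X <- as.data.frame(X)
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  X
}

# Fit the base learner on features X (data.frame) and factor response y.
bl_fit <- function(bl, X, y, seed) {
  stopifnot(inherits(bl, "base_learner"))
  X <- .prep_X(X)
  y <- factor(y)
  if (nlevels(y) < 2) stopf("response has a single class")
  p <- bl$params
  fit <- with_seed(seed, switch(
    bl$name,
    logistic = {
      if (nlevels(y) == 2) {
        df <- cbind(X, .y = y)
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      } else {
        df <- cbind(X, .y = y)
        invisible(utils::capture.output(
          m <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = p$maxit %||% 200)))
        m
      }
    },
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = p$ntree %||% 100),
    svm_poly = suppressWarnings(e1071::svm(
      x = X, y = y, kernel = "polynomial", degree = p$degree %||% 2,
      probability = TRUE)),
    bagged_trees = fit_bagged_trees(X, y, n_trees = p$n_trees %||% 50,
                                    seed = seed)
  ))
  structure(list(learner = bl, fit = fit, levels = levels(y),
                 features = colnames(X)), class = "bl_fit")
}

# Class-probability matrix (one column per training level) on new data.
bl_score <- function(fitted, X) {
  stopifnot(inherits(fitted, "bl_fit"))
  X <- .prep_X(X)
  missing_feats <- setdiff(fitted$features, colnames(X))
  if (length(missing_feats) > 0) {
    stopf("prediction features do not match training schema (missing: %s)",
          paste(head(missing_feats, 3), collapse = ", "))
  }
  X <- X[, fitted$features, drop = FALSE]
  lev <- fitted$levels
  out <- switch(
    fitted$learner$name,
    logistic = {
      if (length(lev) == 2) {
        p1 <- suppressWarnings(predict(fitted$fit, newdata = X, type = "response"))
        cbind(1 - p1, p1)
      } else {
        predict(fitted$fit, newdata = X, type = "probs")
      }
    },
    random_forest = predict(fitted$fit, newdata = X, type = "prob"),
    svm_poly = {
      pr <- predict(fitted$fit, newdata = X, probability = TRUE)
      attr(pr, "probabilities")[, lev, drop = FALSE]
    },
    bagged_trees = predict_bagged_trees(fitted$fit, X)
  )
  out <- matrix(as.numeric(out), nrow = nrow(X),
                dimnames = list(NULL, lev))
  out
}

# Convenience: probability of the positive class ("1") for binary labels.
bl_score1 <- function(fitted, X) {
  s <- bl_score(fitted, X)
  if (!"1" %in% colnames(s)) stopf("no positive class in fitted model")
  s[, "1"]
}

.as_label_mat <- function(Y) {
  if (inherits(Y, "label_matrix")) Y <- Y$labels
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("label_", seq_len(ncol(Y)))
  storage.mode(Y) <- "integer"
  Y
}

#' Label-powerset encoding
#'
#' Maps each complete label tuple to a class index in `[0, 2^L)`. With the
#' two transporter labels ordered (P-gp, BCRP): (0,0) -> 0 (non-inhibitors),
#' (1,0) -> 1 (P-gp-selective), (0,1) -> 2 (BCRP-selective), (1,1) -> 3
#' (dual inhibitors). The encoding is bijective; [powerset_decode()]
#' inverts it. Missing labels are an error: the transformation requires a
#' dense matrix.
#'
#' @param Y A dense `label_matrix` or binary matrix.
#' @return Integer class vector.
#' @export
powerset_encode <- function(Y) {
  Y <- .as_label_mat(Y)
  if (anyNA(Y)) stopf("label-powerset requires a dense label matrix (no missing cells)")
  as.integer(Y %*% 2^(seq_len(ncol(Y)) - 1))
}

#' @rdname powerset_encode
#' @param classes Integer class vector.
#' @param labels Label names (defines L and column order).
#' @export
powerset_decode <- function(classes, labels) {
  L <- length(labels)
  stopifnot(all(classes >= 0), all(classes < 2^L))
  Y <- vapply(seq_len(L), function(j) as.integer(bitwAnd(classes, 2^(j - 1)) > 0),
              integer(length(classes)))
  Y <- matrix(Y, ncol = L, dimnames = list(NULL, labels))
  Y
}

#' Subset an encoded dataset to selected classes
#'
#' @param X Feature table (rows aligned with `classes`).
#' @param classes Integer class vector.
#' @param keep Class indices to retain (e.g. `c(1, 2, 3)` for the
#'   inhibitor-only subset, `c(1, 2)` for the selective inhibitors).
#' @return List with filtered `X` and `classes` (labels unchanged).
#' @export
subset_classes <- function(X, classes, keep) {
  stopifnot(nrow(X) == length(classes))
  sel <- classes %in% keep
  if (!any(sel)) stopf("no rows left after class subsetting")
  list(X = X[sel, , drop = FALSE], classes = classes[sel])
}

.check_label_fit <- function(y, label) {
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2) {
    stopf("label '%s' has a single class among annotated rows", label)
  }
}

#' Fit a binary relevance model
#'
#' One independent binary classifier per label, each trained only on the
#' rows carrying an annotation for that label.
#'
#' @param X Feature table (data.frame or matrix, rows = compounds).
#' @param Y `label_matrix` or binary matrix with NA for missing.
#' @param learner A [base_learner()] (default random forest, 100 trees).
#' @param seed Integer seed controlling learner randomness.
#' @return Object of class `multilabel_model`.
#' @export
fit_binary_relevance <- function(X, Y, learner = base_learner("random_forest"),
                                 seed = 1) {
  Y <- .as_label_mat(Y)
  stopifnot(nrow(X) == nrow(Y))
  fits <- setNames(vector("list", ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    .check_label_fit(y, colnames(Y)[j])
    rows <- !is.na(y)
    fits[[j]] <- bl_fit(learner, as.data.frame(X)[rows, , drop = FALSE],
                        y[rows], derive_seed(seed, j))
  }
  structure(list(strategy = "binary_relevance", base_learner = learner,
                 label_order = colnames(Y), chain_order = NULL,
                 fits = fits, seed = seed),
            class = "multilabel_model")
}

#' Fit a classifiers chain
#'
#' Labels are shuffled (under `seed`, or fixed via `chain_order`); the
#' first submodel is trained on the rows annotated for its label, then used
#' to predict a score in \[0, 1\] for every compound of the dataset --
#' including those without an annotation. That score is appended to the
#' feature matrix as an additional descriptor for the next submodel, and so
#' on along the chain. Scores (not hard labels) are propagated; at
#' prediction time the chain always uses its own predicted scores.
#'
#' @inheritParams fit_binary_relevance
#' @param chain_order Optional explicit label permutation (indices into the
#'   columns of `Y`).
#' @param augment `"insample"` (default): training augmentation uses the
#'   submodels' in-sample fitted scores; `"oof"`: out-of-fold scores from an
#'   internal 3-fold split for annotated rows (unannotated rows are always
#'   scored by the full submodel).
#' @return Object of class `multilabel_model`.
#' @export
fit_classifiers_chain <- function(X, Y, learner = base_learner("random_forest"),
                                  seed = 1, chain_order = NULL,
                                  augment = c("insample", "oof")) {
  augment <- match.arg(augment)
  Y <- .as_label_mat(Y)
  X <- as.data.frame(X)
  stopifnot(nrow(X) == nrow(Y))
  L <- ncol(Y)
  if (is.null(chain_order)) {
    chain_order <- with_seed(derive_seed(seed, 0), sample(L))
  }
  stopifnot(sort(chain_order) == seq_len(L))
  fits <- setNames(vector("list", L), colnames(Y))
  Xaug <- X
  for (k in chain_order) {
    y <- Y[, k]
    .check_label_fit(y, colnames(Y)[k])
    rows <- !is.na(y)
    fit_k <- bl_fit(learner, Xaug[rows, , drop = FALSE], y[rows],
                    derive_seed(seed, k))
    fits[[k]] <- fit_k
    score <- bl_score1(fit_k, Xaug)
    if (augment == "oof") {
      ann <- which(rows)
      oof_fold <- with_seed(derive_seed(seed, 1000 + k),
                            sample(rep_len(1:3, length(ann))))
      for (f in 1:3) {
        tr <- ann[oof_fold != f]
        te <- ann[oof_fold == f]
        if (length(unique(y[tr])) < 2) next
        sub <- bl_fit(learner, Xaug[tr, , drop = FALSE], y[tr],
                      derive_seed(seed, 2000 + 10 * k + f))
        score[te] <- bl_score1(sub, Xaug[te, , drop = FALSE])
      }
    }
    Xaug[[paste0("cc_score_", colnames(Y)[k])]] <- score
  }
  structure(list(strategy = "classifiers_chain", base_learner = learner,
                 label_order = colnames(Y), chain_order = chain_order,
                 fits = fits, seed = seed),
            class = "multilabel_model")
}

#' Fit a label-powerset multi-class model
#'
#' Encodes the dense label matrix into `2^L` classes and fits one
#' multi-class base learner.
#'
#' @inheritParams fit_binary_relevance
#' @param Y Dense `label_matrix` or binary matrix (no missing cells), or an
#'   already-encoded integer class vector (then `labels` must be given).
#' @param labels Label names when `Y` is a class vector.
#' @return Object of class `multilabel_model`.
#' @export
fit_label_powerset <- function(X, Y, learner = base_learner("random_forest"),
                               seed = 1, labels = NULL) {
  if (is.vector(Y) && !is.list(Y)) {
    classes <- as.integer(Y)
    if (is.null(labels)) stopf("labels must be supplied with a class vector")
  } else {
    Y <- .as_label_mat(Y)
    labels <- colnames(Y)
    classes <- powerset_encode(Y)
  }
  fit <- bl_fit(learner, as.data.frame(X), factor(classes),
                derive_seed(seed, 1))
  structure(list(strategy = "label_powerset", base_learner = learner,
                 label_order = labels, chain_order = NULL,
                 fits = list(powerset = fit), seed = seed),
            class = "multilabel_model")
}

#' @export
print.multilabel_model <- function(x, ...) {
  cat(sprintf("<multilabel_model> %s / %s; labels: %s\n", x$strategy,
              x$base_learner$name, paste(x$label_order, collapse = ", ")))
  if (!is.null(x$chain_order)) {
    cat("  chain order:", paste(x$label_order[x$chain_order], collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Predict per-label scores and binary labels
#'
#' @param object A fitted `multilabel_model`.
#' @param X Feature table with the training schema.
#' @param threshold Score threshold for the binary call (default 0.5).
#' @param ... Unused.
#' @return List with `scores` (numeric matrix in \[0, 1\], one column per
#'   label) and `labels` (thresholded 0/1 matrix). Label-powerset models
#'   additionally return `classes` (predicted class index) and
#'   `class_scores` (class-probability matrix).
#' @export
predict.multilabel_model <- function(object, X, threshold = 0.5, ...) {
  X <- as.data.frame(X)
  L <- length(object$label_order)
  if (object$strategy == "label_powerset") {
    cs <- bl_score(object$fits$powerset, X)
    cls_lev <- as.integer(colnames(cs))
    classes <- cls_lev[max.col(cs, ties.method = "first")]
    tuples <- powerset_decode(cls_lev, object$label_order)
    scores <- cs %*% tuples  # P(label_j = 1) = sum of class probs with bit set
    colnames(scores) <- object$label_order
    labels <- matrix(as.integer(scores > threshold), ncol = L,
                     dimnames = dimnames(scores))
    return(list(scores = scores, labels = labels, classes = classes,
                class_scores = cs))
  }
  scores <- matrix(NA_real_, nrow = nrow(X), ncol = L,
                   dimnames = list(rownames(X), object$label_order))
  if (object$strategy == "binary_relevance") {
    for (j in seq_len(L)) scores[, j] <- bl_score1(object$fits[[j]], X)
  } else {
    Xaug <- X
    for (k in object$chain_order) {
      s <- bl_score1(object$fits[[k]], Xaug)
      scores[, k] <- s
      Xaug[[paste0("cc_score_", object$label_order[k])]] <- s
    }
  }
  labels <- matrix(as.integer(scores > threshold), ncol = L,
                   dimnames = dimnames(scores))
  list(scores = scores, labels = labels)
}

.make_folds <- function(Y, folds, seed, stratify = TRUE) {
  n <- nrow(Y)
  if (folds < 2) stopf("folds must be >= 2")
  fold_id <- integer(n)
  if (stratify) {
    strata <- apply(Y, 1, function(r) paste(ifelse(is.na(r), "m", r), collapse = ""))
  } else {
    strata <- rep("all", n)
  }
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold_id[idx] <- rep_len(sample(folds), length(idx))
    }
  })
  fold_id
}

.binary_fold_metrics <- function(truth, pred, score) {
  acc <- mean(truth == pred)
  m <- mcc_from_labels(truth, pred)
  k <- cohen_kappa(factor(truth, levels = 0:1), factor(pred, levels = 0:1))
  a <- auc_score(score, truth)
  c(accuracy = acc, mcc = m, kappa = k, auc = a)
}

#' Cross-validate a multi-label model
#'
#' Folds are assigned over compounds (a compound is entirely in one fold),
#' stratified by annotation pattern so that no fold is emptied of a class;
#' the assignment depends only on the labels, the fold count and the seed,
#' so binary relevance and classifiers chain are evaluated on identical
#' folds when compared under the same seed. Per-label metrics are computed
#' per fold on the held-out annotated cells only, averaged over folds, then
#' over repeats (each repeat uses a distinct derived seed); macro metrics
#' are the unweighted means over labels. Folds where a label's held-out
#' truth is single-class have no defined AUC; they are excluded from that
#' label's AUC mean with a warning.
#'
#' For `strategy = "label_powerset"` the matrix must be dense; the report
#' additionally carries the exact-match accuracy, multi-class kappa and
#' unweighted one-vs-rest AUC of the encoded problem.
#'
#' @inheritParams fit_binary_relevance
#' @param strategy `"binary_relevance"`, `"classifiers_chain"` or
#'   `"label_powerset"`.
#' @param folds Number of cross-validation folds (default 10).
#' @param repeats Number of repetitions with different fold seeds.
#' @param stratify Stratify folds by annotation pattern (default TRUE).
#' @param augment Chain augmentation mode, see [fit_classifiers_chain()].
#' @return Object of class `evaluation_report`.
#' @export
cross_validate <- function(X, Y, strategy = c("binary_relevance",
                                              "classifiers_chain",
                                              "label_powerset"),
                           learner = base_learner("random_forest"),
                           folds = 10, repeats = 1, seed = 1,
                           stratify = TRUE, augment = "insample") {
  strategy <- match.arg(strategy)
  Y <- .as_label_mat(Y)
  X <- as.data.frame(X)
  stopifnot(nrow(X) == nrow(Y))
  if (strategy == "label_powerset" && anyNA(Y)) {
    stopf("label_powerset cross-validation requires a dense label matrix")
  }
  L <- ncol(Y)
  labels <- colnames(Y)
  repeat_seeds <- vapply(seq_len(repeats), function(r) derive_seed(seed, r),
                         integer(1))
  metric_names <- c("accuracy", "mcc", "kappa", "auc")
  rep_label <- array(NA_real_, dim = c(repeats, L, 4),
                     dimnames = list(NULL, labels, metric_names))
  lp_overall <- matrix(NA_real_, nrow = repeats, ncol = 3,
                       dimnames = list(NULL, c("accuracy", "kappa", "auc")))
  n_auc_skipped <- 0

  for (r in seq_len(repeats)) {
    rs <- repeat_seeds[r]
    fold_id <- .make_folds(Y, folds, rs, stratify)
    fold_label <- array(NA_real_, dim = c(folds, L, 4))
    lp_truth <- integer(0); lp_pred <- integer(0)
    lp_scores <- NULL
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      te <- fold_id == f
      if (!any(te)) next
      model <- switch(
        strategy,
        binary_relevance = fit_binary_relevance(
          X[tr, , drop = FALSE], Y[tr, , drop = FALSE], learner,
          seed = derive_seed(rs, f)),
        classifiers_chain = fit_classifiers_chain(
          X[tr, , drop = FALSE], Y[tr, , drop = FALSE], learner,
          seed = derive_seed(rs, f), augment = augment),
        label_powerset = fit_label_powerset(
          X[tr, , drop = FALSE], Y[tr, , drop = FALSE], learner,
          seed = derive_seed(rs, f))
      )
      pr <- predict(model, X[te, , drop = FALSE])
      for (j in seq_len(L)) {
        ann <- !is.na(Y[te, j])
        if (!any(ann)) next
        truth <- Y[te, j][ann]
        fold_label[f, j, ] <- .binary_fold_metrics(
          truth, pr$labels[ann, j], pr$scores[ann, j])
      }
      if (strategy == "label_powerset") {
        lp_truth <- c(lp_truth, powerset_encode(Y[te, , drop = FALSE]))
        lp_pred <- c(lp_pred, pr$classes)
        lp_scores <- rbind(lp_scores, pr$class_scores)
      }
    }
    n_auc_skipped <- n_auc_skipped +
      sum(is.na(fold_label[, , 4]) & !is.na(fold_label[, , 1]))
    rep_label[r, , ] <- apply(fold_label, c(2, 3), mean, na.rm = TRUE)
    if (strategy == "label_powerset") {
      lev <- sort(unique(lp_truth))
      lp_overall[r, ] <- c(
        mean(lp_truth == lp_pred),
        cohen_kappa(factor(lp_truth, levels = lev), factor(lp_pred, levels = lev)),
        auc_score(lp_scores, factor(lp_truth, levels = lev))
      )
    }
  }
  if (n_auc_skipped > 0) {
    warning(sprintf("AUC undefined (single-class truth) in %d fold-label cells; excluded from means",
                    n_auc_skipped), call. = FALSE)
  }
  per_label <- apply(rep_label, c(2, 3), mean, na.rm = TRUE)
  report <- list(
    per_label = as.data.frame(per_label),
    macro_accuracy = macro_average(per_label[, "accuracy"]),
    macro_mcc = macro_average(per_label[, "mcc"]),
    macro_kappa = macro_average(per_label[, "kappa"]),
    macro_auc = macro_average(per_label[, "auc"]),
    cv_spec = list(strategy = strategy, base_learner = learner$name,
                   folds = folds, repeats = repeats, seed = seed,
                   repeat_seeds = repeat_seeds, stratified = stratify)
  )
  if (strategy == "label_powerset") {
    lp <- colMeans(lp_overall)
    report$lp_accuracy <- lp[["accuracy"]]
    report$lp_kappa <- lp[["kappa"]]
    report$lp_auc <- lp[["auc"]]
  }
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s (%d-fold CV x %d repeats)\n",
              x$cv_spec$strategy, x$cv_spec$base_learner, x$cv_spec$folds,
              x$cv_spec$repeats))
  print(round(x$per_label, 3))
  cat(sprintf("macro: accuracy %.3f  MCC %.3f  kappa %.3f  AUC %.3f\n",
              x$macro_accuracy, x$macro_mcc, x$macro_kappa, x$macro_auc))
  if (!is.null(x$lp_accuracy)) {
    cat(sprintf("powerset: exact-match accuracy %.3f  kappa %.3f  ovr-AUC %.3f\n",
                x$lp_accuracy, x$lp_kappa, x$lp_auc))
  }
  invisible(x)
}
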
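# Interpretation machinery: bagged-tree feature importance, per-descriptor
# MCC threshold scans, the fixed two-descriptor selectivity rule, and
# Bemis-Murcko scaffold pharmacology profiles.

#' Fit a bootstrap-aggregated ensemble of classification trees
#'
#' Bagging of rpart trees; the ensemble doubles as an interpretable base
#' learner and as the substrate for [bagging_importance()], since every tree
#' exposes its per-node split feature and sample count.
#'
#' @param X Feature data.frame.
#' @param y Class factor (2 or more levels).
#' @param n_trees Number of bootstrap trees (default 50).
#' @param seed Integer seed for the bootstrap draws.
#' @param control An [rpart::rpart.control()]; default grows moderately deep
#'   trees without cross-validated pruning.
#' @return Object of class `bagged_trees`.
#' @export
fit_bagged_trees <- function(X, y, n_trees = 50, seed = 1,
                             control = rpart::rpart.control(
                               minsplit = 5, cp = 0.002, xval = 0)) {
  X <- as.data.frame(X)
  y <- factor(y)
  stopifnot(nrow(X) > 1, nlevels(y) >= 2)
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- sample(n, n, replace = TRUE)
    df <- cbind(X[idx, , drop = FALSE], .y = y[idx])
    rpart::rpart(.y ~ ., data = df, method = "class", control = control)
  }))
  structure(list(trees = trees, levels = levels(y), features = colnames(X),
                 n_trees = n_trees),
            class = "bagged_trees")
}

#' Predict class probabilities from a bagged-tree ensemble
#' @param object A `bagged_trees` fit.
#' @param X New feature data.frame.
#' @return Matrix of averaged class probabilities (one column per level).
#' @export
predict_bagged_trees <- function(object, X) {
  stopifnot(inherits(object, "bagged_trees"))
  X <- as.data.frame(X)
  probs <- lapply(object$trees, function(tr) {
    p <- predict(tr, newdata = X, type = "prob")
    full <- matrix(0, nrow = nrow(X), ncol = length(object$levels),
                   dimnames = list(NULL, object$levels))
    full[, colnames(p)] <- p
    full
  })
  Reduce(`+`, probs) / length(probs)
}

#' Fraction-of-samples-seen feature importance of bagged trees
#'
#' For each tree and each feature, the fractions of the tree's training
#' samples passing through the nodes where the feature is used to split are
#' summed (a feature splitting only at the root therefore scores exactly 1:
#' the root sees 100 percent of the data). The per-tree sums are averaged
#' over all trees and used to rank the features; features never used score
#' 0.
#'
#' @param object A fitted `bagged_trees` ensemble.
#' @return data.frame (class `feature_importance`) with columns `feature`
#'   and `importance`, sorted decreasingly.
#' @export
bagging_importance <- function(object) {
  if (!inherits(object, "bagged_trees")) {
    stopf("bagging_importance needs a fitted bagged_trees ensemble")
  }
  feats <- object$features
  acc <- setNames(numeric(length(feats)), feats)
  for (tr in object$trees) {
    fr <- tr$frame
    internal <- fr$var != "<leaf>"
    if (!any(internal)) next
    frac <- fr$n[internal] / fr$n[1]
    vars <- as.character(fr$var[internal])
    per_tree <- tapply(frac, vars, sum)
    acc[names(per_tree)] <- acc[names(per_tree)] + per_tree
  }
  imp <- acc / length(object$trees)
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("feature_importance", "data.frame")
  out
}

#' MCC threshold scan of one descriptor
#'
#' For every candidate threshold `t` (the midpoints between consecutive
#' distinct observed values), computes the signed MCC of the rule
#' `value <= t  =>  first-listed class`. A positive peak means low values
#' of the descriptor indicate the first class; a negative peak means the
#' inverse rule separates better. The returned peak is the threshold with
#' maximal `|MCC|`.
#'
#' @param values Numeric descriptor values.
#' @param classes Two-class vector (factor or otherwise); the first level
#'   (or first value encountered) is the "first-listed" class A.
#' @return Object of class `threshold_scan`: list with `descriptor` scan
#'   data.frame (`threshold`, `mcc`), `peak_threshold`, `peak_mcc`,
#'   `classes`.
#' @export
mcc_threshold_scan <- function(values, classes) {
  stopifnot(length(values) == length(classes), length(values) >= 2)
  f <- factor(classes)
  if (nlevels(f) != 2) stopf("threshold scan requires exactly two classes")
  is_a <- f == levels(f)[1]
  v <- sort(unique(values))
  if (length(v) < 2) stopf("descriptor is constant")
  thresholds <- (v[-1] + v[-length(v)]) / 2
  mccs <- vapply(thresholds, function(t) {
    pred_a <- values <= t
    mcc(sum(is_a & pred_a), sum(!is_a & !pred_a),
        sum(!is_a & pred_a), sum(is_a & !pred_a))
  }, numeric(1))
  peak <- which.max(abs(mccs))
  structure(list(scan = data.frame(threshold = thresholds, mcc = mccs),
                 peak_threshold = thresholds[peak], peak_mcc = mccs[peak],
                 classes = levels(f)),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %s vs %s: peak MCC %.3f at threshold %.3f (%d candidates)\n",
              x$classes[1], x$classes[2], x$peak_mcc, x$peak_threshold,
              nrow(x$scan)))
  invisible(x)
}

#' Fixed two-descriptor selectivity rule
#'
#' The rule cascade separating BCRP-selective from P-gp-selective
#' inhibitors: if the number of hydrophobic atoms is less than or equal to
#' 21, the compound is BCRP-selective (class 2); otherwise, if the number
#' of aromatic atoms is greater than or equal to 24, it is BCRP-selective
#' (class 2); otherwise it is P-gp-selective (class 1).
#'
#' @param a_hyd Non-negative integer count(s) of hydrophobic atoms.
#' @param a_aro Non-negative integer count(s) of aromatic atoms.
#' @return Integer class vector (1 = P-gp-selective, 2 = BCRP-selective).
#' @export
selectivity_rule <- function(a_hyd, a_aro) {
  stopifnot(all(a_hyd >= 0), all(a_aro >= 0))
  ifelse(a_hyd <= 21, 2L, ifelse(a_aro >= 24, 2L, 1L))
}

#' Re-derive selectivity thresholds with a tree inducer
#'
#' Fits a plain classification tree on (`a_hyd`, `a_aro`) for a two-class
#' selectivity dataset and reports the first split threshold found for each
#' descriptor, for comparison against the fixed rule's constants (21, 24).
#'
#' @param a_hyd,a_aro Descriptor values.
#' @param classes Two-class vector (1/2).
#' @return Named numeric vector `c(a_hyd = ..., a_aro = ...)`; NA when the
#'   tree never splits on a descriptor.
#' @export
derive_selectivity_thresholds <- function(a_hyd, a_aro, classes) {
  df <- data.frame(a_hyd = a_hyd, a_aro = a_aro, .y = factor(classes))
  tr <- rpart::rpart(.y ~ a_hyd + a_aro, data = df, method = "class",
                     control = rpart::rpart.control(minsplit = 10, cp = 0.01,
                                                    xval = 0))
  splits <- tr$splits
  out <- c(a_hyd = NA_real_, a_aro = NA_real_)
  if (is.null(splits) || nrow(splits) == 0) return(out)
  # tr$splits lists, for each internal node in frame order, the primary
  # split followed by its competitors and surrogates; keep primaries only.
  fr <- tr$frame
  row <- 1
  for (i in which(fr$var != "<leaf>")) {
    v <- as.character(fr$var[i])
    if (v %in% names(out) && is.na(out[v])) out[v] <- splits[row, "index"]
    row <- row + 1 + fr$ncompete[i] + fr$nsurrogate[i]
  }
  out
}

#' Scaffold pharmacology profile
#'
#' Groups compounds by Bemis-Murcko scaffold and summarizes the per-target
#' label profile of every cluster, together with the dataset-level scaffold
#' statistics (unique scaffolds, mean compounds per scaffold, singleton
#' count, counts of scaffolds with at least 5 and more than 20 members).
#' Acyclic molecules (empty scaffold `""`) form one cluster of their own.
#' Enrichment is reported descriptively as per-cluster label proportions.
#'
#' @param scaffolds Named character vector: scaffold key per compound, names
#'   matching rownames of the label matrix (e.g. from [murcko_scaffold()]).
#' @param matrix Optional `label_matrix` with the compounds' annotations.
#' @return Object of class `scaffold_profile`: list with `clusters` (list
#'   of per-scaffold summaries) and `summary` (named counts). Cluster order
#'   and summary are invariant to compound input order.
#' @export
scaffold_profile <- function(scaffolds, matrix = NULL) {
  stopifnot(!is.null(names(scaffolds)))
  groups <- split(names(scaffolds), unname(scaffolds))
  groups <- groups[order(-vapply(groups, length, integer(1)),
                         names(groups))]
  lab <- if (!is.null(matrix)) .as_label_mat(matrix) else NULL
  clusters <- lapply(names(groups), function(scaf) {
    members <- sort(groups[[scaf]])
    cl <- list(scaffold = scaf, members = members, n = length(members))
    if (!is.null(lab)) {
      rows <- intersect(members, rownames(lab))
      cl$label_counts <- lapply(colnames(lab), function(t) {
        col <- lab[rows, t]
        c(active = sum(col == 1, na.rm = TRUE),
          inactive = sum(col == 0, na.rm = TRUE),
          missing = sum(is.na(col)))
      })
      names(cl$label_counts) <- colnames(lab)
    }
    cl
  })
  sizes <- vapply(clusters, `[[`, integer(1), "n")
  summary <- c(
    n_scaffolds = length(clusters),
    n_compounds = length(scaffolds),
    mean_per_scaffold = round(length(scaffolds) / length(clusters), 3),
    n_singletons = sum(sizes == 1),
    n_ge5 = sum(sizes >= 5),
    n_gt20 = sum(sizes > 20)
  )
  structure(list(clusters = clusters, summary = summary),
            class = "scaffold_profile")
}

#' @export
print.scaffold_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scaffold_profile> %d scaffolds over %d compounds (mean %.1f/scaffold)\n",
              s[["n_scaffolds"]], s[["n_compounds"]], s[["mean_per_scaffold"]]))
  cat(sprintf("  singletons: %d; >=5 members: %d; >20 members: %d\n",
              s[["n_singletons"]], s[["n_ge5"]], s[["n_gt20"]]))
  invisible(x)
}

#' Compare descriptor means inside and outside a compound group
#'
#' @param values Numeric descriptor values.
#' @param group Logical mask (or index vector) defining the in-group.
#' @return Named numeric vector `c(mean_in, mean_out)`.
#' @export
class_mean_compare <- function(values, group) {
  if (is.logical(group)) {
    stopifnot(length(group) == length(values))
    sel <- group
  } else {
    sel <- seq_along(values) %in% group
  }
  if (!any(sel) || all(sel)) stopf("both groups must be non-empty")
  c(mean_in = mean(values[sel]), mean_out = mean(values[!sel]))
}
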
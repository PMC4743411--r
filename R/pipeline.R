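# Pipeline driver: one entry point per analysis stage, with validated
# configuration, explicit seeds and a reproducibility manifest accompanying
# every output. A thin command-line front-end over these functions ships in
# inst/scripts/mlefflux-cli.R.

.default_config <- function() {
  list(
    output_dir = ".",
    seed = 1,
    collate = list(cutoff = 5, cap = 1e8),
    model = list(strategy = "binary_relevance", base_learner = "random_forest"),
    cv = list(folds = 10, repeats = 1),
    generator = list()
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

.validate_config <- function(config, subcommand) {
  if (!is.null(config$cv$folds) && config$cv$folds < 2) {
    stopf("config error: cv$folds must be >= 2 (got %s)", config$cv$folds)
  }
  if (!is.null(config$seed) && !is_scalar_number(config$seed)) {
    stopf("config error: seed must be a single number")
  }
  invisible(TRUE)
}

.write_manifest <- function(config, outputs, path) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tf <- tempfile()
  writeLines(cfg_json, tf)
  checksums <- vapply(outputs[file.exists(outputs)], function(f)
    unname(tools::md5sum(f)), character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mlefflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    config_md5 = unname(tools::md5sum(tf)),
    outputs = as.list(checksums)
  )
  unlink(tf)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic study: activity records,
#' descriptors, observed labels), `collate` (raw records -> sparse/dense
#' label matrices), `describe` (structures -> descriptor table), `train` /
#' `evaluate` (fit / cross-validate a multi-label model), `interpret`
#' (bagged-tree importances plus a descriptor threshold scan and the fixed
#' selectivity rule applied to the selective classes) and `scaffolds`
#' (Bemis-Murcko scaffold profile). Every invocation writes its outputs to
#' `config$output_dir` together with a JSON manifest (config, seed, md5
#' checksums), so deterministic stages reproduce bit-for-bit from the
#' manifest.
#'
#' @param subcommand Stage name.
#' @param config Nested configuration list (missing entries fall back to
#'   defaults); for file-based use, parse a YAML/JSON file first.
#' @return List of computed results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(subcommand = c("simulate", "collate", "describe",
                                        "train", "evaluate", "interpret",
                                        "scaffolds"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  config <- .merge_config(.default_config(), config)
  .validate_config(config, subcommand)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)
  result <- switch(
    subcommand,
    simulate = {
      spec <- do.call(generator_spec,
                      c(config$generator, list(seed = config$seed)))
      study <- generate_study(spec)
      write.table(study$records, out("activity_records.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_descriptor_table(study$descriptors, out("descriptors.tsv"))
      write_label_matrix(study$observed, out("observed_labels.tsv"))
      write_label_matrix(study$truth, out("truth_labels.tsv"))
      outputs <- out(c("activity_records.tsv", "descriptors.tsv",
                       "observed_labels.tsv", "truth_labels.tsv"))
      study
    },
    collate = {
      tab <- read_activity_table(config$input %||% out("activity_records.tsv"),
                                 sep = config$sep %||% "\t")
      res <- collate_activity(tab$records, cutoff = config$collate$cutoff,
                              cap = config$collate$cap)
      write_label_matrix(res$sparse, out("sparse_labels.tsv"))
      write_label_matrix(res$dense, out("dense_labels.tsv"))
      outputs <- out(c("sparse_labels.tsv", "dense_labels.tsv"))
      res
    },
    describe = {
      entries <- read_sdf(config$input)
      std <- standardize_compounds(entries)
      keyed <- lapply(std$entries, compute_inchikey)
      keyed <- keyed[!vapply(keyed, is_rejection, logical(1))]
      X <- compute_descriptors(keyed)
      write_descriptor_table(X, out("descriptors.tsv"))
      if (nrow(std$rejections) > 0) {
        write_rejection_log(std$rejections, out("rejections.tsv"))
      }
      outputs <- out("descriptors.tsv")
      X
    },
    train = ,
    evaluate = {
      X <- read_descriptor_table(config$features %||% out("descriptors.tsv"))
      Ym <- read_label_matrix(config$labels %||% out("observed_labels.tsv"))
      common <- intersect(rownames(X), rownames(Ym$labels))
      X <- X[common, , drop = FALSE]
      Y <- Ym$labels[common, , drop = FALSE]
      learner <- base_learner(config$model$base_learner)
      if (subcommand == "train") {
        model <- switch(config$model$strategy,
          binary_relevance = fit_binary_relevance(X, Y, learner, config$seed),
          classifiers_chain = fit_classifiers_chain(X, Y, learner, config$seed),
          label_powerset = fit_label_powerset(X, Y, learner, config$seed),
          stopf("config error: unknown strategy '%s'", config$model$strategy))
        pr <- predict(model, X)
        preds <- data.frame(compound = rownames(X), pr$scores, pr$labels,
                            check.names = FALSE)
        write.table(preds, out("predictions.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs <- out("predictions.tsv")
        model
      } else {
        report <- cross_validate(X, Y, strategy = config$model$strategy,
                                 learner = learner,
                                 folds = config$cv$folds,
                                 repeats = config$cv$repeats,
                                 seed = config$seed)
        jsonlite::write_json(
          list(per_label = report$per_label,
               macro_accuracy = report$macro_accuracy,
               macro_mcc = report$macro_mcc,
               macro_kappa = report$macro_kappa,
               macro_auc = report$macro_auc,
               cv_spec = report$cv_spec),
          out("evaluation.json"), auto_unbox = TRUE, digits = NA)
        outputs <- out("evaluation.json")
        report
      }
    },
    interpret = {
      X <- read_descriptor_table(config$features %||% out("descriptors.tsv"))
      Ym <- read_label_matrix(config$labels %||% out("observed_labels.tsv"))
      common <- intersect(rownames(X), rownames(Ym$labels))
      X <- X[common, , drop = FALSE]
      dense <- build_datasets(label_matrix(Ym$labels[common, , drop = FALSE]))$dense
      cls <- powerset_encode(dense)
      Xd <- X[rownames(dense$labels), , drop = FALSE]
      sel <- subset_classes(Xd, cls, c(1, 2))
      bt <- fit_bagged_trees(sel$X, sel$classes, seed = config$seed)
      imp <- bagging_importance(bt)
      scan <- mcc_threshold_scan(sel$X$SlogP, sel$classes)
      rule_pred <- selectivity_rule(sel$X$a_hyd, sel$X$a_aro)
      rule_acc <- mean(rule_pred == sel$classes)
      write.table(imp, out("feature_importance.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(scan$scan, out("slogp_mcc_scan.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs <- out(c("feature_importance.tsv", "slogp_mcc_scan.tsv"))
      list(importance = imp, scan = scan, rule_accuracy = rule_acc)
    },
    scaffolds = {
      entries <- read_sdf(config$input)
      scafs <- vapply(entries, function(e) murcko_scaffold(e$structure),
                      character(1))
      names(scafs) <- vapply(entries, function(e) e$compound_id, character(1))
      prof <- scaffold_profile(scafs)
      write.table(
        data.frame(compound = names(scafs), scaffold = unname(scafs)),
        out("scaffolds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- out("scaffolds.tsv")
      prof
    }
  )
  .write_manifest(config, outputs, out(paste0(subcommand, "_manifest.json")))
  invisible(result)
}
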
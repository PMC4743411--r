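# Fully controlled synthetic inputs for every pipeline stage: truth label
# matrices with powerset class structure, class-conditional descriptor
# tables, raw activity records (with assay multiplicity, conflicts,
# relation signs and a pre-curated subset), sparsified annotation patterns
# and template-based structures with planted scaffold clusters.
#
# All generators are pure functions of (spec, seed).

#' Specification for the synthetic-data generator
#'
#' Defaults describe the study conditions the package's analyses assume:
#' two transporter labels ordered (P-gp, BCRP), powerset class proportions
#' (27, 48, 39, 47)/161 as observed in the curated dense inhibition panel,
#' an annotation overlap of 0.5, a 10 percent label-noise rate, a mean of
#' two measurements per compound-target pair with a 5 percent conflict
#' rate, 10 percent relation-sign records and a 15 percent pre-curated
#' subset.
#'
#' @param seed Default seed used by generators when none is passed.
#' @param n_compounds Number of compounds.
#' @param n_targets Number of targets/labels (default 2).
#' @param target_names Label names (default `c("P-gp", "BCRP")`).
#' @param annotation_overlap Fraction of compounds keeping annotations for
#'   all targets after sparsification, in \[0, 1\].
#' @param class_proportions Probabilities over the `2^n_targets` powerset
#'   classes; must sum to 1.
#' @param label_noise Per-cell label flip rate in \[0, 0.5).
#' @param assay_multiplicity Mean number of measurements per cell (>= 1).
#' @param conflict_rate Fraction of cells given perfectly conflicting
#'   measurements (median 0.5, dropped by consensus unless rescued by a
#'   pre-curated record).
#' @param relation_rate Fraction of records carrying a `<` / `>` relation.
#' @param precurated_fraction Fraction of cells also receiving a
#'   pre-curated label record.
#' @param structure_mode `"feature_only"` (descriptors drawn directly) or
#'   `"template_structures"` (SMILES assembled from a scaffold library).
#' @param descriptor_params Per-class mixture parameters for the descriptor
#'   panel; see [default_descriptor_params()].
#' @param scaffold_plan Optional integer vector of planted scaffold cluster
#'   sizes (template mode).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1, n_compounds = 1000, n_targets = 2,
                           target_names = NULL,
                           annotation_overlap = 0.5,
                           class_proportions = c(27, 48, 39, 47) / 161,
                           label_noise = 0.1,
                           assay_multiplicity = 2,
                           conflict_rate = 0.05,
                           relation_rate = 0.1,
                           precurated_fraction = 0.15,
                           structure_mode = c("feature_only",
                                              "template_structures"),
                           descriptor_params = NULL,
                           scaffold_plan = NULL) {
  structure_mode <- match.arg(structure_mode)
  target_names <- target_names %||%
    if (n_targets == 2) c("P-gp", "BCRP") else paste0("T", seq_len(n_targets))
  stopifnot(n_compounds >= 1, n_targets >= 1,
            length(target_names) == n_targets,
            annotation_overlap >= 0, annotation_overlap <= 1,
            label_noise >= 0, label_noise < 0.5,
            assay_multiplicity >= 1, conflict_rate >= 0, conflict_rate < 1)
  if (length(class_proportions) != 2^n_targets) {
    stopf("class_proportions must have length 2^n_targets = %d", 2^n_targets)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stopf("class_proportions must be non-negative and sum to 1")
  }
  if (all(class_proportions[-1] == 0) && class_proportions[1] == 1) {
    # degenerate but explicitly allowed: all mass on class 0
  }
  structure(list(
    seed = seed, n_compounds = n_compounds, n_targets = n_targets,
    target_names = target_names, annotation_overlap = annotation_overlap,
    class_proportions = class_proportions, label_noise = label_noise,
    assay_multiplicity = assay_multiplicity, conflict_rate = conflict_rate,
    relation_rate = relation_rate, precurated_fraction = precurated_fraction,
    structure_mode = structure_mode,
    descriptor_params = descriptor_params %||% default_descriptor_params(),
    scaffold_plan = scaffold_plan
  ), class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> n=%d, %d targets, overlap %.2f, noise %.2f, mode %s\n",
              x$n_compounds, x$n_targets, x$annotation_overlap, x$label_noise,
              x$structure_mode))
  invisible(x)
}

# Synthetic compound keys in InChIKey layout (clearly non-chemical: the
# second block spells out SYNTHETIC).
.synthetic_keys <- function(n) {
  suffix <- vapply(seq_len(n), function(i) {
    chars <- character(5)
    x <- i
    for (k in 5:1) {
      chars[k] <- LETTERS[x %% 26 + 1]
      x <- x %/% 26
    }
    paste(chars, collapse = "")
  }, character(1))
  prefix <- vapply(seq_len(n), function(i) {
    paste(sample(LETTERS, 9, replace = TRUE), collapse = "")
  }, character(1))
  paste0(prefix, suffix, "-SYNTHETICX-N")
}

#' Per-class descriptor distribution defaults
#'
#' Gaussian-mixture parameters per powerset class for the eight-descriptor
#' panel, encoding the trends the analyses look for: P-gp-selective
#' inhibitors (class 1) have many hydrophobic atoms and mid-range SlogP;
#' BCRP-selective inhibitors (class 2) split into a low-hydrophobicity /
#' low-SlogP component and an aromatic-rich / high-SlogP component (so the
#' fixed selectivity rule holds for >= 90 percent of class-2 draws and
#' <= 10 percent of class-1 draws); dual inhibitors (class 3) straddle both
#' selective groups in SlogP and have a slightly higher mean polarizability
#' sum (78.2 vs roughly 76.9 elsewhere).
#'
#' @return Nested list: per class, a list of mixture components with
#'   `weight`, `mean` and `sd` vectors over the descriptor panel.
#' @export
default_descriptor_params <- function() {
  d <- function(a_hyd, a_aro, SlogP, vsa_acc, BalabanJ, a_donacc, weinerPath,
                apol) {
    c(a_hyd = a_hyd, a_aro = a_aro, SlogP = SlogP, vsa_acc = vsa_acc,
      BalabanJ = BalabanJ, a_donacc = a_donacc, weinerPath = weinerPath,
      apol = apol)
  }
  sds_common <- d(4, 3, 0.8, 7, 0.4, 2, 400, 9)
  list(
    `0` = list(list(weight = 1,
                    mean = d(18, 15, 1.5, 25, 2.2, 6, 900, 76),
                    sd = d(5, 4, 1.2, 8, 0.5, 2, 300, 10))),
    `1` = list(list(weight = 1,
                    mean = d(28, 19.5, 3.5, 35, 1.6, 8, 2200, 76.9),
                    sd = d(3, 2.3, 0.8, 7, 0.4, 2, 400, 9))),
    `2` = list(list(weight = 0.5,
                    mean = d(16, 18, 1.5, 30, 2.0, 5, 1100, 76.9),
                    sd = d(2.5, 3, 0.7, 6, 0.4, 1.5, 300, 8)),
               list(weight = 0.5,
                    mean = d(28, 27, 5.5, 20, 1.4, 4, 1800, 76.9),
                    sd = d(2.5, 2, 0.7, 6, 0.3, 1.5, 400, 8))),
    `3` = list(list(weight = 0.5,
                    mean = d(27.5, 24, 3.5, 28, 1.8, 6, 2000, 78.2),
                    sd = d(5, 3, 0.8, 7, 0.4, 2, 450, 8)),
               list(weight = 0.5,
                    mean = d(27.5, 24, 5.5, 28, 1.8, 6, 2000, 78.2),
                    sd = d(5, 3, 0.8, 7, 0.4, 2, 450, 8)))
  )
}

#' Generate a dense truth label matrix with powerset class structure
#'
#' Classes are drawn from the spec's proportions; the label matrix is their
#' powerset decoding, so [powerset_encode()] of the returned matrix
#' reproduces the drawn classes exactly.
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return List with `matrix` (dense `label_matrix`) and `classes`.
#' @export
generate_labels <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  if (sum(spec$class_proportions > 0) < 1) stopf("degenerate class proportions")
  L <- spec$n_targets
  n <- spec$n_compounds
  with_seed(derive_seed(seed, 11), {
    classes <- sample(0:(2^L - 1), n, replace = TRUE,
                      prob = spec$class_proportions)
    keys <- .synthetic_keys(n)
  })
  Y <- powerset_decode(classes, spec$target_names)
  rownames(Y) <- keys
  names(classes) <- keys
  list(matrix = label_matrix(Y), classes = classes)
}

#' Flip labels at a fixed noise rate
#'
#' @param matrix A `label_matrix`.
#' @param rate Per-cell flip probability.
#' @param seed Seed.
#' @return The noisy `label_matrix`.
#' @export
apply_label_noise <- function(matrix, rate, seed = 1) {
  lab <- .as_label_mat(matrix)
  if (rate > 0) {
    flips <- with_seed(derive_seed(seed, 13),
                       matrix(runif(length(lab)) < rate, nrow = nrow(lab)))
    flip_cells <- flips & !is.na(lab)
    lab[flip_cells] <- 1L - lab[flip_cells]
  }
  label_matrix(lab)
}

#' Remove annotations to emulate a sparse dataset
#'
#' A fraction of about `overlap` of the rows keeps all annotations; every
#' other row loses the annotation of exactly one target, chosen uniformly.
#' No row loses all its annotations.
#'
#' @param matrix A dense `label_matrix`.
#' @param overlap Fraction of fully annotated rows, in \[0, 1\].
#' @param seed Seed.
#' @return Sparse `label_matrix`.
#' @export
sparsify <- function(matrix, overlap, seed = 1) {
  stopifnot(overlap >= 0, overlap <= 1)
  lab <- .as_label_mat(matrix)
  L <- ncol(lab)
  if (L < 2) stopf("sparsify needs at least two targets")
  with_seed(derive_seed(seed, 17), {
    keep_all <- runif(nrow(lab)) < overlap
    drop_col <- sample.int(L, nrow(lab), replace = TRUE)
  })
  for (i in which(!keep_all)) lab[i, drop_col[i]] <- NA_integer_
  label_matrix(lab)
}

#' Generate class-conditional descriptor tables
#'
#' Draws the eight-descriptor panel from the spec's per-class Gaussian
#' mixtures; count descriptors (`a_hyd`, `a_aro`, `a_donacc`,
#' `weinerPath`) are rounded and clamped at zero.
#'
#' @param classes Integer powerset class vector (named by compound key).
#' @param spec A [generator_spec()].
#' @param seed Seed.
#' @return A `descriptor_table` data.frame, rows aligned with `classes`.
#' @export
generate_descriptors <- function(classes, spec, seed = spec$seed) {
  params <- spec$descriptor_params
  descr <- names(params[[1]][[1]]$mean)
  n <- length(classes)
  out <- matrix(NA_real_, nrow = n, ncol = length(descr),
                dimnames = list(names(classes) %||% paste0("cmp_", seq_len(n)),
                                descr))
  with_seed(derive_seed(seed, 19), {
    for (i in seq_len(n)) {
      p <- params[[as.character(classes[i])]]
      if (is.null(p)) stopf("no descriptor parameters for class %s", classes[i])
      w <- vapply(p, `[[`, numeric(1), "weight")
      comp <- p[[sample.int(length(p), 1, prob = w)]]
      out[i, ] <- rnorm(length(descr), comp$mean[descr], comp$sd[descr])
    }
  })
  counts <- intersect(c("a_hyd", "a_aro", "a_donacc", "weinerPath"), descr)
  out[, counts] <- pmax(round(out[, counts]), 0)
  out <- as.data.frame(out)
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Expand a truth label matrix into raw activity records
#'
#' Every annotated cell becomes one or more measurement records whose
#' binarized consensus reproduces the truth label, except for cells
#' designated conflicting (balanced 0/1 measurements, median 0.5), which
#' the collation pipeline must drop -- unless the cell also receives a
#' pre-curated record, whose label then wins by priority. Records carry
#' nanomolar IC50 values consistent with the 10 uM activity cutoff, a
#' fraction of `<`/`>` relation signs, distinct assay identifiers, and a
#' pre-curated subset.
#'
#' @param matrix Truth `label_matrix` (may be sparse).
#' @param spec A [generator_spec()].
#' @param seed Seed.
#' @return List with `records` (activity record data.frame, ready for
#'   [collate_activity()]) and `cells` (data.frame of per-cell truth and
#'   status: `clean`, `conflict_dropped` or `conflict_rescued`).
#' @export
generate_activity_records <- function(matrix, spec, seed = spec$seed) {
  lab <- .as_label_mat(matrix)
  cells <- which(!is.na(lab), arr.ind = TRUE)
  recs <- list()
  cell_rows <- list()
  assay_counter <- 0
  active_value <- function(k) 10^runif(k, 0, 3.9)      # pActivity in (5.1, 9)
  inactive_value <- function(k) 10^runif(k, 4.1, 7.9)  # pActivity in (1.1, 4.9)
  with_seed(derive_seed(seed, 23), {
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      key <- rownames(lab)[i]; tgt <- colnames(lab)[j]
      y <- lab[i, j]
      conflict <- runif(1) < spec$conflict_rate
      precurated <- runif(1) < spec$precurated_fraction
      if (conflict) {
        vals <- c(active_value(1), inactive_value(1))
        labels01 <- c(1L, 0L)
      } else {
        m <- 1 + rpois(1, spec$assay_multiplicity - 1)
        labels01 <- rep(y, m)
        vals <- ifelse(labels01 == 1, active_value(m), inactive_value(m))
      }
      rel <- rep("=", length(vals))
      use_rel <- runif(length(vals)) < spec$relation_rate
      rel[use_rel & labels01 == 1] <- "<"
      rel[use_rel & labels01 == 0] <- ">"
      assay_ids <- paste0("assay_", assay_counter + seq_along(vals))
      assay_counter <- assay_counter + length(vals)
      df <- data.frame(
        compound_id = key, structure = NA_character_, target_id = tgt,
        endpoint = "IC50", value_nM = vals, unit = "nanomolar",
        relation = rel, assay_id = assay_ids, source = "open",
        precomputed_label = NA_integer_, inchikey = key,
        stringsAsFactors = FALSE
      )
      if (precurated) {
        df <- rbind(df, data.frame(
          compound_id = key, structure = NA_character_, target_id = tgt,
          endpoint = "IC50", value_nM = NA_real_, unit = "nanomolar",
          relation = "=", assay_id = paste0("precurated_", r),
          source = "precurated", precomputed_label = y, inchikey = key,
          stringsAsFactors = FALSE
        ))
      }
      status <- if (!conflict) "clean" else if (precurated) "conflict_rescued"
                else "conflict_dropped"
      recs[[r]] <- df
      cell_rows[[r]] <- data.frame(inchikey = key, target_id = tgt,
                                   truth = y, status = status,
                                   stringsAsFactors = FALSE)
    }
  })
  list(records = do.call(rbind, recs), cells = do.call(rbind, cell_rows))
}

# Scaffold template library: SMILES written so that the first atom can take
# a substituent prefix; all substituents are acyclic, so the Bemis-Murcko
# scaffold of every generated compound is exactly its template framework.
.TEMPLATES <- list(
  quinoline = list(smiles = "c1ccc2ncccc2c1", classes = c(1, 3)),
  naphthalene = list(smiles = "c1ccc2ccccc2c1", classes = 1),
  phenylpiperazine = list(smiles = "C1CN(c2ccccc2)CCN1", classes = 1),
  xanthone = list(smiles = "c1ccc2c(c1)Oc1ccccc1C2=O", classes = c(2, 3)),
  indole = list(smiles = "c1ccc2[nH]ccc2c1", classes = 2),
  biphenyl = list(smiles = "c1ccc(-c2ccccc2)cc1", classes = 3),
  benzimidazole = list(smiles = "c1ccc2[nH]cnc2c1", classes = 0),
  benzene = list(smiles = "c1ccccc1", classes = 0)
)

# Deterministic unique acyclic substituent for index s and chain length len:
# a polar head group followed by an alkyl chain, concatenated as a SMILES
# prefix.
.substituent <- function(s, len) {
  heads <- c("", "O", "N", "ON", "NN")
  paste0(heads[(s %% length(heads)) + 1], strrep("C", len))
}

#' Generate template-based compound structures
#'
#' Assembles valid SMILES from a small scaffold library (quinoline,
#' naphthalene, xanthone, indole and friends) plus acyclic substituents, so
#' that scaffold clustering recovers the planted cluster sizes and the
#' computed descriptors track the planted class trends (long alkyl
#' substituents for P-gp-selective compounds, short polar substituents on
#' aromatic-rich frameworks for BCRP-selective ones).
#'
#' @param classes Integer powerset class vector.
#' @param spec A [generator_spec()]; `spec$scaffold_plan`, when set, fixes
#'   the planted cluster sizes (compound i is assigned to the cluster
#'   covering its index; templates cycle through the library).
#' @param seed Seed.
#' @return List of [compound_entry()] objects (one per class element);
#'   attribute `template` records each compound's scaffold template.
#' @export
generate_structures <- function(classes, spec, seed = spec$seed) {
  if (spec$structure_mode != "template_structures" &&
      is.null(spec$scaffold_plan)) {
    stopf("generate_structures requires template mode (or a scaffold_plan)")
  }
  n <- length(classes)
  tmpl_names <- names(.TEMPLATES)
  assignment <- character(n)
  if (!is.null(spec$scaffold_plan)) {
    plan <- spec$scaffold_plan
    stopifnot(sum(plan) >= n)
    cluster_of <- rep(seq_along(plan), plan)[seq_len(n)]
    assignment <- tmpl_names[((cluster_of - 1) %% length(tmpl_names)) + 1]
  } else {
    for (i in seq_len(n)) {
      pool <- tmpl_names[vapply(.TEMPLATES, function(t)
        classes[i] %in% t$classes, logical(1))]
      if (length(pool) == 0) pool <- tmpl_names
      assignment[i] <- pool[((i - 1) %% length(pool)) + 1]
    }
  }
  base_len <- c(`0` = 2L, `1` = 6L, `2` = 1L, `3` = 3L)
  counter <- integer(length(tmpl_names))
  names(counter) <- tmpl_names
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- assignment[i]
    counter[tm] <- counter[tm] + 1L
    s <- counter[tm]
    len_base <- base_len[as.character(classes[i] %% 4)] %||% 2L
    len <- len_base + (s - 1L) %/% 5L
    smi <- paste0(.substituent(s - 1L, len), .TEMPLATES[[tm]]$smiles)
    can <- .to_can_smiles(smi)
    if (is.na(can)) stopf("internal template '%s' produced invalid SMILES", smi)
    entries[[i]] <- compound_entry(sprintf("SYN%05d", i), can)
  }
  attr(entries, "template") <- assignment
  entries
}

#' Generate a complete synthetic study
#'
#' Orchestrates the generators under one seed: dense truth labels with
#' class structure, class-conditional descriptors, label noise, sparsified
#' observed annotations and the raw activity records that collate back to
#' the observed matrix.
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (defaults to the spec's).
#' @return List with `truth` (dense truth `label_matrix`), `classes`,
#'   `descriptors`, `observed` (noisy, sparsified `label_matrix`),
#'   `records` and `cells` (see [generate_activity_records()]).
#' @export
generate_study <- function(spec, seed = spec$seed) {
  labs <- generate_labels(spec, seed)
  X <- generate_descriptors(labs$classes, spec, seed)
  noisy <- apply_label_noise(labs$matrix, spec$label_noise, seed)
  observed <- if (spec$n_targets >= 2) {
    sparsify(noisy, spec$annotation_overlap, seed)
  } else noisy
  rec <- generate_activity_records(observed, spec, seed)
  list(truth = labs$matrix, classes = labs$classes, descriptors = X,
       observed = observed, records = rec$records, cells = rec$cells)
}

#' Constructed label-dependence scenario
#'
#' A two-label dataset engineered so that a classifiers chain ordered
#' (A, B) beats binary relevance on label B. Label A is a (lightly noised)
#' XOR of the signs of its two informative features and is annotated for
#' every compound; label B is a noisy copy of A (flip rate `flip_rate`)
#' whose own features are pure noise, annotated for only a small fraction
#' of compounds. B's binary-relevance model must learn the interaction from
#' those few rows -- which tree ensembles cannot do reliably -- whereas the
#' chain hands it A's propagated score, a single near-sufficient feature
#' distilled from the full annotation of A.
#'
#' @param n Number of compounds.
#' @param seed Seed.
#' @param flip_rate Noise on the dependent label B.
#' @param b_annotated_fraction Fraction of compounds annotated for B.
#' @return List with `X` (data.frame: 2 informative + 4 noise features),
#'   `Y` (label matrix with missing B annotations) and `Y_full` (complete
#'   truth, for held-out evaluation).
#' @export
generate_chain_scenario <- function(n = 400, seed = 1, flip_rate = 0.1,
                                    b_annotated_fraction = 0.1) {
  with_seed(derive_seed(seed, 29), {
    Xa <- matrix(rnorm(n * 2), ncol = 2,
                 dimnames = list(NULL, paste0("inf_", 1:2)))
    Xn <- matrix(rnorm(n * 4), ncol = 4,
                 dimnames = list(NULL, paste0("noise_", 1:4)))
    A <- as.integer(xor(Xa[, 1] > 0, Xa[, 2] > 0))
    A_flip <- runif(n) < 0.05
    A[A_flip] <- 1L - A[A_flip]
    flip <- runif(n) < flip_rate
    B <- ifelse(flip, 1L - A, A)
    b_ann <- sample(n, max(10, round(b_annotated_fraction * n)))
  })
  Y_full <- cbind(A = as.integer(A), B = as.integer(B))
  rownames(Y_full) <- paste0("cmp_", seq_len(n))
  Y <- Y_full
  Y[setdiff(seq_len(n), b_ann), "B"] <- NA_integer_
  X <- as.data.frame(cbind(Xa, Xn))
  rownames(X) <- rownames(Y)
  list(X = X, Y = Y, Y_full = Y_full)
}
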
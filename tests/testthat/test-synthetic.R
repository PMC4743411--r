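# Synthetic-data generators: class proportions, sparsification geometry,
# descriptor structure, record expansion, planted scaffolds, determinism.

test_that("generator spec validates its invariants", {
  expect_error(generator_spec(class_proportions = c(0.5, 0.5)), "length")
  expect_error(generator_spec(class_proportions = c(2, -1, 0, 0)), "sum to 1")
  expect_error(generator_spec(annotation_overlap = 1.5))
  expect_error(generator_spec(label_noise = 0.6))
})

test_that("drawn classes match the spec proportions within binomial error", {
  spec <- generator_spec(seed = 2, n_compounds = 10000)
  labs <- generate_labels(spec)
  counts <- table(factor(labs$classes, levels = 0:3))
  for (k in 0:3) {
    p <- spec$class_proportions[k + 1]
    sd3 <- 3 * sqrt(10000 * p * (1 - p))
    expect_lt(abs(counts[[k + 1]] - 10000 * p), sd3)
  }
  # encoding the matrix reproduces the drawn classes
  expect_equal(unname(powerset_encode(labs$matrix)), unname(labs$classes))
  # degenerate proportions: everything lands in class 0
  all0 <- generate_labels(generator_spec(seed = 3, n_compounds = 50,
                                         class_proportions = c(1, 0, 0, 0)))
  expect_true(all(all0$classes == 0))
})

test_that("sparsify keeps full rows at the overlap rate, never empties a row", {
  spec <- generator_spec(seed = 5, n_compounds = 400)
  labs <- generate_labels(spec)
  full <- sparsify(labs$matrix, 1, seed = 1)
  expect_identical(full$labels, labs$matrix$labels)
  none <- sparsify(labs$matrix, 0, seed = 1)
  expect_true(all(rowSums(is.na(none$labels)) == 1))
  # the curated-panel-shaped preset: dense subset size ~ overlap * n
  spec2 <- generator_spec(seed = 6, n_compounds = 2191)
  labs2 <- generate_labels(spec2)
  ov <- 161 / 2191
  sp <- sparsify(labs2$matrix, ov, seed = 2)
  n_dense <- sum(rowSums(is.na(sp$labels)) == 0)
  sd3 <- 3 * sqrt(2191 * ov * (1 - ov))
  expect_lt(abs(n_dense - 161), sd3)
  expect_true(all(rowSums(!is.na(sp$labels)) >= 1))
})

test_that("descriptors are class-conditional and reproducible", {
  spec <- generator_spec(seed = 7, n_compounds = 1000)
  labs <- generate_labels(spec)
  X1 <- generate_descriptors(labs$classes, spec)
  X2 <- generate_descriptors(labs$classes, spec)
  expect_identical(X1, X2)  # pure function of (spec, seed)
  # selectivity-rule recoverability is built into the defaults
  sel <- labs$classes %in% c(1, 2)
  acc <- mean(selectivity_rule(X1$a_hyd[sel], X1$a_aro[sel]) ==
                labs$classes[sel])
  expect_gte(acc, 0.85)
  rule2 <- mean(selectivity_rule(X1$a_hyd[labs$classes == 2],
                                 X1$a_aro[labs$classes == 2]) == 2)
  rule1 <- mean(selectivity_rule(X1$a_hyd[labs$classes == 1],
                                 X1$a_aro[labs$classes == 1]) == 2)
  expect_gte(rule2, 0.9)
  expect_lte(rule1, 0.1)
  # dual inhibitors carry the higher mean polarizability
  m <- class_mean_compare(X1$apol, labs$classes == 3)
  expect_gt(m["mean_in"], m["mean_out"])
  # the two rule descriptors are not collinear
  expect_lt(cor(X1$a_hyd, X1$a_aro), 0.5)
  # zero-variance parameters give constant columns
  p0 <- default_descriptor_params()
  for (i in seq_along(p0)) for (j in seq_along(p0[[i]])) {
    p0[[i]][[j]]$sd[] <- 0
  }
  spec0 <- generator_spec(seed = 8, n_compounds = 30, descriptor_params = p0)
  X0 <- generate_descriptors(rep(0L, 30), spec0)
  expect_equal(length(unique(X0$SlogP)), 1)
})

test_that("activity records collate back to the truth with conflicts dropped", {
  spec <- generator_spec(seed = 9, n_compounds = 150, conflict_rate = 0.08)
  labs <- generate_labels(spec)
  gen <- generate_activity_records(labs$matrix, spec)
  res <- collate_activity(gen$records)
  lab <- res$matrix$labels
  for (r in seq_len(nrow(gen$cells))) {
    cell <- gen$cells[r, ]
    got <- lab[cell$inchikey, cell$target_id]
    if (cell$status == "conflict_dropped") {
      expect_true(is.na(got))
    } else {
      expect_equal(got, cell$truth)
    }
  }
  # zero conflict rate: exact truth recovery
  spec0 <- generator_spec(seed = 10, n_compounds = 80, conflict_rate = 0)
  labs0 <- generate_labels(spec0)
  gen0 <- generate_activity_records(labs0$matrix, spec0)
  res0 <- collate_activity(gen0$records)
  expect_identical(res0$matrix$labels[rownames(labs0$matrix$labels),
                                      colnames(labs0$matrix$labels)],
                   labs0$matrix$labels)
})

test_that("relation-sign and pre-curated records appear at the spec rates", {
  spec <- generator_spec(seed = 11, n_compounds = 300, relation_rate = 0.2,
                         precurated_fraction = 0.2)
  labs <- generate_labels(spec)
  gen <- generate_activity_records(labs$matrix, spec)
  expect_gt(sum(gen$records$relation != "="), 0)
  expect_gt(sum(gen$records$source == "precurated"), 0)
  expect_true(all(gen$records$value_nM[!is.na(gen$records$value_nM)] > 0))
})

test_that("planted scaffold clusters are recovered by the profiler", {
  spec <- generator_spec(seed = 12, n_compounds = 20,
                         structure_mode = "template_structures",
                         scaffold_plan = c(17, 3))
  labs <- generate_labels(spec)
  entries <- generate_structures(labs$classes, spec)
  scafs <- vapply(entries, function(e) murcko_scaffold(e$structure),
                  character(1))
  names(scafs) <- vapply(entries, function(e) e$compound_id, character(1))
  prof <- scaffold_profile(scafs)
  sizes <- sort(vapply(prof$clusters, `[[`, integer(1), "n"), decreasing = TRUE)
  expect_equal(sizes, c(17L, 3L))
  # all-distinct templates give all singleton clusters
  spec1 <- generator_spec(seed = 13, n_compounds = 5,
                          structure_mode = "template_structures",
                          scaffold_plan = rep(1, 5))
  e1 <- generate_structures(generate_labels(spec1)$classes, spec1)
  s1 <- vapply(e1, function(e) murcko_scaffold(e$structure), character(1))
  names(s1) <- vapply(e1, function(e) e$compound_id, character(1))
  expect_equal(unname(scaffold_profile(s1)$summary["n_singletons"]), 5)
  # fixed seed reproduces the structure set exactly
  e2 <- generate_structures(generate_labels(spec1)$classes, spec1)
  expect_identical(vapply(e1, `[[`, character(1), "structure"),
                   vapply(e2, `[[`, character(1), "structure"))
})

test_that("template-mode descriptors track the planted class trends", {
  spec <- generator_spec(seed = 14, n_compounds = 60,
                         structure_mode = "template_structures",
                         class_proportions = c(0, 0.5, 0.5, 0))
  labs <- generate_labels(spec)
  entries <- generate_structures(labs$classes, spec)
  panel <- compute_descriptors(entries)
  cls <- labs$classes
  expect_gt(mean(panel$a_hyd[cls == 1]), mean(panel$a_hyd[cls == 2]))
  expect_gt(mean(panel$a_aro[cls == 2]), mean(panel$a_aro[cls == 1]))
})
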
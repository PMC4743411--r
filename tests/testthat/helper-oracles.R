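# Independent oracles and fixture builders used across the suite.

# Plain-R Floyd-Warshall all-pairs shortest paths on an undirected,
# unweighted edge list; independent of the igraph-based implementation.
fw_distances <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Random connected graph: a uniform random tree (random parent attachment)
# plus optionally extra edges to create cycles.
random_graph_edges <- function(n, extra = 0) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  if (extra > 0) {
    pool <- t(combn(n, 2))
    present <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    cand <- pool[!paste(pool[, 1], pool[, 2]) %in% present, , drop = FALSE]
    if (nrow(cand) > 0) {
      take <- cand[sample.int(nrow(cand), min(extra, nrow(cand))), , drop = FALSE]
      edges <- rbind(edges, take)
    }
  }
  edges
}

# Build a bare carbon-skeleton mol_graph directly from an edge list so the
# graph descriptors can be exercised on arbitrary topologies.
make_fake_mol <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  structure(
    list(element = rep("C", n), charge = rep(0L, n),
         aromatic = rep(FALSE, n),
         bonds = data.frame(a1 = as.integer(edges[, 1]),
                            a2 = as.integer(edges[, 2]),
                            order = rep(1L, nrow(edges))),
         n_h = rep(0L, n), graph = g, sdf = NULL),
    class = "mol_graph"
  )
}

# Balaban J evaluated straight from its formula on an oracle distance matrix.
balaban_oracle <- function(n, edges) {
  d <- fw_distances(n, edges)
  s <- rowSums(d)
  q <- nrow(edges)
  mu <- q - n + 1
  (q / (mu + 1)) * sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]]))
}

# Exhaustive-midpoint MCC scan oracle (brute force over all candidate
# thresholds, formula recomputed from raw counts).
scan_oracle <- function(values, is_a) {
  v <- sort(unique(values))
  thr <- (v[-1] + v[-length(v)]) / 2
  best <- c(threshold = NA_real_, mcc = 0)
  for (t in thr) {
    p <- values <= t
    tp <- sum(is_a & p); tn <- sum(!is_a & !p)
    fp <- sum(!is_a & p); fn <- sum(is_a & !p)
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    m <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
    if (abs(m) > abs(best["mcc"])) best <- c(threshold = t, mcc = m)
  }
  best
}

# Small activity-record data.frame builder for collation tests.
make_records <- function(inchikey, target, value = NA, relation = "=",
                         source = "open", label = NA, assay = NULL) {
  k <- max(length(inchikey), length(target), length(value), length(label))
  data.frame(
    compound_id = rep_len(inchikey, k), structure = NA_character_,
    target_id = rep_len(target, k), endpoint = "IC50",
    value_nM = rep_len(value, k), unit = "nanomolar",
    relation = rep_len(relation, k),
    assay_id = assay %||% paste0("a", seq_len(k)),
    source = rep_len(source, k),
    precomputed_label = rep_len(as.integer(label), k),
    inchikey = rep_len(inchikey, k), stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny, diverse SMILES panel reused across chemistry tests.
test_smiles <- c(
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1",
  naphthalene = "c1ccc2ccccc2c1",
  caffeine_like = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ibuprofen_like = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  quinoline = "c1ccc2ncccc2c1"
)
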
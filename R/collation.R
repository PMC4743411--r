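# Collation of raw activity records into consensus binary label matrices.
#
# The rules, in pipeline order: keep only IC50/EC50/Ki endpoints in nanomolar
# units; drop records with unspecified activity or value above 1e8 nM (data
# errors); transform values to pActivity = -log10(molar); binarize at
# pActivity > 5 (i.e. < 10 uM) honouring relation signs; pivot observations
# by InChIKey x target; resolve each cell by pre-curated priority, otherwise
# the median of the open-domain labels, dropping cells whose label median is
# exactly 0.5. The whole procedure is deterministic.

#' Negative log molar activity (pActivity)
#'
#' `pActivity = -log10(value_nM * 1e-9)`. A 10 uM activity (10000 nM) maps
#' to exactly 5.
#'
#' @param value_nM Positive activity value(s) in nanomolar.
#' @return Numeric pActivity value(s).
#' @export
to_plog <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0)) {
    stopf("to_plog requires positive finite values")
  }
  -log10(value_nM * 1e-9)
}

#' Sanity filter for raw activity records
#'
#' Drops records whose activity value exceeds the cap (default 1e8 nM,
#' strictly greater) and records with neither a value nor a pre-assigned
#' label. Records carrying a pre-computed binary label pass.
#'
#' @param records Activity record data.frame (see [read_activity_table()]).
#' @param cap Upper value cap in nanomolar.
#' @return The filtered data.frame; attribute `n_dropped` counts removals.
#' @export
sanity_filter <- function(records, cap = 1e8) {
  has_value <- !is.na(records$value_nM)
  has_label <- !is.na(records$precomputed_label)
  keep <- (has_value & records$value_nM <= cap) | (!has_value & has_label)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Binarize a pActivity value under its relation sign
#'
#' For `relation = "="` the label is 1 when `pActivity > 5` (strict) and 0
#' otherwise. A `"<"`/`"<="` relation on the concentration makes the
#' computed pActivity a lower bound: the record is active when
#' `pActivity >= 5` and ambiguous otherwise. A `">"`/`">="` relation makes
#' it an upper bound: inactive when `pActivity <= 5`, ambiguous otherwise.
#' Ambiguous records are excluded downstream.
#'
#' @param pactivity Numeric pActivity value(s).
#' @param relation Relation sign(s): `=`, `<`, `>`, `<=`, `>=`.
#' @param cutoff Activity cutoff on the pActivity scale (default 5).
#' @return Integer vector with values 0, 1 or NA (ambiguous).
#' @export
binarize_activity <- function(pactivity, relation = "=", cutoff = 5) {
  stopifnot(all(is.finite(pactivity)))
  relation <- rep_len(relation, length(pactivity))
  out <- rep(NA_integer_, length(pactivity))
  eq <- relation == "="
  lo <- relation %in% c("<", "<=")
  hi <- relation %in% c(">", ">=")
  if (!all(eq | lo | hi)) stopf("unknown relation sign")
  out[eq] <- as.integer(pactivity[eq] > cutoff)
  out[lo & pactivity >= cutoff] <- 1L
  out[hi & pactivity <= cutoff] <- 0L
  out
}

#' Convert filtered records to binary observations
#'
#' Applies [to_plog()] and [binarize_activity()] to value-carrying records
#' and passes pre-computed labels through; ambiguous records are dropped.
#' Records must carry an `inchikey` column (attach via [compute_inchikey()]
#' or supply it in the table).
#'
#' @param records Activity record data.frame with an `inchikey` column.
#' @param cutoff pActivity cutoff (default 5).
#' @return data.frame of binary observations: `inchikey`, `target_id`,
#'   `label`, `assay_id`, `source`; attribute `n_ambiguous` counts drops.
#' @export
records_to_observations <- function(records, cutoff = 5) {
  if (!"inchikey" %in% names(records)) {
    stopf("records need an 'inchikey' column before pivoting")
  }
  label <- records$precomputed_label
  has_value <- !is.na(records$value_nM)
  if (any(has_value)) {
    p <- to_plog(records$value_nM[has_value])
    label[has_value] <- binarize_activity(p, records$relation[has_value], cutoff)
  }
  keep <- !is.na(label)
  out <- data.frame(
    inchikey = records$inchikey[keep],
    target_id = records$target_id[keep],
    label = as.integer(label[keep]),
    assay_id = records$assay_id[keep],
    source = records$source[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_ambiguous") <- sum(!keep)
  out
}

#' Consensus label for one compound-target cell
#'
#' Pre-curated labels take priority: if any are present and they agree, that
#' label is returned; conflicting pre-curated labels drop the cell. With
#' open-domain labels only, the median label decides; a median of exactly
#' 0.5 (equally frequent 0 and 1) drops the cell. Invariant to the order of
#' the provenance entries.
#'
#' @param labels Integer vector of 0/1 labels.
#' @param sources Character vector (`"open"`/`"precurated"`), same length.
#' @return 0, 1, or NA (cell dropped).
#' @export
consensus_label <- function(labels, sources) {
  if (length(labels) == 0) stopf("consensus of an empty provenance list")
  stopifnot(length(labels) == length(sources), all(labels %in% c(0L, 1L)))
  pre <- labels[sources == "precurated"]
  if (length(pre) > 0) {
    u <- unique(pre)
    return(if (length(u) == 1) as.integer(u) else NA_integer_)
  }
  m <- median(labels)
  if (m == 0.5) NA_integer_ else as.integer(m > 0.5)
}

#' Pivot binary observations into a label matrix
#'
#' Rows are unique InChIKeys, columns target identifiers. Every cell with at
#' least one observation receives its consensus label ([consensus_label()]);
#' cells dropped by consensus and unmeasured pairs are `NA`. Full per-cell
#' provenance is retained.
#'
#' @param observations data.frame from [records_to_observations()].
#' @param targets Optional explicit column order.
#' @return A `label_matrix`: list with `labels` (integer matrix, `NA` =
#'   missing) and `provenance` (nested list of data.frames).
#' @export
pivot_observations <- function(observations, targets = NULL) {
  keys <- unique(observations$inchikey)
  targets <- targets %||% sort(unique(observations$target_id))
  labels <- matrix(NA_integer_, nrow = length(keys), ncol = length(targets),
                   dimnames = list(keys, targets))
  provenance <- setNames(vector("list", length(keys)), keys)
  idx <- split(seq_len(nrow(observations)),
               list(observations$inchikey, observations$target_id),
               drop = TRUE)
  for (cell in names(idx)) {
    rows <- idx[[cell]]
    key <- observations$inchikey[rows[1]]
    tgt <- observations$target_id[rows[1]]
    prov <- data.frame(assay_id = observations$assay_id[rows],
                       label = observations$label[rows],
                       source = observations$source[rows],
                       stringsAsFactors = FALSE)
    labels[key, tgt] <- consensus_label(prov$label, prov$source)
    if (is.null(provenance[[key]])) provenance[[key]] <- list()
    provenance[[key]][[tgt]] <- prov
  }
  label_matrix(labels, provenance)
}

#' Construct a label matrix
#' @param labels Integer matrix in \{0, 1, NA\} with compound rownames and
#'   target colnames.
#' @param provenance Optional nested list of per-cell provenance.
#' @return Object of class `label_matrix`.
#' @export
label_matrix <- function(labels, provenance = NULL) {
  stopifnot(is.matrix(labels), !is.null(rownames(labels)),
            !is.null(colnames(labels)))
  if (anyDuplicated(rownames(labels))) stopf("duplicate compound keys")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  lab <- x$labels
  cat(sprintf("<label_matrix> %d compounds x %d targets (%d missing cells)\n",
              nrow(lab), ncol(lab), sum(is.na(lab))))
  invisible(x)
}

#' @export
dim.label_matrix <- function(x) dim(x$labels)

#' Split a label matrix into sparse and dense datasets
#'
#' The sparse dataset keeps compounds with at least one annotation; the
#' dense dataset keeps compounds annotated for every target. The dense set
#' is always a subset of the sparse set.
#'
#' @param matrix A `label_matrix`.
#' @return List with elements `sparse` and `dense` (both `label_matrix`).
#' @export
build_datasets <- function(matrix) {
  stopifnot(inherits(matrix, "label_matrix"))
  lab <- matrix$labels
  n_ann <- rowSums(!is.na(lab))
  sparse_rows <- n_ann >= 1
  dense_rows <- n_ann == ncol(lab)
  sub <- function(rows) {
    label_matrix(lab[rows, , drop = FALSE],
                 if (!is.null(matrix$provenance)) matrix$provenance[rownames(lab)[rows]])
  }
  list(sparse = sub(sparse_rows), dense = sub(dense_rows))
}

#' Export a label matrix as a heat-map table
#'
#' @param matrix A `label_matrix`.
#' @return data.frame with a `compound` column and one 0/1/NA column per
#'   target, suitable for TSV export or heat-map rendering (missing cells
#'   are `NA`, distinct from 0).
#' @export
heatmap_table <- function(matrix) {
  stopifnot(inherits(matrix, "label_matrix"))
  if (nrow(matrix$labels) == 0) stopf("empty label matrix")
  data.frame(compound = rownames(matrix$labels), matrix$labels,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a label matrix as TSV
#' @param matrix A `label_matrix` (provenance is not serialized).
#' @param path File path.
#' @return The reader returns a `label_matrix`; the writer its path,
#'   invisibly.
#' @export
write_label_matrix <- function(matrix, path) {
  write.table(heatmap_table(matrix), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  lab <- as.matrix(df[, setdiff(names(df), "compound"), drop = FALSE])
  rownames(lab) <- df$compound
  label_matrix(lab)
}

#' Run the full collation pipeline on raw activity records
#'
#' Sanity filter, log transform, relation-aware binarization, InChIKey
#' pivot, consensus resolution and sparse/dense dataset construction, in
#' that order. Bit-identical across re-runs on the same input.
#'
#' @param records Activity record data.frame with an `inchikey` column.
#' @param cutoff pActivity cutoff (default 5).
#' @param cap Value cap in nanomolar (default 1e8).
#' @return List with `matrix` (full `label_matrix`), `sparse`, `dense`, and
#'   `counts` (records dropped at each stage).
#' @export
collate_activity <- function(records, cutoff = 5, cap = 1e8) {
  filtered <- sanity_filter(records, cap = cap)
  obs <- records_to_observations(filtered, cutoff = cutoff)
  lm <- pivot_observations(obs)
  ds <- build_datasets(lm)
  dropped_consensus <- sum(vapply(rownames(lm$labels), function(k) {
    measured <- names(lm$provenance[[k]] %||% list())
    sum(is.na(lm$labels[k, measured]))
  }, numeric(1)))
  list(matrix = lm, sparse = ds$sparse, dense = ds$dense,
       counts = c(dropped_sanity = attr(filtered, "n_dropped"),
                  dropped_ambiguous = attr(obs, "n_ambiguous"),
                  dropped_consensus = dropped_consensus))
}

#' Summary statistics of a collated dataset
#'
#' Dataset-level statistics of the kind reported for curated transporter
#' inhibition panels: sparse and dense sizes, per-target annotation and
#' active/inactive counts, and per-class counts of the dense dataset under
#' the label-powerset encoding.
#'
#' @param sparse,dense `label_matrix` objects from [build_datasets()].
#' @return List of named counts.
#' @export
dataset_statistics <- function(sparse, dense) {
  per_target <- lapply(colnames(sparse$labels), function(t) {
    col <- sparse$labels[, t]
    c(annotated = sum(!is.na(col)), active = sum(col == 1, na.rm = TRUE),
      inactive = sum(col == 0, na.rm = TRUE))
  })
  names(per_target) <- colnames(sparse$labels)
  cls <- powerset_encode(dense)
  list(
    n_sparse = nrow(sparse$labels),
    n_dense = nrow(dense$labels),
    per_target = per_target,
    class_counts = as.integer(table(factor(cls, levels = 0:(2^ncol(dense$labels) - 1))))
  )
}
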
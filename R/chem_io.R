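# Chemical and activity-data I/O: SDF import, structure standardisation
# (salt stripping, neutralisation, element filtering), InChIKey computation
# and delimited activity tables.

# Drug-like element whitelist used by the standardiser.
ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

# Elements treated as metals for the organometallic rejection rule.
.METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru",
  "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta",
  "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Create a compound entry
#'
#' A compound entry carries an opaque identifier, a structure (SMILES or
#' InChI), an optional standard InChIKey and a source tag distinguishing
#' open-domain from pre-curated records.
#'
#' @param compound_id Opaque identifier string.
#' @param structure SMILES or InChI string.
#' @param inchikey Optional 27-character standard InChIKey.
#' @param source `"open"` or `"precurated"`.
#' @return A list of class `compound_entry`.
#' @export
compound_entry <- function(compound_id, structure, inchikey = NA_character_,
                           source = c("open", "precurated")) {
  source <- match.arg(source)
  if (!is.na(inchikey) && !grepl(.INCHIKEY_RE, inchikey)) {
    stopf("'%s' is not a standard InChIKey", inchikey)
  }
  structure(list(compound_id = as.character(compound_id),
                 structure = as.character(structure),
                 inchikey = inchikey, source = source),
            class = "compound_entry")
}

#' @export
print.compound_entry <- function(x, ...) {
  cat(sprintf("<compound_entry> %s [%s] %s\n", x$compound_id, x$source,
              x$structure))
  invisible(x)
}

# A rejection marker returned in place of an entry that failed a stage.
compound_rejection <- function(compound_id, stage, reason) {
  structure(list(compound_id = compound_id, stage = stage, reason = reason),
            class = "compound_rejection")
}

#' Test whether an object is a stage rejection
#' @param x Any object.
#' @return Logical.
#' @export
is_rejection <- function(x) inherits(x, "compound_rejection")

rejections_df <- function(rejs) {
  if (length(rejs) == 0) {
    return(data.frame(compound_id = character(0), stage = character(0),
                      reason = character(0)))
  }
  do.call(rbind, lapply(rejs, function(r) {
    data.frame(compound_id = r$compound_id, stage = r$stage, reason = r$reason)
  }))
}

#' Write a rejection log as TSV
#' @param rejections data.frame with columns compound_id, stage, reason.
#' @param path Output path.
#' @export
write_rejection_log <- function(rejections, path) {
  write.table(rejections, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.is_inchi <- function(x) startsWith(x, "InChI=")

# One structure string -> canonical SMILES via OpenBabel, or NA on failure.
.to_can_smiles <- function(structure) {
  from <- if (.is_inchi(structure)) "INCHI" else "SMI"
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, "CAN", structure)),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", out))
  out <- strsplit(out, "\n")[[1]][1]
  if (is.null(out) || is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Read compounds from an SDF file
#'
#' Reads a V2000 SD file, keeping one entry per valid molecule block.
#' Unparseable blocks are skipped and counted in the `skipped` attribute.
#'
#' @param path Path to the SDF file.
#' @param source Source tag applied to every entry.
#' @return List of [compound_entry()] objects; attribute `skipped` holds the
#'   number of discarded blocks.
#' @export
read_sdf <- function(path, source = c("open", "precurated")) {
  source <- match.arg(source)
  if (!file.exists(path)) stopf("SDF file '%s' does not exist", path)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- tryCatch(ChemmineR::validSDF(sdfset), error = function(e) logical(0))
  n_total <- length(sdfset)
  sdfset <- sdfset[valid]
  if (length(sdfset) == 0) stopf("no parseable molecules in '%s'", path)
  ids <- ChemmineR::sdfid(sdfset)
  ids[!nzchar(ids)] <- paste0("mol_", which(!nzchar(ids)))
  entries <- vector("list", length(sdfset))
  keep <- logical(length(sdfset))
  for (i in seq_along(sdfset)) {
    smi <- tryCatch({
      tf <- tempfile(fileext = ".sdf")
      ChemmineR::write.SDF(sdfset[[i]], tf)
      on.exit(unlink(tf), add = TRUE)
      .to_can_smiles_sdf(paste(readLines(tf), collapse = "\n"))
    }, error = function(e) NA_character_)
    if (is.na(smi)) next
    entries[[i]] <- compound_entry(ids[i], smi, source = source)
    keep[i] <- TRUE
  }
  entries <- entries[keep]
  if (length(entries) == 0) stopf("no parseable molecules in '%s'", path)
  attr(entries, "skipped") <- n_total - length(entries)
  entries
}

.to_can_smiles_sdf <- function(sdf_text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", sdf_text)),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", strsplit(out, "\n")[[1]][1]))
  if (is.null(out) || is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Write compound entries to an SDF file
#' @param entries List of [compound_entry()] objects.
#' @param path Output path.
#' @export
write_sdf <- function(entries, path) {
  smis <- vapply(entries, function(e) e$structure, character(1))
  ids <- vapply(entries, function(e) e$compound_id, character(1))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smis, ids)))
  ChemmineR::write.SDF(sdfset, path)
  invisible(path)
}

#' Standardize a compound structure
#'
#' Applies the dataset-washing rules: keep the largest organic fragment of a
#' multi-fragment input (salt stripping), neutralize simple protonation
#' states (protonated amines, deprotonated acids; via OpenBabel's neutralize
#' transform), and emit the canonical SMILES. Inputs are rejected when they
#' cannot be parsed, when the two largest fragments have equal heavy-atom
#' counts (unresolvable mixture), when no fragment contains carbon, when the
#' kept fragment has a metal--carbon bond (organometallic) or contains an
#' element outside the drug-like set
#' \{H, B, C, N, O, F, Si, P, S, Cl, Br, I\}.
#'
#' @param entry A [compound_entry()].
#' @return The entry with a canonical standardized structure, or a rejection
#'   object (see [is_rejection()]).
#' @export
standardize_compound <- function(entry) {
  stopifnot(inherits(entry, "compound_entry"))
  can <- .to_can_smiles(entry$structure)
  if (is.na(can)) {
    return(compound_rejection(entry$compound_id, "standardize", "unparseable_structure"))
  }
  # canonical SMILES separates fragments with '.'
  frag_smis <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- lapply(frag_smis, function(s) {
    tryCatch(mol_from_smiles(s), error = function(e) NULL)
  })
  if (any(vapply(frags, is.null, logical(1)))) {
    return(compound_rejection(entry$compound_id, "standardize", "unparseable_structure"))
  }
  sizes <- vapply(frags, function(f) length(f$element), integer(1))
  ord <- order(sizes, decreasing = TRUE)
  if (length(frags) > 1 && sizes[ord[1]] == sizes[ord[2]]) {
    return(compound_rejection(entry$compound_id, "standardize", "unresolvable_mixture"))
  }
  has_c <- vapply(frags, function(f) any(f$element == "C"), logical(1))
  if (!any(has_c)) {
    return(compound_rejection(entry$compound_id, "standardize", "no_organic_fragment"))
  }
  pick <- ord[has_c[ord]][1]
  mol <- frags[[pick]]
  can <- frag_smis[pick]

  bad <- setdiff(unique(mol$element), ALLOWED_ELEMENTS)
  if (length(bad) > 0) {
    # Metal bonded to carbon in the kept fragment -> organometallic.
    metal_atoms <- which(mol$element %in% .METALS)
    organometallic <- any(vapply(metal_atoms, function(i) {
      any(mol$element[.neighbors(mol, i)] == "C")
    }, logical(1)))
    reason <- if (organometallic) "organometallic" else "disallowed_element"
    return(compound_rejection(entry$compound_id, "standardize", reason))
  }

  neut <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", can,
      options = data.frame(names = "neutralize", args = ""))),
    error = function(e) ""
  )
  neut <- trimws(sub("\t.*$", "", strsplit(neut, "\n")[[1]][1]))
  if (!is.na(neut) && nzchar(neut)) can <- neut

  entry$structure <- can
  entry
}

#' Standardize a list of compound entries
#' @param entries List of [compound_entry()] objects.
#' @return List with `entries` (standardized survivors) and `rejections`
#'   (data.frame compound_id / stage / reason).
#' @export
standardize_compounds <- function(entries) {
  out <- lapply(entries, standardize_compound)
  ok <- !vapply(out, is_rejection, logical(1))
  list(entries = out[ok], rejections = rejections_df(out[!ok]))
}

#' Attach the standard InChIKey to a compound entry
#'
#' The key is a pure function of the standardized structure: identical
#' structures always receive identical keys.
#'
#' @param entry A standardized [compound_entry()].
#' @return The entry with `inchikey` filled in, or a rejection object.
#' @export
compute_inchikey <- function(entry) {
  stopifnot(inherits(entry, "compound_entry"))
  key <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", entry$structure)),
    error = function(e) ""
  )
  key <- trimws(strsplit(key, "\n")[[1]][1])
  if (is.null(key) || is.na(key) || !grepl(.INCHIKEY_RE, key)) {
    return(compound_rejection(entry$compound_id, "inchikey", "inchi_generation_failed"))
  }
  entry$inchikey <- key
  entry
}

#' Read an activity table from a delimited file
#'
#' Each row is mapped to an activity record or logged as a rejection. Units
#' other than nanomolar are rejected, as are unknown relation symbols,
#' non-positive values and unknown endpoints. Rows may alternatively carry a
#' pre-assigned binary label (pre-curated data) in place of a value.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named character vector mapping the standard fields
#'   (`compound_id`, `structure`, `target_id`, `endpoint`, `value`, `unit`,
#'   `relation`, `assay_id`, `source`, `label`) to column names in the file.
#'   Fields absent from the map fall back to a column of the same name;
#'   `label`, `structure` and `unit` are optional.
#' @param sep Field separator (default tab; use "," for CSV).
#' @param allowed_endpoints Endpoints accepted (default IC50/EC50/Ki).
#' @return List with `records` (data.frame, one row per accepted record) and
#'   `rejected` (data.frame with a `reason` column).
#' @export
read_activity_table <- function(path, column_map = character(0), sep = "\t",
                                allowed_endpoints = c("IC50", "EC50", "Ki")) {
  if (!file.exists(path)) stopf("activity table '%s' does not exist", path)
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  synonyms <- list(value = c("value", "value_nM"),
                   label = c("label", "precomputed_label"))
  getcol <- function(field, default = NA_character_) {
    cand <- c(if (field %in% names(column_map)) column_map[[field]],
              synonyms[[field]] %||% field)
    hit <- cand[cand %in% names(raw)]
    if (length(hit) > 0) raw[[hit[1]]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    compound_id = as.character(getcol("compound_id")),
    structure = as.character(getcol("structure")),
    inchikey = as.character(getcol("inchikey")),
    target_id = as.character(getcol("target_id")),
    endpoint = as.character(getcol("endpoint")),
    value_nM = suppressWarnings(as.numeric(getcol("value"))),
    unit = as.character(getcol("unit", "nanomolar")),
    relation = as.character(getcol("relation", "=")),
    assay_id = as.character(getcol("assay_id")),
    source = as.character(getcol("source", "open")),
    precomputed_label = suppressWarnings(as.integer(getcol("label", NA))),
    stringsAsFactors = FALSE
  )
  rec$relation[is.na(rec$relation) | !nzchar(rec$relation)] <- "="
  rec$unit[is.na(rec$unit) | !nzchar(rec$unit)] <- "nanomolar"

  reason <- rep(NA_character_, nrow(rec))
  has_label <- !is.na(rec$precomputed_label)
  has_value <- !is.na(rec$value_nM)
  bad_unit <- has_value & !tolower(rec$unit) %in% c("nanomolar", "nm")
  reason[bad_unit] <- "unit_not_nanomolar"
  bad_rel <- has_value & !rec$relation %in% c("=", "<", ">", "<=", ">=")
  reason[bad_rel & is.na(reason)] <- "unknown_relation"
  bad_ep <- has_value & !rec$endpoint %in% allowed_endpoints
  reason[bad_ep & is.na(reason)] <- "endpoint_not_allowed"
  reason[has_value & rec$value_nM <= 0 & is.na(reason)] <- "non_positive_value"
  reason[!has_value & !has_label & is.na(reason)] <- "no_activity"
  reason[has_label & !rec$precomputed_label %in% c(0L, 1L) & is.na(reason)] <-
    "invalid_label"

  keep <- is.na(reason)
  rejected <- rec[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(records = rec[keep, , drop = FALSE], rejected = rejected)
}
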
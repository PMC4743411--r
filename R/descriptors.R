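# Interpretable molecular descriptor panel, fingerprints and Bemis-Murcko
# scaffolds.
#
# The panel mirrors the descriptor names used in 2D QSAR practice (a_aro,
# a_hyd, SlogP, vsa_acc, BalabanJ, a_donacc, weinerPath, apol). The atom
# typing rules are open, documented equivalents of the proprietary originals
# ("approximate-MOE"): same intent, auditable definitions, not bit-identical
# numerics. Graph descriptors (weinerPath, BalabanJ) use heavy atoms only;
# apol includes implicit hydrogens.

# Atomic polarizabilities in cubic Angstroms (CRC Handbook static dipole
# polarizabilities of the elements).
.POLARIZABILITY <- c(
  H = 0.666793, B = 3.03, C = 1.76, N = 1.10, O = 0.802, F = 0.557,
  Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35
)

# Bondi van der Waals radii (Angstroms).
.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# Single-bond covalent radii (Angstroms), used to estimate ideal bond lengths
# for the van der Waals surface approximation.
.COV_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

.as_mol <- function(x) {
  if (inherits(x, "mol_graph")) return(x)
  if (is.character(x)) return(mol_from_smiles(x))
  if (is(x, "SDF")) return(mol_graph(x))
  stopf("cannot interpret input of class '%s' as a molecule", class(x)[1])
}

#' Count aromatic atoms (a_aro)
#'
#' Number of heavy atoms flagged aromatic by the ring perceiver.
#'
#' @param mol A SMILES string, `SDF` object or `mol_graph`.
#' @return Non-negative integer.
#' @export
count_aromatic_atoms <- function(mol) {
  mol <- .as_mol(mol)
  sum(mol$aromatic)
}

#' Count hydrophobic atoms (a_hyd)
#'
#' Typing rule (fixed in code and documentation): an atom is hydrophobic if
#' it is (a) a carbon with no bonded N, O, P or S neighbour, or (b) a halogen
#' (F, Cl, Br, I) bonded to a carbon. Polar-environment carbons (e.g. the
#' carbon of methanol) are excluded.
#'
#' @inheritParams count_aromatic_atoms
#' @return Non-negative integer.
#' @export
count_hydrophobic_atoms <- function(mol) {
  mol <- .as_mol(mol)
  n <- length(mol$element)
  if (n == 0) return(0L)
  hyd <- logical(n)
  for (i in seq_len(n)) {
    nb <- mol$element[.neighbors(mol, i)]
    if (mol$element[i] == "C") {
      hyd[i] <- !any(nb %in% c("N", "O", "P", "S"))
    } else if (mol$element[i] %in% c("F", "Cl", "Br", "I")) {
      hyd[i] <- any(nb == "C")
    }
  }
  sum(hyd)
}

#' Atomic-contribution logP (SlogP)
#'
#' Wildman--Crippen style atomic-contribution octanol/water partition
#' coefficient, computed by OpenBabel. Being a sum of atomic contributions it
#' is additive over disjoint fragments.
#'
#' @param mol A SMILES string, `SDF` object or `mol_graph`.
#' @return Numeric logP estimate.
#' @export
slogp <- function(mol) {
  mol <- .as_mol(mol)
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(.mol_to_smiles(mol)))
  props <- suppressWarnings(ChemmineR::propOB(sdfset))
  out <- props$logP[1]
  if (is.null(out) || is.na(out)) stopf("logP could not be computed")
  as.numeric(out)
}

#' Wiener path index
#'
#' Sum of the lengths of the shortest paths between all unordered pairs of
#' heavy atoms in the molecular graph.
#'
#' @inheritParams slogp
#' @return Non-negative integer; errors on a disconnected heavy-atom graph.
#' @export
wiener_path <- function(mol) {
  mol <- .as_mol(mol)
  n <- length(mol$element)
  if (n <= 1) return(0L)
  d <- igraph::distances(mol$graph)
  if (any(is.infinite(d))) stopf("wiener_path requires a connected molecule")
  as.integer(sum(d[upper.tri(d)]))
}

#' Balaban's J connectivity index
#'
#' `J = q/(mu + 1) * sum over edges (s_i * s_j)^(-1/2)` where `q` is the
#' number of edges, `mu = q - n + 1` the cyclomatic number and `s_i` the row
#' sum of the topological distance matrix. A single-atom molecule is defined
#' to have `J = 0`.
#'
#' @inheritParams slogp
#' @return Numeric index value.
#' @export
balaban_j <- function(mol) {
  mol <- .as_mol(mol)
  n <- length(mol$element)
  if (n <= 1) return(0)
  d <- igraph::distances(mol$graph)
  if (any(is.infinite(d))) stopf("balaban_j requires a connected molecule")
  s <- rowSums(d)
  q <- nrow(mol$bonds)
  mu <- q - n + 1
  edge_terms <- 1 / sqrt(s[mol$bonds$a1] * s[mol$bonds$a2])
  q / (mu + 1) * sum(edge_terms)
}

# Acceptor rule: O with formal charge <= 0, or trivalent-or-less N with
# charge <= 0, excluding pyrrole-type aromatic N-H (lone pair in the ring).
.is_acceptor <- function(mol) {
  n <- length(mol$element)
  vapply(seq_len(n), function(i) {
    el <- mol$element[i]
    if (mol$charge[i] > 0) return(FALSE)
    if (el == "O") return(TRUE)
    if (el == "N") {
      b <- mol$bonds
      bsum <- sum(b$order[b$a1 == i | b$a2 == i])
      if (mol$aromatic[i] && mol$n_h[i] > 0) return(FALSE)
      return(bsum <= 3)
    }
    FALSE
  }, logical(1))
}

# Donor rule: N or O carrying at least one hydrogen.
.is_donor <- function(mol) {
  mol$element %in% c("N", "O") & mol$n_h > 0
}

#' Approximate van der Waals surface area of H-bond acceptors (vsa_acc)
#'
#' Each acceptor atom contributes its exposed sphere surface: the full van
#' der Waals sphere minus the spherical caps occluded by bonded neighbours
#' (including implicit hydrogens), with ideal bond lengths estimated from
#' covalent radii. This is a Labute-style approximation; values are in
#' square Angstroms but are not numerically identical to proprietary
#' implementations.
#'
#' @inheritParams slogp
#' @return Non-negative numeric surface area.
#' @export
vsa_acc <- function(mol) {
  mol <- .as_mol(mol)
  acc <- which(.is_acceptor(mol))
  if (length(acc) == 0) return(0)
  total <- 0
  for (i in acc) {
    ri <- .VDW_RADII[[mol$element[i]]]
    area <- 4 * pi * ri^2
    nb <- .neighbors(mol, i)
    for (j in nb) {
      rj <- .VDW_RADII[[mol$element[j]]]
      dij <- .COV_RADII[[mol$element[i]]] + .COV_RADII[[mol$element[j]]]
      h <- ri - (ri^2 + dij^2 - rj^2) / (2 * dij)
      h <- min(max(h, 0), 2 * ri)
      area <- area - 2 * pi * ri * h
    }
    if (mol$n_h[i] > 0) {
      rj <- .VDW_RADII[["H"]]
      dij <- .COV_RADII[[mol$element[i]]] + .COV_RADII[["H"]]
      h <- ri - (ri^2 + dij^2 - rj^2) / (2 * dij)
      h <- min(max(h, 0), 2 * ri)
      area <- area - mol$n_h[i] * 2 * pi * ri * h
    }
    total <- total + max(area, 0)
  }
  total
}

#' Count hydrogen-bond donor and acceptor atoms (a_donacc)
#'
#' Size of the union of donor atoms (N/O carrying at least one hydrogen) and
#' acceptor atoms (see [vsa_acc()] for the acceptor rule); an atom that is
#' both donor and acceptor is counted once.
#'
#' @inheritParams slogp
#' @return Non-negative integer.
#' @export
a_donacc <- function(mol) {
  mol <- .as_mol(mol)
  sum(.is_donor(mol) | .is_acceptor(mol))
}

#' Sum of atomic polarizabilities (apol)
#'
#' Sum over all atoms, including implicit hydrogens, of tabulated element
#' polarizabilities (cubic Angstroms). Additive over disjoint fragments.
#'
#' @inheritParams slogp
#' @return Positive numeric value.
#' @export
apol <- function(mol) {
  mol <- .as_mol(mol)
  missing_el <- setdiff(unique(mol$element), names(.POLARIZABILITY))
  if (length(missing_el) > 0) {
    stopf("no polarizability tabulated for element(s): %s",
          paste(missing_el, collapse = ", "))
  }
  sum(.POLARIZABILITY[mol$element]) + sum(mol$n_h) * .POLARIZABILITY[["H"]]
}

.obmol_from_smiles <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' MACCS structural keys (166 bits)
#'
#' @param mol A SMILES string or `mol_graph`.
#' @return Integer vector of length 166 with values in \{0, 1\}.
#' @export
maccs_fp <- function(mol) {
  smi <- if (inherits(mol, "mol_graph")) .mol_to_smiles(mol) else mol
  obmol <- .obmol_from_smiles(smi)
  fp <- ChemmineOB::fingerprint_OB(obmol, "MACCS")
  fp <- as.integer(if (is.matrix(fp)) fp[1, ] else fp)
  fp[1:166]
}

#' Morgan (ECFP-like) circular fingerprint
#'
#' Circular fingerprint of diameter `2 * radius` (default diameter 8), folded
#' to `nbits` bits by OR-ing the hash blocks.
#'
#' @param mol A SMILES string or `mol_graph`.
#' @param radius Neighbourhood radius (default 4, i.e. diameter 8).
#' @param nbits Folded width (default 1024).
#' @return Integer vector of length `nbits` with values in \{0, 1\}.
#' @export
morgan_fp <- function(mol, radius = 4, nbits = 1024) {
  stopifnot(radius %in% 1:5)
  smi <- if (inherits(mol, "mol_graph")) .mol_to_smiles(mol) else mol
  obmol <- .obmol_from_smiles(smi)
  fp <- ChemmineOB::fingerprint_OB(obmol, paste0("ECFP", 2 * radius))
  raw <- as.integer(if (is.matrix(fp)) fp[1, ] else fp)
  if (length(raw) %% nbits != 0) {
    stopf("cannot fold %d bits into %d", length(raw), nbits)
  }
  folded <- matrix(raw, nrow = nbits)
  as.integer(rowSums(folded) > 0)
}

.mol_to_smiles <- function(mol) {
  if (!is.null(mol$single_smiles)) return(mol$single_smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  ChemmineR::write.SDF(mol$sdf, tf)
  .to_can_smiles_sdf(paste(readLines(tf), collapse = "\n"))
}

#' Bemis-Murcko scaffold
#'
#' Extracts the molecular framework: ring systems plus the linkers
#' connecting them (the 2-core of the heavy-atom graph, obtained by
#' iteratively deleting terminal atoms), with atoms multiply bonded to the
#' framework retained (so a carbonyl oxygen on a ring survives, while a
#' dangling amide side chain is removed entirely). Acyclic molecules have
#' an empty scaffold, returned as `""`. The scaffold is canonicalized as
#' SMILES so it can serve directly as a cluster key.
#'
#' @inheritParams slogp
#' @return Canonical SMILES of the scaffold, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(mol) {
  mol <- .as_mol(mol)
  n <- length(mol$element)
  if (n == 0 || nrow(mol$bonds) == 0) return("")
  if (igraph::girth(mol$graph)$girth %in% c(0, Inf)) return("")

  # framework = 2-core: iteratively delete degree-1 atoms (any bond order)
  keep <- rep(TRUE, n)
  repeat {
    b <- mol$bonds[keep[mol$bonds$a1] & keep[mol$bonds$a2], , drop = FALSE]
    deg <- tabulate(c(b$a1, b$a2), nbins = n)
    prune <- which(keep & deg <= 1)
    if (length(prune) == 0) break
    keep[prune] <- FALSE
  }
  # re-attach atoms multiply bonded to the framework (exocyclic =O etc.)
  b <- mol$bonds
  add <- c(b$a2[keep[b$a1] & !keep[b$a2] & b$order >= 2],
           b$a1[!keep[b$a1] & keep[b$a2] & b$order >= 2])
  keep[unique(add)] <- TRUE
  idx <- sort(which(keep))
  if (length(idx) == 0) return("")
  sub_sdf <- ChemmineR::atomsubset(mol$sdf, idx)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  ChemmineR::write.SDF(sub_sdf, tf)
  out <- .to_can_smiles_sdf(paste(readLines(tf), collapse = "\n"))
  if (is.na(out)) "" else out
}

#' Compute the interpretable descriptor panel for a set of compounds
#'
#' @param entries List of standardized [compound_entry()] objects, or a
#'   character vector of SMILES.
#' @return A data.frame (class `descriptor_table`) with one row per compound
#'   (rownames = compound ids) and columns `a_aro`, `a_hyd`, `SlogP`,
#'   `vsa_acc`, `BalabanJ`, `a_donacc`, `weinerPath`, `apol`.
#' @export
compute_descriptors <- function(entries) {
  if (is.character(entries)) {
    ids <- names(entries) %||% paste0("cmp_", seq_along(entries))
    smis <- unname(entries)
  } else {
    ids <- vapply(entries, function(e) e$compound_id, character(1))
    smis <- vapply(entries, function(e) e$structure, character(1))
  }
  rows <- lapply(smis, function(s) {
    m <- mol_from_smiles(s)
    data.frame(
      a_aro = count_aromatic_atoms(m),
      a_hyd = count_hydrophobic_atoms(m),
      SlogP = slogp(m),
      vsa_acc = vsa_acc(m),
      BalabanJ = balaban_j(m),
      a_donacc = a_donacc(m),
      weinerPath = wiener_path(m),
      apol = apol(m)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- make.unique(ids)
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Write / read a descriptor table as TSV
#' @param x A descriptor table (data.frame with compound rownames).
#' @param path File path.
#' @return `read_descriptor_table` returns the table; the writer returns the
#'   path invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  df <- data.frame(compound = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rownames(df) <- df$compound
  df$compound <- NULL
  class(df) <- c("descriptor_table", "data.frame")
  df
}
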
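# Internal molecular graph built from a ChemmineR SDF object.
#
# OpenBabel (via ChemmineR/ChemmineOB) does all parsing and canonicalisation;
# this layer only re-expresses one molecule as plain R structures (element
# vector, bond table, igraph) so that graph descriptors and atom-typing rules
# can be computed and audited in R.

# V2000 atom-block charge codes -> formal charges.
.charge_from_code <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

# Lowest standard valences per element; used for implicit hydrogen counts.
.default_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

#' Build the internal molecular graph of one molecule
#'
#' @param sdf A single `SDF` object (ChemmineR).
#' @return An object of class `mol_graph`: a list with `element` (character
#'   per heavy atom), `charge` (formal charges), `aromatic` (logical per
#'   atom, perceived via [ChemmineR::rings()]), `bonds` (data.frame with
#'   `a1`, `a2`, `order`), `n_h` (implicit hydrogens per atom) and `graph`
#'   (an igraph of the heavy-atom skeleton).
#' @keywords internal
mol_graph <- function(sdf) {
  stopifnot(is(sdf, "SDF"))
  ab <- ChemmineR::atomblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  n <- length(element)
  charge <- if (ncol(ab) >= 5) .charge_from_code(ab[, 5]) else rep(0L, n)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb)) bb <- matrix(numeric(0), ncol = 3)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  if (ncol(bb) < 3) bb <- matrix(numeric(0), ncol = 3)  # bond-free molecule
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  bonds <- bonds[bonds$a1 > 0 & bonds$a2 > 0, , drop = FALSE]

  aromatic <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) NULL)
    if (!is.null(rng) && length(rng$RINGS) > 0) {
      arom_atoms <- unique(unlist(rng$RINGS[rng$AROMATIC]))
      idx <- as.integer(sub("^.*_", "", arom_atoms))
      aromatic[idx] <- TRUE
    }
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  }

  bond_sum <- rep(0L, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bond_sum[bonds$a1[k]] <- bond_sum[bonds$a1[k]] + bonds$order[k]
      bond_sum[bonds$a2[k]] <- bond_sum[bonds$a2[k]] + bonds$order[k]
    }
  }
  n_h <- vapply(seq_len(n), function(i) {
    vals <- .default_valences[[element[i]]]
    if (is.null(vals)) return(0L)
    # Charge shifts the usual valence (e.g. N+ -> 4, O- -> 1).
    adj <- if (element[i] %in% c("N", "O", "P", "S")) charge[i] else 0L
    vals <- vals + adj
    v <- vals[vals >= bond_sum[i]]
    if (length(v) == 0) return(0L)
    as.integer(min(v) - bond_sum[i])
  }, integer(1))

  structure(
    list(element = element, charge = charge, aromatic = aromatic,
         bonds = bonds, n_h = n_h, graph = g, sdf = sdf),
    class = "mol_graph"
  )
}

# Single-heavy-atom molecules (methane, water, halide ions ...) come back
# from the SDF reader as degenerate blocks; build their one-node graph
# directly from the SMILES token instead.
.single_atom_graph <- function(smiles) {
  m <- regmatches(smiles,
                  regexec("^\\[?([A-Z][a-z]?)(H([0-9]*))?(([+-])([0-9]*))?\\]?$",
                          smiles))[[1]]
  if (length(m) == 0) return(NULL)
  element <- m[2]
  if (!element %in% names(.default_valences) && !element %in% .METALS) {
    return(NULL)
  }
  charge <- 0L
  if (nzchar(m[6])) {
    mag <- if (nzchar(m[7])) as.integer(m[7]) else 1L
    charge <- if (m[6] == "-") -mag else mag
  }
  if (nzchar(m[3])) {
    n_h <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  } else {
    vals <- .default_valences[[element]] %||% 0L
    adj <- if (element %in% c("N", "O", "P", "S")) charge else 0L
    v <- vals + adj
    v <- v[v >= 0]
    n_h <- if (length(v) > 0) as.integer(min(v)) else 0L
  }
  structure(
    list(element = element, charge = charge, aromatic = FALSE,
         bonds = data.frame(a1 = integer(0), a2 = integer(0),
                            order = integer(0)),
         n_h = n_h, graph = igraph::make_empty_graph(n = 1, directed = FALSE),
         sdf = NULL, single_smiles = smiles),
    class = "mol_graph"
  )
}

#' @keywords internal
mol_from_smiles <- function(smiles) {
  single <- .single_atom_graph(smiles)
  if (!is.null(single)) return(single)
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (length(sdfset) == 0) stopf("SMILES '%s' could not be parsed", smiles)
  mol_graph(sdfset[[1]])
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d heavy atoms (%d aromatic), %d bonds\n",
              length(x$element), sum(x$aromatic), nrow(x$bonds)))
  invisible(x)
}

# Neighbour atom indices of atom i.
.neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# Connected components of the heavy-atom graph, largest first.
.fragments <- function(mol) {
  comp <- igraph::components(mol$graph)
  frags <- split(seq_along(mol$element), comp$membership)
  frags[order(vapply(frags, length, integer(1)), decreasing = TRUE)]
}
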
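#' Molecular graphs
#'
#' A `molgraph` is the package's internal molecule container: a heavy-atom
#' graph with implicit hydrogens stored as per-atom counts. Atoms carry
#' element symbol, formal charge, total hydrogen count, aromaticity and
#' ring-membership flags; bonds carry the kekule bond order (1, 2, 3) plus an
#' aromaticity flag, so matching can address both the aromatic and the kekule
#' form. Every `molgraph` produced by [standardize_pairs()] is indexed in
#' canonical-SMILES output order, so indices are reproducible from the stored
#' SMILES alone.
#'
#' Atom indices are 1-based inside R code; every user-facing table and file
#' (results CSV, SDF properties, fixture truth sets) uses 0-based indices.
#'
#' @param atoms Tibble with columns `element`, `charge`, `n_h`, `aromatic`,
#'   `in_ring`, `map`.
#' @param bonds Tibble with columns `i`, `j` (1-based atom indices), `order`,
#'   `aromatic`, `in_ring`.
#' @param inchikey InChI key of the standardized structure.
#' @param smiles Canonical SMILES whose atom order matches `atoms`.
#' @return An object of class `molgraph`.
#' @keywords internal
new_molgraph <- function(atoms, bonds, inchikey, smiles) {
  n <- nrow(atoms)
  adj <- matrix(0L, n, n)
  arom <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0) {
    idx <- cbind(bonds$i, bonds$j)
    adj[idx] <- bonds$order
    adj[idx[, 2:1, drop = FALSE]] <- bonds$order
    arom[idx] <- bonds$aromatic
    arom[idx[, 2:1, drop = FALSE]] <- bonds$aromatic
  }
  structure(
    list(
      atoms = atoms, bonds = bonds, n = n,
      adj = adj, arom = arom,
      inchikey = inchikey, smiles = smiles
    ),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(
    "<molgraph> ", x$smiles, "\n  ", x$n, " heavy atoms, ",
    nrow(x$bonds), " bonds, key ", x$inchikey, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) {
  paste0("<molgraph: ", x$smiles, ">")
}

n_atoms <- function(mol) mol$n

#' Neighbours of an atom (1-based indices)
#' @noRd
mg_neighbors <- function(mol, i) which(mol$adj[i, ] > 0L)

#' Bond order between two atoms, 0 when not bonded
#' @noRd
mg_order <- function(mol, i, j) mol$adj[i, j]

mg_is_aromatic_bond <- function(mol, i, j) mol$arom[i, j]

#' Element counts used by the routing and dehalogenation gates
#' @noRd
mg_element_counts <- function(mol) table(mol$atoms$element)

mg_count <- function(mol, elements) sum(mol$atoms$element %in% elements)

HALOGENS <- c("F", "Cl", "Br", "I")

#' Induced subgraph on a kept atom set, preserving original attributes
#' @noRd
mg_subgraph <- function(mol, keep) {
  keep <- sort(keep)
  relabel <- integer(mol$n)
  relabel[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  bonds$i <- relabel[bonds$i]
  bonds$j <- relabel[bonds$j]
  out <- new_molgraph(atoms, bonds, inchikey = NA_character_, smiles = NA_character_)
  out$orig_index <- keep
  out
}

#' Connected components as lists of 1-based atom index vectors
#' @noRd
mg_components <- function(mol) {
  g <- mg_igraph(mol)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) which(comp$membership == k))
}

#' Convert to an igraph object (vertex/edge attributes carried along)
#' @noRd
mg_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol$n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  g
}

#' Three-membered C-C-O rings (oxiranes), as rows (c1, c2, o)
#' @noRd
mg_oxiranes <- function(mol) {
  out <- list()
  os <- which(mol$atoms$element == "O")
  for (o in os) {
    nb <- mg_neighbors(mol, o)
    cs <- nb[mol$atoms$element[nb] == "C"]
    if (length(cs) < 2) next
    pairs <- utils::combn(cs, 2)
    for (k in seq_len(ncol(pairs))) {
      c1 <- pairs[1, k]
      c2 <- pairs[2, k]
      if (mol$adj[c1, c2] > 0L) out[[length(out) + 1L]] <- c(c1, c2, o)
    }
  }
  out
}

#' Does atom i carry a double-bonded oxygen (carbonyl-like)?
#' @noRd
mg_has_oxo <- function(mol, i) {
  nb <- mg_neighbors(mol, i)
  any(mol$atoms$element[nb] == "O" & mol$adj[i, nb] == 2L)
}

#' Sulfonyl-type sulfur: S bonded to at least two oxygens
#' @noRd
mg_is_sulfonyl <- function(mol, i) {
  if (mol$atoms$element[i] != "S") return(FALSE)
  nb <- mg_neighbors(mol, i)
  sum(mol$atoms$element[nb] == "O") >= 2
}
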
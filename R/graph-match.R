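#' Graph-matching primitives
#'
#' Shared machinery for all annotation handlers: subgraph monomorphism
#' between molecular graphs, maximum-common-substructure (MCS) atom-to-atom
#' mapping, and symmetry-orbit computation. Two matching regimes are used
#' throughout:
#'
#' * *bond-order-sensitive*: atoms must agree on element (and charge), bonds
#'   on kekule order, with aromatic bonds treated as their own bond class so
#'   that a kekulized ring still matches its aromatic counterpart;
#' * *relaxed*: atoms agree on element only and any bond matches any bond.
#'
#' An atom mapping is a partial injective map from substrate to metabolite
#' atoms under which every mapped substrate bond is present between the
#' image atoms (with order agreement when the sensitive regime is used).
#'
#' @name graph-match
#' @keywords internal
NULL

#' Throw a timeout condition when past the deadline
#' @noRd
check_deadline <- function(deadline) {
  if (is.finite(deadline) && as.numeric(Sys.time()) > deadline) {
    rlang::abort("annotation deadline exceeded", class = "somannot_timeout")
  }
  invisible(NULL)
}

vertex_colors <- function(a, b, use_charge) {
  ka <- a$atoms$element
  kb <- b$atoms$element
  if (use_charge) {
    ka <- paste(ka, a$atoms$charge)
    kb <- paste(kb, b$atoms$charge)
  }
  lev <- unique(c(ka, kb))
  list(a = match(ka, lev), b = match(kb, lev))
}

edge_colors <- function(mol, sensitive) {
  if (nrow(mol$bonds) == 0) return(integer(0))
  if (!sensitive) return(rep(1L, nrow(mol$bonds)))
  ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
}

#' Enumerate embeddings of one molecular graph into another
#'
#' Finds all monomorphisms of `small` into `large` (extra bonds in `large`
#' are permitted, including between image atoms). Matching is by element and
#' formal charge, plus bond order when `sensitive`.
#'
#' @param small,large `molgraph` objects.
#' @param sensitive Bond-order-sensitive matching?
#' @param use_charge Require formal-charge agreement on atoms?
#' @return List of integer vectors; element `k` of a vector is the `large`
#'   atom index matched to `small` atom `k`. Empty list when no embedding
#'   exists. Order is deterministic.
#' @export
find_embeddings <- function(small, large, sensitive = TRUE, use_charge = TRUE) {
  if (small$n > large$n || small$n == 0) return(list())
  vc <- vertex_colors(small, large, use_charge)
  maps <- igraph::subgraph_isomorphisms(
    mg_igraph(small), mg_igraph(large),
    method = "vf2",
    vertex.color1 = vc$b, vertex.color2 = vc$a,
    edge.color1 = edge_colors(large, sensitive),
    edge.color2 = edge_colors(small, sensitive)
  )
  maps <- lapply(maps, as.integer)
  maps[order(vapply(maps, paste, character(1), collapse = ","))]
}

#' Subgraph isomorphism test
#'
#' @inheritParams find_embeddings
#' @return List with `found` (logical) and `embeddings` (as
#'   [find_embeddings()]).
#' @export
is_subgraph <- function(small, large, sensitive = TRUE, use_charge = TRUE) {
  emb <- find_embeddings(small, large, sensitive, use_charge)
  list(found = length(emb) > 0, embeddings = emb)
}

#' Maximum-common-substructure atom mapping
#'
#' Computes maximum connected common substructures between substrate and
#' metabolite and returns them as atom mappings. When one molecule embeds
#' completely into the other the embeddings themselves are the MCS; otherwise
#' a branch-and-bound backtracking search enumerates maximum connected
#' mappings under the constraint that every mapped substrate bond exists
#' between the image atoms (with order agreement when `sensitive`).
#'
#' @param sub,met `molgraph` objects (substrate, metabolite).
#' @param sensitive Bond-order-sensitive matching?
#' @param use_charge Require formal-charge agreement?
#' @param deadline Absolute time (as [Sys.time()] numeric) after which the
#'   search aborts with a timeout condition; `Inf` disables.
#' @param max_maps Cap on the number of co-optimal mappings returned.
#' @return List of mappings; each is an integer vector of length
#'   `n_atoms(sub)` giving the metabolite atom index for each substrate atom,
#'   `NA` where unmapped. Empty list when no atoms can be mapped.
#' @export
mcs_mapping <- function(sub, met, sensitive = FALSE, use_charge = FALSE,
                        deadline = Inf, max_maps = 64L) {
  check_deadline(deadline)
  # fast path: complete containment one way or the other
  if (sub$n <= met$n) {
    emb <- find_embeddings(sub, met, sensitive, use_charge)
    if (length(emb) > 0) return(utils::head(emb, max_maps))
  }
  if (sub$n >= met$n) {
    emb <- find_embeddings(met, sub, sensitive, use_charge)
    if (length(emb) > 0) {
      return(utils::head(lapply(emb, function(e) {
        m <- rep(NA_integer_, sub$n)
        m[e] <- seq_len(met$n)
        m
      }), max_maps))
    }
  }
  mcs_search(sub, met, sensitive, use_charge, deadline, max_maps)
}

#' Branch-and-bound connected MCS search
#' @noRd
mcs_search <- function(sub, met, sensitive, use_charge, deadline, max_maps) {
  ns <- sub$n
  nm <- met$n
  vc <- vertex_colors(sub, met, use_charge)
  ecol_s <- if (sensitive) ifelse(sub$arom, 4L, sub$adj) else sign(sub$adj)
  ecol_m <- if (sensitive) ifelse(met$arom, 4L, met$adj) else sign(met$adj)
  compat <- outer(vc$a, vc$b, "==")
  if (!any(compat)) return(list())

  best_size <- 0L
  best_maps <- list()
  map <- rep(NA_integer_, ns) # sub -> met
  used <- rep(FALSE, nm)
  counter <- 0L

  record <- function(size) {
    if (size > best_size) {
      best_size <<- size
      best_maps <<- list(map)
    } else if (size == best_size && length(best_maps) < max_maps) {
      best_maps[[length(best_maps) + 1L]] <<- map
    }
  }

  extend <- function(size, frontier, forbidden) {
    counter <<- counter + 1L
    if (counter %% 256L == 0L) check_deadline(deadline)
    # bound: every remaining sub atom could in principle still be added
    if (size + sum(is.na(map) & !forbidden) < best_size) return(invisible())
    record(size)
    if (length(frontier) == 0) return(invisible())
    a <- frontier[1]
    rest <- frontier[-1]
    # branch 1: leave a unmapped for this subtree
    forb2 <- forbidden
    forb2[a] <- TRUE
    # candidates b for a: compatible, unused, consistent with mapped neighbours
    mapped_idx <- which(!is.na(map))
    for (b in which(compat[a, ] & !used)) {
      ok <- TRUE
      adjacent <- FALSE
      for (u in mapped_idx) {
        o <- ecol_s[a, u]
        if (o > 0L) {
          if (ecol_m[b, map[u]] != o) {
            ok <- FALSE
            break
          }
          adjacent <- TRUE
        }
      }
      if (!ok || (!adjacent && size > 0L)) next
      map[a] <<- b
      used[b] <<- TRUE
      nbrs <- which(sub$adj[a, ] > 0L & is.na(map) & !forbidden)
      new_frontier <- union(rest, nbrs)
      extend(size + 1L, new_frontier[is.na(map[new_frontier]) & !forbidden[new_frontier]],
             forbidden)
      map[a] <<- NA_integer_
      used[b] <<- FALSE
    }
    extend(size, rest, forb2)
    invisible()
  }

  for (seed in seq_len(ns)) {
    if (!any(compat[seed, ])) next
    if (ns - seed + 1L < best_size) break
    forbidden <- rep(FALSE, ns)
    if (seed > 1L) forbidden[seq_len(seed - 1L)] <- TRUE
    extend(0L, seed, forbidden)
  }
  if (best_size == 0L) return(list())
  keys <- vapply(best_maps, paste, character(1), collapse = ",")
  best_maps[!duplicated(keys)]
}

#' Topological-equivalence orbits of a molecule
#'
#' Partitions atoms into classes interchangeable under automorphisms of the
#' heavy-atom graph, with atoms distinguished by element, formal charge,
#' hydrogen count and aromaticity, and bonds by order (aromatic bonds as
#' their own class). Bond classes are honoured by running the automorphism
#' search on an edge-subdivided auxiliary graph, since the underlying
#' canonical-labelling engine colors vertices only.
#'
#' @param mol A `molgraph`.
#' @return Integer vector of orbit ids, one per atom.
#' @export
symmetry_orbits <- function(mol) {
  n <- mol$n
  if (n == 0) return(integer(0))
  atom_col <- as.integer(factor(paste(
    mol$atoms$element, mol$atoms$charge, mol$atoms$n_h, mol$atoms$aromatic
  )))
  m <- nrow(mol$bonds)
  edges <- integer(0)
  bond_col <- integer(0)
  if (m > 0) {
    for (k in seq_len(m)) {
      bv <- n + k
      edges <- c(edges, mol$bonds$i[k], bv, mol$bonds$j[k], bv)
    }
    bond_col <- max(atom_col) +
      ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
  }
  aux <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  if (length(edges) > 0) aux <- igraph::add_edges(aux, edges)
  gens <- igraph::automorphism_group(aux, colors = c(atom_col, bond_col))

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (g in gens) {
    p <- as.integer(g)
    for (i in seq_len(n)) {
      ri <- find(i)
      rj <- find(p[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Expand a SOM set to full symmetry orbits
#'
#' Returns the union of the topological-equivalence orbits intersecting
#' `soms`; a superset of the input, and idempotent.
#'
#' @param mol A `molgraph`.
#' @param soms Integer vector of 1-based atom indices.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
symmetry_expand <- function(mol, soms) {
  if (length(soms) == 0) return(integer(0))
  stopifnot(all(soms >= 1 & soms <= mol$n))
  orb <- symmetry_orbits(mol)
  sort(which(orb %in% orb[soms]))
}
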
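# Independent brute-force oracles, deliberately written against different
# machinery than the implementation they check.

oracle_edge_color <- function(mol, i, j, sensitive) {
  if (!sensitive) return(sign(mol$adj[i, j]))
  if (mol$arom[i, j]) 4L else mol$adj[i, j]
}

# exhaustive monomorphism enumeration by plain backtracking
brute_embeddings <- function(small, large, sensitive = TRUE, use_charge = TRUE) {
  key_s <- paste(small$atoms$element, if (use_charge) small$atoms$charge else 0)
  key_l <- paste(large$atoms$element, if (use_charge) large$atoms$charge else 0)
  out <- list()
  assign_next <- function(map, used) {
    i <- length(map) + 1L
    if (i > small$n) {
      out[[length(out) + 1L]] <<- map
      return(invisible())
    }
    for (j in seq_len(large$n)) {
      if (used[j] || key_s[i] != key_l[j]) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        cs <- oracle_edge_color(small, i, k, sensitive)
        if (cs > 0L && oracle_edge_color(large, j, map[k], sensitive) != cs) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        used[j] <- TRUE
        assign_next(c(map, j), used)
        used[j] <- FALSE
      }
    }
  }
  assign_next(integer(0), rep(FALSE, large$n))
  out
}

# maximum connected common substructure size via maximal cliques of the
# modular product graph (igraph::max_cliques), connectivity filtered on the
# substrate side
brute_mcs_size <- function(sub, met, sensitive = FALSE, use_charge = FALSE) {
  key_s <- paste(sub$atoms$element, if (use_charge) sub$atoms$charge else 0)
  key_m <- paste(met$atoms$element, if (use_charge) met$atoms$charge else 0)
  pairs <- which(outer(key_s, key_m, "=="), arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0) return(0L)
  edges <- integer(0)
  for (a in seq_len(np - 1L)) {
    for (b in seq((a + 1L), np)) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i == k || j == l) next
      cs <- oracle_edge_color(sub, i, k, sensitive)
      cm <- oracle_edge_color(met, j, l, sensitive)
      if (cs > 0L && cm != cs) next # substrate bonds must carry over
      edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(np, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  best <- 0L
  for (cl in igraph::max_cliques(g)) {
    satoms <- pairs[as.integer(cl), 1]
    gs <- igraph::induced_subgraph(
      igraph::graph_from_adjacency_matrix(sign(sub$adj), mode = "undirected"),
      satoms
    )
    comp <- igraph::components(gs)
    best <- max(best, max(comp$csize))
  }
  best
}

# automorphism orbits by exhaustive color/bond-preserving permutation search
brute_orbits <- function(mol) {
  n <- mol$n
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$n_h,
               mol$atoms$aromatic)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  recurse <- function(map, used) {
    i <- length(map) + 1L
    if (i > n) {
      for (k in seq_len(n)) link(k, map[k])
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (used[j] || key[i] != key[j]) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (oracle_edge_color(mol, i, k, TRUE) !=
            oracle_edge_color(mol, j, map[k], TRUE)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        used[j] <- TRUE
        recurse(c(map, j), used)
        used[j] <- FALSE
      }
    }
  }
  recurse(integer(0), rep(FALSE, n))
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# relabel atoms of a molgraph by a permutation (perm[old] = new index)
permute_molgraph <- function(mol, perm) {
  inv <- match(seq_len(mol$n), perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  bonds <- mol$bonds
  bonds$i <- perm[bonds$i]
  bonds$j <- perm[bonds$j]
  somannot:::new_molgraph(atoms, bonds, mol$inchikey, mol$smiles)
}
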
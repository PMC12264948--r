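#' Elimination-reaction handler
#'
#' Covers transformations in which the metabolite loses heavy atoms and is
#' completely contained in the substrate graph: dealkylations, deacylations,
#' reductive dehalogenation, reductions at heteroatoms. A
#' bond-order-sensitive embedding of the metabolite into the substrate
#' defines the atom mapping; each boundary bond between a mapped and an
#' unmapped substrate atom yields one SOM:
#'
#' * type 1 -- the unmapped atom is a carbon: the carbon is the SOM
#'   (dealkylation convention: the label goes on the removed alpha-carbon);
#' * type 2 -- the unmapped atom is a heteroatom: the mapped neighbour is
#'   the SOM (reductive dehalogenation, heteroatom reductions).
#'
#' Specialized corrections then reassign SOMs for (thio)ester hydrolysis
#' (carbonyl carbon) and hydrolysis of esters of inorganic acids
#' (phosphorus/sulfur center).
#'
#' @name rules-elimination
#' @keywords internal
NULL

#' Annotate a general elimination reaction
#'
#' @inheritParams annotate_glutathione
#' @return Annotation (with the boundary bonds recorded for the correction
#'   step) or `NULL` when the metabolite does not embed into the substrate.
#' @export
annotate_general_elimination <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  if (met$n >= sub$n) return(NULL)
  check_deadline(deadline)
  embs <- find_embeddings(met, sub, sensitive = TRUE, use_charge = TRUE)
  if (length(embs) == 0) return(NULL)

  boundary_soms <- function(emb) {
    image <- emb # substrate atoms covered by the metabolite
    bnd <- list()
    soms <- integer(0)
    for (u in image) {
      for (v in setdiff(mg_neighbors(sub, u), image)) {
        som <- if (sub$atoms$element[v] == "C") v else u
        soms <- c(soms, som)
        bnd[[length(bnd) + 1L]] <- c(mapped = u, unmapped = v, som = som)
      }
    }
    list(som = sort(unique(soms)), boundary = bnd)
  }

  res <- lapply(embs, boundary_soms)
  k <- best_by_som(embs, lapply(res, `[[`, "som"))
  new_annotation(res[[k]]$som, "general elimination",
    embedding = embs[[k]], boundary = res[[k]]$boundary
  )
}

#' Correct ester-type eliminations
#'
#' Reassigns SOMs when the cleaved boundary bond belongs to an ester-type
#' linkage. For (thio)esters the SOM becomes the carbonyl carbon; for esters
#' of inorganic acids (phosphates, thiophosphates, sulfates, sulfonates,
#' sulfamates, sulfonamides) it becomes the phosphorus or sulfur center.
#' Boundary bonds outside such linkages are left untouched.
#'
#' @inheritParams annotate_glutathione
#' @param annotation Annotation from [annotate_general_elimination()].
#' @param enabled Character vector of enabled correction rule labels.
#' @return The (possibly adjusted) annotation.
#' @export
ester_corrections <- function(pair, annotation,
                              enabled = c(
                                "(thio)ester hydrolysis",
                                "inorganic acid ester hydrolysis"
                              )) {
  if (is.null(annotation) || annotation$rule != "general elimination" ||
      length(annotation$boundary) == 0) {
    return(annotation)
  }
  sub <- pair$substrate_mol
  som <- annotation$som
  labels <- character(0)

  inorganic_center <- function(atom) {
    # a bridging O or N singly bonded to phosphorus or a sulfonyl-type sulfur
    nb <- mg_neighbors(sub, atom)
    if (length(nb) < 2) return(NA_integer_)
    hit <- nb[(sub$atoms$element[nb] == "P" |
                 vapply(nb, function(x) mg_is_sulfonyl(sub, x), logical(1))) &
                sub$adj[atom, nb] == 1L]
    if (length(hit) > 0) hit[1] else NA_integer_
  }

  for (b in annotation$boundary) {
    m <- b[["mapped"]]
    u <- b[["unmapped"]]
    raw <- b[["som"]]
    ends <- c(m, u)
    el <- sub$atoms$element[ends]

    # ester of an inorganic acid: the cleaved bond is O/N--(P|sulfonyl-S),
    # or O/N--C where the O/N also carries the P/S center
    center <- NA_integer_
    if (any(el %in% c("P", "S")) && any(el %in% c("O", "N")) &&
        mg_order(sub, m, u) == 1L) {
      x <- ends[el %in% c("P", "S")][1]
      bridge <- ends[el %in% c("O", "N")][1]
      # the O/N must bridge two heavy atoms (an ester/amide linkage, not a
      # terminal oxo/hydroxy of the acid group itself)
      if (length(mg_neighbors(sub, bridge)) >= 2 &&
          (sub$atoms$element[x] == "P" || mg_is_sulfonyl(sub, x))) {
        center <- x
      }
    }
    if (is.na(center)) {
      for (e in ends[el %in% c("O", "N")]) {
        center <- inorganic_center(e)
        if (!is.na(center)) break
      }
    }
    if (!is.na(center) && "inorganic acid ester hydrolysis" %in% enabled) {
      som <- setdiff(som, raw)
      som <- union(som, center)
      labels <- c(labels, "inorganic acid ester hydrolysis")
      next
    }

    # (thio)ester: boundary O/S single-bonded between an alkyl and a
    # carbonyl carbon (either half may be the metabolite)
    if (!"(thio)ester hydrolysis" %in% enabled) next
    link <- if (sub$atoms$element[m] %in% c("O", "S")) m
            else if (sub$atoms$element[u] %in% c("O", "S")) u
            else NA_integer_
    if (is.na(link)) next
    other <- setdiff(ends, link)
    if (sub$atoms$element[other] != "C") next
    if (mg_order(sub, link, other) != 1L) next
    if (mg_has_oxo(sub, other)) {
      # acyl side removed: the raw type-1 SOM already is the carbonyl carbon
      labels <- c(labels, "(thio)ester hydrolysis")
    } else {
      nb <- setdiff(mg_neighbors(sub, link), other)
      acyl <- nb[sub$atoms$element[nb] == "C" &
                   vapply(nb, function(c) mg_has_oxo(sub, c), logical(1)) &
                   sub$adj[link, nb] == 1L]
      if (length(acyl) == 0) next
      som <- setdiff(som, raw)
      som <- union(som, acyl[1])
      labels <- c(labels, "(thio)ester hydrolysis")
    }
  }

  if (length(labels) == 0) return(annotation)
  rule <- if ("inorganic acid ester hydrolysis" %in% labels) {
    "inorganic acid ester hydrolysis"
  } else {
    "(thio)ester hydrolysis"
  }
  new_annotation(som, rule,
    embedding = annotation$embedding, boundary = annotation$boundary
  )
}
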
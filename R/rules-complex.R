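#' Complex-reaction handler
#'
#' Annotates transformations that are neither pure additions nor pure
#' eliminations: redox reactions, halogen/oxygen exchanges, and ring
#' openings. The handler tries, in order: oxidative dehalogenation
#' (carbon count retained, halogen lost, oxygen gained), a complete atom
#' mapping by subgraph isomorphism (bond orders ignored; SOMs where the
#' hydrogen count or formal charge changed), and an MCS mapping (SOMs at
#' atoms undergoing topological changes). Ring-hydrolysis corrections then
#' reassign SOMs for oxacyclopropane, lactone, and other heterocyclic ring
#' openings.
#'
#' @name rules-complex
#' @keywords internal
NULL

#' Annotate an oxidative dehalogenation
#'
#' Fires only when substrate and metabolite retain the same number of
#' carbons while a halogen is lost and an oxygen gained. In the general
#' variant (halogen replaced by hydroxyl) the SOM is the carbon previously
#' bonded to the halogen; in the epoxide-forming variant both carbons of
#' the newly formed oxirane ring are SOMs.
#'
#' @inheritParams annotate_glutathione
#' @return Annotation or `NULL` when the element-balance gate fails.
#' @export
annotate_oxidative_dehalogenation <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  if (mg_count(sub, "C") != mg_count(met, "C")) return(NULL)
  if (mg_count(sub, HALOGENS) <= mg_count(met, HALOGENS)) return(NULL)
  if (mg_count(sub, "O") >= mg_count(met, "O")) return(NULL)
  check_deadline(deadline)
  maps <- mcs_mapping(sub, met, sensitive = FALSE, use_charge = FALSE,
                      deadline = deadline)
  if (length(maps) == 0) return(NULL)

  met_oxiranes <- mg_oxiranes(met)
  epoxide_forming <- length(met_oxiranes) > 0 && length(mg_oxiranes(sub)) == 0

  som_for <- function(f) {
    if (epoxide_forming) {
      soms <- integer(0)
      for (ring in met_oxiranes) {
        pre <- match(ring[1:2], f)
        if (!anyNA(pre)) soms <- c(soms, pre)
      }
      return(sort(unique(soms)))
    }
    mapped <- which(!is.na(f))
    soms <- integer(0)
    for (u in mapped) {
      nb <- mg_neighbors(sub, u)
      lost_hal <- nb[sub$atoms$element[nb] %in% HALOGENS & is.na(f[nb])]
      if (sub$atoms$element[u] == "C" && length(lost_hal) > 0) soms <- c(soms, u)
    }
    sort(unique(soms))
  }

  som_sets <- lapply(maps, som_for)
  nonempty <- which(lengths(som_sets) > 0)
  if (length(nonempty) == 0) return(NULL)
  k <- nonempty[best_by_som(maps[nonempty], som_sets[nonempty])]
  new_annotation(som_sets[[k]], "oxidative dehalogenation", mapping = maps[[k]])
}

#' Annotate via a complete subgraph-isomorphism mapping
#'
#' When substrate and metabolite have the same heavy-atom count and a
#' complete atom mapping exists on element and connectivity alone (bond
#' orders ignored), SOMs are the atoms whose total hydrogen count or formal
#' charge changed -- the signature of (de)hydrogenations and other redox
#' reactions that leave the skeleton intact.
#'
#' @inheritParams annotate_glutathione
#' @return Annotation or `NULL` when no complete mapping exists.
#' @export
annotate_by_full_isomorphism <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  if (sub$n != met$n) return(NULL)
  check_deadline(deadline)
  isos <- find_embeddings(sub, met, sensitive = FALSE, use_charge = FALSE)
  if (length(isos) == 0) {
    # a ring-opened metabolite embeds the other way around
    rev <- find_embeddings(met, sub, sensitive = FALSE, use_charge = FALSE)
    isos <- lapply(rev, function(e) match(seq_len(sub$n), e))
  }
  if (length(isos) == 0) return(NULL)
  som_sets <- lapply(isos, function(f) {
    which(sub$atoms$n_h != met$atoms$n_h[f] |
            sub$atoms$charge != met$atoms$charge[f])
  })
  k <- best_by_som(isos, som_sets)
  if (length(som_sets[[k]]) == 0) return(NULL)
  new_annotation(som_sets[[k]], "subgraph isomorphism mapping", mapping = isos[[k]])
}

#' Annotate via MCS mapping and topological differences
#'
#' Applied when no complete mapping exists. A relaxed (element-only) MCS
#' mapping is computed; SOMs are (i) mapped substrate atoms whose image
#' acquires a neighbour or bond outside the mapped substructure, (ii) mapped
#' carbons whose hydrogen count or whose incident non-aromatic bond orders
#' changed, and (iii) unmapped substrate atoms adjacent to mapped ones.
#' Hydrogen-count or bond-order changes alone never flag heteroatoms, so
#' spectator hydroxyls and the oxygens of e.g. quinone formation stay
#' unlabeled; the reaction is recorded on the carbon skeleton where it
#' initiates.
#'
#' @inheritParams annotate_glutathione
#' @return Annotation or `NULL` when no atoms can be mapped.
#' @export
annotate_by_mcs_diff <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  check_deadline(deadline)
  maps <- mcs_mapping(sub, met, sensitive = FALSE, use_charge = FALSE,
                      deadline = deadline)
  if (length(maps) == 0) return(NULL)

  som_for <- function(f) {
    mapped <- which(!is.na(f))
    image <- f[mapped]
    soms <- integer(0)
    for (u in mapped) {
      x <- f[u]
      is_c <- sub$atoms$element[u] == "C"
      new_nbr <- length(setdiff(mg_neighbors(met, x), image)) > 0
      new_bond <- FALSE
      order_chg <- FALSE
      for (v in mapped) {
        if (v == u) next
        os <- mg_order(sub, u, v)
        om <- mg_order(met, x, f[v])
        if (os == 0L && om > 0L) new_bond <- TRUE
        if (os > 0L && om > 0L && os != om &&
            !mg_is_aromatic_bond(sub, u, v) && !mg_is_aromatic_bond(met, x, f[v])) {
          order_chg <- TRUE
        }
      }
      h_chg <- is_c && sub$atoms$n_h[u] != met$atoms$n_h[x]
      if (new_nbr || new_bond || (is_c && order_chg) || h_chg) soms <- c(soms, u)
    }
    lost <- which(is.na(f))
    lost <- lost[vapply(lost, function(u) any(!is.na(f[mg_neighbors(sub, u)])),
                        logical(1))]
    sort(unique(c(soms, lost)))
  }

  som_sets <- lapply(maps, som_for)
  nonempty <- which(lengths(som_sets) > 0)
  if (length(nonempty) == 0) return(NULL)
  k <- nonempty[best_by_som(maps[nonempty], som_sets[nonempty])]
  new_annotation(som_sets[[k]], "MCS mapping", mapping = maps[[k]])
}

RING_RULES <- c(
  "oxacyclopropane hydrolysis", "lactone hydrolysis",
  "other heterocyclic ring hydrolysis"
)

#' Correct ring-hydrolysis annotations
#'
#' Inspects the atom mapping of a complex-handler annotation for substrate
#' ring bonds to a heteroatom that are no longer present between the image
#' atoms. Matching openings are reassigned: oxacyclopropane (epoxide)
#' hydrolysis puts the SOMs on both ring carbons, lactone hydrolysis on the
#' carbonyl carbon, and other heterocyclic ring openings on the carbon side
#' of the cleaved carbon-heteroatom bond (preferring an acyl carbon when one
#' is present, as in lactams).
#'
#' @inheritParams annotate_glutathione
#' @param annotation Annotation from the complex handler.
#' @param enabled Character vector of enabled correction rule labels.
#' @return The (possibly adjusted) annotation.
#' @export
ring_hydrolysis_corrections <- function(pair, annotation, enabled = RING_RULES) {
  if (is.null(annotation) || is.null(annotation$mapping) ||
      !annotation$rule %in% c("subgraph isomorphism mapping", "MCS mapping")) {
    return(annotation)
  }
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  f <- annotation$mapping

  broken <- function(i, j) {
    is.na(f[i]) || is.na(f[j]) || mg_order(met, f[i], f[j]) == 0L
  }

  # oxacyclopropane: a substrate 3-ring C-C-O with a broken C-O bond
  if ("oxacyclopropane hydrolysis" %in% enabled) {
    for (ring in mg_oxiranes(sub)) {
      c1 <- ring[1]; c2 <- ring[2]; o <- ring[3]
      if (broken(c1, o) || broken(c2, o)) {
        return(new_annotation(c(c1, c2), "oxacyclopropane hydrolysis",
                              mapping = f))
      }
    }
  }

  ring_bonds <- sub$bonds[sub$bonds$in_ring, , drop = FALSE]

  # lactone: ring ester linkage C(=O)-O(ring)-C with a broken ring C-O bond
  if ("lactone hydrolysis" %in% enabled && nrow(ring_bonds) > 0) {
    for (k in seq_len(nrow(ring_bonds))) {
      i <- ring_bonds$i[k]; j <- ring_bonds$j[k]
      els <- sub$atoms$element[c(i, j)]
      if (!("O" %in% els && "C" %in% els)) next
      o <- c(i, j)[els == "O"][1]
      if (!broken(i, j)) next
      acyl <- mg_neighbors(sub, o)
      acyl <- acyl[sub$atoms$element[acyl] == "C" & sub$atoms$in_ring[acyl] &
                     vapply(acyl, function(c) mg_has_oxo(sub, c), logical(1))]
      if (length(acyl) > 0) {
        return(new_annotation(acyl[1], "lactone hydrolysis", mapping = f))
      }
    }
  }

  # other heterocyclic ring opening: broken ring C-X (X = N, O, S)
  if ("other heterocyclic ring hydrolysis" %in% enabled && nrow(ring_bonds) > 0) {
    carbons <- integer(0)
    for (k in seq_len(nrow(ring_bonds))) {
      i <- ring_bonds$i[k]; j <- ring_bonds$j[k]
      els <- sub$atoms$element[c(i, j)]
      if (!("C" %in% els && any(els %in% c("N", "O", "S")) )) next
      if (!broken(i, j)) next
      carbons <- c(carbons, c(i, j)[els == "C"][1])
    }
    carbons <- unique(carbons)
    if (length(carbons) > 0) {
      acyl <- carbons[vapply(carbons, function(c) mg_has_oxo(sub, c), logical(1))]
      som <- if (length(acyl) > 0) acyl else carbons
      return(new_annotation(som, "other heterocyclic ring hydrolysis", mapping = f))
    }
  }

  annotation
}
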
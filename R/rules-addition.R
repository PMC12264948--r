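#' Addition-reaction handler
#'
#' Covers transformations in which the metabolite gains heavy atoms and
#' contains the complete substrate graph: hydroxylations, oxidations at
#' heteroatoms, and phase-II conjugations. The handler first screens for
#' glutathione conjugation (whose Michael-type chemistry breaks
#' bond-order-sensitive containment), then attempts general addition via a
#' bond-order-sensitive embedding of the substrate into the metabolite, and
#' finally corrects carnitine conjugations, where the nucleophile belongs to
#' the cofactor rather than the substrate.
#'
#' @name rules-addition
#' @keywords internal
NULL

# gamma-Glu-Cys-Gly with the cysteine sulfur tagged (map 1)
GSH_SMILES <- "NC(CCC(=O)NC(C[SH:1])C(=O)NCC(=O)O)C(=O)O"
# carnitine with its esterifiable hydroxyl oxygen tagged (map 1)
CARNITINE_SMILES <- "C[N+](C)(C)CC(CC(=O)[O-])[OH:1]"

pattern_mol <- function(smiles) {
  chem_standardize_cached(smiles)[[1]]
}

new_annotation <- function(som, rule, embedding = NULL, boundary = NULL,
                           mapping = NULL) {
  list(
    som = sort(unique(as.integer(som))), rule = rule,
    embedding = embedding, boundary = boundary, mapping = mapping
  )
}

#' Annotate a glutathione conjugation
#'
#' Detects a glutathione tripeptide moiety in the metabolite (absent from
#' the substrate) attached through its cysteine sulfur, removes the matched
#' tripeptide, embeds the remaining metabolite fragment back into the
#' substrate, and places the SOM on the substrate atom corresponding to the
#' atom bonded to the glutathione sulfur.
#'
#' @param pair One accepted row of [standardize_pairs()] output, as a list
#'   with elements `substrate_mol` and `metabolite_mol`.
#' @param deadline Optional absolute deadline (numeric epoch seconds).
#' @return An annotation list (`som`, `rule`, ...) or `NULL` when the
#'   pattern does not apply.
#' @export
annotate_glutathione <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  if (met$n <= sub$n) return(NULL)
  gsh <- pattern_mol(GSH_SMILES)
  if (gsh$n > met$n) return(NULL)
  check_deadline(deadline)
  if (length(find_embeddings(gsh, sub, sensitive = FALSE, use_charge = FALSE)) > 0) {
    return(NULL) # substrate itself carries the moiety; not a conjugation
  }
  embs <- find_embeddings(gsh, met, sensitive = FALSE, use_charge = FALSE)
  s_pat <- which(gsh$atoms$map == 1L)
  for (emb in embs) {
    check_deadline(deadline)
    s_met <- emb[s_pat]
    attach_met <- setdiff(mg_neighbors(met, s_met), emb)
    if (length(attach_met) == 0) next
    remainder <- setdiff(seq_len(met$n), emb)
    frag_all <- mg_subgraph(met, remainder)
    for (att in attach_met) {
      comp <- mg_components(frag_all)
      local_att <- match(att, frag_all$orig_index)
      comp_atoms <- comp[[which(vapply(comp, function(cc) local_att %in% cc, logical(1)))]]
      frag <- mg_subgraph(frag_all, comp_atoms)
      fe <- find_embeddings(frag, sub, sensitive = FALSE, use_charge = FALSE)
      if (length(fe) == 0) next
      att_frag <- match(match(att, frag_all$orig_index), frag$orig_index)
      # prefer the embedding whose hydrogen counts fit best: it places the
      # attachment atom on the substrate atom that actually lost a
      # substituent or hydrogen (e.g. the ipso carbon of an aryl halide)
      score <- vapply(fe, function(e) {
        sum(abs(frag$atoms$n_h - sub$atoms$n_h[e]))
      }, numeric(1))
      best <- fe[[which.min(score)]]
      return(new_annotation(best[att_frag], "glutathione conjugation"))
    }
  }
  NULL
}

som_for_embedding <- function(sub, met, emb) {
  image <- emb
  soms <- integer(0)
  for (a in seq_len(sub$n)) {
    out_nbrs <- setdiff(mg_neighbors(met, emb[a]), image)
    if (length(out_nbrs) > 0) soms <- c(soms, a)
  }
  soms
}

#' Pick the embedding minimizing the SOM count, then the lowest index set
#' @noRd
best_by_som <- function(embs, som_sets) {
  sizes <- lengths(som_sets)
  cand <- which(sizes == min(sizes))
  keys <- vapply(som_sets[cand], function(s) paste(sprintf("%06d", s), collapse = ","),
                 character(1))
  cand[order(keys)][1]
}

#' Annotate a general addition reaction
#'
#' Requires a bond-order-sensitive embedding of the substrate into the
#' heavier metabolite; SOMs are the substrate atoms whose image acquires at
#' least one neighbour outside the embedded image.
#'
#' @inheritParams annotate_glutathione
#' @return Annotation or `NULL` when the substrate does not embed.
#' @export
annotate_general_addition <- function(pair, deadline = Inf) {
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  if (met$n <= sub$n) return(NULL)
  check_deadline(deadline)
  embs <- find_embeddings(sub, met, sensitive = TRUE, use_charge = TRUE)
  if (length(embs) == 0) return(NULL)
  som_sets <- lapply(embs, function(e) som_for_embedding(sub, met, e))
  k <- best_by_som(embs, som_sets)
  new_annotation(som_sets[[k]], "general addition", embedding = embs[[k]])
}

#' Correct a carnitine conjugation
#'
#' When a general-addition SOM sits on the sp3 oxygen of an ester whose
#' alcohol half is carnitine, the SOM is moved to the carboxyl carbon: in
#' carnitine conjugation the carnitine hydroxyl is the nucleophile, so the
#' reaction is initiated at the substrate's carbonyl carbon.
#'
#' @inheritParams annotate_glutathione
#' @param annotation Annotation returned by [annotate_general_addition()].
#' @return The (possibly adjusted) annotation.
#' @export
carnitine_correction <- function(pair, annotation, deadline = Inf) {
  if (is.null(annotation) || annotation$rule != "general addition") {
    return(annotation)
  }
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol
  carn <- pattern_mol(CARNITINE_SMILES)
  if (carn$n > met$n) return(annotation)
  check_deadline(deadline)
  embs <- find_embeddings(carn, met, sensitive = FALSE, use_charge = FALSE)
  if (length(embs) == 0) return(annotation)
  o_pat <- which(carn$atoms$map == 1L)
  emb_sub <- annotation$embedding
  for (emb in embs) {
    o_met <- emb[o_pat]
    for (som in annotation$som) {
      if (sub$atoms$element[som] != "O") next
      if (emb_sub[som] != o_met) next
      # carboxyl carbon: substrate neighbour of the sp3 O bearing =O
      nb <- mg_neighbors(sub, som)
      cand <- nb[sub$atoms$element[nb] == "C" &
                   vapply(nb, function(c) mg_has_oxo(sub, c), logical(1))]
      if (length(cand) == 0) next
      return(new_annotation(cand[1], "carnitine conjugation"))
    }
  }
  annotation
}
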
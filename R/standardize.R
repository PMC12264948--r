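#' Allowed elements for annotation
#'
#' Substrate-metabolite pairs containing any atom outside this set are
#' rejected with reason `disallowed_element`; the gate keeps uncommon atom
#' types (metals, metalloids other than B/Si/Se) out of the rule engine.
#'
#' @return Character vector of element symbols.
#' @export
som_allowed_elements <- function() {
  c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")
}

REJECTION_REASONS <- c(
  "unparseable", "key_failure", "identical_pair", "disallowed_element"
)

#' Validate and standardize substrate-metabolite pairs
#'
#' The entry point of the preprocessing stage. Each row's SMILES pair is
#' parsed and standardized (largest organic parent fragment, normalization,
#' neutralization, canonical tautomer), and the pair is accepted only when
#' both molecules parse, yield InChI keys, contain only allowed elements,
#' and the two keys differ (identical keys mean no net transformation).
#' Rejections are data, not errors: a batch never aborts on a bad row, and
#' every row comes back with exactly one status.
#'
#' @param pairs Data frame with columns `substrate_smiles`, `substrate_id`,
#'   `metabolite_smiles`, `metabolite_id`.
#' @param quiet Suppress the per-rejection log messages.
#' @return The input tibble plus list-columns `substrate_mol` and
#'   `metabolite_mol` (standardized [new_molgraph()] objects, `NULL` on
#'   rejection), a `status` column (`"accepted"`/`"rejected"`), and
#'   `rejection_reason` (`NA` when accepted).
#' @examples
#' \dontrun{
#' pairs <- tibble::tibble(
#'   substrate_smiles = "Nc1ccccc1", substrate_id = 1,
#'   metabolite_smiles = "Nc1ccccc1O", metabolite_id = 2
#' )
#' standardize_pairs(pairs)
#' }
#' @export
standardize_pairs <- function(pairs, quiet = FALSE) {
  required <- c(
    "substrate_smiles", "substrate_id", "metabolite_smiles", "metabolite_id"
  )
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "`pairs` lacks required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  pairs <- tibble::as_tibble(pairs)
  bad_field <- !nzchar(trimws(as.character(pairs$substrate_smiles))) |
    !nzchar(trimws(as.character(pairs$metabolite_smiles))) |
    is.na(pairs$substrate_smiles) | is.na(pairs$metabolite_smiles)

  all_smiles <- unique(c(pairs$substrate_smiles[!bad_field],
                         pairs$metabolite_smiles[!bad_field]))
  std <- chem_standardize(as.character(all_smiles))
  names(std) <- all_smiles

  n <- nrow(pairs)
  sub_mol <- vector("list", n)
  met_mol <- vector("list", n)
  reason <- rep(NA_character_, n)

  for (r in seq_len(n)) {
    if (bad_field[r]) {
      reason[r] <- "unparseable"
      next
    }
    s <- std[[as.character(pairs$substrate_smiles[r])]]
    m <- std[[as.character(pairs$metabolite_smiles[r])]]
    if (is.character(s)) {
      reason[r] <- s
      next
    }
    if (is.character(m)) {
      reason[r] <- m
      next
    }
    allowed <- som_allowed_elements()
    if (!all(s$atoms$element %in% allowed) || !all(m$atoms$element %in% allowed)) {
      reason[r] <- "disallowed_element"
      next
    }
    if (identical(s$inchikey, m$inchikey)) {
      reason[r] <- "identical_pair"
      next
    }
    sub_mol[[r]] <- s
    met_mol[[r]] <- m
  }

  if (!quiet) {
    for (r in which(!is.na(reason))) {
      message(sprintf(
        "rejected pair (substrate_id=%s, metabolite_id=%s): %s",
        pairs$substrate_id[r], pairs$metabolite_id[r], reason[r]
      ))
    }
  }

  dplyr::mutate(
    pairs,
    substrate_mol = sub_mol,
    metabolite_mol = met_mol,
    status = ifelse(is.na(reason), "accepted", "rejected"),
    rejection_reason = reason
  )
}

#' Standardize a single SMILES string
#'
#' Convenience wrapper around the batch standardizer; standardization is
#' idempotent, so feeding the returned canonical SMILES back reproduces the
#' same structure key and atom order.
#'
#' @param smiles One SMILES string.
#' @return A `molgraph`, or an error if the structure cannot be processed.
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  res <- chem_standardize(smiles)[[1]]
  if (is.character(res)) {
    rlang::abort(paste0("standardization failed: ", res))
  }
  res
}
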
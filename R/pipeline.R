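#' Annotation rule labels
#'
#' The twelve annotation rules, grouped into the three handler categories.
#' `som_rules()` returns all rule labels; `som_rule_category()` maps labels
#' to their category (`addition`, `elimination`, `complex`, or `other` for
#' the `unknown`/`timeout`/`invalid` statuses); `som_rule_order()` gives the
#' default ablation order, most frequently applied rule first.
#'
#' @return Character vectors (named, for `som_rule_category()`).
#' @export
som_rules <- function() {
  c(
    "general addition", "glutathione conjugation", "carnitine conjugation",
    "general elimination", "(thio)ester hydrolysis",
    "inorganic acid ester hydrolysis",
    "oxidative dehalogenation", "subgraph isomorphism mapping", "MCS mapping",
    "oxacyclopropane hydrolysis", "lactone hydrolysis",
    "other heterocyclic ring hydrolysis"
  )
}

#' @rdname som_rules
#' @param rule Character vector of rule labels (or statuses).
#' @export
som_rule_category <- function(rule) {
  map <- c(
    "general addition" = "addition",
    "glutathione conjugation" = "addition",
    "carnitine conjugation" = "addition",
    "general elimination" = "elimination",
    "(thio)ester hydrolysis" = "elimination",
    "inorganic acid ester hydrolysis" = "elimination",
    "oxidative dehalogenation" = "complex",
    "subgraph isomorphism mapping" = "complex",
    "MCS mapping" = "complex",
    "oxacyclopropane hydrolysis" = "complex",
    "lactone hydrolysis" = "complex",
    "other heterocyclic ring hydrolysis" = "complex"
  )
  out <- unname(map[rule])
  out[is.na(out)] <- "other"
  out
}

#' @rdname som_rules
#' @export
som_rule_order <- function() {
  c(
    "general addition", "MCS mapping", "general elimination",
    "subgraph isomorphism mapping", "glutathione conjugation",
    "(thio)ester hydrolysis", "other heterocyclic ring hydrolysis",
    "oxidative dehalogenation", "inorganic acid ester hydrolysis",
    "oxacyclopropane hydrolysis", "lactone hydrolysis",
    "carnitine conjugation"
  )
}

#' Annotation configuration
#'
#' @param timeout_seconds Per-reaction wall-clock limit for the annotation
#'   attempt (standardization excluded). Default 20 s.
#' @param rules Enabled rule labels; subset of [som_rules()].
#' @return A `som_config` list.
#' @export
som_config <- function(timeout_seconds = 20, rules = som_rules()) {
  stopifnot(timeout_seconds > 0, all(rules %in% som_rules()))
  structure(list(timeout_seconds = timeout_seconds, rules = rules),
            class = "som_config")
}

#' Annotate one standardized substrate-metabolite pair
#'
#' Routes the pair by heavy-atom balance: a heavier metabolite goes to the
#' addition handler, a lighter one to the elimination handler; equal counts,
#' or a handler finding no SOM, forward the pair to the complex handler.
#' Any SOM set found is expanded to full symmetry orbits. Exceeding the
#' timeout yields the `timeout` status with an empty SOM set.
#'
#' @param pair A list (or one-row tibble slice) with `substrate_mol` and
#'   `metabolite_mol` entries.
#' @param config A [som_config()].
#' @return List with `som` (1-based substrate atom indices), `rule`,
#'   `status` (`annotated`, `unknown` or `timeout`) and `elapsed_s`.
#' @export
annotate_pair <- function(pair, config = som_config()) {
  start <- as.numeric(Sys.time())
  deadline <- start + config$timeout_seconds
  enabled <- config$rules
  sub <- pair$substrate_mol
  met <- pair$metabolite_mol

  ann <- tryCatch(
    {
      check_deadline(deadline)
      ann <- NULL
      if (met$n > sub$n) {
        if ("glutathione conjugation" %in% enabled) {
          ann <- annotate_glutathione(pair, deadline)
        }
        if (is.null(ann) && "general addition" %in% enabled) {
          ann <- annotate_general_addition(pair, deadline)
          if (!is.null(ann) && "carnitine conjugation" %in% enabled) {
            ann <- carnitine_correction(pair, ann, deadline)
          }
        }
      } else if (met$n < sub$n) {
        if ("general elimination" %in% enabled) {
          ann <- annotate_general_elimination(pair, deadline)
          if (!is.null(ann)) {
            ann <- ester_corrections(pair, ann,
              enabled = intersect(enabled, c(
                "(thio)ester hydrolysis", "inorganic acid ester hydrolysis"
              ))
            )
          }
        }
      }
      if (is.null(ann)) {
        if ("oxidative dehalogenation" %in% enabled) {
          ann <- annotate_oxidative_dehalogenation(pair, deadline)
        }
        if (is.null(ann) && "subgraph isomorphism mapping" %in% enabled) {
          ann <- annotate_by_full_isomorphism(pair, deadline)
        }
        if (is.null(ann) && "MCS mapping" %in% enabled) {
          ann <- annotate_by_mcs_diff(pair, deadline)
        }
        if (!is.null(ann)) {
          ann <- ring_hydrolysis_corrections(pair, ann,
            enabled = intersect(enabled, RING_RULES)
          )
        }
      }
      ann
    },
    somannot_timeout = function(cnd) structure(list(), class = "som_timeout")
  )

  elapsed <- as.numeric(Sys.time()) - start
  if (inherits(ann, "som_timeout")) {
    return(list(som = integer(0), rule = "timeout", status = "timeout",
                elapsed_s = elapsed))
  }
  if (is.null(ann) || length(ann$som) == 0) {
    return(list(som = integer(0), rule = "unknown", status = "unknown",
                elapsed_s = elapsed))
  }
  som <- symmetry_expand(sub, ann$som)
  list(som = som, rule = ann$rule, status = "annotated",
       elapsed_s = as.numeric(Sys.time()) - start)
}

#' Annotate sites of metabolism for a table of reaction pairs
#'
#' The main user-facing entry point. Accepts either raw pairs (columns
#' `substrate_smiles`, `substrate_id`, `metabolite_smiles`, `metabolite_id`)
#' or the output of [standardize_pairs()]; raw input is standardized first.
#' Each accepted row is annotated independently; rejected rows are reported
#' with status `invalid` so row counts are conserved.
#'
#' @param pairs Data frame of reaction pairs (raw or standardized).
#' @param config A [som_config()].
#' @param quiet Suppress standardization log messages.
#' @return A tibble with one row per input row: `substrate_id`,
#'   `metabolite_id`, `som_indices` (list-column of 0-based substrate atom
#'   indices), `som` (space-separated 0-based indices), `rule`, `status`
#'   (`annotated`/`unknown`/`timeout`/`invalid`), `elapsed_s`, and the
#'   standardized `substrate_mol`/`metabolite_mol` list-columns.
#' @examples
#' \dontrun{
#' pairs <- tibble::tibble(
#'   substrate_smiles = "Nc1ccccc1", substrate_id = 1,
#'   metabolite_smiles = "Nc1ccccc1O", metabolite_id = 2
#' )
#' annotate_soms(pairs)
#' }
#' @export
annotate_soms <- function(pairs, config = som_config(), quiet = TRUE) {
  if (!"substrate_mol" %in% names(pairs)) {
    pairs <- standardize_pairs(pairs, quiet = quiet)
  }
  n <- nrow(pairs)
  som_list <- vector("list", n)
  rule <- character(n)
  status <- character(n)
  elapsed <- numeric(n)
  for (r in seq_len(n)) {
    if (!identical(pairs$status[r], "accepted")) {
      som_list[[r]] <- integer(0)
      rule[r] <- "invalid"
      status[r] <- "invalid"
      elapsed[r] <- 0
      next
    }
    res <- annotate_pair(
      list(
        substrate_mol = pairs$substrate_mol[[r]],
        metabolite_mol = pairs$metabolite_mol[[r]]
      ),
      config
    )
    som_list[[r]] <- res$som - 1L # exported indices are 0-based
    rule[r] <- res$rule
    status[r] <- res$status
    elapsed[r] <- res$elapsed_s
  }
  tibble::tibble(
    substrate_id = pairs$substrate_id,
    metabolite_id = pairs$metabolite_id,
    som_indices = som_list,
    som = vapply(som_list, paste, character(1), collapse = " "),
    rule = rule,
    status = status,
    elapsed_s = elapsed,
    substrate_mol = if ("substrate_mol" %in% names(pairs)) pairs$substrate_mol else list(NULL)[rep(1, n)],
    metabolite_mol = if ("metabolite_mol" %in% names(pairs)) pairs$metabolite_mol else list(NULL)[rep(1, n)]
  )
}
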
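#' Evaluation metrics for SOM annotations
#'
#' Predicted SOM sets are compared with ground truth per reaction and
#' binned into four mutually exclusive categories:
#'
#' * **full** -- predicted equals truth (no false positives or negatives);
#' * **partial** -- the sets overlap but differ;
#' * **neighbor** -- no true SOM was predicted, but a true SOM is directly
#'   bonded to a predicted atom;
#' * **none** -- anything else (including an empty prediction).
#'
#' Both sets are symmetry-orbit expanded before comparison, so annotations
#' of topologically equivalent atoms by different sources compare equal.
#'
#' @name evaluation
NULL

parse_som <- function(x) {
  if (is.list(x)) return(lapply(x, as.integer))
  lapply(strsplit(trimws(as.character(x)), "\\s+"), function(v) {
    as.integer(v[nzchar(v)])
  })
}

#' Categorize one prediction against ground truth
#'
#' @param predicted,truth Integer vectors of 0-based substrate atom indices.
#' @param mol The standardized substrate `molgraph`.
#' @param expand Orbit-expand both sets before comparison.
#' @return One of `"full"`, `"partial"`, `"neighbor"`, `"none"`.
#' @export
match_category <- function(predicted, truth, mol, expand = TRUE) {
  if (length(truth) == 0) rlang::abort("ground-truth SOM set must be non-empty")
  p <- sort(unique(as.integer(predicted))) + 1L
  t <- sort(unique(as.integer(truth))) + 1L
  stopifnot(all(t >= 1 & t <= mol$n), all(p >= 1 & p <= mol$n))
  if (expand) {
    t <- symmetry_expand(mol, t)
    if (length(p) > 0) p <- symmetry_expand(mol, p)
  }
  if (identical(p, t)) return("full")
  common <- intersect(p, t)
  if (length(common) > 0) return("partial")
  if (length(p) > 0 && any(mol$adj[t, p, drop = FALSE] > 0L)) return("neighbor")
  "none"
}

#' Score annotation results against ground truth
#'
#' Joins predictions and truth on `(substrate_id, metabolite_id)` and
#' assigns each reaction a match category.
#'
#' @param results Output of [annotate_soms()] (or a data frame with
#'   `substrate_id`, `metabolite_id`, a `som_indices` list-column or `som`
#'   string column, a `rule` column, and ideally the `substrate_mol`
#'   list-column).
#' @param truth Data frame with `substrate_id`, `metabolite_id` and a
#'   `truth_soms` list-column (or `som_indices` string column); when
#'   `results` lacks standardized substrates it must also carry
#'   `substrate_smiles`.
#' @param expand Orbit-expand both SOM sets before comparison.
#' @return The joined tibble with `match` (factor full/partial/neighbor/
#'   none) and `category` (addition/elimination/complex/other) columns.
#' @export
score_soms <- function(results, truth, expand = TRUE) {
  if (!"som_indices" %in% names(results)) {
    results$som_indices <- parse_som(results$som)
  }
  if (!"truth_soms" %in% names(truth)) {
    truth$truth_soms <- parse_som(truth$som_indices)
    truth$som_indices <- NULL
  }
  keep <- intersect(
    c("substrate_id", "metabolite_id", "truth_soms", "substrate_smiles",
      "transformation", "family"),
    names(truth)
  )
  scored <- dplyr::inner_join(results, truth[keep],
    by = c("substrate_id", "metabolite_id")
  )
  if (!"substrate_mol" %in% names(scored) ||
      any(vapply(scored$substrate_mol, is.null, logical(1)))) {
    if (!"substrate_smiles" %in% names(scored)) {
      rlang::abort("need substrate structures: supply `substrate_mol` or `substrate_smiles`")
    }
    scored$substrate_mol <- chem_standardize_cached(scored$substrate_smiles)
  }
  scored$match <- factor(
    vapply(seq_len(nrow(scored)), function(r) {
      if (scored$status[r] %in% c("timeout", "invalid")) return("none")
      match_category(
        scored$som_indices[[r]], scored$truth_soms[[r]],
        scored$substrate_mol[[r]], expand = expand
      )
    }, character(1)),
    levels = c("full", "partial", "neighbor", "none")
  )
  scored$category <- som_rule_category(scored$rule)
  scored
}

eval_row <- function(scored, label) {
  n <- nrow(scored)
  tibble::tibble(
    group = label,
    n_reactions = n,
    full_pct = 100 * mean(scored$match == "full"),
    partial_pct = 100 * mean(scored$match == "partial"),
    neighbor_pct = 100 * mean(scored$match == "neighbor")
  )
}

#' Aggregate match categories into an accuracy table
#'
#' Produces the per-rule-category (or per-rule) accuracy table: reaction
#' counts and full/partial/neighbor match percentages, each percentage
#' computed over that row's reaction count, plus an `All` row over every
#' scored reaction that passed the timeout filter.
#'
#' @param scored Output of [score_soms()].
#' @param by `"category"` for the three handler categories, `"rule"` for
#'   individual annotation rules.
#' @return A `som_eval` tibble with columns `group`, `n_reactions`,
#'   `full_pct`, `partial_pct`, `neighbor_pct`.
#' @export
som_match_table <- function(scored, by = c("category", "rule")) {
  by <- rlang::arg_match(by)
  scored <- scored[!scored$status %in% c("timeout", "invalid"), , drop = FALSE]
  key <- if (by == "category") scored$category else scored$rule
  groups <- if (by == "category") {
    intersect(c("addition", "elimination", "complex", "other"), unique(key))
  } else {
    intersect(c(som_rules(), "unknown"), unique(key))
  }
  rows <- dplyr::bind_rows(
    eval_row(scored, "All"),
    dplyr::bind_rows(lapply(groups, function(g) eval_row(scored[key == g, ], g)))
  )
  structure(rows, class = c("som_eval", class(rows)), by = by)
}

#' @export
print.som_eval <- function(x, ...) {
  cat("SOM annotation accuracy (by ", attr(x, "by"), ")\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy som_eval
#' @export
tidy.som_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("group", "n_reactions", "full_pct",
                                 "partial_pct", "neighbor_pct")])
}

#' @method glance som_eval
#' @export
glance.som_eval <- function(x, ...) {
  all_row <- tidy(x)[tidy(x)$group == "All", ]
  names(all_row)[names(all_row) == "group"] <- "scope"
  all_row
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot som_eval
#' @export
autoplot.som_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("full_pct", "partial_pct", "neighbor_pct"),
    names_to = "match", values_to = "pct"
  )
  long$match <- factor(
    sub("_pct$", "", long$match),
    levels = c("neighbor", "partial", "full")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$group, y = .data$pct, fill = .data$match
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "% of reactions", fill = "match",
      title = "SOM annotation accuracy"
    ) +
    ggplot2::theme_minimal()
}
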
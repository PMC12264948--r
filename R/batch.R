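#' Run the annotation pipeline over a CSV of reaction pairs
#'
#' Reads the pairs file, standardizes and annotates every row, and writes
#' four outputs to `out_dir`:
#'
#' * `results.csv` -- one row per input reaction: `substrate_id`,
#'   `metabolite_id`, `som_indices` (space-separated 0-based atom indices on
#'   the standardized substrate), `rule`, `status`, `elapsed_s`;
#' * `substrates.sdf` -- standardized substrates with `SOMS` and `RULE`
#'   properties;
#' * `metabolites.sdf` -- the corresponding standardized metabolites;
#' * `substrates_consolidated.sdf` -- each unique substrate (by InChI key)
#'   once, with the union of all its annotated SOMs.
#'
#' Atom indices in the SD files refer to the atom order of the structures
#' as written, which is the standardized canonical order the indices were
#' computed on. Every input row appears in exactly one output status.
#'
#' @param input Path to the input CSV (columns `substrate_smiles`,
#'   `substrate_id`, `metabolite_smiles`, `metabolite_id`).
#' @param out_dir Output directory, created if needed.
#' @param config A [som_config()].
#' @param quiet Suppress per-rejection messages.
#' @return Invisibly, a list with `results` (the annotation tibble) and
#'   `summary` (a tibble of row counts per status).
#' @export
run_batch <- function(input, out_dir, config = som_config(), quiet = FALSE) {
  if (!file.exists(input)) rlang::abort(paste0("input file not found: ", input))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- readr::read_csv(input, show_col_types = FALSE)
  std <- standardize_pairs(pairs, quiet = quiet)
  results <- annotate_soms(std, config = config)

  out <- dplyr::tibble(
    substrate_id = results$substrate_id,
    metabolite_id = results$metabolite_id,
    som_indices = results$som,
    rule = results$rule,
    status = results$status,
    elapsed_s = round(results$elapsed_s, 4)
  )
  readr::write_csv(out, file.path(out_dir, "results.csv"))

  acc <- which(std$status == "accepted")
  sub_records <- lapply(acc, function(r) {
    list(
      smiles = std$substrate_mol[[r]]$smiles,
      name = as.character(std$substrate_id[r]),
      props = list(SOMS = results$som[r], RULE = results$rule[r])
    )
  })
  met_records <- lapply(acc, function(r) {
    list(
      smiles = std$metabolite_mol[[r]]$smiles,
      name = as.character(std$metabolite_id[r]),
      props = list(RULE = results$rule[r])
    )
  })
  chem_write_sdf(sub_records, file.path(out_dir, "substrates.sdf"))
  chem_write_sdf(met_records, file.path(out_dir, "metabolites.sdf"))

  # consolidated: one entry per unique substrate, SOMs unioned
  keys <- vapply(std$substrate_mol[acc], function(m) m$inchikey, character(1))
  cons <- lapply(unique(keys), function(k) {
    rows <- acc[keys == k]
    soms <- sort(unique(unlist(results$som_indices[rows])))
    list(
      smiles = std$substrate_mol[[rows[1]]]$smiles,
      name = as.character(std$substrate_id[rows[1]]),
      props = list(
        SOMS = paste(soms, collapse = " "),
        INCHIKEY = k,
        RULES = paste(sort(unique(results$rule[rows])), collapse = "; ")
      )
    )
  })
  chem_write_sdf(cons, file.path(out_dir, "substrates_consolidated.sdf"))

  summary <- dplyr::count(out, .data$status, name = "n_reactions")
  invisible(list(results = results, summary = summary))
}

#' Ablation study over the annotation rule set
#'
#' Re-annotates a corpus with growing rule prefixes (most frequently applied
#' rule first, per [som_rule_order()]) and reports, for each prefix length,
#' the coverage (fraction of reactions receiving any SOM) and the match
#' metrics against ground truth. Coverage is monotone non-decreasing in the
#' number of enabled rules because handlers only ever add annotation
#' opportunities.
#'
#' @param pairs Reaction pairs (raw or standardized with
#'   [standardize_pairs()]).
#' @param truth Ground-truth table as for [score_soms()].
#' @param rule_order Character vector; rules are enabled in this order.
#' @param config Base [som_config()]; its `rules` field is overridden.
#' @param include_zero Include the empty rule set (k = 0) baseline row.
#' @return A `som_ablation` tibble with one row per prefix: `n_rules`,
#'   `rule_added`, `coverage`, `full_pct`, `partial_pct`, `neighbor_pct`.
#' @export
ablation_run <- function(pairs, truth, rule_order = som_rule_order(),
                         config = som_config(), include_zero = TRUE) {
  stopifnot(all(rule_order %in% som_rules()))
  if (!"substrate_mol" %in% names(pairs)) {
    pairs <- standardize_pairs(pairs, quiet = TRUE)
  }
  ks <- seq(if (include_zero) 0L else 1L, length(rule_order))
  rows <- lapply(ks, function(k) {
    cfg <- som_config(
      timeout_seconds = config$timeout_seconds,
      rules = if (k == 0) character(0) else rule_order[seq_len(k)]
    )
    res <- annotate_soms(pairs, config = cfg)
    live <- res$status != "invalid"
    scored <- score_soms(res, truth)
    tbl <- glance(som_match_table(scored))
    tibble::tibble(
      n_rules = k,
      rule_added = if (k == 0) NA_character_ else rule_order[k],
      coverage = mean(res$status[live] == "annotated"),
      full_pct = tbl$full_pct,
      partial_pct = tbl$partial_pct,
      neighbor_pct = tbl$neighbor_pct
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("som_ablation", class(out)))
}

#' @method autoplot som_ablation
#' @export
autoplot.som_ablation <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)[c("n_rules", "coverage", "full_pct")])
  long <- tidyr::pivot_longer(
    dplyr::mutate(df, coverage = 100 * .data$coverage),
    cols = c("coverage", "full_pct"),
    names_to = "metric", values_to = "pct"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n_rules, y = .data$pct, color = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "number of enabled rules", y = "%",
      title = "Annotation accuracy vs. rule-set size"
    ) +
    ggplot2::theme_minimal()
}
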
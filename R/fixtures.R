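#' Synthetic substrate-metabolite fixtures
#'
#' Generates labeled reaction pairs by forward-applying biotransformation
#' templates to a panel of small drug-like scaffolds, so every annotation
#' rule can be exercised -- and scored against known ground truth -- without
#' any external database. Each template is a substrate/metabolite SMILES
#' pair in which the substrate atoms that constitute the true site of
#' metabolism carry atom-map numbers; the maps ride through standardization,
#' so the truth set is derived programmatically on the standardized
#' substrate (in canonical atom order), never hand-indexed.
#'
#' @name fixtures
#' @keywords internal
NULL

GLUC <- "C1OC(C(=O)O)C(O)C(O)C1O" # glucuronosyl ring, open attachment at C1
GS_TAIL <- "CC(NC(=O)CCC(N)C(=O)O)C(=O)NCC(=O)O" # glutathionyl minus S

#' Template pool: family, expected rule, mapped substrate, metabolite
#' @noRd
fixture_pool <- function() {
  tribble_ <- tibble::tribble
  tribble_(
    ~family, ~rule, ~sub, ~met,
    # --- aromatic hydroxylation -> general addition
    "aromatic hydroxylation", "general addition", "Cc1cc[cH:1]cc1", "Cc1ccc(O)cc1",
    "aromatic hydroxylation", "general addition", "Clc1cc[cH:1]cc1", "Oc1ccc(Cl)cc1",
    "aromatic hydroxylation", "general addition", "[cH:1]1cccc2ccccc12", "Oc1cccc2ccccc12",
    "aromatic hydroxylation", "general addition", "Nc1[cH:1]cccc1", "Nc1ccccc1O",
    "aromatic hydroxylation", "general addition", "COc1cc[cH:1]cc1", "COc1ccc(O)cc1",
    "aromatic hydroxylation", "general addition", "Cc1[cH:1]cc(C)cc1", "Cc1ccc(C)c(O)c1",
    # --- aliphatic hydroxylation -> general addition
    "aliphatic hydroxylation", "general addition", "[CH3:1]CCCc1ccccc1", "OCCCCc1ccccc1",
    "aliphatic hydroxylation", "general addition", "[CH2:1]1CCCCC1", "OC1CCCCC1",
    "aliphatic hydroxylation", "general addition", "[CH3:1]c1ccccc1", "OCc1ccccc1",
    "aliphatic hydroxylation", "general addition", "C[CH2:1]c1ccccc1", "CC(O)c1ccccc1",
    # --- glucuronidation -> general addition
    "glucuronidation", "general addition", "[OH:1]c1ccccc1",
    paste0("O(c1ccccc1)", GLUC),
    "glucuronidation", "general addition", "[OH:1]C(=O)c1ccccc1",
    paste0("O=C(c1ccccc1)O", GLUC),
    "glucuronidation", "general addition", "[OH:1]c1ccc2ccccc2c1",
    paste0("O(c1ccc2ccccc2c1)", GLUC),
    "glucuronidation", "general addition", "[OH:1]c1ccc(C)cc1",
    paste0("O(c1ccc(C)cc1)", GLUC),
    # --- sulfation -> general addition
    "sulfation", "general addition", "[OH:1]c1ccc(C)cc1", "Cc1ccc(OS(=O)(=O)O)cc1",
    "sulfation", "general addition", "[OH:1]c1ccc(F)cc1", "O=S(=O)(O)Oc1ccc(F)cc1",
    # --- glutathione conjugation
    "glutathione conjugation", "glutathione conjugation", "[CH2:1]=CC=O",
    paste0("O=CCCS", GS_TAIL),
    "glutathione conjugation", "glutathione conjugation", "[CH2:1]=CC(C)=O",
    paste0("CC(=O)CCS", GS_TAIL),
    "glutathione conjugation", "glutathione conjugation", "Cl[c:1]1ccccc1",
    paste0("c1ccccc1S", GS_TAIL),
    "glutathione conjugation", "glutathione conjugation", "[CH2:1]1OC1c1ccccc1",
    paste0("OC(c1ccccc1)CS", GS_TAIL),
    # --- carnitine conjugation
    "carnitine conjugation", "carnitine conjugation", "C[C:1](=O)O",
    "CC(=O)OC(CC(=O)[O-])C[N+](C)(C)C",
    "carnitine conjugation", "carnitine conjugation", "CCC[C:1](=O)O",
    "CCCC(=O)OC(CC(=O)[O-])C[N+](C)(C)C",
    "carnitine conjugation", "carnitine conjugation", "CCCCC[C:1](=O)O",
    "CCCCCC(=O)OC(CC(=O)[O-])C[N+](C)(C)C",
    "carnitine conjugation", "carnitine conjugation", "O=[C:1](O)Cc1ccccc1",
    "O=C(Cc1ccccc1)OC(CC(=O)[O-])C[N+](C)(C)C",
    # --- N-/O-dealkylation -> general elimination (type 1)
    "dealkylation", "general elimination", "[CH3:1]N1CCN(C)CC1", "CN1CCNCC1",
    "dealkylation", "general elimination", "[CH3:1]N(C)c1ccccc1", "CNc1ccccc1",
    "dealkylation", "general elimination", "[CH3:1]Oc1ccccc1", "Oc1ccccc1",
    "dealkylation", "general elimination", "C[CH2:1]N(CC)CC(=O)Nc1ccccc1",
    "CCNCC(=O)Nc1ccccc1",
    "dealkylation", "general elimination", "[CH3:1]Oc1ccc(C)cc1", "Cc1ccc(O)cc1",
    # --- (thio)ester hydrolysis
    "(thio)ester hydrolysis", "(thio)ester hydrolysis",
    "CO[C:1](=O)c1ccccc1", "OC(=O)c1ccccc1",
    "(thio)ester hydrolysis", "(thio)ester hydrolysis", "CCO[C:1](C)=O", "CC(=O)O",
    "(thio)ester hydrolysis", "(thio)ester hydrolysis", "CCO[C:1](C)=O", "CCO",
    "(thio)ester hydrolysis", "(thio)ester hydrolysis",
    "C[C:1](=O)Oc1ccccc1C(=O)O", "Oc1ccccc1C(=O)O",
    "(thio)ester hydrolysis", "(thio)ester hydrolysis",
    "C[C:1](=O)SCc1ccccc1", "SCc1ccccc1",
    # --- hydrolysis of esters of inorganic acids
    "inorganic acid ester hydrolysis", "inorganic acid ester hydrolysis",
    "CCO[P:1](=O)(OCC)Oc1ccccc1", "Oc1ccccc1",
    "inorganic acid ester hydrolysis", "inorganic acid ester hydrolysis",
    "CCO[P:1](=S)(OCC)Oc1ccccc1", "Oc1ccccc1",
    "inorganic acid ester hydrolysis", "inorganic acid ester hydrolysis",
    "CO[P:1](=O)(O)OC", "COP(=O)(O)O",
    "inorganic acid ester hydrolysis", "inorganic acid ester hydrolysis",
    "O[S:1](=O)(=O)Oc1ccccc1", "Oc1ccccc1",
    "inorganic acid ester hydrolysis", "inorganic acid ester hydrolysis",
    "C[S:1](=O)(=O)Nc1ccccc1", "Nc1ccccc1",
    # --- reductive dehalogenation -> general elimination (type 2)
    "reductive dehalogenation", "general elimination", "Cl[c:1]1ccccc1", "c1ccccc1",
    "reductive dehalogenation", "general elimination", "Cc1cc[c:1](Br)cc1", "Cc1ccccc1",
    "reductive dehalogenation", "general elimination", "Cl[c:1]1ccccn1", "c1ccncc1",
    "reductive dehalogenation", "general elimination", "Br[CH:1]1CCCCC1", "C1CCCCC1",
    # --- heteroatom reduction -> general elimination (type 2)
    "heteroatom reduction", "general elimination", "C[S:1](=O)c1ccccc1", "CSc1ccccc1",
    "heteroatom reduction", "general elimination",
    "O=[S:1](Cc1ccccc1)Cc1ccccc1", "C(c1ccccc1)SCc1ccccc1",
    "heteroatom reduction", "general elimination", "O[CH2:1]c1ccccc1", "Cc1ccccc1",
    # --- oxidative dehalogenation
    "oxidative dehalogenation", "oxidative dehalogenation",
    "Cl[c:1]1ccccc1", "Oc1ccccc1",
    "oxidative dehalogenation", "oxidative dehalogenation",
    "Cc1cc[c:1](Br)cc1", "Cc1ccc(O)cc1",
    "oxidative dehalogenation", "oxidative dehalogenation",
    "CCC[CH2:1]Cl", "CCCCO",
    "oxidative dehalogenation", "oxidative dehalogenation",
    "Cl[C:1](Cl)=[CH2:2]", "ClC1CO1",
    # --- (de)hydrogenation -> subgraph isomorphism mapping
    "dehydrogenation", "subgraph isomorphism mapping",
    "[CH2:1]1[CH2:2]N=C(N1)c1ccccc1", "c1ccc(-c2ncc[nH]2)cc1",
    "dehydrogenation", "subgraph isomorphism mapping",
    "C[CH2:1][CH2:2]C", "CC=CC",
    "dehydrogenation", "subgraph isomorphism mapping",
    "[CH2:1]1[CH2:2]c2ccccc2C=C1", "c1ccc2ccccc2c1",
    "dehydrogenation", "subgraph isomorphism mapping",
    "[OH:1]c1ccccc1[OH:2]", "O=C1C=CC=CC1=O",
    "dehydrogenation", "subgraph isomorphism mapping",
    "c1ccccc1[CH:1]=[CH:2]c1ccccc1", "c1ccccc1CCc1ccccc1",
    "dehydrogenation", "subgraph isomorphism mapping",
    "[CH2:1]1[CH2:2]Nc2ccccc21", "c1ccc2[nH]ccc2c1",
    # --- epoxidation / quinone formation -> MCS mapping
    "epoxidation", "MCS mapping", "[CH2:2]=[CH:1]c1ccccc1", "c1ccccc1C1CO1",
    "epoxidation", "MCS mapping", "[CH:1]1=[CH:2]CCCC1", "C1CC2OC2CC1",
    "epoxidation", "MCS mapping",
    "c1ccccc1[CH:1]=[CH:2]c1ccccc1", "c1ccccc1C1OC1c1ccccc1",
    "quinone formation", "MCS mapping", "O[c:1]1[cH:2]cccc1", "O=C1C(=O)C=CC=C1",
    "quinone formation", "MCS mapping", "O[c:1]1[cH:2]cc(C)cc1", "O=C1C=C(C)C=CC1=O",
    # --- epoxide hydrolysis -> oxacyclopropane correction
    "epoxide hydrolysis", "oxacyclopropane hydrolysis",
    "[CH2:2]1O[CH:1]1c1ccccc1", "OCC(O)c1ccccc1",
    "epoxide hydrolysis", "oxacyclopropane hydrolysis",
    "C1C[CH:1]2O[CH:2]2CC1", "OC1CCCCC1O",
    "epoxide hydrolysis", "oxacyclopropane hydrolysis",
    "C[CH:1]1[CH2:2]O1", "CC(O)CO",
    # --- lactone hydrolysis
    "lactone hydrolysis", "lactone hydrolysis", "O=[C:1]1CCCO1", "OCCCC(=O)O",
    "lactone hydrolysis", "lactone hydrolysis", "O=[C:1]1CCCCO1", "OCCCCC(=O)O",
    "lactone hydrolysis", "lactone hydrolysis",
    "O=[C:1]1CCc2ccccc2O1", "OC(=O)CCc1ccccc1O",
    # --- other heterocyclic ring opening
    "heterocyclic ring opening", "other heterocyclic ring hydrolysis",
    "O=[C:1]1CCCN1", "NCCCC(=O)O",
    "heterocyclic ring opening", "other heterocyclic ring hydrolysis",
    "O=[C:1]1CCC(=O)N1", "NC(=O)CCC(=O)O",
    "heterocyclic ring opening", "other heterocyclic ring hydrolysis",
    "[CH2:1]1CCCO1", "OCCCCO"
  )
}

#' Generate synthetic fixtures with ground-truth SOMs
#'
#' Draws `n` reaction pairs from the template pool in a seeded round-robin
#' over a shuffled pool order, standardizes both sides, and derives the
#' ground-truth SOM set from the anchor atom maps on the standardized
#' substrate. Pairs that fail validation (a template that collapses to an
#' identical pair, for instance) are skipped with a message.
#'
#' @param seed Integer seed; the same seed reproduces the same fixtures.
#' @param n Number of fixtures to generate.
#' @return Tibble with columns `substrate_smiles`, `substrate_id`,
#'   `metabolite_smiles`, `metabolite_id`, `truth_soms` (list-column of
#'   0-based atom indices on the standardized substrate), `transformation`
#'   (the rule label the pair should exercise), `family`, and `seed`. The
#'   SMILES are standardized canonical strings, so re-standardization
#'   reproduces the atom numbering the truth refers to.
#' @examples
#' \dontrun{
#' generate_fixtures(seed = 1, n = 50)
#' }
#' @export
generate_fixtures <- function(seed, n) {
  stopifnot(n > 0)
  pool <- fixture_pool()
  m <- nrow(pool)

  std_sub <- chem_standardize_cached(pool$sub)
  std_met <- chem_standardize_cached(pool$met)

  ok <- logical(m)
  truth <- vector("list", m)
  sub_smiles <- character(m)
  met_smiles <- character(m)
  allowed <- som_allowed_elements()
  for (k in seq_len(m)) {
    s <- std_sub[[k]]
    mt <- std_met[[k]]
    if (is.character(s) || is.character(mt) ||
        identical(s$inchikey, mt$inchikey) ||
        !all(c(s$atoms$element, mt$atoms$element) %in% allowed) ||
        !any(s$atoms$map > 0L)) {
      message("skipping inapplicable fixture template ", k)
      next
    }
    ok[k] <- TRUE
    truth[[k]] <- which(s$atoms$map > 0L) - 1L
    sub_smiles[k] <- s$smiles
    met_smiles[k] <- mt$smiles
  }
  pool_ok <- which(ok)
  if (length(pool_ok) == 0) rlang::abort("no applicable fixture templates")

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  order_idx <- withr_seed({
    reps <- ceiling(n / length(pool_ok))
    unlist(lapply(seq_len(reps), function(i) sample(pool_ok)))
  })[seq_len(n)]

  sub_key <- vapply(std_sub[order_idx], function(s) s$inchikey, character(1))
  tibble::tibble(
    substrate_smiles = sub_smiles[order_idx],
    substrate_id = 1000L + match(sub_key, unique(sub_key)),
    metabolite_smiles = met_smiles[order_idx],
    metabolite_id = 2000L + seq_len(n),
    truth_soms = truth[order_idx],
    transformation = pool$rule[order_idx],
    family = pool$family[order_idx],
    seed = seed
  )
}

#' Write a fixture set as the pipeline's CSV dialect plus a truth file
#'
#' @param fixtures Output of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of `pairs.csv` and `truth.csv`.
#' @export
write_fixture_files <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs_path <- file.path(dir, "pairs.csv")
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(
    fixtures[c("substrate_smiles", "substrate_id", "metabolite_smiles", "metabolite_id")],
    pairs_path
  )
  truth <- dplyr::mutate(
    fixtures,
    som_indices = vapply(.data$truth_soms, paste, character(1), collapse = " ")
  )
  readr::write_csv(
    truth[c("substrate_id", "metabolite_id", "substrate_smiles",
            "som_indices", "transformation", "family")],
    truth_path
  )
  invisible(c(pairs = pairs_path, truth = truth_path))
}
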
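Package: somannot
Title: Rule-Based Annotation of Sites of Metabolism from Substrate-Metabolite Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates chemically meaningful sites of metabolism (SOMs) on
    substrate atoms from unbalanced substrate-metabolite pairs. Reactions are
    routed by heavy-atom balance to addition, elimination, and complex
    handlers built on subgraph isomorphism and maximum-common-substructure
    atom mapping, with dedicated rules for conjugations (glutathione,
    carnitine), ester and inorganic-acid-ester hydrolysis, oxidative
    dehalogenation, and ring hydrolyses, followed by symmetry-orbit
    expansion of the annotated atoms. Includes full/partial/neighbor match
    evaluation metrics, an ablation harness over the rule set, and a
    synthetic fixture generator with ground-truth SOMs for testing.
    Molecule standardization (parent extraction, neutralization, canonical
    tautomers, InChI keys) and SDF output are delegated to RDKit through a
    bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package on PATH as
    'python' or 'python3'
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
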
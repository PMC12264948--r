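# Shared fixtures: standardized molecules and the annotated corpus are
# memoized so the chemistry back end is invoked once per test run.

corpus_env <- new.env()

mol_of <- function(smiles) somannot:::chem_standardize_cached(smiles)[[1]]

std_pair <- function(sub_smiles, met_smiles) {
  mols <- somannot:::chem_standardize_cached(c(sub_smiles, met_smiles))
  list(substrate_mol = mols[[1]], metabolite_mol = mols[[2]])
}

test_corpus <- function(n = 200, seed = 1) {
  key <- paste0("c", seed, "_", n)
  if (is.null(corpus_env[[key]])) {
    fx <- generate_fixtures(seed = seed, n = n)
    std <- standardize_pairs(fx, quiet = TRUE)
    res <- annotate_soms(std)
    corpus_env[[key]] <- list(
      fx = fx, std = std, res = res, scored = score_soms(res, fx)
    )
  }
  corpus_env[[key]]
}

# structural query helper: 1-based indices of atoms satisfying a predicate
atoms_where <- function(mol, fn) {
  which(vapply(seq_len(mol$n), function(i) isTRUE(fn(mol, i)), logical(1)))
}

is_carbonyl_c <- function(mol, i) {
  mol$atoms$element[i] == "C" && somannot:::mg_has_oxo(mol, i)
}
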
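test_that("pairs with identical structure keys are rejected", {
  out <- standardize_pairs(
    tibble::tibble(
      substrate_smiles = "CCO", substrate_id = 1,
      metabolite_smiles = "CCO", metabolite_id = 2
    ),
    quiet = TRUE
  )
  expect_equal(out$status, "rejected")
  expect_equal(out$rejection_reason, "identical_pair")
})

test_that("disallowed elements and unparseable SMILES are rejected as data", {
  out <- standardize_pairs(
    tibble::tibble(
      substrate_smiles = c("C[As](C)C", "not_a_smiles", "c1ccccc1N"),
      substrate_id = 1:3,
      metabolite_smiles = c("CCO", "CCO", "Nc1ccccc1O"),
      metabolite_id = 11:13
    ),
    quiet = TRUE
  )
  expect_equal(out$status, c("rejected", "rejected", "accepted"))
  expect_equal(out$rejection_reason[1:2], c("disallowed_element", "unparseable"))
  # accepted pair has distinct keys and populated graphs
  expect_false(identical(
    out$substrate_mol[[3]]$inchikey, out$metabolite_mol[[3]]$inchikey
  ))
  expect_true(all(out$substrate_mol[[3]]$atoms$element %in% som_allowed_elements()))
})

test_that("standardization strips counterions and neutralizes", {
  mol <- mol_of("CC(=O)[O-].[Na+]")
  expect_equal(mol$smiles, "CC(=O)O")
  expect_equal(sum(mol$atoms$charge), 0)
  expect_equal(mol$n, 4)
  # an already standard aromatic survives untouched
  expect_equal(mol_of("c1ccccc1")$smiles, "c1ccccc1")
})

test_that("tautomers collapse to one canonical form", {
  a <- mol_of("Oc1ccccn1")
  b <- mol_of("O=c1cccc[nH]1")
  expect_equal(a$inchikey, b$inchikey)
  expect_equal(a$smiles, b$smiles)
})

test_that("standardization is idempotent on fixture molecules", {
  fx <- test_corpus()$fx
  smiles <- unique(c(fx$substrate_smiles, fx$metabolite_smiles))
  once <- somannot:::chem_standardize_cached(smiles)
  again <- somannot:::chem_standardize_cached(
    vapply(once, function(m) m$smiles, character(1))
  )
  expect_equal(
    vapply(once, function(m) m$inchikey, character(1)),
    vapply(again, function(m) m$inchikey, character(1))
  )
  # atom order is reproducible from the emitted SMILES
  expect_equal(
    lapply(once, function(m) m$atoms$element),
    lapply(again, function(m) m$atoms$element)
  )
})

test_that("every input row yields exactly one status (rejection totality)", {
  pairs <- tibble::tibble(
    substrate_smiles = c("CCO", "C[As](C)C", "xxx", "c1ccccc1", ""),
    substrate_id = 1:5,
    metabolite_smiles = c("CCO", "CCO", "CCO", "Oc1ccccc1", "CC"),
    metabolite_id = 11:15
  )
  out <- standardize_pairs(pairs, quiet = TRUE)
  expect_equal(nrow(out), nrow(pairs))
  expect_true(all(
    (out$status == "accepted") == is.na(out$rejection_reason)
  ))
  expect_true(all(
    out$rejection_reason[out$status == "rejected"] %in%
      somannot:::REJECTION_REASONS
  ))
})
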
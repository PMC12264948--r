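test_that("subgraph tests match exhaustive enumeration on small molecules", {
  benzene <- mol_of("c1ccccc1")
  phenol <- mol_of("Oc1ccccc1")
  quinone <- mol_of("O=C1C(=O)C=CC=C1")
  ethanol <- mol_of("CCO")

  expect_true(is_subgraph(benzene, phenol)$found)
  expect_false(is_subgraph(phenol, quinone)$found)
  r <- is_subgraph(ethanol, ethanol)
  expect_true(r$found)
  expect_true(any(vapply(r$embeddings, function(e) all(e == seq_len(3)), logical(1))))

  # cross-check embedding sets against the brute-force enumerator
  for (pair in list(list(benzene, phenol, TRUE), list(phenol, quinone, TRUE),
                    list(phenol, quinone, FALSE))) {
    got <- find_embeddings(pair[[1]], pair[[2]], sensitive = pair[[3]])
    want <- brute_embeddings(pair[[1]], pair[[2]], sensitive = pair[[3]])
    expect_setequal(
      vapply(got, paste, character(1), collapse = ","),
      vapply(want, paste, character(1), collapse = ",")
    )
  }
})

test_that("MCS mapping recovers the expected mapped-atom counts", {
  aniline <- mol_of("Nc1ccccc1")
  aminophenol <- mol_of("Nc1ccccc1O")
  maps <- mcs_mapping(aniline, aminophenol, sensitive = TRUE, use_charge = TRUE)
  expect_equal(sum(!is.na(maps[[1]])), 7) # all aniline atoms mapped

  ester <- mol_of("COC(=O)c1ccccc1")
  acid <- mol_of("OC(=O)c1ccccc1")
  maps <- mcs_mapping(ester, acid, sensitive = TRUE, use_charge = TRUE)
  expect_equal(sum(!is.na(maps[[1]])), 9) # methyl carbon left out

  m <- mol_of("CCO")
  maps <- mcs_mapping(m, m)
  expect_equal(sum(!is.na(maps[[1]])), 3)
})

test_that("every atom mapping is a partial isomorphism (bonds carry over)", {
  corp <- test_corpus()
  std <- corp$std
  rows <- which(std$status == "accepted")[1:40]
  for (r in rows) {
    sub <- std$substrate_mol[[r]]
    met <- std$metabolite_mol[[r]]
    for (sensitive in c(TRUE, FALSE)) {
      maps <- mcs_mapping(sub, met, sensitive = sensitive,
                          use_charge = sensitive)
      if (length(maps) == 0) next
      f <- maps[[1]]
      for (k in seq_len(nrow(sub$bonds))) {
        i <- sub$bonds$i[k]; j <- sub$bonds$j[k]
        if (is.na(f[i]) || is.na(f[j])) next
        expect_gt(met$adj[f[i], f[j]], 0)
        if (sensitive && !sub$arom[i, j]) {
          expect_equal(met$adj[f[i], f[j]], sub$adj[i, j])
        }
      }
    }
  }
})

test_that("symmetry orbits group equivalent atoms and expansion is sound", {
  aniline <- mol_of("Nc1ccccc1")
  orb <- symmetry_orbits(aniline)
  # N atom 1, ipso 2, ortho {3, 7}, meta {4, 6}, para 5 in canonical order
  ortho <- which(orb == orb[3])
  expect_setequal(ortho, c(3, 7))
  expect_setequal(symmetry_expand(aniline, 3L), c(3L, 7L))

  asym <- mol_of("CC(=O)OC")
  expect_equal(symmetry_expand(asym, 1L), 1L)
  expect_equal(symmetry_expand(asym, integer(0)), integer(0))
})

test_that("symmetry expansion is idempotent and monotone on fixtures", {
  corp <- test_corpus()
  mols <- corp$std$substrate_mol[corp$std$status == "accepted"]
  mols <- mols[!duplicated(vapply(mols, function(m) m$inchikey, character(1)))]
  for (mol in mols) {
    soms <- unique(c(1L, mol$n))
    once <- symmetry_expand(mol, soms)
    expect_true(all(soms %in% once))
    expect_identical(symmetry_expand(mol, once), once)
  }
})
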
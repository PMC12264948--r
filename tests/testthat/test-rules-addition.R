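GS <- "CC(NC(=O)CCC(N)C(=O)O)C(=O)NCC(=O)O" # glutathionyl tail minus S

test_that("glutathione handler places the SOM on the sulfur-bearing carbon", {
  # Michael addition to acrolein: SOM is the beta-carbon bonded to S
  pair <- std_pair("C=CC=O", paste0("O=CCCS", GS))
  ann <- annotate_glutathione(pair)
  expect_equal(ann$rule, "glutathione conjugation")
  sub <- pair$substrate_mol
  beta <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 2
  })
  expect_equal(ann$som, beta)

  # epoxide ring opening: SOM is the ring-opened carbon bearing S
  pair <- std_pair("C1OC1c1ccccc1", paste0("OC(c1ccccc1)CS", GS))
  ann <- annotate_glutathione(pair)
  sub <- pair$substrate_mol
  ch2 <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 2 && m$atoms$in_ring[i]
  })
  expect_equal(ann$som, ch2)

  # no thioether-linked tripeptide -> handler declines
  pair <- std_pair("Oc1ccccc1", "Cc1ccc(O)cc1")
  expect_null(annotate_glutathione(pair))
})

test_that("general addition marks atoms acquiring a new neighbour", {
  # ortho-hydroxylation of aniline (one ortho carbon before expansion)
  pair <- std_pair("Nc1ccccc1", "Nc1ccccc1O")
  ann <- annotate_general_addition(pair)
  expect_equal(ann$rule, "general addition")
  sub <- pair$substrate_mol
  orb <- symmetry_orbits(sub)
  ortho <- which(orb == orb[3])
  expect_length(ann$som, 1)
  expect_true(ann$som %in% ortho)

  # acyl glucuronidation of benzoic acid: SOM is the sp3 oxygen
  pair <- std_pair(
    "OC(=O)c1ccccc1",
    "O=C(c1ccccc1)OC1OC(C(=O)O)C(O)C(O)C1O"
  )
  ann <- annotate_general_addition(pair)
  sub <- pair$substrate_mol
  sp3_o <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "O" && m$atoms$n_h[i] == 1
  })
  expect_equal(ann$som, sp3_o)

  # phenol -> 1,2-benzoquinone has no bond-order-sensitive embedding
  pair <- std_pair("Oc1ccccc1", "O=C1C(=O)C=CC=C1")
  expect_null(annotate_general_addition(pair))
})

test_that("addition handler never fires without a heavy-atom gain", {
  corp <- test_corpus()
  std <- corp$std
  for (r in which(std$status == "accepted")) {
    sub <- std$substrate_mol[[r]]
    met <- std$metabolite_mol[[r]]
    if (met$n > sub$n) next
    pair <- list(substrate_mol = sub, metabolite_mol = met)
    expect_null(annotate_general_addition(pair))
    expect_null(annotate_glutathione(pair))
  }
})

test_that("carnitine correction moves the SOM to the carboxyl carbon", {
  pair <- std_pair("CC(=O)O", "CC(=O)OC(CC(=O)[O-])C[N+](C)(C)C")
  ann <- annotate_general_addition(pair)
  fixed <- carnitine_correction(pair, ann)
  expect_equal(fixed$rule, "carnitine conjugation")
  sub <- pair$substrate_mol
  expect_equal(fixed$som, atoms_where(sub, is_carbonyl_c))

  # glucuronide of the same acid is left untouched
  pair <- std_pair(
    "OC(=O)c1ccccc1",
    "O=C(c1ccccc1)OC1OC(C(=O)O)C(O)C(O)C1O"
  )
  ann <- annotate_general_addition(pair)
  expect_identical(carnitine_correction(pair, ann), ann)
})

test_that("on fixtures built by atom addition, SOMs lie on the recorded anchors", {
  corp <- test_corpus()
  scored <- corp$scored
  add <- scored[scored$category == "addition", ]
  expect_gt(nrow(add), 0)
  for (r in seq_len(nrow(add))) {
    mol <- add$substrate_mol[[r]]
    truth <- symmetry_expand(mol, add$truth_soms[[r]] + 1L)
    expect_true(all((add$som_indices[[r]] + 1L) %in% truth))
  }
})
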
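test_that("oxidative dehalogenation fires only on the element-balance gate", {
  # Ar-Cl -> Ar-OH: SOM on the ipso carbon
  pair <- std_pair("Clc1ccccc1", "Oc1ccccc1")
  ann <- annotate_oxidative_dehalogenation(pair)
  expect_equal(ann$rule, "oxidative dehalogenation")
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "C" &&
      any(m$atoms$element[somannot:::mg_neighbors(m, i)] == "Cl")
  }))

  # epoxide-forming variant: both oxirane carbons
  pair <- std_pair("ClC(Cl)=C", "ClC1CO1")
  ann <- annotate_oxidative_dehalogenation(pair)
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "C"
  }))

  # a demethylation pair changes the carbon count: gate rejects it
  pair <- std_pair("COc1ccccc1", "Oc1ccccc1")
  expect_null(annotate_oxidative_dehalogenation(pair))
})

test_that("full isomorphism mapping flags hydrogen-count changes", {
  # imidazoline -> imidazole dehydrogenation: the two CH2 carbons
  pair <- std_pair("C1CN=C(N1)c1ccccc1", "c1ccc(-c2ncc[nH]2)cc1")
  ann <- annotate_by_full_isomorphism(pair)
  expect_equal(ann$rule, "subgraph isomorphism mapping")
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 2
  }))

  # alkene hydrogenation: both former double-bond carbons
  pair <- std_pair("c1ccccc1C=Cc1ccccc1", "c1ccccc1CCc1ccccc1")
  ann <- annotate_by_full_isomorphism(pair)
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 1 && !m$atoms$aromatic[i]
  }))
})

test_that("full-isomorphism SOMs are invariant under atom relabeling", {
  pair <- std_pair("C1CN=C(N1)c1ccccc1", "c1ccc(-c2ncc[nH]2)cc1")
  base <- annotate_by_full_isomorphism(pair)
  sub <- pair$substrate_mol
  set.seed(42)
  for (k in 1:3) {
    perm <- sample(sub$n)
    pair2 <- list(
      substrate_mol = permute_molgraph(sub, perm),
      metabolite_mol = pair$metabolite_mol
    )
    ann2 <- annotate_by_full_isomorphism(pair2)
    expect_setequal(perm[base$som], ann2$som)
  }
})

test_that("MCS diff labels the topologically changed carbons", {
  # phenol -> 1,2-benzoquinone: both oxygen-bearing ring carbons, no oxygens
  pair <- std_pair("Oc1ccccc1", "O=C1C(=O)C=CC=C1")
  ann <- annotate_by_mcs_diff(pair)
  expect_equal(ann$rule, "MCS mapping")
  sub <- pair$substrate_mol
  c_o <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" &&
      any(m$atoms$element[somannot:::mg_neighbors(m, i)] == "O")
  })
  expect_length(ann$som, 2)
  expect_true(c_o %in% ann$som)
  expect_true(all(sub$atoms$element[ann$som] == "C"))

  # disjoint molecules: empty MCS, no annotation
  pair <- std_pair("CCCC", "O=S(=O)(O)O")
  expect_null(annotate_by_mcs_diff(pair))
})

test_that("ring-hydrolysis corrections reassign the SOM", {
  # oxacyclopropane hydrolysis: both former ring carbons
  pair <- std_pair("C1OC1c1ccccc1", "OCC(O)c1ccccc1")
  ann <- ring_hydrolysis_corrections(pair, annotate_by_mcs_diff(pair))
  expect_equal(ann$rule, "oxacyclopropane hydrolysis")
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$in_ring[i] &&
      any(m$atoms$element[somannot:::mg_neighbors(m, i)] == "O")
  }))

  # butyrolactone hydrolysis: the carbonyl carbon
  pair <- std_pair("O=C1CCCO1", "OCCCC(=O)O")
  ann <- ring_hydrolysis_corrections(pair, annotate_by_mcs_diff(pair))
  expect_equal(ann$rule, "lactone hydrolysis")
  expect_equal(ann$som, atoms_where(pair$substrate_mol, is_carbonyl_c))

  # a non-ring reaction passes through unchanged
  pair <- std_pair("Oc1ccccc1", "O=C1C(=O)C=CC=C1")
  ann <- annotate_by_mcs_diff(pair)
  expect_identical(ring_hydrolysis_corrections(pair, ann), ann)
})
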
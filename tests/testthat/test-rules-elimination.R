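test_that("type 1: the removed alpha-carbon of a dealkylation is the SOM", {
  pair <- std_pair("CN1CCN(C)CC1", "CN1CCNCC1")
  ann <- annotate_general_elimination(pair)
  expect_equal(ann$rule, "general elimination")
  sub <- pair$substrate_mol
  methyls <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 3
  })
  expect_length(ann$som, 1)
  expect_true(ann$som %in% methyls)
  # no ester linkage at the boundary: correction leaves it untouched
  expect_identical(ester_corrections(pair, ann), ann)
})

test_that("type 2: reductive dehalogenation marks the ipso carbon", {
  pair <- std_pair("Clc1ccccc1", "c1ccccc1")
  ann <- annotate_general_elimination(pair)
  sub <- pair$substrate_mol
  ipso <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" &&
      any(m$atoms$element[somannot:::mg_neighbors(m, i)] == "Cl")
  })
  expect_equal(ann$som, ipso)

  # sulfoxide reduction: SOM on the sulfur
  pair <- std_pair("CS(=O)c1ccccc1", "CSc1ccccc1")
  ann <- annotate_general_elimination(pair)
  expect_equal(ann$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "S"
  }))
})

test_that("ester hydrolysis is corrected to the carbonyl carbon", {
  pair <- std_pair("COC(=O)c1ccccc1", "OC(=O)c1ccccc1")
  raw <- annotate_general_elimination(pair)
  sub <- pair$substrate_mol
  methyl <- atoms_where(sub, function(m, i) {
    m$atoms$element[i] == "C" && m$atoms$n_h[i] == 3
  })
  expect_equal(raw$som, methyl) # raw type-1 SOM is the methyl carbon
  fixed <- ester_corrections(pair, raw)
  expect_equal(fixed$rule, "(thio)ester hydrolysis")
  expect_equal(fixed$som, atoms_where(sub, is_carbonyl_c))
})

test_that("inorganic acid esters are corrected to the P/S center", {
  # dialkyl thiophosphate hydrolysis -> phosphorus
  pair <- std_pair("CCOP(=S)(OCC)Oc1ccccc1", "Oc1ccccc1")
  fixed <- ester_corrections(pair, annotate_general_elimination(pair))
  expect_equal(fixed$rule, "inorganic acid ester hydrolysis")
  expect_equal(fixed$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "P"
  }))

  # sulfonamide cleavage -> sulfonyl sulfur
  pair <- std_pair("CS(=O)(=O)Nc1ccccc1", "Nc1ccccc1")
  fixed <- ester_corrections(pair, annotate_general_elimination(pair))
  expect_equal(fixed$rule, "inorganic acid ester hydrolysis")
  expect_equal(fixed$som, atoms_where(pair$substrate_mol, function(m, i) {
    m$atoms$element[i] == "S"
  }))
})

test_that("elimination never fires without a heavy-atom loss, and dealkylation
           fixtures recover the recorded alpha-carbon", {
  corp <- test_corpus()
  std <- corp$std
  for (r in which(std$status == "accepted")) {
    sub <- std$substrate_mol[[r]]
    met <- std$metabolite_mol[[r]]
    if (met$n < sub$n) next
    expect_null(annotate_general_elimination(
      list(substrate_mol = sub, metabolite_mol = met)
    ))
  }
  scored <- corp$scored
  deal <- scored[scored$family == "dealkylation", ]
  expect_gt(nrow(deal), 0)
  expect_true(all(deal$match == "full"))
})
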
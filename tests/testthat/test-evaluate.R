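test_that("match categories follow the full/partial/neighbor/none definitions", {
  mol <- mol_of("CCCCO") # simple chain, trivial orbits
  expect_equal(match_category(3, 3, mol), "full")
  expect_equal(match_category(c(3, 1), 3, mol), "partial")
  expect_equal(match_category(2, 3, mol), "neighbor")
  expect_equal(match_category(0, 3, mol), "none")
  expect_equal(match_category(integer(0), 3, mol), "none")
  expect_error(match_category(1, integer(0), mol), "non-empty")
})

test_that("orbit expansion makes equivalent-atom annotations compare equal", {
  aniline <- mol_of("Nc1ccccc1")
  # one ortho carbon vs the other: identical after expansion, not even
  # adjacent without it (they sit across the ring)
  expect_equal(match_category(2, 6, aniline), "full")
  expect_equal(match_category(2, 6, aniline, expand = FALSE), "none")
  # ortho vs meta are bonded: a neighbor match either way
  expect_equal(match_category(2, 3, aniline, expand = FALSE), "neighbor")
  expect_equal(match_category(2, 3, aniline), "neighbor")
})

test_that("aggregation reproduces an independent tally", {
  corp <- test_corpus()
  scored <- corp$scored
  tbl <- som_match_table(scored)

  # independent tally with base table()
  live <- scored[!scored$status %in% c("timeout", "invalid"), ]
  counts <- table(live$category, live$match)
  for (g in setdiff(tbl$group, "All")) {
    row <- tbl[tbl$group == g, ]
    expect_equal(row$n_reactions, sum(counts[g, ]))
    expect_equal(row$full_pct, 100 * counts[g, "full"] / sum(counts[g, ]))
  }
  all_row <- tbl[tbl$group == "All", ]
  expect_equal(all_row$n_reactions, nrow(live))
  # percentages never exceed 100 per row
  expect_true(all(tbl$full_pct + tbl$partial_pct + tbl$neighbor_pct <= 100 + 1e-9))

  # category partition: every scored reaction is in exactly one category
  expect_equal(
    sum(!is.na(live$match)),
    sum(counts)
  )
})

test_that("simple arithmetic: 9 full + 1 partial gives 90/10/0", {
  mol <- mol_of("CCCCO")
  scored <- tibble::tibble(
    som_indices = c(rep(list(1L), 9), list(c(1L, 2L))),
    truth_soms = rep(list(1L), 10),
    substrate_mol = rep(list(mol), 10),
    status = "annotated",
    rule = "general addition"
  )
  scored$match <- factor(
    vapply(seq_len(10), function(r) {
      match_category(scored$som_indices[[r]], scored$truth_soms[[r]], mol)
    }, character(1)),
    levels = c("full", "partial", "neighbor", "none")
  )
  scored$category <- som_rule_category(scored$rule)
  tbl <- tidy(som_match_table(scored))
  all_row <- tbl[tbl$group == "All", ]
  expect_equal(all_row$full_pct, 90)
  expect_equal(all_row$partial_pct, 10)
  expect_equal(all_row$neighbor_pct, 0)
  # single-category input: the category row equals the All row
  cat_row <- tbl[tbl$group == "addition", ]
  expect_equal(cat_row$full_pct, all_row$full_pct)

  g <- glance(som_match_table(scored))
  expect_equal(g$n_reactions, 10)
  p <- autoplot(som_match_table(scored))
  expect_s3_class(p, "ggplot")
})
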
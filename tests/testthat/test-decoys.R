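# Property-matched decoy generation and active-set curation.

test_that("decoy spec validates its fields", {
  expect_error(decoy_spec(mw_window = -1), "non-negative")
  expect_error(decoy_spec(max_fingerprint_similarity = 1.2), "similarity")
  expect_error(decoy_spec(decoys_per_active = 0), "decoys_per_active")
})

test_that("no actives means no decoys; empty universe is an error", {
  fx <- small_fixture()
  out <- generate_decoys(list(), fx$universe, decoy_spec())
  expect_length(out$decoys, 0L)
  expect_error(generate_decoys(fx$actives, list(), decoy_spec()), "empty")
})

test_that("ratio conservation: k decoys per active when no shortfall is logged", {
  fx <- small_fixture()
  dg <- small_decoys()
  expect_equal(nrow(dg$shortfalls), 0L)
  expect_length(dg$decoys, 8L * 6L)
  expect_equal(nrow(dg$provenance), 8L * 6L)
  expect_equal(unname(table(dg$provenance$active_id)), rep(6L, 8L), ignore_attr = TRUE)
  # no decoy serves two actives, no duplicates
  expect_false(anyDuplicated(dg$provenance$decoy_id) > 0)
})

test_that("every emitted decoy lies inside all windows under independent recomputation", {
  fx <- small_fixture()
  dg <- small_decoys()
  spec <- decoy_spec(decoys_per_active = 6L, seed = 42L)
  # independent recomputation: re-parse each decoy from its SMILES string
  fresh_d <- attach_descriptors(parse_smiles(canonical_smiles(dg$decoys),
                                             vapply(dg$decoys, `[[`, "", "id")))
  fresh_a <- attach_descriptors(parse_smiles(canonical_smiles(fx$actives),
                                             vapply(fx$actives, `[[`, "", "id")))
  dd <- descriptor_table(fresh_d)
  da <- descriptor_table(fresh_a)
  sim <- tanimoto_matrix(ecfp_fingerprints(fresh_a), ecfp_fingerprints(fresh_d))
  for (r in seq_len(nrow(dg$provenance))) {
    i <- match(dg$provenance$active_id[r], da$id)
    j <- match(dg$provenance$decoy_id[r], dd$id)
    expect_lte(abs(dd$MW[j] - da$MW[i]), spec$mw_window)
    expect_lte(abs(dd$logP[j] - da$logP[i]), spec$logp_window)
    expect_lte(abs(dd$rotatable_bonds[j] - da$rotatable_bonds[i]), spec$rotb_window)
    expect_lte(abs(dd$hbd[j] - da$hbd[i]), spec$hbd_window)
    expect_lte(abs(dd$hba[j] - da$hba[i]), spec$hba_window)
    expect_equal(dd$net_charge[j], da$net_charge[i])
    expect_lt(sim[i, j], spec$max_fingerprint_similarity)
  }
})

test_that("decoy sampling is seed-deterministic and disjointness is enforced", {
  fx <- small_fixture()
  d1 <- generate_decoys(fx$actives, fx$universe, decoy_spec(decoys_per_active = 6L, seed = 9L))
  d2 <- generate_decoys(fx$actives, fx$universe, decoy_spec(decoys_per_active = 6L, seed = 9L))
  expect_identical(d1$provenance, d2$provenance)
  d3 <- generate_decoys(fx$actives, fx$universe, decoy_spec(decoys_per_active = 6L, seed = 10L))
  expect_false(identical(d1$provenance$decoy_id, d3$provenance$decoy_id))
  # an active smuggled into the universe trips the disjointness check
  expect_error(generate_decoys(fx$actives, c(fx$universe, fx$actives[1]), decoy_spec()),
               "not disjoint")
})

test_that("active curation applies the stated annotation filters", {
  smi <- c(a1 = "CCC(CC(=O)OC1CC(COC(=O)Cc2ccco2)CC(=O)C1)C",  # in-range nonbasic
           a2 = "CCC(CC(=O)OC1CC(COC(=O)Cc2ccco2)CC(=O)C1)C",  # duplicate of a1
           a3 = "CCOC(=O)c1ccccc1",                             # MW 150 -> out of range
           a4 = "CC(CC(=O)OC1CC(COC(=O)Cc2ccco2)CC(=O)C1)C",
           a5 = "CC(CC(=O)OC1CC(COC(=O)Cc2ccco2)CC(=O)C1)C",
           a6 = "CNCCC1CC(OC(=O)Cc2ccco2)CC(OC(C)=O)C1")       # basic amine
  recs <- parse_smiles(unname(smi), names(smi))
  ann <- data.frame(id = names(smi),
                    ec50 = c("12.5", "40", "3.3", ">1000", "250", "8"),
                    assay = c("[35S]GTPgS", "[35S]GTPgS", "[35S]GTPgS",
                              "[35S]GTPgS", "[35S]GTPgS", "[35S]GTPgS"),
                    units = c("nM", "nM", "nM", "nM", "nM", "nM"))
  out <- curate_actives(recs, ann)
  ids <- vapply(out$actives, `[[`, "", "id")
  # a4 dropped (inexact EC50), a3 dropped (MW), a6 dropped (basic),
  # a2 dropped as duplicate of a1
  expect_setequal(ids, c("a1", "a5"))
  expect_equal(unname(out$stage_counts["input"]), 6L)
  expect_equal(unname(out$stage_counts["exact_ec50_nM"]), 5L)
  expect_equal(unname(out$stage_counts["deduplicated"]), 2L)
  # assay filter: cAMP-tagged entries are dropped
  ann2 <- ann; ann2$assay[1] <- "cAMP"
  out2 <- curate_actives(recs, ann2)
  expect_false("a1" %in% vapply(out2$actives, `[[`, "", "id"))
})
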
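# Hit merging, filtering, pose re-scoring, contact annotation.

test_that("merge respects set identity on union, intersection and disjoint lists", {
  fx <- small_fixture()
  lib <- fx$actives
  ids <- vapply(lib, `[[`, "", "id")
  mk <- function(sel, scores) {
    out <- data.frame(id = ids[sel], score = scores, n_matched = 1L, conformer_index = 1L)
    class(out) <- c("ranked_screen", class(out)); out
  }
  A <- mk(1:5, 5:1); B <- mk(3:8, 12:7)
  merged <- merge_hits(list(pharm_screen = A, shape_screen = B), lib)
  expect_equal(nrow(merged), 5 + 6 - 3)                 # |A| + |B| - |A∩B|
  expect_equal(sum(merged$origin == "both"), 3L)
  # best score per method survives the collapse
  expect_equal(merged$score_shape_screen[match(ids[3], merged$id)], 12)
  expect_equal(merged$score_pharm_screen[match(ids[3], merged$id)], 3)
  # identical lists collapse to one copy; disjoint lists concatenate
  expect_equal(nrow(merge_hits(list(a = A, b = A), lib)), nrow(A))
  expect_equal(nrow(merge_hits(list(a = mk(1:2, 2:1), b = mk(3:4, 2:1)), lib)), 4L)
  # duplicate structures with different ids collapse by canonical identity
  dup <- lib[[1]]; dup$id <- "DUPLICATE"
  merged2 <- merge_hits(list(a = mk(1, 1),
                             b = {
                               d <- data.frame(id = "DUPLICATE", score = 9,
                                               n_matched = 1L, conformer_index = 1L)
                               class(d) <- c("ranked_screen", class(d)); d
                             }),
                        c(lib, list(dup)))
  expect_equal(nrow(merged2), 1L)
  expect_equal(merged2$origin, "both")
})

test_that("physicochemical filters are boundary-inclusive and commute", {
  fx <- small_fixture()
  mols <- c(fx$actives, test_molecules()[c("tma", "morphine")])
  mols <- lapply(mols, with_conformer)
  mols <- attach_descriptors(mols)
  out <- apply_filters(mols, mw_max = 500, rotb_max = 10)
  expect_equal(unname(out$counts["input"]),
               unname(out$counts["survivors"]) + sum(out$flags$charged) +
                 sum(out$flags$basic & !out$flags$charged) +
                 sum(out$flags$mw_gt_max & !out$flags$charged & !out$flags$basic) +
                 sum(out$flags$rotb_gt_max & !out$flags$mw_gt_max &
                       !out$flags$charged & !out$flags$basic))
  expect_true("tma" %in% out$flags$id[out$flags$charged])
  expect_true("morphine" %in% out$flags$id[out$flags$basic])

  # boundary values pass; just above fails
  m <- fx$actives[[1]]
  d <- m$descriptors
  at_mw <- apply_filters(list(m), mw_max = d$MW, rotb_max = d$rotatable_bonds)
  expect_length(at_mw$survivors, 1L)
  over_mw <- apply_filters(list(m), mw_max = d$MW - 0.1, rotb_max = d$rotatable_bonds)
  expect_length(over_mw$survivors, 0L)
  expect_true(over_mw$flags$mw_gt_max)
  over_rotb <- apply_filters(list(m), mw_max = d$MW, rotb_max = d$rotatable_bonds - 1L)
  expect_true(over_rotb$flags$rotb_gt_max)

  # commutation: the survivor set is an intersection, independent of order
  ids_all <- unname(vapply(out$survivors, `[[`, "", "id"))
  s1 <- apply_filters(mols, mw_max = 500, rotb_max = Inf)$survivors
  s2 <- apply_filters(s1, mw_max = Inf, rotb_max = 10)$survivors
  expect_setequal(unname(vapply(s2, `[[`, "", "id")), ids_all)
})

test_that("fixed-frame pose re-scoring keeps in-place poses and drops displaced ones", {
  q <- reference_query(reduced = FALSE)
  pose <- reference_molecule(); pose$id <- "P1"
  displaced <- reference_molecule(); displaced$id <- "P2"
  displaced$conformers[[1]] <- displaced$conformers[[1]] + 15
  rs <- rescore_poses(list(pose, displaced), q)
  expect_true(rs$kept[rs$id == "P1"])
  expect_gt(rs$pose_score[rs$id == "P1"], 0)
  expect_false(rs$kept[rs$id == "P2"])
  expect_equal(rs$pose_score[rs$id == "P2"], 0)
  # C2-analogue acceptor matched iff its residual fits the tolerance
  expect_true(rs$c2_analog_matched[rs$id == "P1"])
  shifted <- pose; shifted$id <- "P3"
  o10 <- shifted$anchor_atoms$hba[["C2"]]
  shifted$conformers[[1]][o10, ] <- shifted$conformers[[1]][o10, ] + c(0, 3, 0)
  rs3 <- rescore_poses(list(shifted), q)
  expect_true(rs3$kept)
  expect_false(rs3$c2_analog_matched)
  # frame mismatch warning when everything is far away
  lost <- pose; lost$id <- "P4"
  lost$conformers[[1]] <- lost$conformers[[1]] + 40
  expect_warning(rescore_poses(list(lost), q), "frame")
})

test_that("contact annotation is geometrically self-consistent", {
  pk <- pocket_fixture()
  ct <- annotate_contacts(pk$pose, pk$pdb)
  expect_gt(nrow(ct), 0L)
  expect_true(all(ct$residue %in% c("Q115", "V118", "Y139", "Y312", "Y313")))
  # reported distances equal recomputed atom-pair distances
  pdb <- bio3d::read.pdb(pk$pdb)
  for (r in seq_len(nrow(ct))) {
    la <- pk$pose$conformers[[1]][ct$ligand_atom[r], ]
    sel <- paste0(substr(pdb$atom$resid, 1, 1), pdb$atom$resno) ==
      sub("^([A-Z])", "\\1", ct$residue[r]) &
      trimws(pdb$atom$elety) == ct$receptor_atom[r]
    # resid initial letter may differ from one-letter code; match by resno
    sel <- pdb$atom$resno == as.integer(sub("^[A-Z]+", "", ct$residue[r])) &
      trimws(pdb$atom$elety) == ct$receptor_atom[r]
    ra <- unlist(pdb$atom[which(sel)[1], c("x", "y", "z")])
    expect_equal(ct$distance[r], sqrt(sum((la - ra)^2)), tolerance = 1e-3)
  }
  # hydrophobic contact with the valine side chain is present by construction
  expect_true(any(ct$kind == "hydrophobic" & ct$residue == "V118"))
  expect_error(annotate_contacts(pk$pose, file.path(tempdir(), "missing.pdb")))
})
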
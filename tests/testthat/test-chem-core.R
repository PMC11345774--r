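# Molecule I/O, feature perception, charge/basicity filter, descriptors.

test_that("SMILES and SDF libraries round-trip with skip accounting", {
  tf <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CC(=O)C\tm1", "c1ccccc1\tm2", "not_a_smiles((\tm3"), tf)
  expect_message(lib <- read_library(tf, "smiles"), "skipped 1 invalid")
  expect_length(lib, 2L)
  expect_equal(vapply(lib, `[[`, "", "id"), c("m1", "m2"))

  # SDF round trip preserves id, heavy-atom count and charges
  mols <- lapply(test_molecules()[c("acetone", "tma", "water")], with_conformer)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_library(mols, sdf)
  back <- read_library(sdf, "sdf")
  expect_equal(vapply(back, `[[`, "", "id"), unname(vapply(mols, `[[`, "", "id")))
  expect_equal(vapply(back, n_heavy, 0L), unname(vapply(mols, n_heavy, 0L)))
  expect_equal(vapply(back, net_formal_charge, 0L), c(0L, 1L, 0L),
               ignore_attr = TRUE)

  expect_error(read_library(file.path(tempdir(), "nope.smi"), "smiles"), "no such file")
  empty <- withr::local_tempfile(fileext = ".smi", lines = "((((")
  expect_error(suppressMessages(read_library(empty, "smiles")), "empty library")
})

test_that("feature perception follows the declared chemistry rules", {
  mols <- lapply(test_molecules(), with_conformer)
  kinds <- function(nm) sort(perceive_features(mols[[nm]])$kind)
  # acetone: one carbonyl acceptor, no donor, one carbon island
  expect_equal(kinds("acetone"), c("HBA", "HY"))
  # benzene: aromatic ring + one hydrophobic cluster, nothing polar
  expect_equal(kinds("benzene"), c("AR", "HY"))
  # methane: single heavy atom, cluster size < 2, no polar features
  expect_equal(nrow(perceive_features(mols$methane)), 0L)
  # furan oxygen is not an acceptor; ester sp3 O is not an acceptor
  expect_equal(kinds("furan"), c("AR", "HY"))
  f <- perceive_features(mols$ethyl_benzoate)
  expect_equal(sum(f$kind == "HBA"), 1L)   # carbonyl O only
  # pyridine N accepts; aniline N donates but does not accept
  expect_equal(sum(perceive_features(mols$pyridine)$kind == "HBA"), 1L)
  fa <- perceive_features(mols$aniline)
  expect_equal(sum(fa$kind == "HBA"), 0L)
  expect_equal(sum(fa$kind == "HBD"), 1L)
  # feature centers are source-atom centroids
  hy <- f[f$kind == "HY", ][1, ]
  ctr <- colMeans(mols$ethyl_benzoate$conformers[[1]][hy$source_atoms[[1]], , drop = FALSE])
  expect_equal(unlist(hy[c("x", "y", "z")]), ctr, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(perceive_features(mols$acetone, 5L), "conformer")
})

test_that("perception is covariant under rigid motion of the conformer", {
  mol <- with_conformer(test_molecules()$ethyl_benzoate)
  f0 <- perceive_features(mol)
  R <- kappascreen:::.rotation_from_axis_angle(c(0.3, -1.2, 0.8))
  t <- c(4, -2, 7)
  mol2 <- mol
  mol2$conformers[[1]] <- kappascreen:::.apply_transform(mol$conformers[[1]], R, t)
  f1 <- perceive_features(mol2)
  expect_equal(f1$kind, f0$kind)
  moved <- kappascreen:::.apply_transform(as.matrix(f0[, c("x", "y", "z")]), R, t)
  expect_equal(as.matrix(f1[, c("x", "y", "z")]), moved, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("nonbasic filter separates charged, basic and acceptable molecules", {
  mols <- test_molecules()
  expect_equal(nonbasic_filter(mols$morphine), "fail_basic")     # tertiary aliphatic amine
  expect_equal(nonbasic_filter(mols$ethylamine), "fail_basic")
  expect_equal(nonbasic_filter(mols$guanidine), "fail_basic")
  expect_equal(nonbasic_filter(mols$tma), "fail_charged")
  # amide, anilinic and aromatic-ring N do not count as basic
  expect_equal(nonbasic_filter(mols$nma), "pass")
  expect_equal(nonbasic_filter(mols$aniline), "pass")
  expect_equal(nonbasic_filter(mols$pyridine), "pass")
  # Salvinorin A has no nitrogen at all
  sala <- parse_smiles(salvinorin_a_smiles(), "SalA")[[1]]
  expect_equal(nonbasic_filter(sala), "pass")
  # conformer-independent: pure function of the connection table
  m <- test_molecules()$morphine
  expect_equal(nonbasic_filter(with_conformer(m, 1)), nonbasic_filter(with_conformer(m, 99)))
})

test_that("descriptors follow the stated definitions", {
  mols <- test_molecules()
  d <- function(nm) compute_descriptors(mols[[nm]], logP = FALSE)$descriptors
  expect_equal(d("water")$MW, 18.02, tolerance = 1e-3)
  expect_equal(d("water")$rotatable_bonds, 0L)
  expect_equal(d("butane")$rotatable_bonds, 1L)
  # amide C-N is not rotatable
  expect_equal(d("nma")$rotatable_bonds, 0L)
  expect_equal(d("nma")$hbd, 1L)
  d2 <- compute_descriptors(mols$acetone)$descriptors
  expect_equal(d2$hba, 1L)
  expect_true(is.finite(d2$logP_estimate))
  expect_equal(d2$net_formal_charge, 0L)
})

test_that("descriptors are invariant to atom input order", {
  # same structure entered with different atom orderings
  a <- parse_smiles("CCOC(=O)c1ccccc1", "a")[[1]]
  b <- parse_smiles("c1ccccc1C(=O)OCC", "b")[[1]]
  da <- compute_descriptors(a)$descriptors
  db <- compute_descriptors(b)$descriptors
  expect_equal(da[c("MW", "rotatable_bonds", "hbd", "hba", "logP_estimate")],
               db[c("MW", "rotatable_bonds", "hbd", "hba", "logP_estimate")])
  expect_equal(canonical_smiles(list(a)), canonical_smiles(list(b)))
})

test_that("conformer-free polar counts agree with geometric feature perception", {
  mols <- lapply(test_molecules(), with_conformer)
  for (m in mols) {
    f <- perceive_features(m)
    pc <- kappascreen:::.polar_counts(m)
    expect_equal(pc$hba, sum(f$kind == "HBA"), info = m$id)
    expect_equal(pc$hbd, sum(f$kind == "HBD"), info = m$id)
  }
})
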
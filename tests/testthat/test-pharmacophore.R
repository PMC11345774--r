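# Query handling, rigid matching, scoring, screening.

test_that("query construction and editing obey their contracts", {
  q <- reference_query()
  expect_equal(nrow(q$features), 6L)
  expect_setequal(q$required_labels, q$features$label)
  # drop / re-add round trip on the feature set
  q5 <- drop_feature(q, "C2-HBA")
  expect_equal(nrow(q5$features), 5L)
  expect_false("C2-HBA" %in% q5$required_labels)
  expect_equal(nrow(q5$exclusion_volumes), nrow(q$exclusion_volumes))
  back <- pharmacophore_query(rbind(q5$features, q$features[q$features$label == "C2-HBA", ]),
                              q5$exclusion_volumes)
  expect_setequal(back$features$label, q$features$label)
  expect_error(drop_feature(q, "nope"), "no feature labelled")
  expect_error(pharmacophore_query(q$features[0, ]), "at least one feature")
  expect_error(pharmacophore_query(transform(q$features, radius = 0)), "positive")

  # JSON and YAML round trips
  for (ext in c(".json", ".yaml")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_query(q, tf)
    q2 <- read_query(tf)
    expect_equal(q2$features$label, q$features$label)
    expect_equal(as.matrix(q2$features[, c("x", "y", "z", "radius")]),
                 as.matrix(q$features[, c("x", "y", "z", "radius")]),
                 tolerance = 1e-9)
  }
  # the bundled reduced query ships with 3 HY + 2 HBA
  bundled <- read_query(system.file("extdata", "sala_kor_reduced.json",
                                    package = "kappascreen"))
  expect_equal(sort(table(bundled$features$kind), decreasing = TRUE),
               sort(c(HY = 3L, HBA = 2L), decreasing = TRUE), ignore_attr = TRUE)
})

test_that("a molecule matches a query built from its own features exactly", {
  ref <- reference_molecule()
  q <- reference_query()
  m <- match_pharmacophore(q, ref, "full")
  expect_equal(m$n_matched, 6L)
  expect_equal(unname(m$residuals), rep(0, 6), tolerance = 1e-9)
  expect_equal(m$score, 10 * 6, tolerance = 1e-9)  # S = 9N + N at zero residuals
  expect_false(m$clash)
})

test_that("matching is invariant to rigid motion of ligand and query", {
  ref <- reference_molecule()
  q <- reference_query()
  base <- match_pharmacophore(q, ref, "full")$score
  for (seed in 1:3) {
    set.seed(seed)
    R <- kappascreen:::.rotation_from_axis_angle(runif(3, -pi, pi))
    t <- runif(3, -10, 10)
    rot <- ref
    rot$conformers[[1]] <- kappascreen:::.apply_transform(ref$conformers[[1]], R, t)
    expect_equal(match_pharmacophore(q, rot, "full")$score, base, tolerance = 1e-6)
    # moving the query rigidly moves features and exclusion spheres together
    qrot <- q
    qrot$features[, c("x", "y", "z")] <-
      kappascreen:::.apply_transform(as.matrix(q$features[, c("x", "y", "z")]), R, t)
    qrot$exclusion_volumes[, c("x", "y", "z")] <-
      kappascreen:::.apply_transform(as.matrix(q$exclusion_volumes[, c("x", "y", "z")]), R, t)
    expect_equal(match_pharmacophore(qrot, ref, "full")$score, base, tolerance = 1e-6)
  }
})

test_that("an exclusion sphere on a ligand atom causes a clash rejection", {
  ref <- reference_molecule()
  q <- reference_query()
  atom1 <- ref$conformers[[1]][1, ]
  qx <- pharmacophore_query(q$features,
                            data.frame(x = atom1[1], y = atom1[2], z = atom1[3],
                                       radius = 1.0))
  m <- match_pharmacophore(qx, ref, "full")
  expect_true(m$clash)
  sc <- screen_pharmacophore(qx, list(ref), "full")
  expect_equal(nrow(sc), 0L)  # screening mode rejects clashing poses
})

test_that("pruned search equals exhaustive brute-force assignment enumeration", {
  fx <- small_fixture()
  mols <- c(fx$actives[1:3], lapply(fx$universe[1:5], ensure_conformer))
  queries <- list(
    toy_query(),
    toy_query(kinds = c("HBA", "HBA", "HY"),
              centers = rbind(c(0, 0, 0), c(4, 1, 0), c(2, -3, 1))),
    drop_feature(drop_feature(reference_query(), "C2-HBA"), "HY-furan")
  )
  for (q in queries) {
    for (mode in c("full", "partial")) {
      for (mol in mols) {
        feats <- perceive_features(mol, 1L)
        if (nrow(feats) > 6L) next
        expected <- brute_force_match(q, feats, mode)
        got <- match_pharmacophore(q, mol, mode)
        if (is.null(expected)) {
          expect_true(is.null(got) || got$clash, info = mol$id)
        } else {
          expect_false(is.null(got), info = mol$id)
          expect_equal(got$score, expected, tolerance = 1e-6, info = mol$id)
        }
      }
    }
  }
})

test_that("screen output is ordered, tie-broken by id, and thresholded at zero", {
  fx <- small_fixture()
  q <- reference_query()
  lib <- c(fx$actives, lapply(fx$universe[1:10], ensure_conformer))
  sc_full <- screen_pharmacophore(q, lib, "full")
  expect_true(all(diff(sc_full$score) <= 0))
  expect_true(all(sc_full$n_matched == 6L))
  sc_part <- screen_pharmacophore(q, lib, "partial")
  expect_equal(nrow(sc_part), length(lib))  # partial mode scores everything
  # score > 0 exactly for molecules with >= 1 matched feature
  expect_equal(sc_part$score > 0, sc_part$n_matched >= 1L)
  # ties broken by id ascending
  tied <- sc_part[sc_part$score == max(sc_part$score), ]
  expect_equal(tied$id, sort(tied$id))
})

test_that("monotonicity: exclusion volumes only shrink, dropping features only grows the hit set", {
  fx <- small_fixture()
  lib <- fx$actives
  q <- reference_query()
  n0 <- nrow(screen_pharmacophore(q, lib, "full"))
  # extra exclusion sphere never increases accepted molecules
  q_more <- pharmacophore_query(q$features,
                                rbind(q$exclusion_volumes,
                                      data.frame(x = 0, y = 0, z = 0, radius = 1.0)))
  expect_lte(nrow(screen_pharmacophore(q_more, lib, "full")), n0)
  # dropping a required feature never decreases accepted molecules
  q_less <- drop_feature(q, "C2-HBA")
  expect_gte(nrow(screen_pharmacophore(q_less, lib, "full")), n0)
})
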
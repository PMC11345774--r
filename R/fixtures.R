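#' Fixture specification for synthetic screening inputs
#'
#' Describes the synthetic data the pipeline fixtures emulate: an active set
#' of nonbasic, query-satisfying molecules in the 300-500 Da window and a
#' larger property-matched decoy universe with scrambled 3D geometry. The
#' default active-to-decoy ratio is 1:50.
#'
#' @param seed integer; all fixture randomness derives from it, and identical
#'   specs give byte-identical outputs.
#' @param n_actives number of active molecules (>= 1, <= 192 scaffold
#'   variants).
#' @param decoys_per_active decoys requested per active (>= 0).
#' @param conformers_per_molecule conformers built per active (>= 1).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_actives = 82L, decoys_per_active = 50L,
                         conformers_per_molecule = 1L) {
  if (n_actives < 1L) stop("n_actives must be >= 1")
  if (decoys_per_active < 0L) stop("decoys_per_active must be >= 0")
  if (conformers_per_molecule < 1L) stop("conformers_per_molecule must be >= 1")
  if (n_actives > 192L) stop("at most 192 distinct active scaffold variants are available")
  structure(list(seed = as.integer(seed), n_actives = as.integer(n_actives),
                 decoys_per_active = as.integer(decoys_per_active),
                 conformers_per_molecule = as.integer(conformers_per_molecule)),
            class = "fixture_spec")
}

#' Reference pharmacophore query ("SalA-like")
#'
#' Builds the screening hypothesis from the unmodified scaffold template: the
#' three carbonyl hydrogen-bond acceptors (labelled `C1-HBA`, `C2-HBA`,
#' `C4-HBA` after the substituent positions of the Salvinorin A carbonyls
#' they emulate) and the three hydrophobic islands (`HY-core`, `HY-acetoxy`,
#' `HY-furan`), each as a tolerance sphere, plus an exclusion-volume coat
#' above and below the query plane. The coordinates are a geometric stand-in,
#' not the published model's.
#'
#' @param tolerance feature sphere radius in Angstrom.
#' @param exclusion_radius exclusion sphere radius in Angstrom.
#' @param reduced drop the `C2-HBA` feature (the query-reduction found to
#'   improve screening performance).
#' @return a [pharmacophore_query].
#' @export
reference_query <- function(tolerance = 1.5, exclusion_radius = 1.0, reduced = FALSE) {
  ref <- reference_molecule()
  feats <- perceive_features(ref, 1L)
  anchors <- ref$anchor_atoms$hba
  bm <- .bond_order_matrix(ref)
  hba_rows <- which(feats$kind == "HBA")
  hba_label <- vapply(hba_rows, function(i) {
    a <- feats$source_atoms[[i]][1L]
    names(anchors)[match(a, anchors)]
  }, "")
  # each HBA's carbonyl carbon sits in one HY island; label islands through it
  hy_rows <- which(feats$kind == "HY")
  carbonyl_c <- vapply(anchors, function(o) which(bm[o, ] >= 2)[1L], 0L)
  hy_label <- vapply(hy_rows, function(i) {
    atoms <- feats$source_atoms[[i]]
    if (carbonyl_c[["C1"]] %in% atoms) "HY-core"
    else if (carbonyl_c[["C2"]] %in% atoms) "HY-acetoxy"
    else "HY-furan"
  }, "")
  rows <- c(hba_rows, hy_rows)
  features <- data.frame(
    kind = feats$kind[rows],
    x = feats$x[rows], y = feats$y[rows], z = feats$z[rows],
    radius = tolerance,
    label = c(paste0(hba_label, "-HBA"), hy_label)
  )
  ex_centers <- features[, c("x", "y", "z")]
  exclusion <- rbind(
    data.frame(x = ex_centers$x, y = ex_centers$y, z = 4.5, radius = exclusion_radius),
    data.frame(x = ex_centers$x, y = ex_centers$y, z = -4.5, radius = exclusion_radius)
  )
  q <- pharmacophore_query(features, exclusion)
  if (reduced) q <- drop_feature(q, "C2-HBA")
  q
}

#' Salvinorin A connection table (SMILES, no stereo descriptors)
#'
#' The nonbasic natural-product KOR agonist whose modelled binding mode seeds
#' the screening query: methyl 9-acetoxy-2-(furan-3-yl)-6a,10b-dimethyl-
#' 4,10-dioxo-dodecahydro-2H-benzo\[f\]isochromene-7-carboxylate (C23H28O8,
#' 432.46 Da). Stereocenters are omitted; the filters and descriptors in this
#' package are stereo-agnostic.
#' @return a SMILES string.
#' @export
salvinorin_a_smiles <- function() {
  "O=C1OC(c2ccoc2)CC3(C)C1CCC1(C)C3C(=O)C(OC(C)=O)CC1C(=O)OC"
}

#' The unmodified scaffold template molecule
#' @return a [molecule_record] with one conformer at template coordinates.
#' @export
reference_molecule <- function() {
  choices <- stats::setNames(as.list(rep(1L, length(.ACTIVE_SITES))), names(.ACTIVE_SITES))
  .build_salvinoid("SALREF", choices)
}

#' Generate the synthetic active set and decoy universe
#'
#' Actives are decorated variants of the rigid scaffold template (nonbasic,
#' MW 300-500 Da, each satisfying [reference_query] at full-match settings by
#' construction). The decoy universe is a combinatorial family of substituted
#' aromatic and alicyclic esters/ketones/ethers spanning the same property
#' ranges but with different topology; universe conformers are scrambled
#' folds assigned lazily via [ensure_conformer].
#'
#' @param spec a [fixture_spec].
#' @return list with elements `actives` and `universe` (lists of
#'   [molecule_record]s with descriptors attached).
#' @export
make_compound_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  grid <- .active_variant_grid()
  actives <- lapply(seq_len(spec$n_actives), function(i) {
    choices <- as.list(stats::setNames(as.integer(grid[i, ]), names(.ACTIVE_SITES)))
    mol <- .build_salvinoid(sprintf("ACT%03d", i), choices,
                            jitter_sd = 0.08, seed = spec$seed * 1000L + i)
    if (spec$conformers_per_molecule > 1L) {
      base <- mol$conformers[[1L]]
      for (k in seq_len(spec$conformers_per_molecule - 1L)) {
        extra <- with_private_rng(spec$seed * 1000L + i + 500L * k,
                                  base + matrix(stats::rnorm(length(base), 0, 0.06),
                                                nrow(base), 3L))
        mol$conformers[[k + 1L]] <- extra
      }
    }
    mol
  })
  actives <- attach_descriptors(actives)
  universe <- .decoy_universe(spec, descriptor_table(actives))
  list(actives = actives, universe = universe)
}

# Combinatorial decoy candidate family: a benzene or cyclohexane core bearing
# an ester arm, a ketone arm and an ether arm of varying lengths, an optional
# fourth substituent and a variable ether cap, in two substitution-pattern
# isomers. Same descriptor envelope as the actives (3 HBA, 0 HBD, neutral),
# different topology. Candidates are pruned analytically (exact formula MW,
# rotatable-bond estimate) to the actives' property windows before any
# conversion, then capped to roughly twice the requested decoy count.
.decoy_universe <- function(spec, active_desc) {
  caps <- c(Me = "C", Et = "CC", iPr = "C(C)C", tBu = "C(C)(C)C", Cy = "C1CCCCC1")
  cap_atoms <- list(Me = c(C = 1, H = 3), Et = c(C = 2, H = 5), iPr = c(C = 3, H = 7),
                    tBu = c(C = 4, H = 9), Cy = c(C = 6, H = 11))
  extra_levels <- c("", "F", "Cl", "Br", "C", "OC")
  extra_masses <- c(0, 18.998, 35.453, 79.904, 12.011 + 3 * 1.008, 15.999 + 12.011 + 3 * 1.008)
  abc <- expand.grid(a = 0:7, b = 0:7, c = 0:7)
  abc <- abc[abc$a + abc$b + abc$c <= 9L, , drop = FALSE]
  rest <- expand.grid(core = c("arom", "ali"),
                      extra = extra_levels,
                      extra2 = c("", "F", "Cl", "Br", "OC"),
                      cap = names(caps),
                      arm2 = c("ket", "est"),
                      pat = c(1L, 2L),
                      stringsAsFactors = FALSE)
  combos <- merge(abc, rest, by = NULL)
  mC <- 12.011; mO <- 15.999; mH <- 1.008
  nC <- with(combos, 6 + (a + 2) + (b + 2) + c +
               vapply(cap, function(k) cap_atoms[[k]][["C"]], 0))
  nH <- with(combos, ifelse(core == "arom", 3, 9) - (extra != "") - (extra2 != "") +
               (2 * a + 3) + (2 * b + 3) + 2 * c +
               vapply(cap, function(k) cap_atoms[[k]][["H"]], 0))
  mw <- nC * mC + 4 * mO + nH * mH + extra_masses[match(combos$extra, extra_levels)] +
    extra_masses[match(combos$extra2, extra_levels)] +
    ifelse(combos$arm2 == "est", mO, 0)
  rotb_est <- with(combos, 4 + a + b + c + (cap != "Me") +
                     (extra == "OC") + (extra2 == "OC") + (arm2 == "est"))
  hba_est <- with(combos, 3 + (extra == "OC") + (extra2 == "OC"))
  # additive logP estimate for this family, calibrated against Open Babel's
  # atomic-contribution values (R^2 ~ 0.997, sigma ~ 0.09 within the family)
  extra_logp <- c(0, 0.050, 0.430, 0.571, 0.282, -0.177)
  logp_est <- with(combos, 2.394 + 0.386 * (a + b + c) + 0.745 * (core == "arom") +
                     extra_logp[match(extra, extra_levels)] +
                     extra_logp[match(extra2, extra_levels)] +
                     c(Me = -1.583, Et = -1.189, iPr = -0.929, tBu = -0.536, Cy = 0)[cap] +
                     0.425 * (arm2 == "ket"))
  lo <- min(active_desc$MW) - 25; hi <- max(active_desc$MW) + 25
  rlo <- min(active_desc$rotatable_bonds) - 3; rhi <- max(active_desc$rotatable_bonds) + 3
  plo <- min(active_desc$logP) - 0.75; phi <- max(active_desc$logP) + 0.75
  keep <- mw >= lo & mw <= hi & rotb_est >= rlo & rotb_est <= rhi &
    logp_est >= plo & logp_est <= phi &
    hba_est <= max(active_desc$hba) + 1L
  combos <- combos[keep, , drop = FALSE]

  chain <- function(n) vapply(n, function(k) paste(rep("C", k), collapse = ""), "")
  smi <- with(combos, {
    r1 <- paste0("OC(=O)", chain(a), "C")
    r2 <- paste0(ifelse(arm2 == "est", "C(=O)O", "C(=O)"), chain(b), "C")
    r3 <- paste0("O", chain(c), caps[cap])
    x <- ifelse(extra == "", "", sprintf("(%s)", extra))
    y <- ifelse(extra2 == "", "", sprintf("(%s)", extra2))
    ifelse(core == "arom",
           ifelse(pat == 1L,
                  sprintf("c2c(%s)c%sc(%s)c%sc2%s", r1, y, r2, x, r3),
                  sprintf("c2c(%s)c(%s)c%sc%sc2%s", r1, r2, y, x, r3)),
           ifelse(pat == 1L,
                  sprintf("C2C(%s)C%sC(%s)C%sC2%s", r1, y, r2, x, r3),
                  sprintf("C2C(%s)C(%s)C%sC%sC2%s", r1, r2, y, x, r3)))
  })
  keep <- !duplicated(smi)
  smi <- smi[keep]
  n_needed <- spec$n_actives * max(spec$decoys_per_active, 1L)
  cap_size <- max(3L * n_needed + 600L, 1500L)
  if (length(smi) > cap_size) {
    idx <- with_private_rng(spec$seed * 31L + 7L,
                            sort(sample.int(length(smi), cap_size)))
    smi <- smi[idx]
  }
  ids <- sprintf("UNV%05d", seq_along(smi))
  recs <- parse_smiles(smi, ids)
  recs <- attach_descriptors(recs)
  # lazily embedded scrambled conformers, seeded off the fixture seed
  for (i in seq_along(recs)) recs[[i]]$embed_seed <- spec$seed * 7919L + i
  recs
}

#' Ensure a molecule has a conformer
#'
#' Molecules from the fixture universe carry an `embed_seed` and receive a
#' deterministic scrambled fold on first use; molecules read from 3D SDF keep
#' their coordinates.
#' @param mol a [molecule_record].
#' @return the record with at least one conformer.
#' @export
ensure_conformer <- function(mol) {
  if (length(mol$conformers)) return(mol)
  seed <- if (!is.null(mol$embed_seed)) mol$embed_seed
          else sum(utf8ToInt(mol$id)) * 131L
  toy_embed(mol, seed)
}

#' The partially specified validation rank list printed for the shape screen
#'
#' The shape-based validation screen of 82 actives against 4100 decoys placed
#' 79 actives within the top 87 molecules; the first decoys appeared at
#' positions 59, 67, 74, 79 and 83-86, and the three straggler actives ranked
#' 702, 848 and 1476.
#'
#' @return an object of class `partial_rank_list` with fields `total_actives`,
#'   `total_decoys`, `listed_decoy_ranks`, `straggler_active_ranks`,
#'   `top_block_size`.
#' @export
paper_rank_fixture <- function() {
  partial_rank_list(total_actives = 82L, total_decoys = 4100L,
                    listed_decoy_ranks = c(59L, 67L, 74L, 79L, 83L, 84L, 85L, 86L),
                    straggler_active_ranks = c(702L, 848L, 1476L),
                    top_block_size = 87L)
}

#' Construct a partial rank list
#'
#' A ranked screen known only through its printed summary: every molecule in
#' the top block is an active except at the listed decoy ranks, the
#' straggler actives sit at their listed ranks below the block, and all other
#' positions are decoys.
#'
#' @param total_actives,total_decoys class totals.
#' @param listed_decoy_ranks 1-based ranks of decoys inside the top block,
#'   strictly increasing.
#' @param straggler_active_ranks 1-based ranks of actives below the block.
#' @param top_block_size size of the fully-characterized top block.
#' @return an object of class `partial_rank_list`.
#' @export
partial_rank_list <- function(total_actives, total_decoys, listed_decoy_ranks,
                              straggler_active_ranks, top_block_size) {
  if (is.unsorted(listed_decoy_ranks, strictly = TRUE))
    stop("listed decoy ranks must be strictly increasing")
  if (length(straggler_active_ranks) && any(straggler_active_ranks <= top_block_size))
    stop("straggler active ranks must lie below the top block")
  in_block <- sum(listed_decoy_ranks <= top_block_size)
  implied_actives <- top_block_size - in_block + length(straggler_active_ranks)
  if (implied_actives != total_actives)
    stop(sprintf("inconsistent rank list: %d actives implied, %d declared",
                 implied_actives, total_actives))
  n <- total_actives + total_decoys
  if (any(c(listed_decoy_ranks, straggler_active_ranks) > n))
    stop("ranks exceed list length")
  structure(list(total_actives = as.integer(total_actives),
                 total_decoys = as.integer(total_decoys),
                 listed_decoy_ranks = as.integer(listed_decoy_ranks),
                 straggler_active_ranks = as.integer(straggler_active_ranks),
                 top_block_size = as.integer(top_block_size)),
            class = "partial_rank_list")
}

#' Materialize the label vector of a partial rank list
#' @param p a [partial_rank_list].
#' @return character vector (`"active"`/`"decoy"`) of length
#'   `total_actives + total_decoys`, in rank order.
#' @export
materialize_labels <- function(p) {
  stopifnot(inherits(p, "partial_rank_list"))
  n <- p$total_actives + p$total_decoys
  lab <- rep("decoy", n)
  lab[seq_len(p$top_block_size)] <- "active"
  lab[p$listed_decoy_ranks[p$listed_decoy_ranks <= p$top_block_size]] <- "decoy"
  lab[p$straggler_active_ranks] <- "active"
  if (sum(lab == "active") != p$total_actives)
    stop("internal inconsistency while materializing rank list")
  lab
}

# ---- pocket fixture --------------------------------------------------------

#' Build a minimal receptor-pocket fixture with a posed ligand
#'
#' Writes a small PDB pocket containing residues labelled Q115, V118, Y139,
#' Y312 and Y313 (the positions highlighted as crucial for Salvinorin A
#' affinity in mutagenesis work), with the Y312 hydroxyl within hydrogen-bond
#' distance of the posed ligand's ketone oxygen and a V118 methyl in
#' hydrophobic contact with the ligand core. Coordinates are an invented
#' minimal set in the same frame as the bundled pose; only contact-detection
#' geometry is meaningful.
#'
#' @param dir output directory.
#' @return list with `pdb` (receptor path), `sdf` (pose path) and `pose`
#'   (the posed [molecule_record]).
#' @export
make_pocket_fixture <- function(dir = tempdir()) {
  lig <- reference_molecule()
  lig$id <- "POSE1"
  xyz <- lig$conformers[[1L]]
  centroid <- colMeans(xyz)
  o7 <- lig$anchor_atoms$hba[["C1"]]

  res <- list()
  add_res <- function(resid, resno, elety, coords) {
    res[[length(res) + 1L]] <<- list(resid = resid, resno = resno,
                                     elety = elety, coords = coords)
  }
  stub <- function(origin, dir_vec) {
    # tiny backbone stub: CA at origin + 1.5*dir, N and C flanking
    d <- dir_vec / sqrt(sum(dir_vec^2))
    ca <- origin + 1.5 * d
    rbind(N = ca + c(1.2, 0.3, 0.2), CA = ca, C = ca + c(-1.1, 0.6, -0.3),
          O = ca + c(-1.5, 1.6, -0.4))
  }
  # Y312: hydroxyl O 2.85 A from the ligand ketone O (hydrogen bond)
  oh <- xyz[o7, ] + c(1.70, 1.70, 1.35)
  outward <- (oh - centroid) / sqrt(sum((oh - centroid)^2))
  ring_c <- oh + outward * 1.4
  bb <- stub(ring_c + outward * 2.8, outward)
  add_res("TYR", 312L, c("N", "CA", "C", "O", "CB", "CG", "CZ", "OH"),
          rbind(bb, CB = ring_c + outward * 2.2, CG = ring_c + outward * 1.4,
                CZ = ring_c, OH = oh))
  # V118: CG1 within 4.5 A of a core ring carbon (hydrophobic contact)
  core_c <- xyz[2L, ]
  cg1 <- core_c + c(0.0, -2.6, 2.6)
  outward2 <- (cg1 - centroid) / sqrt(sum((cg1 - centroid)^2))
  bb2 <- stub(cg1 + outward2 * 2.5, outward2)
  add_res("VAL", 118L, c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
          rbind(bb2, CB = cg1 + outward2 * 1.5, CG1 = cg1,
                CG2 = cg1 + outward2 * 1.5 + c(1.4, 0, 0)))
  # remaining pocket residues: present but out of contact range (> 5 A)
  far <- function(offset) sweep(stub(centroid + offset, offset), 1L, 0, `+`)
  add_res("GLN", 115L, c("N", "CA", "C", "O", "CD", "OE1", "NE2"), {
    base <- centroid + c(0, 9, 4)
    rbind(far(c(0, 9, 4)), CD = base, OE1 = base + c(0.6, 1.0, 0), NE2 = base + c(-0.9, 0.9, 0))
  })
  add_res("TYR", 139L, c("N", "CA", "C", "O", "CZ", "OH"), {
    base <- centroid + c(-9, 2, 5)
    rbind(far(c(-9, 2, 5)), CZ = base, OH = base + c(0.8, 0.9, 0.4))
  })
  add_res("TYR", 313L, c("N", "CA", "C", "O", "CZ", "OH"), {
    base <- centroid + c(8, -4, 5)
    rbind(far(c(8, -4, 5)), CZ = base, OH = base + c(-0.5, 1.1, 0.3))
  })

  elety <- unlist(lapply(res, `[[`, "elety"))
  coords <- do.call(rbind, lapply(res, `[[`, "coords"))
  resid <- unlist(lapply(res, function(r) rep(r$resid, length(r$elety))))
  resno <- unlist(lapply(res, function(r) rep(r$resno, length(r$elety))))
  pdb_path <- file.path(dir, "pocket_synthetic.pdb")
  bio3d::write.pdb(file = pdb_path, xyz = as.numeric(t(coords)),
                   type = rep("ATOM", length(elety)), resno = resno,
                   resid = resid, eleno = seq_along(elety), elety = elety,
                   chain = rep("A", length(elety)))
  sdf_path <- file.path(dir, "pose_synthetic.sdf")
  write_sdf_library(list(lig), sdf_path)
  list(pdb = pdb_path, sdf = sdf_path, pose = lig)
}
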
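# Programmatic molecule construction for the synthetic-data module.
#
# Fixture chemistry is a hand-curated internal scaffold family: a rigid
# "salvinoid-like" template (cyclohexanone core, two ester arms, one ending in
# a furan) whose three carbonyl oxygens and three carbon islands sit at fixed
# template coordinates. Variants decorate sites away from the feature
# centroids, so every active satisfies the reference pharmacophore query by
# construction. Geometry is idealized fragment geometry, not a force-field
# minimum; only feature placement and gross shape matter downstream.

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character()
  env$charge <- integer()
  env$xyz <- matrix(numeric(), 0L, 3L)
  env$bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  env
}

.bld_atom <- function(b, element, xyz, charge = 0L) {
  b$element <- c(b$element, element)
  b$charge <- c(b$charge, as.integer(charge))
  b$xyz <- rbind(b$xyz, as.numeric(xyz))
  length(b$element)
}

.bld_bond <- function(b, i, j, order = 1) {
  b$bonds <- rbind(b$bonds, data.frame(a1 = i, a2 = j, order = order))
  invisible(NULL)
}

.bld_record <- function(b, id) {
  atoms <- data.frame(element = b$element, charge = b$charge, nH = 0L,
                      stringsAsFactors = FALSE)
  # implicit H from valence
  bos <- numeric(nrow(atoms))
  for (k in seq_len(nrow(b$bonds))) {
    bos[b$bonds$a1[k]] <- bos[b$bonds$a1[k]] + b$bonds$order[k]
    bos[b$bonds$a2[k]] <- bos[b$bonds$a2[k]] + b$bonds$order[k]
  }
  atoms$nH <- implicit_h_count(atoms$element, atoms$charge, bos)
  molecule_record(id = id, atoms = atoms, bonds = b$bonds,
                  conformers = list(unname(b$xyz)))
}

# ---- the salvinoid-like active template ------------------------------------

# Decoration choices per site; index 1 is always "unmodified".
.ACTIVE_SITES <- list(
  ringA_c2 = c("H", "F", "Cl", "C"),
  ringA_c4 = c("H", "F", "Cl", "C"),
  ringA_c6 = c("H", "C", "F"),
  furan_me = c("H", "C"),
  branch_ethyl = c("no", "yes")
)

# Build one active variant. `choices` is a named integer vector indexing
# .ACTIVE_SITES; `jitter` a per-molecule coordinate perturbation (Angstrom).
.build_salvinoid <- function(id, choices, jitter_sd = 0, seed = NULL) {
  b <- .new_builder()
  u <- function(angle) c(cos(angle), sin(angle), 0)

  # ring A: cyclohexanone, hexagon in the xy-plane
  ringA_xyz <- .polygon_coords(c(0, 0, 0), 1.54, 6L)
  ringA <- vapply(seq_len(6L), function(i) .bld_atom(b, "C", ringA_xyz[i, ]), 0L)
  for (i in seq_len(6L)) .bld_bond(b, ringA[i], ringA[i %% 6L + 1L], 1)
  angA <- 2 * pi * (seq_len(6L) - 1L) / 6L

  # C1 ketone -> HBA "C1"
  o7 <- .bld_atom(b, "O", ringA_xyz[1L, ] + 1.23 * u(angA[1L]))
  .bld_bond(b, ringA[1L], o7, 2)

  # C3 ester arm -> gem-dimethyl branch (HY island B, HBA "C2 analogue")
  o8 <- .bld_atom(b, "O", ringA_xyz[3L, ] + 1.43 * u(angA[3L]))
  .bld_bond(b, ringA[3L], o8, 1)
  c9 <- .bld_atom(b, "C", b$xyz[o8, ] + c(0.0, 1.40, 0.25))
  .bld_bond(b, o8, c9, 1)
  o10 <- .bld_atom(b, "O", b$xyz[c9, ] + c(1.15, 0.45, 0.0))
  .bld_bond(b, c9, o10, 2)
  c11 <- .bld_atom(b, "C", b$xyz[c9, ] + c(-0.95, 1.20, 0.0))
  .bld_bond(b, c9, c11, 1)
  c12 <- .bld_atom(b, "C", b$xyz[c11, ] + c(0.0, 1.50, 0.30))
  .bld_bond(b, c11, c12, 1)
  me1 <- .bld_atom(b, "C", b$xyz[c12, ] + c(-1.45, 0.40, 0.0))
  .bld_bond(b, c12, me1, 1)
  me2 <- .bld_atom(b, "C", b$xyz[c12, ] + c(0.70, 0.60, 1.25))
  .bld_bond(b, c12, me2, 1)

  # C5 ester arm -> furan (HY island C, HBA "C4 analogue")
  c13 <- .bld_atom(b, "C", ringA_xyz[5L, ] + 1.54 * u(angA[5L]))
  .bld_bond(b, ringA[5L], c13, 1)
  o14 <- .bld_atom(b, "O", b$xyz[c13, ] + c(-0.50, -1.30, 0.20))
  .bld_bond(b, c13, o14, 1)
  c15 <- .bld_atom(b, "C", b$xyz[o14, ] + c(-1.25, -0.70, 0.0))
  .bld_bond(b, o14, c15, 1)
  o16 <- .bld_atom(b, "O", b$xyz[c15, ] + c(-0.30, -1.22, 0.0))
  .bld_bond(b, c15, o16, 2)
  c17 <- .bld_atom(b, "C", b$xyz[c15, ] + c(-1.40, 0.55, 0.20))
  .bld_bond(b, c15, c17, 1)
  fur_center <- b$xyz[c17, ] + c(-2.05, 0.35, 0.0)
  fur_xyz <- .polygon_coords(fur_center, 1.17, 5L, z_offset = 0,
                             start_angle = atan2(b$xyz[c17, 2] - fur_center[2],
                                                 b$xyz[c17, 1] - fur_center[1]))
  fur <- vapply(seq_len(5L), function(i) {
    .bld_atom(b, if (i == 5L) "O" else "C", fur_xyz[i, ])
  }, 0L)
  .bld_bond(b, c17, fur[1L], 1)
  .bld_bond(b, fur[1L], fur[2L], 2)
  .bld_bond(b, fur[2L], fur[3L], 1)
  .bld_bond(b, fur[3L], fur[4L], 2)
  .bld_bond(b, fur[4L], fur[5L], 1)
  .bld_bond(b, fur[5L], fur[1L], 1)

  # decorations
  dec <- function(site, anchor, dir, dist_c = 1.54, dist_hal = 1.65) {
    ch <- .ACTIVE_SITES[[site]][choices[[site]]]
    if (ch == "H" || ch == "no") return(invisible(NULL))
    if (ch %in% c("F", "Cl")) {
      a <- .bld_atom(b, ch, anchor_xyz(anchor) + dist_hal * dir)
      .bld_bond(b, anchor, a, 1)
    } else if (ch == "C") {
      a <- .bld_atom(b, "C", anchor_xyz(anchor) + dist_c * dir)
      .bld_bond(b, anchor, a, 1)
    }
    invisible(NULL)
  }
  anchor_xyz <- function(i) b$xyz[i, ]
  dec("ringA_c2", ringA[2L], u(angA[2L]))
  dec("ringA_c4", ringA[4L], u(angA[4L]))
  dec("ringA_c6", ringA[6L], u(angA[6L]))
  dec("furan_me", fur[3L], c(-0.6, -0.8, 0.0))
  if (.ACTIVE_SITES$branch_ethyl[choices[["branch_ethyl"]]] == "yes") {
    a <- .bld_atom(b, "C", b$xyz[me2, ] + c(0.6, 0.4, 1.3))
    .bld_bond(b, me2, a, 1)
  }

  if (jitter_sd > 0) {
    stopifnot(!is.null(seed))
    b$xyz <- with_private_rng(seed, b$xyz + matrix(stats::rnorm(length(b$xyz), 0, jitter_sd),
                                                   nrow(b$xyz), 3L))
  }
  rec <- .bld_record(b, id)
  rec$anchor_atoms <- list(hba = c(C1 = o7, C2 = o10, C4 = o16))
  rec
}

# all decoration combinations, deterministically ordered
.active_variant_grid <- function() {
  g <- expand.grid(lapply(.ACTIVE_SITES, seq_along), KEEP.OUT.ATTRS = FALSE)
  # unmodified template first, then increasing decoration count
  g[order(rowSums(g != 1L), g$ringA_c2, g$ringA_c4, g$ringA_c6, g$furan_me, g$branch_ethyl), ]
}

# ---- toy conformer embedding (for decoys / SMILES-only molecules) ----------

# Deterministic pseudo-random 3D fold of a molecular graph: atoms placed in
# BFS order at bonded distance from their parent, avoiding close contacts.
# These are "scrambled" geometries - deliberately not physical conformations.
toy_embed <- function(mol, seed = 1L) {
  n <- n_heavy(mol)
  adj <- .adjacency(mol)
  with_private_rng(seed, {
    xyz <- matrix(NA_real_, n, 3L)
    placed <- logical(n)
    for (root in seq_len(n)) {
      if (placed[root]) next
      xyz[root, ] <- if (any(placed)) colMeans(xyz[placed, , drop = FALSE]) + 8 * .runif_unit() else c(0, 0, 0)
      placed[root] <- TRUE
      queue <- root
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) {
          if (placed[w]) next
          for (try in seq_len(60L)) {
            cand <- xyz[v, ] + 1.5 * .runif_unit()
            d <- sqrt(rowSums(sweep(xyz[placed, , drop = FALSE], 2L, cand)^2))
            if (all(d >= 1.15)) break
          }
          xyz[w, ] <- cand
          placed[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    mol$conformers <- list(unname(xyz))
    mol
  })
}
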
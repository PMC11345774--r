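#' Pharmacophore feature perception
#'
#' Perceives interaction features on one conformer of a molecule. The rules
#' are a declared convention mirroring common pharmacophore toolkits:
#'
#' * **HBA** — acceptor-capable N/O: carbonyl O, hydroxyl O, sp3 ether O
#'   (excluding the ester sp3 O and aromatic-ring O such as furan), nitrile N,
#'   and aromatic N without H. Positively charged atoms and amide N never
#'   accept.
#' * **HBD** — N or O bearing at least one hydrogen (implicit or explicit),
#'   not positively charged oxygen chemistry aside.
#' * **HY** — centroid of each connected cluster (size >= 2) of apolar atoms
#'   (carbon, sulfide S, halogens), excluding atoms adjacent to formally
#'   charged atoms. Heteroatoms break clusters, so hydrophobic fragments
#'   separated by esters/ethers yield distinct features, and connected
#'   components merge fused rings into a single feature.
#' * **AR** — centroid of each aromatic ring.
#'
#' @param mol a [molecule_record].
#' @param conformer_index which conformer to place features on.
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `weight` and a list
#'   column `source_atoms`.
#' @export
perceive_features <- function(mol, conformer_index = 1L) {
  if (conformer_index < 1L || conformer_index > length(mol$conformers))
    stop("conformer ", conformer_index, " does not exist for molecule ", mol$id)
  xyz <- mol$conformers[[conformer_index]]
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  nH <- mol$atoms$nH
  bm <- .bond_order_matrix(mol)
  adj <- .adjacency(mol)
  arom <- aromatic_atoms(mol)
  n <- n_heavy(mol)

  has_double_to <- function(i, target_el) {
    any(bm[i, ] >= 2 & el == target_el)
  }
  neighbours_el <- function(i) el[adj[[i]]]

  feats <- list()
  add <- function(kind, atoms_idx) {
    ctr <- colMeans(xyz[atoms_idx, , drop = FALSE])
    feats[[length(feats) + 1L]] <<- list(kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
                                         weight = length(atoms_idx), source_atoms = atoms_idx)
  }

  is_carbonyl_O <- function(i) el[i] == "O" && any(bm[i, ] >= 2 & el == "C")
  is_amide_N <- function(i) {
    if (el[i] != "N") return(FALSE)
    any(vapply(adj[[i]], function(c) el[c] == "C" && any(bm[c, ] >= 2 & el == "O"), logical(1)))
  }
  is_ester_sp3_O <- function(i) {
    if (el[i] != "O" || any(bm[i, ] >= 2)) return(FALSE)
    # single-bonded O attached to a carbonyl carbon
    any(vapply(adj[[i]], function(c) el[c] == "C" && any(bm[c, ] >= 2 & el == "O"), logical(1)))
  }

  # HBA
  for (i in seq_len(n)) {
    if (chg[i] > 0L) next
    ok <- FALSE
    if (el[i] == "O") {
      if (is_carbonyl_O(i)) ok <- TRUE
      else if (!arom[i] && nH[i] >= 1L) ok <- TRUE                    # hydroxyl
      else if (!arom[i] && nH[i] == 0L && !is_ester_sp3_O(i) &&
               length(adj[[i]]) == 2L) ok <- TRUE                     # sp3 ether
    } else if (el[i] == "N") {
      if (sum(bm[i, ]) >= 3 && any(bm[i, ] == 3)) ok <- TRUE          # nitrile
      else if (arom[i] && nH[i] == 0L && !is_amide_N(i)) ok <- TRUE   # pyridine-like
    }
    if (ok) add("HBA", i)
  }

  # HBD
  for (i in seq_len(n)) {
    if (el[i] %in% c("N", "O") && nH[i] >= 1L && chg[i] <= 0L) add("HBD", i)
  }

  # HY: connected apolar clusters
  next_to_charged <- vapply(seq_len(n), function(i) any(chg[adj[[i]]] != 0L), logical(1))
  apolar <- vapply(seq_len(n), function(i) {
    if (chg[i] != 0L || next_to_charged[i]) return(FALSE)
    if (el[i] == "C") return(TRUE)
    if (el[i] == "S") return(!any(bm[i, ] >= 2) && !any(neighbours_el(i) == "O"))
    el[i] %in% .HALOGENS
  }, logical(1))
  if (any(apolar)) {
    comp <- rep(NA_integer_, n); cid <- 0L
    for (s in which(apolar)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (apolar[w] && is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
    for (k in seq_len(cid)) {
      members <- which(comp == k)
      if (length(members) >= 2L) add("HY", members)
    }
  }

  # AR: aromatic ring centroids
  if (length(mol$rings)) {
    for (r in seq_along(mol$rings)) if (mol$aromatic[r]) add("AR", mol$rings[[r]])
  }

  if (!length(feats)) {
    return(data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
                      weight = integer(), source_atoms = I(list())))
  }
  data.frame(
    kind = vapply(feats, `[[`, "", "kind"),
    x = vapply(feats, `[[`, 0, "x"),
    y = vapply(feats, `[[`, 0, "y"),
    z = vapply(feats, `[[`, 0, "z"),
    weight = vapply(feats, function(f) as.integer(f$weight), 0L),
    source_atoms = I(lapply(feats, `[[`, "source_atoms"))
  )
}

#' Charge and basicity filter
#'
#' Classifies a molecule as `"pass"` (nonbasic, neutral), `"fail_charged"`
#' (any nonzero formal charge), or `"fail_basic"` (carries an amine predicted
#' protonated at physiological pH: aliphatic primary/secondary/tertiary amine,
#' amidine, or guanidine). Amide N, anilinic N, and aromatic-ring N do not
#' count as basic. Pure function of the connection table.
#'
#' @param mol a [molecule_record].
#' @return one of `"pass"`, `"fail_charged"`, `"fail_basic"`.
#' @export
nonbasic_filter <- function(mol) {
  if (any(mol$atoms$charge != 0L) || net_formal_charge(mol) != 0L) return("fail_charged")
  el <- mol$atoms$element
  bm <- .bond_order_matrix(mol)
  adj <- .adjacency(mol)
  arom <- aromatic_atoms(mol)
  for (i in which(el == "N")) {
    if (arom[i]) next                                   # aromatic-ring N
    if (any(bm[i, ] == 3)) next                         # nitrile
    nbrs <- adj[[i]]
    # amide: attached to carbonyl/thiocarbonyl carbon
    amide <- any(vapply(nbrs, function(c) el[c] == "C" && any(bm[c, ] >= 2 & el %in% c("O", "S")),
                        logical(1)))
    if (amide) next
    # anilinic: attached to an aromatic atom via a single bond
    anilinic <- any(vapply(nbrs, function(c) arom[c] && bm[i, c] == 1, logical(1)))
    # amidine / guanidine: N singly bonded to C that is double-bonded to another N
    amidine <- any(vapply(nbrs, function(c) el[c] == "C" && any(bm[c, ] == 2 & el == "N"),
                          logical(1)))
    if (amidine) return("fail_basic")
    # imine-type N (C=N) itself: amidine central N is basic; plain imine is not
    if (any(bm[i, ] == 2 & el == "C")) {
      cdbl <- which(bm[i, ] == 2 & el == "C")
      if (any(vapply(cdbl, function(c) sum(el[adj[[c]]] == "N") >= 2, logical(1))))
        return("fail_basic")
      next
    }
    if (anilinic) next
    # remaining sp3 N bonded only via single bonds: aliphatic amine
    if (all(bm[i, nbrs] == 1)) return("fail_basic")
  }
  "pass"
}

#' Physicochemical descriptors
#'
#' Computes molecular weight (standard atomic masses including implicit H),
#' rotatable bonds (non-ring single bonds between two heavy atoms each bearing
#' at least one further heavy neighbour, amide C-N excluded), HBD/HBA counts
#' consistent with the perception rules, a logP estimate (Open Babel's
#' atomic-contribution scheme), and the net formal charge. Results are cached
#' on the record.
#'
#' @param mol a [molecule_record].
#' @param logP compute the logP estimate (one Open Babel call; set `FALSE` or
#'   supply via [attach_descriptors] in batch when speed matters).
#' @return the record with `$descriptors` filled.
#' @export
compute_descriptors <- function(mol, logP = TRUE) {
  d <- .descriptors_no_logp(mol)
  if (logP) {
    d$logP_estimate <- .ob_properties(list(mol))$logP[1L]
  } else d$logP_estimate <- NA_real_
  mol$descriptors <- d
  mol$flags <- list(is_charged = d$net_formal_charge != 0L || any(mol$atoms$charge != 0L),
                    has_basic_amine = nonbasic_filter(mol) == "fail_basic")
  mol
}

.descriptors_no_logp <- function(mol) {
  el <- mol$atoms$element
  mw <- sum(atomic_mass(el)) + sum(mol$atoms$nH) * atomic_mass("H")
  bm <- .bond_order_matrix(mol)
  adj <- .adjacency(mol)
  ring_bond <- .ring_bonds(mol)
  deg <- lengths(adj)
  rotb <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    if (ring_bond[k] || mol$bonds$order[k] != 1) next
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    # amide C-N exclusion (either direction)
    amide <- (el[i] == "C" && el[j] == "N" && any(bm[i, ] >= 2 & el == "O")) ||
             (el[j] == "C" && el[i] == "N" && any(bm[j, ] >= 2 & el == "O"))
    if (amide) next
    rotb <- rotb + 1L
  }
  counts <- .polar_counts(mol)
  list(MW = mw, rotatable_bonds = rotb, hbd = counts$hbd, hba = counts$hba,
       logP_estimate = NA_real_, net_formal_charge = net_formal_charge(mol))
}

# HBD/HBA counts from the same chemistry rules as perceive_features, but
# conformer-free and vectorized (the screening-scale hot path). Consistency
# with perceive_features is asserted property-style in the test suite.
.polar_counts <- function(mol) {
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  nH <- mol$atoms$nH
  n <- n_heavy(mol)
  bm <- .bond_order_matrix(mol)
  arom <- aromatic_atoms(mol)
  deg <- rowSums(bm > 0)
  isC <- el == "C"; isO <- el == "O"; isN <- el == "N"
  # carbonyl carbons: C with a double bond to O
  carbonyl_C <- isC & (bm %*% (isO + 0) > 0) & apply(bm >= 2, 1L, function(r) any(r & isO))
  # oxygens singly bonded to a carbonyl carbon (ester/acid sp3 O)
  single_to_carbonyl <- (bm == 1) %*% (carbonyl_C + 0) > 0
  has_double <- apply(bm, 1L, max) >= 2
  carbonyl_O <- isO & apply(bm >= 2, 1L, function(r) any(r & isC))
  hydroxyl_O <- isO & !arom & nH >= 1L & !has_double
  ether_O <- isO & !arom & nH == 0L & !has_double & deg == 2 & !single_to_carbonyl
  nitrile_N <- isN & apply(bm, 1L, max) >= 3
  amide_N <- isN & ((bm == 1) %*% (carbonyl_C + 0) > 0)
  aromatic_N <- isN & arom & nH == 0L & !amide_N
  hba <- sum((carbonyl_O | hydroxyl_O | ether_O | nitrile_N | aromatic_N) & chg <= 0L)
  hbd <- sum((isN | isO) & nH >= 1L & chg <= 0L)
  list(hbd = hbd, hba = hba)
}

#' Attach descriptors to many records in one batch
#'
#' Like [compute_descriptors] but with a single batched Open Babel call for
#' the logP column.
#' @param records list of [molecule_record]s.
#' @return list of records with `$descriptors` and `$flags` filled.
#' @export
attach_descriptors <- function(records) {
  if (!length(records)) return(records)
  props <- .ob_properties(records)
  for (i in seq_along(records)) {
    records[[i]] <- compute_descriptors(records[[i]], logP = FALSE)
    records[[i]]$descriptors$logP_estimate <- props$logP[i]
    records[[i]]$smiles <- props$cansmiNS[i]
  }
  records
}

#' Tabulate descriptors across records
#' @param records list of [molecule_record]s with descriptors attached.
#' @return data.frame with one row per molecule.
#' @export
descriptor_table <- function(records) {
  do.call(rbind, lapply(records, function(m) {
    d <- m$descriptors
    if (is.null(d)) stop("descriptors not computed for ", m$id)
    data.frame(id = m$id, MW = d$MW, rotatable_bonds = d$rotatable_bonds,
               hbd = d$hbd, hba = d$hba, logP = d$logP_estimate,
               net_charge = d$net_formal_charge)
  }))
}
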
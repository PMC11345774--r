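#' Molecule records
#'
#' A `molecule_record` is the package's working representation of one library
#' compound: a heavy-atom connection table with formal charges, implicit
#' hydrogen counts, perceived rings/aromaticity, zero or more 3D conformers
#' (heavy atoms only, Angstrom), and optional cached descriptors and filter
#' flags. Explicit hydrogens in the input are collapsed onto their heavy
#' neighbours on read.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `element`, `charge`, `nH`.
#' @param bonds data.frame with columns `a1`, `a2`, `order` (1, 2, 3, or 1.5
#'   for aromatic).
#' @param conformers list of numeric matrices (heavy atoms x 3).
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, atoms, bonds, conformers = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            all(c("element", "charge", "nH") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1L) stop("molecule must have at least one heavy atom")
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("a1", "a2", "order") %in% names(bonds)),
              all(bonds$a1 >= 1L & bonds$a1 <= n),
              all(bonds$a2 >= 1L & bonds$a2 <= n))
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  }
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3L)
      stop("each conformer must be an n_heavy x 3 coordinate matrix")
  }
  rec <- structure(list(
    id = id,
    atoms = atoms[, c("element", "charge", "nH")],
    bonds = bonds[, c("a1", "a2", "order")],
    conformers = conformers,
    rings = NULL,
    aromatic = NULL,
    smiles = NA_character_,
    descriptors = NULL,
    flags = NULL
  ), class = "molecule_record")
  rec <- .perceive_rings(rec)
  rec
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s: %d heavy atoms, %d bonds, %d conformer(s)>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  if (!is.null(x$descriptors)) {
    d <- x$descriptors
    cat(sprintf("  MW %.2f Da, RotB %d, HBD %d, HBA %d, logP %.2f, net charge %+d\n",
                d$MW, d$rotatable_bonds, d$hbd, d$hba, d$logP_estimate,
                d$net_formal_charge))
  }
  invisible(x)
}

n_heavy <- function(mol) nrow(mol$atoms)

net_formal_charge <- function(mol) as.integer(sum(mol$atoms$charge))

# adjacency list over heavy atoms
.adjacency <- function(mol) {
  n <- n_heavy(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

.bond_order_matrix <- function(mol) {
  n <- n_heavy(mol)
  m <- matrix(0, n, n)
  b <- mol$bonds
  if (nrow(b)) {
    m[cbind(b$a1, b$a2)] <- b$order
    m[cbind(b$a2, b$a1)] <- b$order
  }
  m
}

# ---- ring / aromaticity perception -----------------------------------------

# Smallest-ring enumeration by bounded BFS per bond, then a local aromaticity
# convention: a 5- or 6-ring is aromatic when every member is C/N/O/S and each
# ring carbon takes part in at least one double or aromatic bond (in-ring or
# exocyclic). This covers the kekulized output of standard SMILES writers.
.perceive_rings <- function(mol) {
  n <- n_heavy(mol)
  b <- mol$bonds
  rings <- list()
  if (nrow(b) >= 3L && n >= 3L) {
    adj <- .adjacency(mol)
    # restrict to the 2-core: iteratively strip degree-1 atoms; only bonds
    # inside the core can lie on cycles
    deg <- lengths(adj)
    core <- deg >= 1L
    repeat {
      leaves <- which(core & vapply(seq_len(n), function(i)
        sum(core[adj[[i]]]) <= 1L, logical(1)))
      if (!length(leaves)) break
      core[leaves] <- FALSE
    }
    core_bonds <- which(core[b$a1] & core[b$a2])
    adj <- lapply(seq_len(n), function(i) adj[[i]][core[adj[[i]]]])
    seen <- character()
    for (k in core_bonds) {
      # shortest cycle through bond k: BFS from a1 to a2 avoiding the bond
      src <- b$a1[k]; dst <- b$a2[k]
      prev <- rep(NA_integer_, n); prev[src] <- 0L
      queue <- src
      while (length(queue) && is.na(prev[dst])) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) {
          if ((v == src && w == dst) || (v == dst && w == src)) next
          if (is.na(prev[w])) { prev[w] <- v; queue <- c(queue, w) }
        }
      }
      if (!is.na(prev[dst])) {
        path <- dst
        while (path[1L] != src) path <- c(prev[path[1L]], path)
        if (length(path) <= 8L) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
        }
      }
    }
  }
  arom <- vapply(rings, function(r) .ring_is_aromatic(mol, r), logical(1))
  mol$rings <- rings
  mol$aromatic <- arom
  mol
}

.ring_is_aromatic <- function(mol, ring) {
  sz <- length(ring)
  if (sz != 5L && sz != 6L) return(FALSE)
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  bm <- .bond_order_matrix(mol)
  if (any(bm[ring, ] == 1.5)) return(TRUE)  # explicit aromatic bonds
  for (a in ring) {
    if (mol$atoms$element[a] == "C") {
      if (!any(bm[a, ] >= 2)) return(FALSE)  # sp3 carbon breaks the ring system
    }
  }
  # require the unsaturation to be conjugated around the ring, not exocyclic
  # only: count in-ring double bonds
  pairs <- cbind(ring, ring[c(2:sz, 1L)])
  n_double <- sum(bm[pairs] >= 2)
  n_double >= if (sz == 6L) 3L else 2L
}

ring_membership <- function(mol) {
  in_ring <- rep(FALSE, n_heavy(mol))
  for (r in mol$rings) in_ring[r] <- TRUE
  in_ring
}

aromatic_atoms <- function(mol) {
  ar <- rep(FALSE, n_heavy(mol))
  if (length(mol$rings)) {
    for (i in seq_along(mol$rings)) if (mol$aromatic[i]) ar[mol$rings[[i]]] <- TRUE
  }
  ar
}

# bond in a ring?
.ring_bonds <- function(mol) {
  rb <- rep(FALSE, nrow(mol$bonds))
  for (r in mol$rings) {
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$a1[k] %in% r && mol$bonds$a2[k] %in% r) {
        sz <- length(r)
        pos1 <- match(mol$bonds$a1[k], r); pos2 <- match(mol$bonds$a2[k], r)
        if (abs(pos1 - pos2) == 1L || abs(pos1 - pos2) == sz - 1L) rb[k] <- TRUE
      }
    }
  }
  rb
}
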
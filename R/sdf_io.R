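#' Library input and output
#'
#' Reading and writing compound libraries. Parsing of SMILES and SDF V2000 is
#' delegated to ChemmineR/ChemmineOB (Open Babel); results are converted into
#' [molecule_record] objects with explicit hydrogens collapsed and formal
#' charges taken from ctab charge codes and `M  CHG` blocks. A minimal
#' fixed-width ctab reader backs up the ChemmineR path for blocks it rejects
#' (single-heavy-atom molecules).
#'
#' @name library_io
NULL

.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

# Assemble a molecule_record from raw ctab pieces shared by both parse paths.
.assemble_record <- function(id, element, coords, charge, a1, a2, ord, lines) {
  ord[ord == 4] <- 1.5
  # M CHG lines override legacy codes
  if (!is.null(lines)) {
    chg <- grep("^M  CHG", lines, value = TRUE)
    if (length(chg)) {
      charge[] <- 0L
      for (ln in chg) {
        f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
        k <- f[1L]
        idx <- f[seq(2L, by = 2L, length.out = k)]
        val <- f[seq(3L, by = 2L, length.out = k)]
        charge[idx] <- val
      }
    }
  }
  heavy <- which(element != "H")
  if (!length(heavy)) return(NULL)
  map <- match(seq_along(element), heavy)

  explicitH <- integer(length(heavy))
  keep <- logical(length(a1))
  for (k in seq_along(a1)) {
    i <- a1[k]; j <- a2[k]
    hi <- element[i] == "H"; hj <- element[j] == "H"
    if (hi && hj) next
    if (hi || hj) {
      hv <- if (hi) j else i
      if (!is.na(map[hv])) explicitH[map[hv]] <- explicitH[map[hv]] + 1L
    } else keep[k] <- TRUE
  }
  bos <- numeric(length(heavy))
  for (k in which(keep)) {
    bos[map[a1[k]]] <- bos[map[a1[k]]] + ord[k]
    bos[map[a2[k]]] <- bos[map[a2[k]]] + ord[k]
  }
  bos <- bos + explicitH

  el_h <- element[heavy]
  ch_h <- as.integer(charge[heavy])
  nH <- explicitH + implicit_h_count(el_h, ch_h, bos)

  atoms <- data.frame(element = el_h, charge = ch_h, nH = nH, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = map[a1[keep]], a2 = map[a2[keep]], order = ord[keep])
  xyz <- coords[heavy, , drop = FALSE]
  conf <- if (any(abs(xyz[, 3]) > 1e-8) || .sdf_is_3d(lines)) list(unname(xyz)) else list()
  molecule_record(id = id, atoms = atoms, bonds = bonds, conformers = conf)
}

.sdf_is_3d <- function(lines) {
  if (is.null(lines) || length(lines) < 2L) return(FALSE)
  grepl("3D", lines[2L], fixed = TRUE)
}

# ChemmineR-parsed SDF -> record
.sdf_to_record <- function(sdf, id, lines = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(dim(ab)) || ncol(ab) < 6L || nrow(ab) < 1L) return(NULL)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(numeric(), 0L, 3L)
  element <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charge <- .CHARGE_CODE[as.character(ab[, "C6"])]
  charge[is.na(charge)] <- 0L
  nb <- nrow(bb)
  .assemble_record(id, element, coords, charge,
                   a1 = if (nb) as.integer(bb[, 1L]) else integer(),
                   a2 = if (nb) as.integer(bb[, 2L]) else integer(),
                   ord = if (nb) as.numeric(bb[, 3L]) else numeric(),
                   lines = lines)
}

# Fallback fixed-width V2000 reader for blocks ChemmineR rejects.
.ctab_to_record <- function(lines, id) {
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) return(NULL)
  at <- lines[5L:(4L + na)]
  coords <- cbind(as.numeric(substr(at, 1L, 10L)),
                  as.numeric(substr(at, 11L, 20L)),
                  as.numeric(substr(at, 21L, 30L)))
  element <- trimws(substr(at, 32L, 34L))
  charge <- .CHARGE_CODE[as.character(as.integer(substr(at, 37L, 39L)))]
  charge[is.na(charge)] <- 0L
  if (nb > 0L) {
    bd <- lines[(5L + na):(4L + na + nb)]
    a1 <- as.integer(substr(bd, 1L, 3L))
    a2 <- as.integer(substr(bd, 4L, 6L))
    ord <- as.numeric(substr(bd, 7L, 9L))
  } else { a1 <- integer(); a2 <- integer(); ord <- numeric() }
  .assemble_record(id, element, coords, charge, a1, a2, ord, lines)
}

# One SDF block (no $$$$ terminator) -> record or NULL. The fixed-width ctab
# reader runs first (it is fast and handles the uniform output of Open Babel
# and of this package's writer, including single-atom molecules); ChemmineR's
# parser backs it up for nonstandard blocks.
.block_to_record <- function(lines, id = NULL) {
  if (is.null(id)) {
    id <- trimws(lines[1L])
    if (!nzchar(id)) id <- "unnamed"
  }
  rec <- tryCatch(.ctab_to_record(lines, id), error = function(e) NULL)
  if (is.null(rec)) rec <- tryCatch({
    str <- suppressWarnings(ChemmineR::read.SDFstr(textConnection(c(lines, "$$$$"))))
    sdfset <- suppressWarnings(as(str, "SDFset"))
    .sdf_to_record(sdfset[[1L]], id, lines)
  }, error = function(e) NULL)
  rec
}

.split_sdf_blocks <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(if (length(lines) >= 4L) list(lines) else list())
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (i in seq_along(ends)) {
    blk <- lines[starts[i]:(ends[i] - 1L)]
    if (sum(nzchar(trimws(blk))) >= 2L) out[[length(out) + 1L]] <- blk
  }
  out
}

#' Read a compound library
#'
#' @param path file path.
#' @param format `"smiles"` (one molecule per line, optional whitespace-
#'   separated ID) or `"sdf"` (V2000, multi-molecule).
#' @return A list of [molecule_record]s. Invalid entries are skipped with a
#'   message reporting the count.
#' @export
read_library <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "smiles") {
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty library: no molecules in ", path)
    parts <- strsplit(trimws(lines), "[\t ]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("mol%04d", i)
    }, "")
    recs <- parse_smiles(smi, ids)
    n_bad <- length(smi) - length(recs)
    if (n_bad > 0L) message(sprintf("read_library: skipped %d invalid entr%s of %d",
                                    n_bad, if (n_bad == 1L) "y" else "ies", length(smi)))
    if (!length(recs)) stop("empty library: no valid molecules in ", path)
    recs
  } else {
    blocks <- .split_sdf_blocks(lines)
    if (!length(blocks)) stop("empty library: no molecules in ", path)
    recs <- list(); n_bad <- 0L
    for (i in seq_along(blocks)) {
      rec <- .block_to_record(blocks[[i]])
      if (is.null(rec)) n_bad <- n_bad + 1L else recs[[length(recs) + 1L]] <- rec
    }
    if (n_bad > 0L) message(sprintf("read_library: skipped %d invalid block%s of %d",
                                    n_bad, if (n_bad == 1L) "" else "s", length(blocks)))
    if (!length(recs)) stop("empty library: no valid molecules in ", path)
    recs
  }
}

#' Parse SMILES strings into molecule records
#'
#' @param smiles character vector of SMILES.
#' @param ids matching identifiers (defaults to `mol0001`...).
#' @return list of [molecule_record]s; unparseable entries are dropped.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("mol%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste0(paste(smiles, ids), "\n", collapse = ""))
  blocks <- .split_sdf_blocks(strsplit(txt, "\n", fixed = TRUE)[[1L]])
  recs <- list()
  for (blk in blocks) {
    rec <- .block_to_record(blk)
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  # keep input order; OB preserves order but drops failures
  got <- vapply(recs, `[[`, "", "id")
  recs[order(match(got, ids))]
}

# ---- writing ---------------------------------------------------------------

# V2000 text for one record; conformer_index 0 means a flat dummy layout.
.record_to_sdf_lines <- function(mol, conformer_index = 1L) {
  n <- n_heavy(mol); nb <- nrow(mol$bonds)
  if (conformer_index >= 1L && length(mol$conformers) >= conformer_index) {
    xyz <- mol$conformers[[conformer_index]]
    dim_tag <- "3D"
  } else {
    # all-zero layout marks "no coordinates"; nonzero placeholder geometry
    # (e.g. collinear points) would mislead geometry-based perception in
    # downstream toolkits
    xyz <- matrix(0, n, 3L)
    dim_tag <- "2D"
  }
  header <- c(mol$id, sprintf(" kappascreen     %s", dim_tag), "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element)
  ord <- mol$bonds$order
  ord_out <- ifelse(ord == 1.5, 4L, as.integer(ord))
  bonds <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, ord_out) else character()
  chg_idx <- which(mol$atoms$charge != 0L)
  chg <- character()
  if (length(chg_idx)) {
    for (grp in split(chg_idx, ceiling(seq_along(chg_idx) / 8))) {
      chg <- c(chg, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste(sprintf("%4d%4d", grp, mol$atoms$charge[grp]), collapse = "")))
    }
  }
  c(header, counts, atoms, bonds, chg, "M  END")
}

.records_to_sdf_text <- function(records, conformer_index = 1L) {
  paste0(unlist(lapply(records, function(m)
    c(.record_to_sdf_lines(m, conformer_index), "$$$$"))), "\n", collapse = "")
}

#' Write molecules to an SDF V2000 file
#' @param records list of [molecule_record]s.
#' @param path output path.
#' @param conformer_index which conformer's coordinates to write (0 = none).
#' @export
write_sdf_library <- function(records, path, conformer_index = 1L) {
  writeLines(unlist(lapply(records, function(m)
    c(.record_to_sdf_lines(m, conformer_index), "$$$$"))), path)
  invisible(path)
}

#' Write molecules as SMILES, one per line with ID
#' @inheritParams write_sdf_library
#' @export
write_smiles_library <- function(records, path) {
  smi <- canonical_smiles(records)
  writeLines(paste(smi, vapply(records, `[[`, "", "id"), sep = "\t"), path)
  invisible(path)
}

# Open Babel property table for a set of records (batched). Canonical SMILES
# is derived from the connection table first, and logP is then computed from
# that canonical form, so the value is independent of which concrete input
# form (builder graph, SDF file, SMILES string) produced the record. Small
# sets go through the in-process ChemmineOB bindings; large sets through
# obabel subprocesses, which are far faster per molecule.
.ob_properties <- function(records) {
  ids <- vapply(records, `[[`, "", "id")
  if (length(records) <= 50L) {
    txt <- .records_to_sdf_text(records, conformer_index = 0L)
    out <- ChemmineOB::forEachMol("SDF", txt, ChemmineOB::prop_OB)
    smi <- vapply(out, function(d) d$cansmiNS[1L], "")
    out2 <- ChemmineOB::forEachMol("SMILES",
                                   paste0(paste(smi, ids), "\n", collapse = ""),
                                   ChemmineOB::prop_OB)
    logp <- vapply(out2, function(d) d$logP[1L], 0)
    return(data.frame(cansmiNS = smi, logP = logp, stringsAsFactors = FALSE))
  }
  tmp <- tempfile(fileext = ".sdf")
  tmp2 <- tempfile(fileext = ".smi")
  on.exit(unlink(c(tmp, tmp2)))
  writeLines(unlist(lapply(records, function(m)
    c(.record_to_sdf_lines(m, 0L), "$$$$"))), tmp)
  can <- suppressWarnings(system2("obabel", c(tmp, "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  parts <- strsplit(can, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, "", 1L)
  got <- trimws(vapply(parts, function(x) if (length(x) >= 2L) x[[2L]] else "", ""))
  ord <- match(ids, got)
  if (anyNA(ord)) stop("Open Babel failed to process ",
                       sum(is.na(ord)), " molecule(s) in the property batch")
  smi <- smi[ord]
  writeLines(paste(smi, ids), tmp2)
  out <- suppressWarnings(system2("obabel", c(tmp2, "-osmi", "--append", "logP"),
                                  stdout = TRUE, stderr = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  rest <- strsplit(trimws(vapply(parts, `[[`, "", 2L)), "[ ]+")
  ids2 <- vapply(rest, `[[`, "", 1L)
  logp <- as.numeric(vapply(rest, function(x) x[[length(x)]], ""))
  data.frame(cansmiNS = smi, logP = logp[match(ids, ids2)], stringsAsFactors = FALSE)
}

#' ECFP4 circular fingerprints
#'
#' Computes Open Babel ECFP4 (circular, radius 2, 4096-bit) fingerprints for
#' a set of records in one batched subprocess; used for the decoy generator's
#' topology-dissimilarity cap.
#' @param records list of [molecule_record]s.
#' @return logical matrix, molecules x 4096 bits.
#' @export
ecfp_fingerprints <- function(records) {
  stopifnot(length(records) >= 1L)
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  smi <- canonical_smiles(records)
  ids <- vapply(records, `[[`, "", "id")
  writeLines(paste(smi, ids), tmp)
  out <- suppressWarnings(system2("obabel", c(tmp, "-ofpt", "-xfECFP4", "-xh"),
                                  stdout = TRUE, stderr = FALSE))
  heads <- grep("^>", out)
  if (length(heads) != length(records))
    stop("fingerprint batch returned ", length(heads), " entries for ",
         length(records), " molecules")
  starts <- heads + 1L
  stops <- c(heads[-1L] - 1L, length(out))
  bits <- matrix(FALSE, length(records), 4096L)
  lut <- matrix(FALSE, 16L, 4L)  # hex nibble -> 4 bits
  for (v in 0:15) lut[v + 1L, ] <- as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L)))
  for (i in seq_along(heads)) {
    blk <- out[starts[i]:stops[i]]
    blk <- blk[grepl("^[0-9a-fA-F ]+$", blk)]  # drop annotation lines
    hex <- gsub(" ", "", paste(blk, collapse = ""), fixed = TRUE)
    nib <- strtoi(strsplit(hex, "")[[1L]], 16L)
    bits[i, ] <- as.vector(t(lut[nib + 1L, , drop = FALSE]))
  }
  got_ids <- sub("^>([^ ]+).*", "\\1", out[heads])
  bits[match(ids, got_ids), , drop = FALSE]
}

#' Tanimoto similarity between two fingerprint sets
#'
#' @param a,b logical matrices (molecules x bits) from [ecfp_fingerprints].
#' @return numeric matrix `nrow(a)` x `nrow(b)` of Tanimoto coefficients.
#' @export
tanimoto_matrix <- function(a, b) {
  am <- matrix(as.numeric(a), nrow(a)); bm <- matrix(as.numeric(b), nrow(b))
  inter <- am %*% t(bm)
  na <- rowSums(am); nb <- rowSums(bm)
  denom <- outer(na, nb, `+`) - inter
  out <- ifelse(denom > 0, inter / denom, 0)
  out
}

#' Canonical SMILES for a set of records
#'
#' Computed by Open Babel; used as the method-independent structure identity
#' for de-duplication and active/decoy disjointness checks.
#' @param records list of [molecule_record]s.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(records) {
  if (!length(records)) return(character())
  cached <- vapply(records, `[[`, "", "smiles")
  todo <- which(is.na(cached))
  if (length(todo)) cached[todo] <- .ob_properties(records[todo])$cansmiNS
  cached
}
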
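#' Merge hit lists from parallel screens
#'
#' Combines ranked screens (e.g. the pharmacophore and the shape screen) into
#' one triage table, de-duplicating by canonical-structure identity and
#' recording each compound's origin. When the same structure appears in both
#' screens the best score from each method is kept.
#'
#' @param screens named list of `ranked_screen` data.frames; names become the
#'   origin tags (conventionally `pharm_screen` and `shape_screen`).
#' @param molecules list of [molecule_record]s covering every ID in the
#'   screens (used for canonical identity and descriptors).
#' @return data.frame with one row per unique structure: `id`, `origin`,
#'   per-screen score columns, and a `canonical` key.
#' @export
merge_hits <- function(screens, molecules) {
  stopifnot(length(screens) >= 1L, !is.null(names(screens)))
  ids <- vapply(molecules, `[[`, "", "id")
  canon <- canonical_smiles(molecules)
  canon_of <- stats::setNames(canon, ids)
  rows <- list()
  for (origin in names(screens)) {
    sc <- screens[[origin]]
    for (i in seq_len(nrow(sc))) {
      key <- canon_of[[sc$id[i]]]
      if (is.null(key) || is.na(key)) stop("no molecule supplied for id ", sc$id[i])
      if (is.null(rows[[key]])) {
        rows[[key]] <- list(id = sc$id[i], canonical = key,
                            origin = origin, scores = list())
      } else if (!grepl(origin, rows[[key]]$origin, fixed = TRUE)) {
        rows[[key]]$origin <- "both"
      }
      prev <- rows[[key]]$scores[[origin]]
      if (is.null(prev) || sc$score[i] > prev)
        rows[[key]]$scores[[origin]] <- sc$score[i]
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(id = r$id, canonical = r$canonical, origin = r$origin)
    for (o in names(screens))
      d[[paste0("score_", o)]] <- if (is.null(r$scores[[o]])) NA_real_ else r$scores[[o]]
    d
  }))
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Charge, basicity and physicochemical hit filters
#'
#' Drops charged molecules, molecules with a basic amine, molecules above the
#' molecular-weight cap and molecules above the rotatable-bond cap. Boundary
#' values (MW equal to the cap, RotB equal to the cap) pass. Filters commute:
#' the survivor set is independent of application order.
#'
#' @param molecules list of [molecule_record]s with descriptors attached.
#' @param mw_max molecular-weight cap in Da (default 500).
#' @param rotb_max rotatable-bond cap (default 10).
#' @return list with `survivors` (records), `flags` (data.frame id/charged/
#'   basic/mw_gt_max/rotb_gt_max) and `counts` (named drops per flag plus
#'   `input` and `survivors`).
#' @export
apply_filters <- function(molecules, mw_max = 500, rotb_max = 10L) {
  if (length(molecules) && is.null(molecules[[1L]]$descriptors))
    molecules <- attach_descriptors(molecules)
  flags <- do.call(rbind, lapply(molecules, function(m) {
    nb <- nonbasic_filter(m)
    data.frame(id = m$id,
               charged = nb == "fail_charged",
               basic = nb == "fail_basic",
               mw_gt_max = m$descriptors$MW > mw_max,
               rotb_gt_max = m$descriptors$rotatable_bonds > rotb_max)
  }))
  if (is.null(flags))
    flags <- data.frame(id = character(), charged = logical(), basic = logical(),
                        mw_gt_max = logical(), rotb_gt_max = logical())
  ok <- !(flags$charged | flags$basic | flags$mw_gt_max | flags$rotb_gt_max)
  counts <- c(input = length(molecules),
              charged = sum(flags$charged), basic = sum(flags$basic),
              mw_gt_max = sum(flags$mw_gt_max), rotb_gt_max = sum(flags$rotb_gt_max),
              survivors = sum(ok))
  list(survivors = molecules[ok], flags = flags, counts = counts)
}

#' Re-score docking poses against a pharmacophore query in a fixed frame
#'
#' Poses are scored in place (no realignment) with a partial-match
#' pharmacophore fit toward the query in the shared receptor frame; poses
#' with score 0 are dropped, mirroring the "score greater than zero" pose
#' filter. Whether the feature emulating the C2-acetoxy carbonyl acceptor is
#' matched is recorded per pose.
#'
#' @param poses list of [molecule_record]s with conformers in the receptor
#'   frame.
#' @param query a [pharmacophore_query] in the same frame.
#' @param c2_label label of the C2-analogue acceptor feature (default
#'   `"C2-HBA"`; ignored when the query lacks it).
#' @return data.frame `id`, `pose_score`, `n_matched`, `c2_analog_matched`,
#'   `kept`.
#' @export
rescore_poses <- function(poses, query, c2_label = "C2-HBA") {
  stopifnot(length(poses) >= 1L)
  # frame-mismatch heuristic: every feature far from every pose atom
  qcent <- as.matrix(query$features[, c("x", "y", "z")])
  far <- vapply(poses, function(p) {
    if (!length(p$conformers)) return(TRUE)
    xyz <- p$conformers[[1L]]
    d2 <- outer(rowSums(qcent^2), rowSums(xyz^2), `+`) - 2 * qcent %*% t(xyz)
    min(d2) > 20^2
  }, logical(1))
  if (all(far))
    warning("all poses lie > 20 Angstrom from every query feature; ",
            "are poses and query in the same coordinate frame?")
  rows <- lapply(poses, function(p) {
    res <- match_pharmacophore(query, p, "partial", fixed_frame = TRUE)
    score <- if (is.null(res) || isTRUE(res$clash)) 0 else res$score
    c2 <- if (score > 0 && c2_label %in% query$features$label)
      c2_label %in% res$assignment$query_label else NA
    data.frame(id = p$id, pose_score = score,
               n_matched = if (score > 0) res$n_matched else 0L,
               c2_analog_matched = c2, kept = score > 0)
  })
  out <- do.call(rbind, rows)
  out[order(-out$pose_score, out$id), , drop = FALSE]
}

#' Annotate receptor contacts of a docking pose
#'
#' Detects hydrogen bonds (ligand acceptor/donor heavy atom within
#' `hbond_dist` of a receptor N/O atom; with no explicit hydrogens present
#' the criterion is distance-only) and hydrophobic contacts (ligand apolar
#' carbon within `hydrophobic_dist` of a receptor carbon). By default only
#' residues on the whitelist are reported.
#'
#' @param pose a [molecule_record] with a conformer in the receptor frame.
#' @param receptor_pdb path to the receptor PDB file.
#' @param residue_whitelist residue labels like `"Y312"`, or NULL for all
#'   residues.
#' @param hbond_dist,hydrophobic_dist cutoffs in Angstrom.
#' @return data.frame `residue`, `kind` (`hbond`/`hydrophobic`),
#'   `ligand_atom`, `receptor_atom`, `distance`.
#' @export
annotate_contacts <- function(pose, receptor_pdb,
                              residue_whitelist = c("Q115", "V118", "Y139", "Y312", "Y313"),
                              hbond_dist = 3.5, hydrophobic_dist = 4.5) {
  pdb <- bio3d::read.pdb(receptor_pdb)
  at <- pdb$atom
  res_label <- paste0(substr(at$resid, 1L, 1L), at$resno)
  # map three-letter code initial to one-letter where they differ
  one <- c(TYR = "Y", VAL = "V", GLN = "Q", PHE = "F", TRP = "W", ARG = "R",
           LYS = "K", HIS = "H", ASP = "D", GLU = "E", SER = "S", THR = "T",
           ASN = "N", MET = "M", ILE = "I", LEU = "L", ALA = "A", GLY = "G",
           PRO = "P", CYS = "C")
  res_label <- paste0(ifelse(at$resid %in% names(one), one[at$resid],
                             substr(at$resid, 1L, 1L)), at$resno)
  if (!is.null(residue_whitelist)) {
    keep <- res_label %in% residue_whitelist
    at <- at[keep, , drop = FALSE]; res_label <- res_label[keep]
  }
  if (!nrow(at)) return(data.frame(residue = character(), kind = character(),
                                   ligand_atom = integer(), receptor_atom = character(),
                                   distance = numeric()))
  rxyz <- as.matrix(at[, c("x", "y", "z")])
  elesy <- trimws(at$elesy)
  relem <- ifelse(!is.na(elesy) & nzchar(elesy), elesy,
                  substr(trimws(at$elety), 1L, 1L))

  feats <- perceive_features(pose, 1L)
  polar_idx <- unique(unlist(feats$source_atoms[feats$kind %in% c("HBA", "HBD")]))
  apolar_idx <- unique(unlist(feats$source_atoms[feats$kind == "HY"]))
  lxyz <- pose$conformers[[1L]]

  d_all <- sqrt(outer(rowSums(lxyz^2), rowSums(rxyz^2), `+`) - 2 * lxyz %*% t(rxyz))
  out <- list()
  if (length(polar_idx)) {
    rp <- which(relem %in% c("N", "O"))
    for (i in polar_idx) for (j in rp) {
      if (d_all[i, j] <= hbond_dist)
        out[[length(out) + 1L]] <- data.frame(residue = res_label[j], kind = "hbond",
                                              ligand_atom = i,
                                              receptor_atom = trimws(at$elety[j]),
                                              distance = d_all[i, j])
    }
  }
  if (length(apolar_idx)) {
    rc <- which(relem == "C" & !trimws(at$elety) %in% c("C", "CA"))
    for (i in apolar_idx) for (j in rc) {
      if (d_all[i, j] <= hydrophobic_dist)
        out[[length(out) + 1L]] <- data.frame(residue = res_label[j], kind = "hydrophobic",
                                              ligand_atom = i,
                                              receptor_atom = trimws(at$elety[j]),
                                              distance = d_all[i, j])
    }
  }
  if (!length(out)) return(data.frame(residue = character(), kind = character(),
                                      ligand_atom = integer(), receptor_atom = character(),
                                      distance = numeric()))
  out <- do.call(rbind, out)
  out[order(out$residue, out$kind, out$distance), , drop = FALSE]
}
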
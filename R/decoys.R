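#' Decoy generation settings
#'
#' Property windows and topology-dissimilarity cap for DUD-E-style
#' property-matched decoy selection. A universe compound is a candidate decoy
#' for an active when it lies inside every window around that active's
#' descriptors and its circular-fingerprint Tanimoto to the active is below
#' the cap.
#'
#' @param mw_window Da (default 25).
#' @param logp_window log units (default 1.0).
#' @param rotb_window rotatable bonds (default 2).
#' @param hbd_window,hba_window H-bond donor/acceptor counts (default 1).
#' @param max_fingerprint_similarity ECFP4 Tanimoto cap, in (0, 1)
#'   (default 0.35).
#' @param decoys_per_active decoys sampled per active (default 50).
#' @param seed sampling seed.
#' @return an object of class `decoy_spec`.
#' @export
decoy_spec <- function(mw_window = 25, logp_window = 1.0, rotb_window = 2L,
                       hbd_window = 1L, hba_window = 1L,
                       max_fingerprint_similarity = 0.35,
                       decoys_per_active = 50L, seed = 1L) {
  if (any(c(mw_window, logp_window, rotb_window, hbd_window, hba_window) < 0))
    stop("property windows must be non-negative")
  if (max_fingerprint_similarity <= 0 || max_fingerprint_similarity >= 1)
    stop("max_fingerprint_similarity must lie in (0, 1)")
  if (decoys_per_active < 1L) stop("decoys_per_active must be >= 1")
  structure(list(mw_window = mw_window, logp_window = logp_window,
                 rotb_window = as.integer(rotb_window),
                 hbd_window = as.integer(hbd_window),
                 hba_window = as.integer(hba_window),
                 max_fingerprint_similarity = max_fingerprint_similarity,
                 decoys_per_active = as.integer(decoys_per_active),
                 seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Generate property-matched decoys for an active set
#'
#' For each active, candidates are the universe members inside every property
#' window (MW, logP, rotatable bonds, HBD, HBA, exact net-charge match) whose
#' ECFP4 Tanimoto to that active is below the similarity cap;
#' `decoys_per_active` of them are sampled without replacement under the
#' spec's seed. A universe member is assigned to at most one active (first
#' assignment wins); when fewer candidates than requested remain, all are
#' taken and a shortfall is logged.
#'
#' @param actives list of [molecule_record]s with descriptors attached.
#' @param universe list of candidate [molecule_record]s, disjoint from the
#'   actives by canonical-structure identity.
#' @param spec a [decoy_spec].
#' @return list with `decoys` (records), `provenance` (data.frame
#'   decoy_id/active_id), and `shortfalls` (data.frame active_id/available,
#'   empty when every active received its full complement).
#' @export
generate_decoys <- function(actives, universe, spec = decoy_spec()) {
  stopifnot(inherits(spec, "decoy_spec"))
  if (!length(universe)) stop("decoy universe is empty")
  if (!length(actives))
    return(list(decoys = list(),
                provenance = data.frame(decoy_id = character(), active_id = character()),
                shortfalls = data.frame(active_id = character(), available = integer())))
  if (is.null(actives[[1L]]$descriptors)) actives <- attach_descriptors(actives)
  if (is.null(universe[[1L]]$descriptors)) universe <- attach_descriptors(universe)
  smi_a <- canonical_smiles(actives)
  smi_u <- canonical_smiles(universe)
  if (length(common <- intersect(smi_a, smi_u)))
    stop("universe is not disjoint from the actives (", length(common),
         " shared canonical structures)")
  da <- descriptor_table(actives)
  du <- descriptor_table(universe)
  fp_a <- ecfp_fingerprints(actives)
  fp_u <- ecfp_fingerprints(universe)
  sim <- tanimoto_matrix(fp_a, fp_u)   # actives x universe

  nA <- length(actives)
  candlist <- lapply(seq_len(nA), function(i) {
    which(abs(du$MW - da$MW[i]) <= spec$mw_window &
            abs(du$logP - da$logP[i]) <= spec$logp_window &
            abs(du$rotatable_bonds - da$rotatable_bonds[i]) <= spec$rotb_window &
            abs(du$hbd - da$hbd[i]) <= spec$hbd_window &
            abs(du$hba - da$hba[i]) <= spec$hba_window &
            du$net_charge == da$net_charge[i] &
            sim[i, ] < spec$max_fingerprint_similarity)
  })
  k <- spec$decoys_per_active
  owner <- integer(length(universe))  # 0 = unassigned, else active index
  # seeded sampling pass: each active draws k of its still-free candidates
  with_private_rng(spec$seed, {
    for (i in seq_len(nA)) {
      free <- candlist[[i]][owner[candlist[[i]]] == 0L]
      take <- if (length(free) <= k) free else free[sample.int(length(free), k)]
      owner[take] <- i
    }
  })
  # repair pass: augmenting paths (bipartite b-matching) fill remaining slots
  # whenever the candidate structure allows it, by reassigning earlier picks
  # along alternating chains; iterative BFS, deterministic
  n_owned <- tabulate(owner, nA)
  augment <- function(root) {
    visited <- logical(length(universe))
    in_tree <- logical(nA)
    parent_active <- integer(nA)  # active that reached this active
    enter_c <- integer(nA)        # candidate (owned by this active) used to reach it
    in_tree[root] <- TRUE
    queue <- root
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      for (c in candlist[[i]]) {
        if (visited[c]) next
        visited[c] <- TRUE
        j <- owner[c]
        if (j == 0L) {
          # free candidate found: shift assignments back along the chain
          owner[c] <<- i
          while (i != root) {
            ci <- enter_c[i]
            owner[ci] <<- parent_active[i]
            i <- parent_active[i]
          }
          return(TRUE)
        }
        if (!in_tree[j]) {
          in_tree[j] <- TRUE
          parent_active[j] <- i
          enter_c[j] <- c
          queue <- c(queue, j)
        }
      }
    }
    FALSE
  }
  for (i in seq_len(nA)) {
    while (n_owned[i] < k) {
      if (!augment(i)) break
      n_owned[i] <- n_owned[i] + 1L
    }
  }
  shortfalls <- data.frame(active_id = da$id[n_owned < k],
                           available = n_owned[n_owned < k])
  if (nrow(shortfalls))
    message(sprintf("generate_decoys: %d active(s) with candidate shortfall", nrow(shortfalls)))
  sel <- which(owner > 0L)
  sel <- sel[order(owner[sel], du$id[sel])]
  prov <- data.frame(decoy_id = du$id[sel], active_id = da$id[owner[sel]])
  list(decoys = universe[sel], provenance = prov, shortfalls = shortfalls)
}

#' Curate an annotated active set
#'
#' Applies the activity-data curation rules used to assemble the validation
#' actives: keep entries with an exact EC50 in nM, measured in a
#' \[35S\]GTPgammaS assay, molecular weight within 300-500 Da, and uncharged
#' per [nonbasic_filter]; duplicates by canonical structure are collapsed.
#'
#' @param records list of [molecule_record]s.
#' @param annotations data.frame with columns `id`, `ec50` (character or
#'   numeric; inexact values such as ">1000" are rejected), `assay`, `units`.
#' @param mw_range numeric length-2, Da.
#' @return list with `actives` (surviving records) and `stage_counts` (named
#'   integer vector of survivors after each filter stage).
#' @export
curate_actives <- function(records, annotations, mw_range = c(300, 500)) {
  stopifnot(all(c("id", "ec50", "assay", "units") %in% names(annotations)))
  ids <- vapply(records, `[[`, "", "id")
  ann <- annotations[match(ids, annotations$id), ]
  counts <- c(input = length(records))

  ec <- suppressWarnings(as.numeric(as.character(ann$ec50)))
  keep <- !is.na(ec) & !is.na(ann$units) & trimws(ann$units) == "nM"
  records <- records[keep]; ann <- ann[keep, ]
  counts["exact_ec50_nM"] <- length(records)

  keep <- grepl("GTP", ann$assay, ignore.case = TRUE)
  records <- records[keep]; ann <- ann[keep, ]
  counts["gtpgs_assay"] <- length(records)

  if (length(records) && is.null(records[[1L]]$descriptors))
    records <- attach_descriptors(records)
  mw <- vapply(records, function(m) m$descriptors$MW, 0)
  keep <- mw >= mw_range[1L] & mw <= mw_range[2L]
  records <- records[keep]
  counts["mw_in_range"] <- length(records)

  keep <- vapply(records, function(m) nonbasic_filter(m) == "pass", logical(1))
  records <- records[keep]
  counts["uncharged"] <- length(records)

  smi <- canonical_smiles(records)
  records <- records[!duplicated(smi)]
  counts["deduplicated"] <- length(records)

  list(actives = records, stage_counts = counts)
}
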
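#' Run the end-to-end virtual-screening pipeline
#'
#' Orchestrates the parallel pharmacophore and shape screens, merges their
#' hit lists by canonical structure, applies the charge/basicity and
#' physicochemical filters, optionally re-scores externally docked poses in
#' the receptor frame and annotates key-residue contacts, and returns a
#' ranked candidate report with per-stage counts. Fully deterministic under
#' `config$seed`. The final manual selection of compounds for testing is
#' deliberately not automated: the report exposes every criterion (pose
#' score, shape combo, C2-analogue match, contacts, descriptors) as sortable
#' columns.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{seed}{integer, drives fixture generation.}
#'     \item{fixture}{list(n_actives, decoys_per_active) to build a synthetic
#'       library, or NULL when `library_paths` is given.}
#'     \item{library_paths}{named list of SMILES/SDF paths (alternative to
#'       `fixture`).}
#'     \item{query}{"reduced" (default), "full", or a query file path.}
#'     \item{shape_top_n}{shape-screen retrieval depth (default 500).}
#'     \item{mw_max, rotb_max}{triage filter caps (defaults 500 Da, 10).}
#'     \item{poses, receptor}{optional SDF/PDB paths for pose re-scoring and
#'       contact annotation.}
#'   }
#' @return a `triage_report`: list with `stage_counts`, `candidates`
#'   (data.frame), `screens`, and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("seed")) if (is.null(config[[key]]))
    stop("pipeline config is missing required key '", key, "'")
  seed <- as.integer(config$seed)
  top_n <- config$shape_top_n %||% 500L
  if (top_n < 1L) stop("pipeline config error: shape_top_n must be >= 1")
  mw_max <- config$mw_max %||% 500
  rotb_max <- config$rotb_max %||% 10L

  query <- .resolve_query(config$query %||% "reduced")
  reference <- reference_molecule()

  if (!is.null(config$library_paths)) {
    library <- list()
    for (p in config$library_paths) {
      fmt <- if (grepl("\\.sdf$", p)) "sdf" else "smiles"
      library <- c(library, read_library(p, fmt))
    }
    labels <- NULL
  } else {
    fx_cfg <- config$fixture %||% list()
    spec <- fixture_spec(seed = seed,
                         n_actives = fx_cfg$n_actives %||% 82L,
                         decoys_per_active = fx_cfg$decoys_per_active %||% 50L)
    fx <- make_compound_fixture(spec)
    dg <- generate_decoys(fx$actives, fx$universe,
                          decoy_spec(decoys_per_active = spec$decoys_per_active,
                                     seed = seed))
    library <- c(fx$actives, lapply(dg$decoys, ensure_conformer))
    labels <- stats::setNames(
      c(rep("active", length(fx$actives)), rep("decoy", length(dg$decoys))),
      vapply(library, `[[`, "", "id"))
  }
  counts <- c(library = length(library))

  pharm <- screen_pharmacophore(query, library, mode = "full", labels = labels)
  counts["pharm_hits"] <- nrow(pharm)
  shape <- shape_screen(reference, library, top_n = top_n, labels = labels)
  counts["shape_hits"] <- nrow(shape)

  merged <- merge_hits(list(pharm_screen = pharm, shape_screen = shape), library)
  counts["merged_unique"] <- nrow(merged)
  counts["overlap"] <- counts[["pharm_hits"]] + counts[["shape_hits"]] - nrow(merged)

  lib_ids <- vapply(library, `[[`, "", "id")
  hits <- library[match(merged$id, lib_ids)]
  filt <- apply_filters(hits, mw_max = mw_max, rotb_max = rotb_max)
  counts <- c(counts, stats::setNames(filt$counts[c("charged", "basic", "mw_gt_max", "rotb_gt_max")],
                                      paste0("drop_", c("charged", "basic", "mw", "rotb"))))
  counts["survivors"] <- filt$counts[["survivors"]]

  surv_ids <- vapply(filt$survivors, `[[`, "", "id")
  cand <- merged[merged$id %in% surv_ids, , drop = FALSE]
  desc <- descriptor_table(filt$survivors)
  cand <- merge(cand, desc, by = "id", sort = FALSE)

  if (!is.null(config$poses)) {
    poses <- read_library(config$poses, "sdf")
    rs <- rescore_poses(poses, .resolve_query(config$rescore_query %||% "full"))
    counts["poses"] <- nrow(rs)
    counts["poses_kept"] <- sum(rs$kept)
    cand <- merge(cand, rs[, c("id", "pose_score", "c2_analog_matched")],
                  by = "id", all.x = TRUE, sort = FALSE)
    if (!is.null(config$receptor)) {
      kept <- poses[vapply(poses, `[[`, "", "id") %in% rs$id[rs$kept]]
      contact_summary <- vapply(kept, function(p) {
        ct <- annotate_contacts(p, config$receptor)
        paste(unique(paste0(ct$residue, ":", ct$kind)), collapse = ";")
      }, "")
      cs <- data.frame(id = vapply(kept, `[[`, "", "id"), contacts = contact_summary)
      cand <- merge(cand, cs, by = "id", all.x = TRUE, sort = FALSE)
    }
  }
  ord <- order(-replace(cand$score_shape_screen, is.na(cand$score_shape_screen), -Inf),
               cand$id)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(stage_counts = counts, candidates = cand,
                 screens = list(pharm = pharm, shape = shape),
                 config = config),
            class = "triage_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_query <- function(q) {
  if (inherits(q, "pharmacophore_query")) return(q)
  if (q == "reduced") return(reference_query(reduced = TRUE))
  if (q == "full") return(reference_query(reduced = FALSE))
  read_query(q)
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>\nstage counts:\n")
  print(x$stage_counts)
  cat(sprintf("%d ranked candidates\n", nrow(x$candidates)))
  invisible(x)
}

#' Write a triage report to disk
#'
#' @param report a `triage_report`.
#' @param dir output directory (created if missing).
#' @return paths of the written files (candidates TSV + JSON summary).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "candidates.tsv")
  utils::write.table(report$candidates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(stage_counts = as.list(report$stage_counts)),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Write / read a ranked screen as TSV
#' @param screen a `ranked_screen` data.frame.
#' @param path file path.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_tsv
#' @export
read_screen_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("ranked_screen", class(out))
  out
}
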
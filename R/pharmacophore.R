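#' Pharmacophore queries
#'
#' A pharmacophore query is a set of typed tolerance spheres (features) plus
#' an exclusion-volume coat: spheres marking receptor-occupied space that no
#' ligand heavy atom may enter. `required_labels` names the features that must
#' all be matched in full-match mode (defaults to every feature).
#'
#' @param features data.frame with columns `kind` (HBA/HBD/HY/AR/PI/NI),
#'   `x`, `y`, `z` (Angstrom), `radius` (tolerance, Angstrom), `label`.
#' @param exclusion_volumes data.frame with columns `x`, `y`, `z`, `radius`,
#'   or NULL.
#' @param required_labels character vector, subset of `features$label`.
#' @return an object of class `pharmacophore_query`.
#' @export
pharmacophore_query <- function(features, exclusion_volumes = NULL,
                                required_labels = features$label) {
  stopifnot(is.data.frame(features),
            all(c("kind", "x", "y", "z", "radius", "label") %in% names(features)))
  if (nrow(features) < 1L) stop("a pharmacophore query needs at least one feature")
  if (any(features$radius <= 0)) stop("feature tolerance radii must be positive")
  if (anyDuplicated(features$label)) stop("feature labels must be unique")
  if (is.null(exclusion_volumes))
    exclusion_volumes <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                                    radius = numeric())
  stopifnot(all(c("x", "y", "z", "radius") %in% names(exclusion_volumes)))
  if (any(exclusion_volumes$radius <= 0)) stop("exclusion radii must be positive")
  if (!all(required_labels %in% features$label)) stop("unknown required label(s)")
  structure(list(features = features,
                 exclusion_volumes = exclusion_volumes,
                 required_labels = required_labels),
            class = "pharmacophore_query")
}

#' @export
print.pharmacophore_query <- function(x, ...) {
  cat(sprintf("<pharmacophore_query: %d features (%s), %d exclusion spheres>\n",
              nrow(x$features), paste(x$features$kind, collapse = ","),
              nrow(x$exclusion_volumes)))
  invisible(x)
}

#' Remove one feature from a query
#'
#' Used for query-reduction experiments such as omitting the C2-acetoxy HBA.
#' Exclusion volumes are untouched; if the label was required it is removed
#' from `required_labels` too.
#'
#' @param query a [pharmacophore_query].
#' @param label feature label to drop.
#' @return the reduced query.
#' @export
drop_feature <- function(query, label) {
  i <- match(label, query$features$label)
  if (is.na(i)) stop("no feature labelled '", label, "' in query")
  pharmacophore_query(query$features[-i, , drop = FALSE],
                      query$exclusion_volumes,
                      setdiff(query$required_labels, label))
}

#' Read / write a query as JSON or YAML
#'
#' Format: `{"features": [{"kind","center":[x,y,z],"radius","label"}, ...],
#' "exclusion_volumes": [{"center":[x,y,z],"radius"}, ...],
#' "required_labels": [...]}`.
#'
#' @param path file path (`.json`, `.yml`/`.yaml`).
#' @return a [pharmacophore_query].
#' @export
read_query <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  feats <- do.call(rbind, lapply(obj$features, function(f)
    data.frame(kind = f$kind, x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
               radius = f$radius, label = f$label)))
  ex <- if (length(obj$exclusion_volumes))
    do.call(rbind, lapply(obj$exclusion_volumes, function(f)
      data.frame(x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
                 radius = f$radius)))
  else NULL
  req <- if (is.null(obj$required_labels)) feats$label else unlist(obj$required_labels)
  pharmacophore_query(feats, ex, req)
}

#' @rdname read_query
#' @param query a [pharmacophore_query].
#' @export
write_query <- function(query, path) {
  obj <- list(
    features = lapply(seq_len(nrow(query$features)), function(i) {
      f <- query$features[i, ]
      list(kind = f$kind, center = c(f$x, f$y, f$z), radius = f$radius, label = f$label)
    }),
    exclusion_volumes = lapply(seq_len(nrow(query$exclusion_volumes)), function(i) {
      f <- query$exclusion_volumes[i, ]
      list(center = c(f$x, f$y, f$z), radius = f$radius)
    }),
    required_labels = as.list(query$required_labels)
  )
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path, precision = 15L)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- matching --------------------------------------------------------------

#' Match a molecule against a pharmacophore query
#'
#' Enumerates kind-compatible assignments of query features to perceived
#' ligand features whose inter-feature distance matrix agrees with the
#' query's within pairwise slack (r_i + r_j), superposes the matched ligand
#' feature centers onto the query centers by least-squares rigid rotation
#' (proper rotations only), and accepts an assignment when every matched
#' feature lands inside its tolerance sphere and no ligand heavy atom falls
#' inside an exclusion sphere. The fit score is
#' `S = 9 * n_matched + sum(1 - d_f / r_f)`, so matching one more feature
#' always outranks placing fewer features better.
#'
#' @param query a [pharmacophore_query].
#' @param mol a [molecule_record] with at least one conformer.
#' @param mode `"full"` (all `required_labels` must match) or `"partial"`
#'   (best-scoring subset of size >= 1).
#' @param fixed_frame if TRUE the pose is scored in place (transform fixed to
#'   the identity); used for re-scoring docking poses in the receptor frame.
#' @return a `match_result` (list with `assignment`, `transform`, `residuals`,
#'   `n_matched`, `score`, `conformer_index`, `clash`) or `NULL` when no
#'   acceptable assignment exists.
#' @export
match_pharmacophore <- function(query, mol, mode = c("full", "partial"),
                                fixed_frame = FALSE) {
  mode <- match.arg(mode)
  if (!length(mol$conformers)) stop("molecule ", mol$id, " has no conformer")
  best <- NULL
  for (ci in seq_along(mol$conformers)) {
    feats <- perceive_features(mol, ci)
    if (!nrow(feats)) next
    res <- .match_one_conformer(query, feats, mol$conformers[[ci]], mode,
                                fixed_frame, prune = TRUE)
    if (!is.null(res)) {
      res$conformer_index <- ci
      if (is.null(best) || res$score > best$score) best <- res
    }
  }
  best
}

# Core assignment search over one conformer's features. Exported logic is
# shared with the brute-force reference in tests through `prune = FALSE`.
.match_one_conformer <- function(query, feats, xyz, mode, fixed_frame, prune = TRUE) {
  qf <- query$features
  nq <- nrow(qf)
  qcent <- as.matrix(qf[, c("x", "y", "z")])
  lcent <- as.matrix(feats[, c("x", "y", "z")])
  qd <- as.matrix(stats::dist(qcent))
  ld <- as.matrix(stats::dist(lcent))
  required <- if (mode == "full") match(query$required_labels, qf$label) else integer()

  cand <- lapply(seq_len(nq), function(i) which(feats$kind == qf$kind[i]))
  best <- NULL        # best clash-free assignment
  best_any <- NULL    # best assignment ignoring clashes

  evaluate <- function(qidx, lidx) {
    n <- length(qidx)
    if (fixed_frame) {
      R <- diag(3); tv <- c(0, 0, 0)
      d <- sqrt(rowSums((lcent[lidx, , drop = FALSE] - qcent[qidx, , drop = FALSE])^2))
    } else {
      tr <- .kabsch(lcent[lidx, , drop = FALSE], qcent[qidx, , drop = FALSE])
      R <- tr$R; tv <- tr$t
      moved <- .apply_transform(lcent[lidx, , drop = FALSE], R, tv)
      d <- sqrt(rowSums((moved - qcent[qidx, , drop = FALSE])^2))
    }
    r <- qf$radius[qidx]
    if (any(d > r)) return(NULL)
    clash <- FALSE
    ex <- query$exclusion_volumes
    if (nrow(ex)) {
      atoms <- if (fixed_frame) xyz else .apply_transform(xyz, R, tv)
      for (k in seq_len(nrow(ex))) {
        dx <- sqrt(rowSums(sweep(atoms, 2L, c(ex$x[k], ex$y[k], ex$z[k]))^2))
        if (any(dx < ex$radius[k])) { clash <- TRUE; break }
      }
    }
    list(assignment = data.frame(query_label = qf$label[qidx],
                                 ligand_feature = lidx,
                                 residual = d),
         transform = list(R = R, t = tv),
         residuals = stats::setNames(d, qf$label[qidx]),
         n_matched = n,
         score = 9 * n + sum(1 - d / r),
         clash = clash)
  }

  recurse <- function(i, qidx, lidx) {
    if (i > nq) {
      if (!length(qidx)) return()
      if (mode == "full" && !all(required %in% qidx)) return()
      res <- evaluate(qidx, lidx)
      if (!is.null(res)) {
        if (is.null(best_any) || res$score > best_any$score) best_any <<- res
        if (!res$clash && (is.null(best) || res$score > best$score)) best <<- res
      }
      return()
    }
    # try assigning query feature i
    for (l in setdiff(cand[[i]], lidx)) {
      ok <- TRUE
      if (prune) {
        for (k in seq_along(qidx)) {
          slack <- qf$radius[i] + qf$radius[qidx[k]]
          if (abs(ld[l, lidx[k]] - qd[i, qidx[k]]) > slack) { ok <- FALSE; break }
        }
        if (ok && fixed_frame) {
          if (sqrt(sum((lcent[l, ] - qcent[i, ])^2)) > qf$radius[i]) ok <- FALSE
        }
      }
      if (ok) recurse(i + 1L, c(qidx, i), c(lidx, l))
    }
    # or skip it (always allowed during search; full-mode coverage of
    # required labels is enforced at the leaf)
    if (!(mode == "full" && i %in% required)) recurse(i + 1L, qidx, lidx)
  }
  recurse(1L, integer(), integer())
  # prefer a clash-free assignment; report the clashing best only when no
  # clash-free one exists (callers in screening mode then reject it)
  if (!is.null(best)) best else best_any
}

#' Screen a library against a pharmacophore query
#'
#' Scores every molecule with [match_pharmacophore]. Non-matchers (and, in
#' screening use, clashing poses) score 0; in full mode they are excluded
#' from the ranked list. Output is ordered by score descending, ties broken
#' by molecule ID ascending.
#'
#' @param query a [pharmacophore_query].
#' @param library list of [molecule_record]s.
#' @param mode `"full"` or `"partial"`.
#' @param labels optional named character vector (`active`/`decoy`/`unknown`)
#'   keyed by molecule ID; carried into the ranked screen.
#' @param verbose log hit counts.
#' @return a `ranked_screen` data.frame with columns `id`, `score`,
#'   `n_matched`, `conformer_index` (and `label` when supplied).
#' @export
screen_pharmacophore <- function(query, library, mode = c("full", "partial"),
                                 labels = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!length(library)) stop("library is empty")
  rows <- lapply(library, function(mol) {
    res <- tryCatch(match_pharmacophore(query, mol, mode), error = function(e) NULL)
    if (is.null(res) || isTRUE(res$clash))
      data.frame(id = mol$id, score = 0, n_matched = 0L, conformer_index = NA_integer_)
    else
      data.frame(id = mol$id, score = res$score, n_matched = res$n_matched,
                 conformer_index = res$conformer_index)
  })
  out <- do.call(rbind, rows)
  if (mode == "full") out <- out[out$n_matched > 0L, , drop = FALSE]
  out <- out[order(-out$score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(labels)) out$label <- unname(labels[out$id])
  if (verbose) message(sprintf("pharmacophore screen: %d of %d molecules scored > 0",
                               sum(out$score > 0), length(library)))
  class(out) <- c("ranked_screen", class(out))
  out
}
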
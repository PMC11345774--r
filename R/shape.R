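#' Gaussian shape overlay and shape/color Tanimoto scoring
#'
#' Molecular shape is modelled as a sum of atom-centred Gaussians over heavy
#' atoms: atom i contributes `p * exp(-alpha_i * |r - R_i|^2)` with a global
#' amplitude `p = 2.70` and `alpha_i = pi * (3p/(4pi))^(2/3) / sigma_i^2`,
#' where `sigma_i` is the van der Waals radius, so an isolated atom's Gaussian
#' volume equals its hard-sphere volume. Overlap volumes are evaluated in the
#' first-order (pairwise) approximation. The "color" term applies the same
#' machinery to same-kind perceived pharmacophore features as unit-width
#' Gaussians (`sigma = 1.0` Angstrom).
#'
#' @name shape_model
NULL

.SHAPE_P <- 2.70

.alpha_for_sigma <- function(sigma) pi * (3 * .SHAPE_P / (4 * pi))^(2 / 3) / sigma^2

#' Build the Gaussian shape model of one conformer
#'
#' @param mol a [molecule_record].
#' @param conformer_index conformer to use.
#' @return list with `xyz` (heavy-atom coordinates), `alpha` (widths) and the
#'   amplitude `p`; class `gaussian_model`.
#' @export
gaussian_model <- function(mol, conformer_index = 1L) {
  if (!length(mol$conformers)) stop("molecule ", mol$id, " has no conformer")
  xyz <- mol$conformers[[conformer_index]]
  sigma <- vdw_radius(mol$atoms$element)
  structure(list(xyz = xyz, alpha = .alpha_for_sigma(sigma), p = .SHAPE_P),
            class = "gaussian_model")
}

# feature "color" model: one unit-width Gaussian per perceived feature
.color_model <- function(mol, conformer_index = 1L,
                         kinds = c("HBA", "HBD", "AR", "HY")) {
  f <- perceive_features(mol, conformer_index)
  f <- f[f$kind %in% kinds, , drop = FALSE]
  structure(list(xyz = as.matrix(f[, c("x", "y", "z")]),
                 alpha = rep(.alpha_for_sigma(1.0), nrow(f)),
                 p = .SHAPE_P, kind = f$kind),
            class = "gaussian_model")
}

#' First-order Gaussian overlap volume between two models
#'
#' `O_AB = sum_ij p^2 (pi/(a_i+a_j))^{3/2} exp(-a_i a_j d_ij^2 / (a_i+a_j))`.
#'
#' @param A,B `gaussian_model` objects (B optionally transformed first).
#' @return overlap volume in cubic Angstrom.
#' @export
overlap_volume <- function(A, B) {
  if (!nrow(A$xyz) || !nrow(B$xyz)) stop("empty Gaussian model")
  asum <- outer(A$alpha, B$alpha, `+`)
  aprod <- outer(A$alpha, B$alpha, `*`)
  d2 <- outer(rowSums(A$xyz^2), rowSums(B$xyz^2), `+`) - 2 * A$xyz %*% t(B$xyz)
  d2[d2 < 0] <- 0
  sum(A$p * B$p * (pi / asum)^1.5 * exp(-aprod * d2 / asum))
}

# kind-restricted overlap for color models
.color_overlap <- function(A, B) {
  if (!nrow(A$xyz) || !nrow(B$xyz)) return(0)
  asum <- outer(A$alpha, B$alpha, `+`)
  aprod <- outer(A$alpha, B$alpha, `*`)
  d2 <- outer(rowSums(A$xyz^2), rowSums(B$xyz^2), `+`) - 2 * A$xyz %*% t(B$xyz)
  d2[d2 < 0] <- 0
  same <- outer(A$kind, B$kind, `==`)
  sum((A$p * B$p * (pi / asum)^1.5 * exp(-aprod * d2 / asum))[same])
}

.transform_model <- function(M, R, t) {
  M$xyz <- .apply_transform(M$xyz, R, t)
  M
}

# principal-axes initial alignments: 4 proper sign combinations
.pca_inits <- function(ref_xyz, probe_xyz) {
  orient <- function(xyz) {
    c0 <- colMeans(xyz)
    if (nrow(xyz) < 2L) return(list(center = c0, V = diag(3)))
    cv <- stats::cov(sweep(xyz, 2L, c0))
    if (any(!is.finite(cv))) return(list(center = c0, V = diag(3)))
    V <- eigen(cv, symmetric = TRUE)$vectors
    if (det(V) < 0) V[, 3L] <- -V[, 3L]
    list(center = c0, V = V)
  }
  r <- orient(ref_xyz); q <- orient(probe_xyz)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(signs, function(s) {
    R <- q$V %*% diag(s) %*% t(r$V)
    t_vec <- r$center - as.numeric(q$center %*% R)
    list(R = R, t = t_vec)
  })
}

#' Align a probe molecule onto a reference and score shape similarity
#'
#' For each probe conformer, rigid-body alignments are initialized from
#' centroid-and-principal-axes superposition (all four proper sign
#' combinations) and, when a shared pharmacophore query is supplied, from the
#' pharmacophore match transform. Each start is refined by a derivative-free
#' simplex search over the six rigid degrees of freedom maximizing the shape
#' overlap `O_AB`; the best conformer's score is reported. Tanimoto values:
#' `T_shape = O_AB / (O_AA + O_BB - O_AB)`, analogously `T_color` over
#' same-kind feature Gaussians; `combo = T_shape + T_color`.
#'
#' @param reference a [molecule_record] (first conformer is the reference
#'   frame).
#' @param probe a [molecule_record].
#' @param query optional [pharmacophore_query] shared by both molecules;
#'   adds a pharmacophore-based starting pose.
#' @param maxit iteration cap for each simplex refinement.
#' @return a `shape_score` list: `O_AA`, `O_BB`, `O_AB`, `T_shape`,
#'   `T_color`, `combo`, `transform`, `conformer_index`.
#' @export
align_and_score <- function(reference, probe, query = NULL, maxit = 300L) {
  if (!length(reference$conformers) || !length(probe$conformers))
    stop("both molecules need at least one conformer")
  A <- gaussian_model(reference, 1L)
  colA <- .color_model(reference, 1L)
  O_AA <- overlap_volume(A, A)
  C_AA <- .color_overlap(colA, colA)
  best <- NULL
  for (ci in seq_along(probe$conformers)) {
    B0 <- gaussian_model(probe, ci)
    O_BB <- overlap_volume(B0, B0)
    inits <- .pca_inits(A$xyz, B0$xyz)
    if (!is.null(query)) {
      m <- match_pharmacophore(query, probe, "partial")
      if (!is.null(m) && m$conformer_index == ci)
        inits <- c(inits, list(m$transform))
    }
    obj <- function(par, R0, t0) {
      Rv <- .rotation_from_axis_angle(par[4:6])
      B <- .transform_model(B0, R0 %*% Rv, t0 + par[1:3])
      -overlap_volume(A, B)
    }
    for (init in inits) {
      o <- stats::optim(rep(0, 6), obj, R0 = init$R, t0 = init$t,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-4))
      O_AB <- -o$value
      if (is.null(best) || O_AB > best$O_AB) {
        Rv <- .rotation_from_axis_angle(o$par[4:6])
        best <- list(O_AB = O_AB, O_BB = O_BB,
                     transform = list(R = init$R %*% Rv, t = init$t + o$par[1:3]),
                     conformer_index = ci)
      }
    }
  }
  colB <- .color_model(probe, best$conformer_index)
  colB <- .transform_model(colB, best$transform$R, best$transform$t)
  C_BB <- .color_overlap(.color_model(probe, best$conformer_index),
                         .color_model(probe, best$conformer_index))
  C_AB <- .color_overlap(colA, colB)
  T_shape <- best$O_AB / (O_AA + best$O_BB - best$O_AB)
  cden <- C_AA + C_BB - C_AB
  T_color <- if (cden > 0) C_AB / cden else 0
  structure(list(O_AA = O_AA, O_BB = best$O_BB, O_AB = best$O_AB,
                 T_shape = T_shape, T_color = T_color,
                 combo = T_shape + T_color,
                 transform = best$transform,
                 conformer_index = best$conformer_index),
            class = "shape_score")
}

#' @export
print.shape_score <- function(x, ...) {
  cat(sprintf("<shape_score: T_shape %.3f, T_color %.3f, combo %.3f>\n",
              x$T_shape, x$T_color, x$combo))
  invisible(x)
}

#' Shape-similarity screen of a library against a reference
#'
#' Scores every library molecule with [align_and_score] and returns the top
#' `top_n` by combo score (shape + color Tanimoto), ties broken by molecule
#' ID. The default retrieval depth is 500 per library.
#'
#' @param reference a [molecule_record].
#' @param library list of [molecule_record]s.
#' @param top_n retrieval depth (>= 1).
#' @param query optional shared [pharmacophore_query] for extra starting
#'   poses.
#' @param labels optional named label vector carried into the result.
#' @param verbose log progress.
#' @return a `ranked_screen` data.frame with columns `id`, `score` (combo),
#'   `T_shape`, `T_color`, `conformer_index`.
#' @export
shape_screen <- function(reference, library, top_n = 500L, query = NULL,
                         labels = NULL, verbose = FALSE) {
  if (top_n < 1L) stop("top_n must be >= 1")
  if (!length(library)) stop("library is empty")
  rows <- lapply(library, function(mol) {
    mol <- ensure_conformer(mol)
    s <- align_and_score(reference, mol, query = query)
    data.frame(id = mol$id, score = s$combo, T_shape = s$T_shape,
               T_color = s$T_color, conformer_index = s$conformer_index)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$id), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  if (!is.null(labels)) out$label <- unname(labels[out$id])
  if (verbose) message(sprintf("shape screen: kept %d of %d molecules",
                               nrow(out), length(library)))
  class(out) <- c("ranked_screen", class(out))
  out
}
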
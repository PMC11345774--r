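# Independent reference implementations used as oracles. They deliberately
# use different algorithms from the package internals: superposition by
# Horn's quaternion method (the package uses SVD), AUC by explicit pairwise
# counting (the package uses the rank-sum estimator), and Gaussian overlap by
# grid quadrature (the package uses the closed form).

# Horn (1987) closed-form quaternion superposition: rotate `moving` onto
# `fixed` (row-vector convention, as in the package).
horn_superpose <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  # row-vector convention: moved = moving %*% Rrow + t
  Rrow <- t(R)
  list(R = Rrow, t = cf - as.numeric(cm %*% Rrow))
}

# Exhaustive pharmacophore assignment search: all injective kind-compatible
# assignments of query-feature subsets to ligand features, no pruning.
# Returns the best score or NULL.
brute_force_match <- function(query, feats, mode = "full") {
  qf <- query$features
  nq <- nrow(qf)
  qcent <- as.matrix(qf[, c("x", "y", "z")])
  lcent <- as.matrix(feats[, c("x", "y", "z")])
  required <- match(query$required_labels, qf$label)
  best <- NULL
  eval_assign <- function(qidx, lidx) {
    if (length(qidx) == 1L) {
      tr <- list(R = diag(3), t = as.numeric(qcent[qidx, ] - lcent[lidx, ]))
    } else {
      tr <- horn_superpose(lcent[lidx, , drop = FALSE], qcent[qidx, , drop = FALSE])
    }
    moved <- sweep(lcent[lidx, , drop = FALSE] %*% tr$R, 2, tr$t, `+`)
    d <- sqrt(rowSums((moved - qcent[qidx, , drop = FALSE])^2))
    r <- qf$radius[qidx]
    if (any(d > r)) return(NULL)
    9 * length(qidx) + sum(1 - d / r)
  }
  subsets <- unlist(lapply(seq_len(nq), function(k)
    utils::combn(nq, k, simplify = FALSE)), recursive = FALSE)
  for (qidx in subsets) {
    if (mode == "full" && !all(required %in% qidx)) next
    cands <- lapply(qidx, function(i) which(feats$kind == qf$kind[i]))
    if (any(lengths(cands) == 0L)) next
    assigns <- Reduce(function(acc, cs) {
      out <- list()
      for (a in acc) for (c in cs) if (!c %in% a) out[[length(out) + 1L]] <- c(a, c)
      out
    }, cands, accumulate = FALSE, init = list(integer()))
    for (lidx in assigns) {
      s <- eval_assign(qidx, lidx)
      if (!is.null(s) && (is.null(best) || s > best)) best <- s
    }
  }
  best
}

# Gaussian product-density overlap by grid quadrature (0.1 A spacing).
grid_overlap <- function(A, B, spacing = 0.1, pad = 3.5) {
  allxyz <- rbind(A$xyz, B$xyz)
  lo <- apply(allxyz, 2, min) - pad
  hi <- apply(allxyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  dens <- function(M) {
    rho <- numeric(nrow(grid))
    for (i in seq_len(nrow(M$xyz))) {
      d2 <- rowSums(sweep(grid, 2, M$xyz[i, ])^2)
      rho <- rho + M$p * exp(-M$alpha[i] * d2)
    }
    rho
  }
  sum(dens(A) * dens(B)) * spacing^3
}

# AUC by explicit counting over all active-decoy pairs.
pairwise_auc <- function(score, is_active) {
  sa <- score[is_active]; sd <- score[!is_active]
  tot <- 0
  for (a in sa) tot <- tot + sum(a > sd) + 0.5 * sum(a == sd)
  tot / (length(sa) * length(sd))
}
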
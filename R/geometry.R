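# Small 3D geometry helpers shared by the builder, the pharmacophore engine
# and the shape engine.

# n-gon of given circumradius in a plane of constant z
.polygon_coords <- function(center, radius, n, z_offset = 0, start_angle = 0) {
  ang <- start_angle + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radius * cos(ang),
        center[2] + radius * sin(ang),
        center[3] + z_offset)
}

# rotation matrix from axis-angle vector (Rodrigues); |v| is the angle
.rotation_from_axis_angle <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# least-squares rigid superposition (Kabsch): returns R, t with
# moving %*% R + t ~= fixed; proper rotation only (reflections rejected).
.kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed))
  if (nrow(moving) == 1L) {
    return(list(R = diag(3), t = as.numeric(fixed[1L, ] - moving[1L, ])))
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2L, cm); B <- sweep(fixed, 2L, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- cf - as.numeric(cm %*% R)
  list(R = R, t = t_vec)
}

.apply_transform <- function(xyz, R, t) {
  sweep(xyz %*% R, 2L, t, `+`)
}

# random unit vector under the current RNG
.runif_unit <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-4 && n2 <= 1) return(v / sqrt(n2))
  }
}

# evaluate expr with a private RNG stream; the caller's RNG state is restored
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
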
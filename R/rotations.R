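# Rotation encoding: scaled Cayley (Gibbs) vectors g = tan(theta/2) * axis,
# stored in configuration vectors as c = scale * g. The scale is declared in
# the parameter-set metadata (default 10).

#' @noRd
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# R(g) = I + 2/(1+|g|^2) * ([g]x + [g]x^2)
#' @noRd
gibbs_to_rot <- function(g) {
  S <- skew3(g)
  a <- 2 / (1 + sum(g * g))
  diag(3) + a * (S + S %*% S)
}

# Inverse of gibbs_to_rot. Undefined for rotations of angle pi (trace -1).
#' @noRd
rot_to_gibbs <- function(R) {
  denom <- 1 + R[1, 1] + R[2, 2] + R[3, 3]
  if (denom < 1e-8) {
    stop("rotation decode failure: angle too close to pi for the Cayley encoding")
  }
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / denom
}

# Gibbs vector of the half rotation (square root): tan(theta/4) * axis.
#' @noRd
gibbs_half <- function(g) {
  g / (1 + sqrt(1 + sum(g * g)))
}

# Derivatives dR/dg_k of gibbs_to_rot, returned as a list of three 3x3 matrices.
#' @noRd
dgibbs_rot <- function(g) {
  S <- skew3(g)
  SS <- S %*% S
  cc <- 1 + sum(g * g)
  a <- 2 / cc
  da <- -4 * g / (cc * cc)
  lapply(1:3, function(k) {
    Ek <- skew3(c(k == 1, k == 2, k == 3))
    da[k] * (S + SS) + a * (Ek + Ek %*% S + S %*% Ek)
  })
}

# Derivatives dS/dg_k of the half-rotation matrix S = R(h(g)),
# h(g) = g / (1 + sqrt(1+|g|^2)).
#' @noRd
dgibbs_half_rot <- function(g) {
  alpha <- sqrt(1 + sum(g * g))
  h <- g / (1 + alpha)
  # Jacobian dh/dg
  Jh <- diag(3) / (1 + alpha) -
    (h %o% g) / (alpha * (1 + alpha))
  dRh <- dgibbs_rot(h)
  lapply(1:3, function(k) {
    Jh[1, k] * dRh[[1]] + Jh[2, k] * dRh[[2]] + Jh[3, k] * dRh[[3]]
  })
}

#' @noRd
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && det(R) > 0
}
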
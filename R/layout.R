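# Canonical coordinate layout.
#
# A configuration of an n base-pair molecule is
#   w = (y_1, eta_1, y_2, eta_2, ..., eta_{n-1}, y_n),
# with y_a in R^6 the intra base-pair coordinates of base pair a and
# eta_a in R^18 the junction block of junction a, ordered as
# (Crick phosphate 6, inter base-pair 6, Watson phosphate 6). Every 6-block is
# (rotation 3, translation 3); rotations are scaled Cayley vectors,
# translations are in Angstrom. Total dimension N = 24 n - 18.

#' Number of configuration coordinates for an n base-pair molecule
#'
#' @param n number of base pairs (n >= 2).
#' @return The integer `24 * n - 18`.
#' @export
n_coords <- function(n) {
  stopifnot(n >= 2)
  24L * as.integer(n) - 18L
}

#' @noRd
idx_intra <- function(a) (a - 1L) * 24L + 1:6

#' @noRd
idx_phos_crick <- function(a) (a - 1L) * 24L + 7:12

#' @noRd
idx_inter <- function(a) (a - 1L) * 24L + 13:18

#' @noRd
idx_phos_watson <- function(a) (a - 1L) * 24L + 19:24

#' @noRd
idx_step_block <- function(a) (a - 1L) * 24L + 1:30

# Split a configuration vector into component matrices (6 x count each).
#' @noRd
split_config <- function(w, n) {
  stopifnot(length(w) == n_coords(n))
  list(
    intra = vapply(seq_len(n), function(a) w[idx_intra(a)], numeric(6)),
    pc    = vapply(seq_len(n - 1L), function(a) w[idx_phos_crick(a)], numeric(6)),
    inter = vapply(seq_len(n - 1L), function(a) w[idx_inter(a)], numeric(6)),
    pw    = vapply(seq_len(n - 1L), function(a) w[idx_phos_watson(a)], numeric(6))
  )
}

#' @noRd
join_config <- function(intra, pc, inter, pw) {
  n <- ncol(intra)
  w <- numeric(n_coords(n))
  for (a in seq_len(n)) w[idx_intra(a)] <- intra[, a]
  for (a in seq_len(n - 1L)) {
    w[idx_phos_crick(a)] <- pc[, a]
    w[idx_inter(a)] <- inter[, a]
    w[idx_phos_watson(a)] <- pw[, a]
  }
  w
}

# Per-6-block sign matrix of the reverse-complement involution: the first
# rotation and first translation coordinate flip sign (tilt/shift-like), the
# others are preserved.
#' @noRd
e6_signs <- function() c(-1, 1, 1, -1, 1, 1)

#' @noRd
e6_matrix <- function() diag(e6_signs())

# 30-dim reverse-complement involution acting on a dimer-step block
# (y1, pC, inter, pW, y2) -> (E6 y2, E6 pW, E6 inter, E6 pC, E6 y1).
#' @noRd
e30_matrix <- function() {
  E <- matrix(0, 30, 30)
  E6 <- e6_matrix()
  E[1:6, 25:30] <- E6
  E[7:12, 19:24] <- E6
  E[13:18, 13:18] <- E6
  E[19:24, 7:12] <- E6
  E[25:30, 1:6] <- E6
  E
}

#' Reverse-complement involution operator on configuration space
#'
#' Returns the signed permutation matrix `E` (as a sparse [Matrix::Matrix])
#' such that for a parameter set consistent under reverse complementation,
#' `mu(revcomp(s)) = E %*% mu(s)` and `K(revcomp(s)) = E K(s) t(E)`.
#'
#' @param n number of base pairs.
#' @return A sparse `N x N` matrix with `N = 24 n - 18`; an involution
#'   (`E %*% E` is the identity).
#' @export
involution_operator <- function(n) {
  N <- n_coords(n)
  s <- e6_signs()
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_block <- function(ri, ci) {
    ii <<- c(ii, ri); jj <<- c(jj, ci); xx <<- c(xx, s)
  }
  for (a in seq_len(n)) add_block(idx_intra(a), idx_intra(n + 1L - a))
  for (a in seq_len(n - 1L)) {
    add_block(idx_phos_crick(a), idx_phos_watson(n - a))
    add_block(idx_inter(a), idx_inter(n - a))
    add_block(idx_phos_watson(a), idx_phos_crick(n - a))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
}
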
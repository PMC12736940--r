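# Sequence-dependent Gaussian model: ground state mu and banded SPD
# stiffness K, assembled from per-dimer-step parameter blocks, with energy,
# partition function, log density and entropy.
#
# The model assigns a 147*24-18 = 3510 dimensional (for a nucleosome-length
# fragment) Gaussian over configurations w, with energy in kT
#   U(w) = 1/2 (w - mu) . K (w - mu).

#' @noRd
step_label_for_junction <- function(seq, a) {
  r <- which(seq$mods$step_index == a)
  if (length(r) == 1L) {
    if (seq$mods$kind[r] == "methyl") "MN" else "HK"
  } else {
    paste0(seq$chars[a], seq$chars[a + 1L])
  }
}

#' Build the Gaussian model for a sequence
#'
#' Assembles the banded stiffness matrix `K` by overlapping addition of
#' per-step 30-dim blocks (adjacent blocks share the 6 intra coordinates of
#' the common base pair), plus optional terminal corrections; the
#' stiffness-weighted mean `sigma` is assembled identically and the ground
#' state solves `K mu = sigma` by sparse Cholesky.
#'
#' @param seq a `mod_sequence` (or string); modified CpG steps use the MN/HK
#'   parameter blocks.
#' @param params a `parameter_set` covering every step label of `seq`.
#' @return An object of class `gaussian_model` with fields `n`, `N`
#'   (`= 24 n - 18`), `mu`, `K` (sparse symmetric), `rotation_scale`, `meta`.
#' @export
build_model <- function(seq, params) {
  seq <- as_mod_sequence(seq)
  n <- length(seq)
  if (n < 2) stop("build_model needs at least 2 base pairs")
  N <- n_coords(n)
  labels <- vapply(seq_len(n - 1L), function(a) step_label_for_junction(seq, a),
                   character(1))
  missing <- setdiff(unique(labels), names(params$steps))
  if (length(missing) > 0) {
    stop("parameter set lacks blocks for step label(s): ",
         paste(missing, collapse = ", "))
  }
  # triplet assembly of K and sigma
  blk_n <- 30L * 30L
  n_steps <- n - 1L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  sigma <- numeric(N)
  tmpl <- rep(1:30, times = 30)
  tmpl_j <- rep(1:30, each = 30)
  for (a in seq_len(n_steps)) {
    blk <- params$steps[[labels[a]]]
    off <- (a - 1L) * 24L
    ii <- c(ii, off + tmpl)
    jj <- c(jj, off + tmpl_j)
    xx <- c(xx, as.vector(blk$stiffness))
    sigma[idx_step_block(a)] <- sigma[idx_step_block(a)] + blk$weighted_mean
  }
  if (!is.null(params$ends)) {
    fb <- params$ends$first[[seq$chars[1]]]
    if (!is.null(fb)) {
      ii <- c(ii, rep(1:6, times = 6)); jj <- c(jj, rep(1:6, each = 6))
      xx <- c(xx, as.vector(fb$stiffness))
      sigma[1:6] <- sigma[1:6] + fb$weighted_mean
    }
    lb <- params$ends$last[[seq$chars[n]]]
    if (!is.null(lb)) {
      off <- (n - 1L) * 24L
      ii <- c(ii, off + rep(1:6, times = 6)); jj <- c(jj, off + rep(1:6, each = 6))
      xx <- c(xx, as.vector(lb$stiffness))
      sigma[idx_intra(n)] <- sigma[idx_intra(n)] + lb$weighted_mean
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
  ch <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE),
                 error = function(e) {
                   stop("assembled stiffness matrix is not positive definite: ",
                        conditionMessage(e))
                 })
  mu <- as.numeric(Matrix::solve(ch, sigma, system = "A"))
  new_gaussian_model(mu, K, n = n,
                     rotation_scale = params$meta$rotation_scale,
                     meta = params$meta, chol = ch)
}

#' Low-level Gaussian model constructor
#'
#' Wraps a ground state and SPD stiffness into a `gaussian_model` without
#' going through a parameter set. Mainly useful for toy models in tests and
#' validation studies; geometric operations require `N = 24 n - 18` with the
#' canonical layout.
#'
#' @param mu length-`N` ground-state vector.
#' @param K `N x N` symmetric positive-definite matrix (dense or sparse).
#' @param n number of base pairs, or `NULL` for layout-free toy models.
#' @param rotation_scale Cayley scale used by geometric reconstruction.
#' @param meta optional convention metadata.
#' @param chol optional precomputed `Matrix::Cholesky` factor of `K`.
#' @export
new_gaussian_model <- function(mu, K, n = NULL, rotation_scale = 10,
                               meta = NULL, chol = NULL) {
  N <- length(mu)
  K <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
  stopifnot(nrow(K) == N)
  if (!is.null(n) && n_coords(n) != N) {
    stop("mu has length ", N, " but n = ", n, " implies N = ", n_coords(n))
  }
  if (is.null(chol)) {
    chol <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE),
                     error = function(e) stop("K is not positive definite"))
  }
  ldet <- as.numeric(2 * Matrix::determinant(chol, sqrt = TRUE)$modulus)
  structure(list(n = n, N = N, mu = mu, K = K, chol = chol, ldetK = ldet,
                 rotation_scale = rotation_scale, meta = meta,
                 layout = "canonical"),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("gaussian_model: n = %s bp, N = %d coordinates\n",
              ifelse(is.null(x$n), "?", x$n), x$N))
  cat(sprintf("  ln det K = %.6g, half-bandwidth <= %d\n", x$ldetK,
              band_halfwidth(x$K)))
  invisible(x)
}

#' @noRd
band_halfwidth <- function(K) {
  K <- methods::as(methods::as(K, "generalMatrix"), "TsparseMatrix")
  if (length(K@i) == 0) return(0L)
  max(abs(K@i - K@j))
}

#' Elastic energy of a configuration
#'
#' `U(w) = 1/2 (w - mu) . K (w - mu)` in units of kT; zero exactly at the
#' ground state.
#'
#' @param w configuration vector of length `model$N`.
#' @param model a `gaussian_model`.
#' @return Non-negative scalar (kT).
#' @export
energy <- function(w, model) {
  if (length(w) != model$N) {
    stop("configuration has length ", length(w), ", expected ", model$N)
  }
  d <- w - model$mu
  sum(d * as.numeric(model$K %*% d)) / 2
}

#' Log partition function
#'
#' `ln Z = (N/2) ln(2*pi) - (1/2) ln det K`, with the log-determinant from
#' the sparse Cholesky factorisation.
#'
#' @param model a `gaussian_model`.
#' @return Scalar.
#' @export
log_partition <- function(model) {
  model$N / 2 * log(2 * pi) - model$ldetK / 2
}

#' Log probability density of a configuration
#'
#' `ln rho(w) = -U(w) + (1/2) ln det K - (N/2) ln(2*pi)`.
#'
#' @inheritParams energy
#' @return Scalar.
#' @export
log_density <- function(w, model) {
  -energy(w, model) + model$ldetK / 2 - model$N / 2 * log(2 * pi)
}

#' Differential entropy of the Gaussian model
#'
#' `H = (N/2)(1 + ln 2*pi) - (1/2) ln det K`, so that
#' `ln rho(w) = -U(w) - H + N/2` holds exactly.
#'
#' @param model a `gaussian_model`.
#' @return Scalar (nats).
#' @export
entropy <- function(model) {
  model$N / 2 * (1 + log(2 * pi)) - model$ldetK / 2
}
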
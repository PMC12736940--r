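# Shared fixtures, built once per test run, and small independent oracles.

fixture_params <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- synthetic_parameter_set(seed = 1)
    ps
  }
})

# toy constraint set near the ground-state phosphate positions of a model;
# the pulls alternate in sign per record so the displacement field is not a
# rigid motion (which would be absorbed by the rigid-placement alignment)
toy_constraints <- function(model, junctions, strands, pull = c(2, -1, 3),
                            coefficient = 2) {
  bound <- data.frame(strand = strands, junction = junctions)
  pos <- phosphate_positions(model$mu, model$n, bound, model$rotation_scale)
  sgn <- (-1)^seq_along(junctions)
  constraint_set(data.frame(strand = strands, junction = junctions,
                            x = pos[1, ] + sgn * pull[1],
                            y = pos[2, ] + sgn * pull[2],
                            z = pos[3, ] + sgn * pull[3], c = coefficient))
}

# brute-force enumeration of all dinucleotide-preserving shuffles of a short
# string (depth-first over the edge multiset; oracle for the AE shuffle)
enumerate_shuffles <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  edges <- table(factor(paste0(ch[-n], ch[-1])))
  counts <- as.list(edges)
  out <- character(0)
  recurse <- function(cur, path, remaining, left) {
    if (left == 0) {
      out <<- c(out, paste(path, collapse = ""))
      return(invisible())
    }
    for (key in names(remaining)) {
      if (remaining[[key]] > 0 && substr(key, 1, 1) == cur) {
        remaining[[key]] <- remaining[[key]] - 1
        recurse(substr(key, 2, 2), c(path, substr(key, 2, 2)), remaining,
                left - 1)
        remaining[[key]] <- remaining[[key]] + 1
      }
    }
  }
  recurse(ch[1], ch[1], counts, n - 1)
  unique(out)
}

# Horn quaternion absolute-orientation solver: independent oracle for the
# SVD-based Kabsch superposition
quaternion_superpose_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(X, Y)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  Nq <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(Nq, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(X^2) + sum(Y^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(mobile))
}

# random banded SPD matrix (dense) for log-determinant oracles
random_banded_spd <- function(N, bw = 5) {
  A <- matrix(0, N, N)
  for (d in 0:bw) {
    v <- stats::rnorm(N - d, sd = 0.3)
    A[cbind(seq_len(N - d), seq_len(N - d) + d)] <- v
    A[cbind(seq_len(N - d) + d, seq_len(N - d))] <- v
  }
  diag(A) <- abs(diag(A)) + bw
  A
}
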
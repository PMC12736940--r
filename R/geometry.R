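# Bidirectional map between internal coordinates and absolute rigid-body
# frames, phosphate Cartesian positions with analytic Jacobians, and
# point-set utilities for structure ensembles.
#
# Conventions (recorded in parameter-set meta):
#  - successive base-pair frames are placed by mid-frame composition: the
#    inter translation is expressed in the half-rotated (mid) frame, which is
#    what makes the reverse-complement involution exact;
#  - the two base frames of a pair are split off the base-pair frame by the
#    half intra rotation (Crick axes flipped about x);
#  - each junction's Watson phosphate is referred to the Watson base frame of
#    the 3'-side base pair (a+1), the Crick phosphate to the Crick base frame
#    of base pair a.

#' @noRd
FLIP <- diag(c(1, -1, -1))

#' Construct a rigid frame
#' @param origin 3-vector (Angstrom).
#' @param R 3x3 rotation matrix.
#' @return List with class `rigid_frame`.
#' @export
rigid_frame <- function(origin = c(0, 0, 0), R = diag(3)) {
  if (!is_rotation(R)) stop("orientation is not a proper rotation matrix")
  structure(list(origin = as.numeric(origin), R = R), class = "rigid_frame")
}

#' Reconstruct absolute frames from internal coordinates
#'
#' Sequentially composes base-pair frames from the inter coordinates
#' (mid-frame construction), splits each base pair into Watson and Crick base
#' frames via the intra coordinates, and places each junction's phosphates
#' relative to their reference base frames.
#'
#' @param w configuration vector in the canonical layout.
#' @param n number of base pairs.
#' @param rotation_scale Cayley scale of the rotation coordinates.
#' @param anchor `rigid_frame` of the first base pair (default identity at
#'   the origin).
#' @return An `embedded_config`: lists of base-pair/base frame arrays and
#'   3 x (n-1) phosphate position matrices (plus phosphate orientations, so
#'   the map is invertible).
#' @export
coords_to_frames <- function(w, n, rotation_scale = 10, anchor = NULL) {
  if (is.null(anchor)) anchor <- rigid_frame()
  stopifnot(length(w) == n_coords(n))
  emb <- cpp_embed(w, as.integer(n), rotation_scale, anchor$R, anchor$origin)
  structure(c(list(n = n, rotation_scale = rotation_scale, anchor = anchor),
              emb),
            class = "embedded_config")
}

#' Recover internal coordinates from absolute frames
#'
#' Exact inverse of [coords_to_frames()]; invariant under rigid motions of
#' the whole configuration.
#'
#' @param config an `embedded_config`.
#' @param rotation_scale Cayley scale (defaults to the one stored in
#'   `config`).
#' @return Configuration vector `w`.
#' @export
frames_to_coords <- function(config, rotation_scale = NULL) {
  s <- if (is.null(rotation_scale)) config$rotation_scale else rotation_scale
  n <- config$n
  for (a in seq_len(n)) {
    if (!is_rotation(config$bp_R[, , a], tol = 1e-7) ||
        !is_rotation(config$watson_R[, , a], tol = 1e-7) ||
        !is_rotation(config$crick_R[, , a], tol = 1e-7)) {
      stop("non-orthonormal input frame at base pair ", a)
    }
  }
  intra <- matrix(0, 6, n); inter <- matrix(0, 6, n - 1L)
  pw <- matrix(0, 6, n - 1L); pc <- matrix(0, 6, n - 1L)
  for (a in seq_len(n)) {
    G <- config$bp_R[, , a]
    P <- crossprod(G, config$watson_R[, , a])
    intra[1:3, a] <- rot_to_gibbs(P %*% P) * s
    intra[4:6, a] <- crossprod(G, config$watson_o[, a] - config$crick_o[, a])
  }
  for (a in seq_len(n - 1L)) {
    G <- config$bp_R[, , a]
    Lam <- crossprod(G, config$bp_R[, , a + 1L])
    g <- rot_to_gibbs(Lam)
    S <- gibbs_to_rot(gibbs_half(g))
    inter[1:3, a] <- g * s
    inter[4:6, a] <- crossprod(S, crossprod(G, config$bp_o[, a + 1L] - config$bp_o[, a]))
    Rwb <- config$watson_R[, , a + 1L]
    pw[1:3, a] <- rot_to_gibbs(crossprod(Rwb, config$phosW_R[, , a])) * s
    pw[4:6, a] <- crossprod(Rwb, config$phosW_o[, a] - config$watson_o[, a + 1L])
    Rcb <- config$crick_R[, , a]
    pc[1:3, a] <- rot_to_gibbs(crossprod(Rcb, config$phosC_R[, , a])) * s
    pc[4:6, a] <- crossprod(Rcb, config$phosC_o[, a] - config$crick_o[, a])
  }
  join_config(intra, pc, inter, pw)
}

#' @noRd
check_bound_table <- function(bound, n) {
  bound <- as.data.frame(bound)
  stopifnot(all(c("strand", "junction") %in% names(bound)))
  bound$strand <- as.character(bound$strand)
  if (!all(bound$strand %in% c("watson", "crick"))) {
    stop("strand must be 'watson' or 'crick'")
  }
  if (any(bound$junction < 1L | bound$junction > n - 1L)) {
    stop("phosphate junction index out of range 1..", n - 1L)
  }
  bound
}

#' Cartesian positions of selected phosphates
#'
#' @inheritParams coords_to_frames
#' @param bound data.frame with columns `strand` ("watson"/"crick") and
#'   `junction` (1-based), in the order positions are wanted.
#' @return 3 x m matrix of positions (Angstrom).
#' @export
phosphate_positions <- function(w, n, bound, rotation_scale = 10, anchor = NULL) {
  bound <- check_bound_table(bound, n)
  if (is.null(anchor)) anchor <- rigid_frame()
  cpp_phos_positions(w, as.integer(n), rotation_scale, anchor$R,
                     anchor$origin,
                     ifelse(bound$strand == "watson", 1L, 2L),
                     as.integer(bound$junction))
}

# Analytic Jacobian of selected phosphate positions with respect to the full
# configuration vector (compiled kernel). Returns positions (3 x m) and
# J ((3m) x N); row block (3i-2):(3i) belongs to constraint i.
#' @noRd
phosphate_jacobian <- function(w, n, bound, rotation_scale = 10,
                               anchor = NULL) {
  bound <- check_bound_table(bound, n)
  if (is.null(anchor)) anchor <- rigid_frame()
  cpp_phos_jacobian(w, as.integer(n), rotation_scale, anchor$R,
                    anchor$origin,
                    ifelse(bound$strand == "watson", 1L, 2L),
                    as.integer(bound$junction))
}

#' All phosphate positions of a configuration
#'
#' @inheritParams coords_to_frames
#' @return data.frame with columns `strand`, `index` (junction), `x`, `y`,
#'   `z`.
#' @export
all_phosphate_positions <- function(w, n, rotation_scale = 10, anchor = NULL) {
  emb <- coords_to_frames(w, n, rotation_scale, anchor)
  data.frame(
    strand = rep(c("watson", "crick"), each = n - 1L),
    index = rep(seq_len(n - 1L), 2),
    x = c(emb$phosW_o[1, ], emb$phosC_o[1, ]),
    y = c(emb$phosW_o[2, ], emb$phosC_o[2, ]),
    z = c(emb$phosW_o[3, ], emb$phosC_o[3, ])
  )
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum || R mobile_i + t - reference_i ||^2` (no reflection).
#'
#' @param mobile,reference m x 3 matrices of corresponding points, m >= 3
#'   and not collinear.
#' @return List with `R`, `t`, `rmsd`, and `transform(points)`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  sv <- svd(crossprod(X, Y))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) geometry; superposition not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(R = R, t = t_vec, rmsd = rmsd,
       transform = function(p) sweep(as.matrix(p) %*% t(R), 2, t_vec, "+"))
}

#' Principal axis of a point cloud
#'
#' The axis of smallest coordinate variance through the centroid; for a
#' nucleosome-like disc of phosphates this is the superhelical (central)
#' axis.
#'
#' @param points m x 3 matrix.
#' @return List `(point, direction)` with unit `direction`.
#' @export
principal_axis <- function(points) {
  points <- as.matrix(points)
  ev <- eigen(stats::cov(points), symmetric = TRUE)
  dir <- ev$vectors[, 3]
  list(point = colMeans(points), direction = dir / sqrt(sum(dir^2)))
}

#' Fitted cylindrical symmetry axis of a point cloud
#'
#' Refines the principal axis by minimising the variance of point-to-axis
#' distances (a cylinder fit), which removes the tilt bias the raw inertia
#' axis picks up from partial-turn helical clouds such as the ~1.65-turn
#' nucleosome superhelix.
#'
#' @param points m x 3 matrix.
#' @return List `(point, direction)` with unit `direction`.
#' @export
fit_symmetry_axis <- function(points) {
  points <- as.matrix(points)
  ax0 <- principal_axis(points)
  d0 <- ax0$direction
  ref <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d0) * d0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d0[2] * e1[3] - d0[3] * e1[2],
          d0[3] * e1[1] - d0[1] * e1[3],
          d0[1] * e1[2] - d0[2] * e1[1])
  ctr <- colMeans(points)
  obj <- function(par) {
    d <- d0 + par[1] * e1 + par[2] * e2
    d <- d / sqrt(sum(d^2))
    p0 <- ctr + par[3] * e1 + par[4] * e2
    rel <- sweep(points, 2, p0)
    h <- rel %*% d
    stats::var(sqrt(pmax(rowSums(rel^2) - h^2, 0)))
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  d <- d0 + fit$par[1] * e1 + fit$par[2] * e2
  d <- d / sqrt(sum(d^2))
  list(point = as.numeric(ctr + fit$par[3] * e1 + fit$par[4] * e2),
       direction = as.numeric(d))
}

#' Cylindrical coordinates of points about an axis
#'
#' @param points m x 3 matrix of positions (Angstrom).
#' @param axis list `(point, direction)`; default the principal axis of the
#'   cloud.
#' @return data.frame with `radius` (distance to the axis), `angle`
#'   (radians about the axis), `height` (along the axis).
#' @export
cylindrical_profile <- function(points, axis = NULL) {
  points <- as.matrix(points)
  if (is.null(axis)) axis <- principal_axis(points)
  d <- as.numeric(axis$direction)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("zero-length axis direction")
  d <- d / nd
  # orthonormal in-plane basis
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  rel <- sweep(points, 2, as.numeric(axis$point))
  h <- rel %*% d
  u <- rel %*% e1; v <- rel %*% e2
  data.frame(radius = sqrt(u^2 + v^2), angle = atan2(v, u), height = as.numeric(h))
}

## ---- structure ensembles ----

#' Construct a structure ensemble from a coordinate table
#'
#' @param df data.frame with columns `structure_id`, `strand`
#'   ("watson"/"crick"), `index` (junction), `x`, `y`, `z` (Angstrom).
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(df) {
  df <- as.data.frame(df)
  need <- c("structure_id", "strand", "index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("structure table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$strand %in% c("watson", "crick"))) {
    stop("strand must be 'watson' or 'crick'")
  }
  structure(list(table = df,
                 n_structures = length(unique(df$structure_id))),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d structures, %d phosphate records\n",
              x$n_structures, nrow(x$table)))
  invisible(x)
}

#' Read a structure ensemble from a tabular file
#'
#' Tab-separated with header `structure_id strand index x y z` (Angstrom).
#'
#' @param path file path.
#' @return A `structure_ensemble`.
#' @export
read_structure_ensemble <- function(path) {
  structure_ensemble(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
}

#' Write a structure ensemble to a tabular file
#' @param ens a `structure_ensemble`.
#' @param path output path.
#' @export
write_structure_ensemble <- function(ens, path) {
  utils::write.table(ens$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract phosphorus atoms from a PDB file as one ensemble structure
#'
#' Minimal reader for the backbone phosphorus records of a nucleosome PDB
#' file; junction indexing follows residue order per chain (first chain is
#' taken as Watson, second as Crick).
#'
#' @param path PDB file.
#' @param structure_id identifier to assign.
#' @return data.frame in the [structure_ensemble()] column schema.
#' @export
structure_from_pdb <- function(path, structure_id = basename(path)) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  name <- trimws(substr(at, 13, 16))
  keep <- name == "P"
  if (!any(keep)) stop("no phosphorus atoms found in ", path)
  at <- at[keep]
  chain <- substr(at, 22, 22)
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  chains <- unique(chain)
  if (length(chains) > 2) chains <- chains[1:2]
  out <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    sel <- chain == chains[ci]
    data.frame(structure_id = structure_id,
               strand = if (ci == 1) "watson" else "crick",
               index = seq_len(sum(sel)),
               x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3])
  }))
  out
}
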
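# Synthetic-data generators: every stage of the pipeline is testable with no
# external downloads. The parameter sets are structurally valid (symmetric,
# SPD-assembling, reverse-complement consistent) stand-ins with B-DNA-like
# ground states, not fits to simulation data; constraint geometries follow
# the standard nucleosome superhelix.

#' Superhelix specification
#'
#' Default geometry is the standard nucleosome superhelix (radius 41.9 A,
#' pitch 25.9 A, 1.65 turns, ~10.2 bp contact spacing), used here only as a
#' fixture default.
#'
#' @param radius superhelix radius in Angstrom.
#' @param pitch rise per superhelical turn in Angstrom.
#' @param turns number of superhelical turns over the fragment.
#' @param bp_per_turn DNA helical repeat (junctions between successive
#'   histone contacts on one strand).
#' @param handedness `"left"` or `"right"`.
#' @return Object of class `superhelix_spec`.
#' @export
superhelix_spec <- function(radius = 41.9, pitch = 25.9, turns = 1.65,
                            bp_per_turn = 10.2, handedness = "left") {
  stopifnot(radius > 0, bp_per_turn > 0)
  handedness <- match.arg(handedness, c("left", "right"))
  structure(list(radius = radius, pitch = pitch, turns = turns,
                 bp_per_turn = bp_per_turn, handedness = handedness),
            class = "superhelix_spec")
}

#' @noRd
superhelix_point <- function(spec, frac) {
  # frac in [0,1] along the fragment; returns position on the superhelix
  sgn <- if (spec$handedness == "left") -1 else 1
  phi <- sgn * 2 * pi * spec$turns * frac
  z <- spec$pitch * spec$turns * (frac - 0.5)
  cbind(spec$radius * cos(phi), spec$radius * sin(phi), z)
}

#' Synthetic parameter set
#'
#' Random symmetric positive-definite 30-dim stiffness blocks for all 18
#' extended-alphabet step labels, constructed to satisfy the
#' reverse-complement involution exactly, with B-DNA-like weighted means
#' (~34 deg twist, 3.4 A rise, phosphates ~9 A off-axis). The modified-step
#' blocks (MN/HK) are stiffened copies of the CG block with shifted roll and
#' twist means, emulating the qualitative effect of cytosine modification.
#'
#' @param seed integer seed; the result is bit-reproducible.
#' @param block_scale overall multiplier on all stiffness blocks.
#' @param include_ends include small terminal base corrections.
#' @return A validated [parameter_set()].
#' @export
synthetic_parameter_set <- function(seed = 1, block_scale = 1,
                                    include_ends = TRUE) {
  set.seed(seed)
  E30 <- e30_matrix()
  E6 <- e6_matrix()
  scale <- 10
  # B-DNA-ish base mean: zero intra, ~34.3 deg twist, 3.4 A rise,
  # phosphates at |q| ~ 9 A from their base frames
  tw <- scale * tan(pi / 10.5)
  q_w <- c(-1.5, 8.6, 2.2)
  q_c <- c(1.5, 8.6, 2.2)
  mu_base <- c(rep(0, 6),
               c(0, 0, 0, q_c),
               c(0, 0, tw, 0, 0, 3.4),
               c(0, 0, 0, q_w),
               rep(0, 6))
  d_base <- c(c(4, 4, 4, 8, 8, 8),
              c(3, 3, 3, 6, 6, 6),
              c(5, 5, 6, 8, 8, 10),
              c(3, 3, 3, 6, 6, 6),
              c(4, 4, 4, 8, 8, 8))
  jitter_sd <- rep(c(0.25, 0.12), times = 5, each = 3)
  make_block <- function(stiff_mult = 1, mean_shift = rep(0, 30)) {
    mu <- mu_base + stats::rnorm(30, sd = jitter_sd) + mean_shift
    A <- matrix(stats::rnorm(900, sd = 0.25), 30, 30)
    B <- diag(d_base * (1 + stats::runif(30, -0.15, 0.15))) + (A + t(A)) / 2
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0.5) B <- B + (0.5 - min(ev)) * diag(30)
    B <- B * stiff_mult * block_scale
    list(stiffness = B, mu = mu)
  }
  raw <- list()
  for (lab in all_dimer_labels()) raw[[lab]] <- make_block()
  # modified CpG steps: stiffer, roll up / twist down in the mean
  mod_shift <- numeric(30)
  mod_shift[14] <- 0.35   # inter roll (block position 13+2)
  mod_shift[15] <- -0.30  # inter twist
  raw[["MN"]] <- make_block(stiff_mult = 1.15, mean_shift = mod_shift)
  raw[["HK"]] <- make_block(stiff_mult = 1.18, mean_shift = 1.1 * mod_shift)
  # enforce reverse-complement consistency exactly
  done <- character(0)
  steps <- list()
  for (lab in names(raw)) {
    if (lab %in% done) next
    rc <- rc_step_label(lab)
    if (rc == lab) {
      B <- (raw[[lab]]$stiffness + E30 %*% raw[[lab]]$stiffness %*% E30) / 2
      mu <- (raw[[lab]]$mu + as.vector(E30 %*% raw[[lab]]$mu)) / 2
      steps[[lab]] <- list(stiffness = B, weighted_mean = as.vector(B %*% mu))
      done <- c(done, lab)
    } else {
      B <- raw[[lab]]$stiffness
      mu <- raw[[lab]]$mu
      Brc <- E30 %*% B %*% E30
      steps[[lab]] <- list(stiffness = B, weighted_mean = as.vector(B %*% mu))
      steps[[rc]] <- list(stiffness = Brc,
                          weighted_mean = as.vector(Brc %*% (E30 %*% mu)))
      done <- c(done, lab, rc)
    }
  }
  ends <- NULL
  if (include_ends) {
    first <- list()
    for (b in c("A", "C", "G", "T")) {
      A6 <- matrix(stats::rnorm(36, sd = 0.1), 6, 6)
      B6 <- diag(c(1, 1, 1, 2, 2, 2) * (1 + stats::runif(6, -0.1, 0.1))) +
        (A6 + t(A6)) / 2
      ev <- eigen(B6, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 0.2) B6 <- B6 + (0.2 - min(ev)) * diag(6)
      mu6 <- stats::rnorm(6, sd = 0.2)
      first[[b]] <- list(stiffness = B6 * block_scale,
                         weighted_mean = as.vector(B6 %*% mu6) * block_scale)
    }
    last <- list()
    for (b in c("A", "C", "G", "T")) {
      fb <- first[[unname(COMPLEMENT_EXT[b])]]
      last[[b]] <- list(stiffness = E6 %*% fb$stiffness %*% E6,
                        weighted_mean = as.vector(E6 %*% fb$weighted_mean))
    }
    ends <- list(first = first, last = last)
  }
  parameter_set(steps, ends = ends)
}

#' Ideal-superhelix constraint set
#'
#' Places `n_contacts` reference points evenly along the superhelix,
#' alternating Watson/Crick strands, so that consecutive same-strand contacts
#' are ~`bp_per_turn` junctions apart. The default geometry spans two DNA
#' gyres of the standard nucleosome.
#'
#' @param spec a [superhelix_spec()].
#' @param n_contacts even number of bound phosphates (28 for the standard
#'   nucleosome).
#' @param n_bp fragment length (147 for the standard nucleosome).
#' @param coefficient elastic penalty coefficient c (kT/A^2) applied to all
#'   contacts.
#' @return A [constraint_set()].
#' @export
ideal_superhelix_constraints <- function(spec, n_contacts = 28, n_bp = 147,
                                         coefficient = default_penalty_coefficient()) {
  if (n_contacts %% 2 != 0) stop("n_contacts must be even")
  n_junc <- n_bp - 1L
  spacing <- spec$bp_per_turn / 2
  span <- (n_contacts - 1) * spacing
  if (span > n_junc - 1) {
    stop("infeasible spacing: ", n_contacts, " contacts at ", spacing,
         " junctions apart exceed ", n_junc, " junctions")
  }
  j_start <- (n_junc - span) / 2 + 1
  j <- round(j_start + (seq_len(n_contacts) - 1) * spacing)
  pos <- superhelix_point(spec, (j - 1) / (n_junc - 1))
  constraint_set(data.frame(
    strand = rep(c("watson", "crick"), length.out = n_contacts),
    junction = as.integer(j),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    c = coefficient
  ), provenance = sprintf(
    "ideal superhelix fixture (radius=%g pitch=%g turns=%g bp_per_turn=%g %s-handed)",
    spec$radius, spec$pitch, spec$turns, spec$bp_per_turn, spec$handedness))
}

#' Synthetic aligned nucleosome structure ensemble
#'
#' Phosphate tracks along the superhelix with a near-periodic radial
#' modulation — wells of depth `radial_modulation` centred on integer
#' junction indices spaced `bp_per_turn` apart (the histone-contact
#' periodicity), realised as a phase-warped cosine so that the noiseless
#' radial profile has its strict local minima exactly at the planted
#' indices — plus isotropic Gaussian jitter of standard deviation
#' `noise_sd`.
#'
#' @param spec a [superhelix_spec()].
#' @param n_structures number of structures.
#' @param noise_sd isotropic per-coordinate jitter (Angstrom).
#' @param radial_modulation amplitude of the radial modulation (Angstrom).
#' @param seed integer seed.
#' @param n_bp fragment length.
#' @return A `structure_ensemble`; attribute `ground_truth` records the
#'   planted minima indices per strand.
#' @export
synthetic_structure_ensemble <- function(spec, n_structures = 100,
                                         noise_sd = 0.5,
                                         radial_modulation = 3,
                                         seed = 1, n_bp = 147) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  n_junc <- n_bp - 1L
  per <- spec$bp_per_turn
  planted <- function(j0) {
    m <- as.integer(round(j0 + per * (0:200)))
    m[m >= 2L & m <= n_junc - 1L]
  }
  truth <- list(watson = planted(8), crick = planted(5))
  radial_curve <- function(minima) {
    # phase-warped cosine: theta(minima_k) = (2k+1) pi, linear in between
    anchors_x <- minima
    anchors_th <- pi + 2 * pi * (seq_along(minima) - 1)
    th <- stats::approx(anchors_x, anchors_th, xout = seq_len(n_junc),
                        rule = 2)$y
    # extrapolate linearly beyond the first/last well at the nominal rate
    lo <- seq_len(n_junc) < minima[1]
    hi <- seq_len(n_junc) > minima[length(minima)]
    th[lo] <- anchors_th[1] - 2 * pi / per * (minima[1] - which(lo))
    th[hi] <- anchors_th[length(minima)] +
      2 * pi / per * (which(hi) - minima[length(minima)])
    spec$radius + radial_modulation * cos(th)
  }
  rw <- radial_curve(truth$watson)
  rc <- radial_curve(truth$crick)
  sgn <- if (spec$handedness == "left") -1 else 1
  frac <- (seq_len(n_junc) - 1) / (n_junc - 1)
  phi <- sgn * 2 * pi * spec$turns * frac
  z <- spec$pitch * spec$turns * (frac - 0.5)
  phi_c <- phi + sgn * 2 * pi * 0.25 / spec$turns / 40  # slight strand offset
  base <- rbind(
    data.frame(strand = "watson", index = seq_len(n_junc),
               x = rw * cos(phi), y = rw * sin(phi), z = z),
    data.frame(strand = "crick", index = seq_len(n_junc),
               x = rc * cos(phi_c), y = rc * sin(phi_c), z = z + 1.5)
  )
  tabs <- lapply(seq_len(n_structures), function(s) {
    jit <- matrix(stats::rnorm(3 * nrow(base), sd = noise_sd), ncol = 3)
    data.frame(structure_id = sprintf("synth%03d", s),
               strand = base$strand, index = base$index,
               x = base$x + jit[, 1], y = base$y + jit[, 2],
               z = base$z + jit[, 3])
  })
  ens <- structure_ensemble(do.call(rbind, tabs))
  attr(ens, "ground_truth") <- truth
  ens
}
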
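# Nucleosome wrapping energy: minimisation of the Gaussian model energy
# under elastic constraints pinning the histone-bound phosphates,
#   w_opt = argmin U(w) + sum_i c_i || p_i(w) - pbar_i ||^2 ,
# constraint-set derivation from aligned structure ensembles, and
# diagnostics (residuals, steric self-overlap).

#' Default global penalty coefficient (kT per square Angstrom)
#'
#' Calibrated on the shipped synthetic fixtures so that bound-phosphate
#' residuals at the optimum fall in the 0.1-2 Angstrom range typical of the
#' positional spread in experimental nucleosome structures.
#'
#' @return Scalar coefficient.
#' @export
default_penalty_coefficient <- function() 10

#' Construct a constraint set
#'
#' @param records data.frame with columns `strand` ("watson"/"crick"),
#'   `junction` (1-based), `x`, `y`, `z` (reference position, Angstrom) and
#'   `c` (elastic coefficient, kT/A^2).
#' @param provenance free-text provenance note stored with the set.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(records, provenance = "") {
  records <- as.data.frame(records)
  need <- c("strand", "junction", "x", "y", "z", "c")
  if (!all(need %in% names(records))) {
    stop("constraint records need columns: ", paste(need, collapse = ", "))
  }
  if (!all(records$strand %in% c("watson", "crick"))) {
    stop("strand must be 'watson' or 'crick'")
  }
  if (anyDuplicated(records[c("strand", "junction")])) {
    stop("duplicate (strand, junction) constraint records")
  }
  if (any(records$c <= 0)) stop("all penalty coefficients must be positive")
  records$junction <- as.integer(records$junction)
  structure(list(records = records, provenance = provenance),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: %d bound phosphates (%d watson / %d crick)\n",
              nrow(x$records), sum(x$records$strand == "watson"),
              sum(x$records$strand == "crick")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Write a constraint set (tab-separated, bit-exact)
#' @param cs a `constraint_set`.
#' @param path output path.
#' @export
write_constraint_set <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nucwrap constraint set",
               paste0("# provenance: ", cs$provenance),
               "# units: positions angstrom; coefficient kT/angstrom^2",
               paste(c("strand", "junction", "x", "y", "z", "c"),
                     collapse = "\t")), con)
  r <- cs$records
  writeLines(sprintf("%s\t%d\t%.17g\t%.17g\t%.17g\t%.17g",
                     r$strand, r$junction, r$x, r$y, r$z, r$c), con)
  invisible(path)
}

#' Read a constraint set written by [write_constraint_set()]
#' @param path file path.
#' @return A `constraint_set`.
#' @export
read_constraint_set <- function(path) {
  lines <- readLines(path)
  prov <- sub("^# provenance: ", "", grep("^# provenance: ", lines, value = TRUE))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  constraint_set(df, provenance = if (length(prov)) prov[1] else "")
}

#' @noRd
cs_bound <- function(cs) cs$records[c("strand", "junction")]

#' @noRd
cs_refs <- function(cs) t(as.matrix(cs$records[c("x", "y", "z")]))

# Objective parts at w: value, exact gradient, Jacobian and residuals for
# the Gauss-Newton Hessian. Empty constraint sets give the bare model energy.
#' @noRd
objective_parts <- function(w, model, cs, anchor = NULL) {
  d <- w - model$mu
  Kd <- as.numeric(model$K %*% d)
  U <- sum(d * Kd) / 2
  if (is.null(cs) || nrow(cs$records) == 0) {
    return(list(value = U, energy = U, penalty = 0, grad = Kd,
                J = NULL, resid = NULL, wts = NULL))
  }
  pj <- phosphate_jacobian(w, model$n, cs_bound(cs), model$rotation_scale,
                           anchor = anchor)
  resid <- pj$pos - cs_refs(cs)
  ci <- cs$records$c
  pen <- sum(ci * colSums(resid^2))
  wts <- rep(2 * ci, each = 3)
  grad <- Kd + as.numeric(crossprod(pj$J, as.vector(resid) * wts))
  list(value = U + pen, energy = U, penalty = pen, grad = grad,
       J = pj$J, resid = resid, wts = wts)
}

# Value-only evaluation (no Jacobian) for line searches.
#' @noRd
objective_value <- function(w, model, cs, anchor = NULL) {
  d <- w - model$mu
  U <- sum(d * as.numeric(model$K %*% d)) / 2
  if (is.null(cs) || nrow(cs$records) == 0) return(U)
  pos <- phosphate_positions(w, model$n, cs_bound(cs), model$rotation_scale,
                             anchor = anchor)
  resid <- pos - cs_refs(cs)
  U + sum(cs$records$c * colSums(resid^2))
}

#' Constrained objective: value, gradient, Hessian
#'
#' Evaluates `U(w) + sum_i c_i ||p_i(w) - pbar_i||^2` with its exact
#' (chain-rule) gradient and the Gauss-Newton Hessian `K + 2 J' C J`, whose
#' penalty part is symmetric positive semi-definite and exact wherever the
#' residuals vanish.
#'
#' @param w configuration vector.
#' @param model a `gaussian_model` built for the sequence.
#' @param constraints a `constraint_set` (or `NULL` for the bare energy).
#' @param hessian if `TRUE`, also return the assembled Hessian matrix.
#' @return List with `value` (kT), `gradient`, and optionally `hessian`.
#' @export
objective <- function(w, model, constraints = NULL, hessian = FALSE) {
  ev <- objective_parts(w, model, constraints)
  out <- list(value = ev$value, gradient = ev$grad)
  if (hessian) {
    H <- as.matrix(model$K)
    if (!is.null(ev$J)) H <- H + crossprod(ev$J * sqrt(ev$wts))
    out$hessian <- H
  }
  out
}

# Weighted-Kabsch update of the anchor frame: the rigid motion M minimising
# sum_i c_i || M(p_i(w)) - pbar_i ||^2 costs no elastic energy, so applying
# it to the anchor is an exact block-coordinate-descent step over the
# molecule's six rigid placement degrees of freedom.
#' @noRd
align_anchor <- function(anchor, w, model, cs) {
  pos <- t(phosphate_positions(w, model$n, cs_bound(cs),
                               model$rotation_scale, anchor = anchor))
  refs <- t(cs_refs(cs))
  wt <- cs$records$c
  wt <- wt / sum(wt)
  cm <- colSums(pos * wt); cr <- colSums(refs * wt)
  X <- sweep(pos, 2, cm); Y <- sweep(refs, 2, cr)
  sv <- svd(crossprod(X * wt, Y))
  dsgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsgn)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  rigid_frame(as.numeric(R %*% anchor$origin) + tr, R %*% anchor$R)
}

# Rigid-motion Jacobian of the constrained positions: translations and
# rotations about the position centroid c0 (d p / d omega_k = e_k x (p-c0)).
#' @noRd
rigid_cols <- function(pos) {
  m <- ncol(pos)
  c0 <- rowMeans(pos)
  Jr <- matrix(0, 3L * m, 6L)
  for (i in seq_len(m)) {
    rows <- (3L * i - 2L):(3L * i)
    Jr[rows, 1:3] <- diag(3)
    d <- pos[, i] - c0
    Jr[rows, 4] <- c(0, -d[3], d[2])
    Jr[rows, 5] <- c(d[3], 0, -d[1])
    Jr[rows, 6] <- c(-d[2], d[1], 0)
  }
  list(Jr = Jr, c0 = c0)
}

# Apply an incremental rigid motion xi = (t, omega), rotating about c0, to
# the anchor frame.
#' @noRd
apply_rigid <- function(anchor, xi, c0) {
  tvec <- xi[1:3]
  om <- xi[4:6]
  th <- sqrt(sum(om^2))
  R <- if (th < 1e-14) diag(3) else gibbs_to_rot(tan(th / 2) * om / th)
  rigid_frame(as.numeric(R %*% (anchor$origin - c0)) + c0 + tvec,
              R %*% anchor$R)
}

# Newton step via Woodbury on the augmented variables (w, xi): solve
# (blockdiag(K + lam I, rho I6) + A' W A) d = -g with A = [J, Jr], using the
# sparse factor of K + lam I and a dense m x m core (m = 3 * #constraints).
#' @noRd
newton_step <- function(model, ev, lam, Jr = NULL) {
  ch <- if (lam > 0) {
    Matrix::Cholesky(model$K, LDL = FALSE, perm = TRUE, Imult = lam)
  } else model$chol
  g <- ev$grad
  x1 <- as.numeric(Matrix::solve(ch, g, system = "A"))
  if (is.null(ev$J)) return(list(dw = -x1, dxi = NULL))
  rvec <- as.vector(ev$resid) * ev$wts
  Y <- as.matrix(Matrix::solve(ch, t(ev$J), system = "A"))
  core <- diag(1 / ev$wts) + ev$J %*% Y
  Ax1 <- as.numeric(ev$J %*% x1)
  if (!is.null(Jr)) {
    g_xi <- as.numeric(crossprod(Jr, rvec))
    rho <- max(lam, 1e-3)
    x1x <- g_xi / rho
    core <- core + Jr %*% t(Jr) / rho
    Ax1 <- Ax1 + as.numeric(Jr %*% x1x)
    sol <- solve(core, Ax1)
    dw <- -(x1 - as.numeric(Y %*% sol))
    dxi <- -(x1x - as.numeric((t(Jr) / rho) %*% sol))
    list(dw = dw, dxi = dxi, g_xi = g_xi)
  } else {
    sol <- solve(core, Ax1)
    list(dw = -(x1 - as.numeric(Y %*% sol)), dxi = NULL)
  }
}

#' Minimise the wrapping objective for a sequence
#'
#' Builds the Gaussian model for `seq` and minimises
#' `U(w) + sum_i c_i ||p_i(w) - pbar_i||^2` by a damped (Levenberg-style)
#' Newton iteration with the exact gradient and Gauss-Newton Hessian,
#' Armijo backtracking line search, and adaptive damping. Deterministic
#' given `(seq, params, constraints, init)`.
#'
#' @param seq a `mod_sequence` (147 bp for the standard nucleosome; other
#'   lengths for toys).
#' @param params a `parameter_set`.
#' @param constraints a `constraint_set` (may be empty: the minimiser then
#'   returns the ground state).
#' @param init `"superhelix"` (ideal superhelix fitted to the constraint
#'   references; the default, falling back to `"ground"` when fewer than six
#'   constraints are available), `"ground"` (the linear ground state), or a
#'   numeric configuration vector.
#' @param tol convergence tolerance on the gradient infinity norm (kT per
#'   coordinate unit).
#' @param maxit maximum number of Newton iterations.
#' @return A `wrap_result` with fields `w_opt`, `wrap_energy` (kT,
#'   `U(w_opt)` alone — the penalty sum is reported separately as
#'   `penalty_value`), `residuals` (Angstrom, per constraint), `log_density`
#'   (`ln rho(w_opt)`), `iterations`, `grad_norm`, `converged`, `trace`.
#' @export
minimize_wrap <- function(seq, params, constraints, init = "superhelix",
                          tol = 1e-6, maxit = 500, align = TRUE) {
  seq <- as_mod_sequence(seq)
  model <- build_model(seq, params)
  minimize_wrap_model(model, constraints, init = init, tol = tol,
                      maxit = maxit, align = align)
}

#' Minimise the wrapping objective for a prebuilt model
#'
#' Workhorse behind [minimize_wrap()]; useful when the same model is reused
#' with several constraint sets.
#'
#' @param model a `gaussian_model` with layout information (`model$n` set).
#' @inheritParams minimize_wrap
#' @export
minimize_wrap_model <- function(model, constraints, init = "superhelix",
                                tol = 1e-6, maxit = 500, align = TRUE) {
  if (is.null(model$n)) stop("model has no base-pair layout (toy model?)")
  empty <- is.null(constraints) || nrow(constraints$records) == 0
  if (!empty && any(constraints$records$junction > model$n - 1L)) {
    stop("constraint junction index exceeds n - 1")
  }
  w <- if (is.numeric(init)) {
    if (length(init) != model$N) stop("init configuration has wrong length")
    init
  } else if (identical(init, "ground") || empty) {
    model$mu
  } else if (identical(init, "superhelix")) {
    if (nrow(constraints$records) >= 6) {
      superhelix_init(model, constraints)
    } else {
      model$mu
    }
  } else {
    stop("unknown init: ", init)
  }
  if (empty) {
    return(new_wrap_result(model, model$mu, constraints, rigid_frame(),
                           iterations = 0L, grad_norm = 0, converged = TRUE,
                           trace = numeric(0)))
  }
  lam <- 0
  anchor <- rigid_frame()
  if (align) anchor <- align_anchor(anchor, w, model, constraints)
  ev <- objective_parts(w, model, constraints, anchor)
  trace <- ev$value
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    gn <- max(abs(ev$grad))
    if (gn <= tol) { converged <- TRUE; break }
    pos <- cs_refs(constraints) + ev$resid
    rc <- if (align) rigid_cols(pos) else NULL
    step <- newton_step(model, ev, lam, Jr = rc$Jr)
    gtd <- sum(ev$grad * step$dw) +
      if (is.null(step$dxi)) 0 else sum(step$g_xi * step$dxi)
    if (!is.finite(gtd) || gtd >= 0) {
      lam <- max(lam * 10, 1e-4)
      if (lam > 1e10) break
      next
    }
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      wt <- w + alpha * step$dw
      anct <- if (is.null(step$dxi)) anchor else {
        apply_rigid(anchor, alpha * step$dxi, rc$c0)
      }
      vt <- tryCatch(objective_value(wt, model, constraints, anct),
                     error = function(e) NA_real_)
      if (is.finite(vt) && vt <= ev$value + 1e-4 * alpha * gtd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      lam <- max(lam * 10, 1e-4)
      if (lam > 1e10) break
      next
    }
    w <- wt
    anchor <- anct
    if (align) anchor <- align_anchor(anchor, w, model, constraints)
    ev <- objective_parts(w, model, constraints, anchor)
    trace <- c(trace, ev$value)
    if (alpha == 1 && lam > 0) lam <- if (lam < 1e-3) 0 else lam / 10
  }
  gn <- max(abs(ev$grad))
  if (gn <= tol) converged <- TRUE
  new_wrap_result(model, w, constraints, anchor, iterations = it,
                  grad_norm = gn, converged = converged, trace = trace)
}

#' @noRd
new_wrap_result <- function(model, w, constraints, anchor, iterations,
                            grad_norm, converged, trace) {
  if (is.null(constraints) || nrow(constraints$records) == 0) {
    resid <- numeric(0)
    pen <- 0
  } else {
    pos <- phosphate_positions(w, model$n, cs_bound(constraints),
                               model$rotation_scale, anchor = anchor)
    dd <- pos - cs_refs(constraints)
    resid <- sqrt(colSums(dd^2))
    pen <- sum(constraints$records$c * resid^2)
  }
  structure(list(
    w_opt = w,
    wrap_energy = energy(w, model),
    penalty_value = pen,
    residuals = resid,
    log_density = log_density(w, model),
    iterations = iterations,
    grad_norm = grad_norm,
    converged = converged,
    trace = trace,
    n = model$n,
    rotation_scale = model$rotation_scale,
    anchor = anchor,
    constraints = constraints
  ), class = "wrap_result")
}

#' @export
print.wrap_result <- function(x, ...) {
  cat(sprintf("wrap_result: U = %.4f kT, penalty = %.4f kT, ln rho = %.4f\n",
              x$wrap_energy, x$penalty_value, x$log_density))
  cat(sprintf("  %d iterations, |grad|_inf = %.3g, converged: %s\n",
              x$iterations, x$grad_norm, x$converged))
  if (length(x$residuals)) {
    cat(sprintf("  residuals (A): median %.3f, max %.3f\n",
                stats::median(x$residuals), max(x$residuals)))
  }
  invisible(x)
}

#' Export a wrap result summary to JSON
#'
#' @param result a `wrap_result`.
#' @param path output path.
#' @param include_configuration dump the full optimal configuration vector.
#' @export
write_wrap_result <- function(result, path, include_configuration = FALSE) {
  out <- list(wrap_energy = result$wrap_energy,
              penalty_value = result$penalty_value,
              log_density = result$log_density,
              residuals = result$residuals,
              iterations = result$iterations,
              grad_norm = result$grad_norm,
              converged = result$converged)
  if (include_configuration) out$w_opt <- result$w_opt
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Initial configuration: ideal superhelix fitted (axis, radius, angular and
# axial rates) to the constraint reference positions by least squares, with
# intra and phosphate coordinates taken from the ground state and the twist
# register chosen by a coarse scan. The published method starts from an
# averaged experimental configuration, which is data we do not ship.
#' @noRd
superhelix_init <- function(model, constraints) {
  refs <- t(cs_refs(constraints))
  jn <- constraints$records$junction
  ax <- principal_axis(refs)
  cp <- cylindrical_profile(refs, ax)
  if (stats::cor(cp$height, jn) < 0) {
    ax$direction <- -ax$direction
    cp <- cylindrical_profile(refs, ax)
  }
  ord <- order(jn)
  th <- cp$angle[ord]
  # unwrap in junction order (consecutive contacts are < pi apart)
  for (i in seq_along(th)[-1]) {
    while (th[i] - th[i - 1] > pi) th[i] <- th[i] - 2 * pi
    while (th[i] - th[i - 1] < -pi) th[i] <- th[i] + 2 * pi
  }
  jfit <- jn[ord]
  fit_th <- stats::lm.fit(cbind(1, jfit), th)$coefficients
  fit_h <- stats::lm.fit(cbind(1, jfit), cp$height[ord])$coefficients
  r_ph <- mean(cp$radius)
  # bp-centre superhelix sits outward of the bound phosphates by roughly the
  # base-frame-to-phosphate offset
  mu_sp <- split_config(model$mu, model$n)
  r_off <- mean(sqrt(colSums(mu_sp$pw[4:6, , drop = FALSE]^2)))
  r_bp <- r_ph + 0.85 * r_off
  # mean helical twist from the ground state
  tw <- mean(2 * atan(mu_sp$inter[3, ] / model$rotation_scale))
  d <- ax$direction
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  n <- model$n
  build_w <- function(psi0) {
    G <- array(0, c(3, 3, n)); o <- matrix(0, 3, n)
    for (a in seq_len(n)) {
      j <- a - 0.5
      phi <- fit_th[1] + fit_th[2] * j
      h <- fit_h[1] + fit_h[2] * j
      radial <- cos(phi) * e1 + sin(phi) * e2
      o[, a] <- ax$point + r_bp * radial + h * d
      tang <- -r_bp * fit_th[2] * sin(phi) * e1 +
        r_bp * fit_th[2] * cos(phi) * e2 + fit_h[2] * d
      tang <- tang / sqrt(sum(tang^2))
      u <- -radial - sum(-radial * tang) * tang
      u <- u / sqrt(sum(u^2))
      tu <- c(tang[2] * u[3] - tang[3] * u[2],
              tang[3] * u[1] - tang[1] * u[3],
              tang[1] * u[2] - tang[2] * u[1])
      psi <- psi0 + tw * (a - 1)
      d1 <- cos(psi) * u + sin(psi) * tu
      d2 <- c(tang[2] * d1[3] - tang[3] * d1[2],
              tang[3] * d1[1] - tang[1] * d1[3],
              tang[1] * d1[2] - tang[2] * d1[1])
      G[, , a] <- cbind(d1, d2, tang)
    }
    inter <- matrix(0, 6, n - 1L)
    for (a in seq_len(n - 1L)) {
      Lam <- crossprod(G[, , a], G[, , a + 1L])
      g <- rot_to_gibbs(Lam)
      S <- gibbs_to_rot(gibbs_half(g))
      inter[1:3, a] <- g * model$rotation_scale
      inter[4:6, a] <- crossprod(S, crossprod(G[, , a], o[, a + 1L] - o[, a]))
    }
    join_config(mu_sp$intra, mu_sp$pc, inter, mu_sp$pw)
  }
  best <- NULL; best_val <- Inf
  for (psi0 in seq(0, 2 * pi, length.out = 25)[-25]) {
    wc <- build_w(psi0)
    pos <- phosphate_positions(wc, n, cs_bound(constraints),
                               model$rotation_scale)
    val <- sum((pos - cs_refs(constraints))^2)
    if (val < best_val) { best_val <- val; best <- wc }
  }
  best
}

## ---- structure-ensemble derived constraints ----

#' Identify histone-bound phosphate indices from an aligned ensemble
#'
#' Computes the per-index mean radial distance to the nucleosome axis across
#' the ensemble, takes the strict local minima of the mean profile on each
#' strand, keeps those on the inner (histone-facing) side of the profile
#' midrange, clusters them by helical turn, and returns one index per
#' cluster — the one closest to the nucleosome centre. The per-index
#' standard-deviation profile is returned alongside.
#'
#' @param ensemble a `structure_ensemble` of aligned structures with common
#'   indexing (at least 2 structures).
#' @param axis nucleosome axis as `list(point, direction)`; default the
#'   fitted symmetry axis ([fit_symmetry_axis()]) of the pooled phosphate
#'   cloud.
#' @param min_separation cluster gap (junctions): consecutive minima closer
#'   than this are treated as one helical-turn cluster.
#' @return List with `watson` and `crick` index vectors, the per-index
#'   `profile` (mean and sd of radius), and the axis used.
#' @export
identify_bound_indices <- function(ensemble, axis = NULL, min_separation = 3) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (ensemble$n_structures < 2) stop("need at least 2 aligned structures")
  tab <- ensemble$table
  pts <- as.matrix(tab[c("x", "y", "z")])
  if (is.null(axis)) axis <- fit_symmetry_axis(pts)
  cyl <- cylindrical_profile(pts, axis)
  tab$radius <- cyl$radius
  prof <- stats::aggregate(radius ~ strand + index, data = tab,
                           FUN = function(r) c(mean = mean(r), sd = stats::sd(r)))
  prof <- data.frame(strand = prof$strand, index = prof$index,
                     mean_radius = prof$radius[, "mean"],
                     sd_radius = prof$radius[, "sd"])
  prof <- prof[order(prof$strand, prof$index), ]
  pick <- function(strand) {
    p <- prof[prof$strand == strand, ]
    r <- p$mean_radius
    k <- length(r)
    if (k < 3) stop("profile too short on strand ", strand)
    if (diff(range(r)) < 1e-6 * mean(r)) {
      stop("flat radial profile on strand ", strand,
           ": no strict local minima")
    }
    marg <- 1e-8 * mean(r)
    isminn <- which(r[2:(k - 1)] < r[1:(k - 2)] - marg &
                      r[2:(k - 1)] < r[3:k] - marg) + 1L
    if (length(isminn) == 0) {
      stop("flat radial profile on strand ", strand, ": no strict local minima")
    }
    cutoff <- (max(r) + min(r)) / 2
    isminn <- isminn[r[isminn] <= cutoff]
    if (length(isminn) == 0) {
      stop("no inner-side radial minima on strand ", strand)
    }
    idx <- p$index[isminn]
    gaps <- c(Inf, diff(idx))
    cluster <- cumsum(gaps > min_separation)
    out <- vapply(split(seq_along(idx), cluster), function(grp) {
      idx[grp[which.min(r[isminn[grp]])]]
    }, numeric(1))
    as.integer(unname(out))
  }
  list(watson = pick("watson"), crick = pick("crick"),
       profile = prof, axis = axis)
}

#' Build a constraint set from an aligned structure ensemble
#'
#' Reference positions are ensemble means of the bound phosphate positions.
#'
#' @param ensemble a `structure_ensemble`.
#' @param bound_indices list with `watson`/`crick` junction index vectors
#'   (e.g. from [identify_bound_indices()]).
#' @param coefficient elastic coefficient applied to every constraint
#'   (scalar or per-record vector).
#' @return A [constraint_set()].
#' @export
build_constraints <- function(ensemble, bound_indices,
                              coefficient = default_penalty_coefficient()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  tab <- ensemble$table
  sel <- rbind(
    data.frame(strand = "watson", junction = bound_indices$watson),
    data.frame(strand = "crick", junction = bound_indices$crick)
  )
  sel <- sel[order(sel$junction, sel$strand), ]
  pos <- t(vapply(seq_len(nrow(sel)), function(i) {
    rows <- tab$strand == sel$strand[i] & tab$index == sel$junction[i]
    if (!any(rows)) {
      stop("missing coordinates for ", sel$strand[i], " phosphate ",
           sel$junction[i])
    }
    c(mean(tab$x[rows]), mean(tab$y[rows]), mean(tab$z[rows]))
  }, numeric(3)))
  constraint_set(data.frame(strand = sel$strand, junction = sel$junction,
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            c = coefficient),
                 provenance = sprintf("ensemble mean over %d structures",
                                      ensemble$n_structures))
}

#' Per-constraint residual report
#'
#' @param result a converged `wrap_result`.
#' @param ranges optional allowed distance ranges: either a length-2 vector
#'   `c(lower, upper)` applied to all constraints or a data.frame with
#'   columns `lower`, `upper` per constraint (Angstrom).
#' @return data.frame with `strand`, `junction`, `residual`, and `flagged`
#'   (outside the provided range).
#' @export
residual_report <- function(result, ranges = NULL) {
  stopifnot(inherits(result, "wrap_result"))
  if (!result$converged) warning("result did not converge; residuals reported anyway")
  rec <- result$constraints$records
  out <- data.frame(strand = rec$strand, junction = rec$junction,
                    residual = result$residuals)
  if (is.null(ranges)) {
    out$flagged <- FALSE
  } else {
    if (is.numeric(ranges) && length(ranges) == 2) {
      lower <- rep(ranges[1], nrow(out)); upper <- rep(ranges[2], nrow(out))
    } else {
      lower <- ranges$lower; upper <- ranges$upper
    }
    out$flagged <- out$residual < lower | out$residual > upper
  }
  out
}

#' Check steric self-overlap between the two DNA gyres
#'
#' Minimum pairwise distance between phosphates whose junction indices
#' differ by more than `turn_separation` (i.e. that sit on different
#' superhelical turns), compared against a clash threshold.
#'
#' @param result a `wrap_result`, or a data.frame of phosphate positions
#'   with columns `strand`, `index`, `x`, `y`, `z`.
#' @param min_distance clash threshold (Angstrom).
#' @param turn_separation junction-index separation defining "different
#'   turns".
#' @return List with `pass`, `min_distance` observed, and the `worst` pair.
#' @export
check_self_overlap <- function(result, min_distance = 15,
                               turn_separation = 40) {
  ph <- if (inherits(result, "wrap_result")) {
    all_phosphate_positions(result$w_opt, result$n, result$rotation_scale)
  } else {
    as.data.frame(result)
  }
  pts <- as.matrix(ph[c("x", "y", "z")])
  idx <- ph$index
  m <- nrow(ph)
  best <- Inf; worst <- c(NA, NA)
  for (i in seq_len(m - 1)) {
    far <- which(abs(idx[(i + 1):m] - idx[i]) > turn_separation) + i
    if (length(far) == 0) next
    dd <- sqrt(colSums((t(pts[far, , drop = FALSE]) - pts[i, ])^2))
    k <- which.min(dd)
    if (dd[k] < best) { best <- unname(dd[k]); worst <- c(i, far[k]) }
  }
  list(pass = best >= min_distance, min_distance = best,
       worst = if (is.finite(best)) ph[worst, c("strand", "index")] else NULL)
}

#' Predicted-configuration ensemble from wrap results
#'
#' Collects the phosphate positions of optimal configurations into a
#' `structure_ensemble`, enabling the same radial-profile analysis as for
#' experimental structures.
#'
#' @param results list of `wrap_result`s (same n).
#' @return A `structure_ensemble`.
#' @export
ensemble_from_wrap_results <- function(results) {
  tabs <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    ph <- all_phosphate_positions(r$w_opt, r$n, r$rotation_scale)
    cbind(structure_id = sprintf("pred%04d", i), ph)
  })
  structure_ensemble(do.call(rbind, tabs))
}
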
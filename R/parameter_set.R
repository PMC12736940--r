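# Model parameter sets: per-dimer-step 30-dim stiffness and weighted-mean
# blocks over the extended alphabet (16 unmodified dimer steps plus MN and
# HK), optional terminal base-pair corrections, and coordinate-convention
# metadata.

#' @noRd
COMPLEMENT_EXT <- c(A = "T", C = "G", G = "C", T = "A",
                    M = "N", N = "M", H = "K", K = "H")

#' Step labels of the extended dimer alphabet
#' @return Character vector of the 16 unmodified dimer labels plus "MN", "HK".
#' @export
extended_step_labels <- function() c(all_dimer_labels(), "MN", "HK")

#' Reverse complement of a dimer-step label
#' @param label e.g. "AC", "MN".
#' @return The complementary step label read on the other strand.
#' @export
rc_step_label <- function(label) {
  vapply(label, function(l) {
    ch <- strsplit(l, "", fixed = TRUE)[[1]]
    paste(rev(unname(COMPLEMENT_EXT[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
default_meta <- function() {
  list(
    alphabet = extended_step_labels(),
    block_dim = 30L,
    layout = "intra6-crickP6-inter6-watsonP6-intra6",
    rotation = "gibbs",
    rotation_scale = 10,
    units = "kT; angstrom",
    phosphate_ref = "3prime",
    involution_signs = e6_signs()
  )
}

#' Construct a parameter set
#'
#' @param steps named list; each element a list with `stiffness` (symmetric
#'   30x30 matrix, kT per squared coordinate) and `weighted_mean` (length-30
#'   vector, the stiffness-weighted ground-state contribution of the step).
#' @param ends `NULL`, or a list with elements `first` and `last`, each a
#'   named list (by terminal base) of lists with `stiffness` (6x6) and
#'   `weighted_mean` (length 6) corrections applied to the terminal intra
#'   coordinates.
#' @param meta coordinate-convention metadata; defaults describe the
#'   canonical layout (Cayley/Gibbs rotations scaled by 10, Angstrom
#'   translations, 3'-side phosphate reference frames).
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(steps, ends = NULL, meta = list()) {
  m <- utils::modifyList(default_meta(), meta)
  ps <- structure(list(steps = steps, ends = ends, meta = m),
                  class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("parameter_set: %d step blocks (dim %d), %s end corrections\n",
              length(x$steps), x$meta$block_dim,
              if (is.null(x$ends)) "no" else "with"))
  cat("  rotation:", x$meta$rotation, "scale", x$meta$rotation_scale, "\n")
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks block dimensions, symmetry of every stiffness block, and the
#' reverse-complement consistency `B[rc(step)] = E30 B[step] E30`,
#' `sigma[rc(step)] = E30 sigma[step]` under the declared involution.
#'
#' @param ps a `parameter_set`.
#' @param tol relative tolerance for symmetry/consistency checks.
#' @return `ps`, invisibly; errors name the offending entry.
#' @export
validate_parameter_set <- function(ps, tol = 1e-8) {
  d <- ps$meta$block_dim
  E30 <- e30_matrix()
  E6 <- e6_matrix()
  for (lab in names(ps$steps)) {
    blk <- ps$steps[[lab]]
    if (is.null(blk$stiffness) || is.null(blk$weighted_mean)) {
      stop("step block '", lab, "' is missing stiffness or weighted_mean")
    }
    B <- blk$stiffness
    if (!is.matrix(B) || any(dim(B) != c(d, d))) {
      stop("step block '", lab, "' stiffness is not ", d, "x", d)
    }
    if (length(blk$weighted_mean) != d) {
      stop("step block '", lab, "' weighted_mean has wrong length")
    }
    sc <- max(abs(B), 1)
    if (max(abs(B - t(B))) > tol * sc) {
      stop("step block '", lab, "' stiffness is not symmetric")
    }
    rc <- rc_step_label(lab)
    if (!is.null(ps$steps[[rc]])) {
      Brc <- ps$steps[[rc]]$stiffness
      if (max(abs(Brc - E30 %*% B %*% E30)) > 1e-6 * sc) {
        stop("complement-consistency violated between steps '", lab,
             "' and '", rc, "'")
      }
      src <- ps$steps[[rc]]$weighted_mean
      if (max(abs(src - as.vector(E30 %*% blk$weighted_mean))) >
          1e-6 * max(abs(blk$weighted_mean), 1)) {
        stop("complement-consistency violated for weighted means of '",
             lab, "' / '", rc, "'")
      }
    }
  }
  if (!is.null(ps$ends)) {
    for (side in c("first", "last")) {
      for (b in names(ps$ends[[side]])) {
        eb <- ps$ends[[side]][[b]]
        if (!is.matrix(eb$stiffness) || any(dim(eb$stiffness) != c(6, 6)) ||
            length(eb$weighted_mean) != 6) {
          stop("malformed ", side, " end block for base '", b, "'")
        }
      }
    }
    for (b in names(ps$ends$first)) {
      cb <- unname(COMPLEMENT_EXT[b])
      lb <- ps$ends$last[[cb]]
      if (!is.null(lb)) {
        fb <- ps$ends$first[[b]]
        if (max(abs(lb$stiffness - E6 %*% fb$stiffness %*% E6)) > 1e-6) {
          stop("end-block complement-consistency violated for base '", b, "'")
        }
      }
    }
  }
  invisible(ps)
}

#' Save a parameter set to the portable JSON container
#'
#' The container holds a metadata record (alphabet, block dimension,
#' coordinate ordering, rotation encoding and scale, units) and full-precision
#' float arrays per step label; round trips are bit-exact.
#'
#' @param ps a `parameter_set`.
#' @param path output file path.
#' @export
save_parameter_set <- function(ps, path) {
  # float arrays are serialised as %.17g strings: IEEE doubles round-trip
  # exactly through 17 significant digits, which plain JSON number emission
  # does not guarantee
  pack_vec <- function(x) sprintf("%.17g", as.numeric(x))
  pack_mat <- function(m) list(dim = dim(m), data = pack_vec(m))
  payload <- list(
    container = "nucwrap-parameter-set",
    version = 1L,
    meta = ps$meta,
    steps = lapply(ps$steps, function(b) list(
      stiffness = pack_mat(b$stiffness),
      weighted_mean = pack_vec(b$weighted_mean)
    )),
    ends = if (is.null(ps$ends)) NULL else {
      lapply(ps$ends, function(side) lapply(side, function(eb) list(
        stiffness = pack_mat(eb$stiffness),
        weighted_mean = pack_vec(eb$weighted_mean)
      )))
    }
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a parameter set from the portable JSON container
#'
#' @param path file written by [save_parameter_set()] (or converted from a
#'   published parameter file by an external converter into this schema).
#' @return A validated `parameter_set`; malformed metadata, asymmetric
#'   blocks, or complement inconsistencies raise an error naming the entry.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter-set file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$container) || raw$container != "nucwrap-parameter-set") {
    stop("not a parameter-set container: ", path)
  }
  if (is.null(raw$meta$block_dim)) stop("malformed meta: missing block_dim")
  unpack_mat <- function(m) {
    if (is.list(m) && !is.null(m$data)) {
      matrix(as.numeric(m$data), m$dim[1], m$dim[2])
    } else {
      as.matrix(m)
    }
  }
  unpack_vec <- function(v) as.numeric(v)
  steps <- lapply(raw$steps, function(b) list(
    stiffness = unpack_mat(b$stiffness),
    weighted_mean = unpack_vec(b$weighted_mean)
  ))
  ends <- raw$ends
  if (!is.null(ends) && length(ends) > 0) {
    ends <- lapply(ends, function(side) lapply(side, function(eb) list(
      stiffness = unpack_mat(eb$stiffness),
      weighted_mean = unpack_vec(eb$weighted_mean)
    )))
  } else {
    ends <- NULL
  }
  parameter_set(steps, ends = ends, meta = raw$meta)
}
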
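# Sequences over the extended alphabet {A, C, G, T, MpN, HpK}.
#
# Epigenetic modifications are symmetric by construction: one record at a CpG
# junction marks both strands' cytosines as 5-methylated (MpN) or
# 5-hydroxymethylated (HpK). Modifications are stored as junction annotations,
# never as extra letters; the extended-FASTA dialect writes a modified CpG
# step as "MN" (methyl) or "HK" (hydroxymethyl).

MOD_KINDS <- c("methyl", "hydroxymethyl")

#' Construct a modified DNA sequence
#'
#' A `mod_sequence` is a DNA string over \{A, C, G, T\} together with a set of
#' symmetric CpG-step modifications. Each modification record refers to the
#' 1-based junction position `j` of a CpG step (`bases[j] == "C"`,
#' `bases[j+1] == "G"`) and modifies the cytosines on both strands.
#'
#' @param bases a single string over A/C/G/T (case-insensitive), or a string
#'   in the extended dialect where a modified CpG step is written `MN`
#'   (methyl) or `HK` (hydroxymethyl).
#' @param mods `NULL`, or a data.frame with columns `step_index` (integer)
#'   and `kind` (one of `"methyl"`, `"hydroxymethyl"`).
#' @return An object of class `mod_sequence`.
#' @export
mod_sequence <- function(bases, mods = NULL) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("M", "N", "H", "K"))) {
    parsed <- parse_extended_string(bases)
    chars <- parsed$chars
    bases <- paste(chars, collapse = "")
    mods <- rbind(parsed$mods, mods)
  }
  bad <- setdiff(unique(chars), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop("sequence contains letters outside {A,C,G,T}: ",
         paste(bad, collapse = ", "),
         " (ambiguity codes are not part of the model alphabet)")
  }
  if (is.null(mods)) {
    mods <- data.frame(step_index = integer(0), kind = character(0),
                       stringsAsFactors = FALSE)
  }
  mods <- as.data.frame(mods, stringsAsFactors = FALSE)
  mods$step_index <- as.integer(mods$step_index)
  obj <- structure(list(bases = bases, chars = chars, mods = mods),
                   class = "mod_sequence")
  validate_mod_sequence(obj)
  obj
}

#' @noRd
validate_mod_sequence <- function(seq) {
  mods <- seq$mods
  if (nrow(mods) == 0) return(invisible(seq))
  if (anyDuplicated(mods$step_index)) {
    stop("duplicate modification records at step_index ",
         paste(mods$step_index[duplicated(mods$step_index)], collapse = ", "))
  }
  if (!all(mods$kind %in% MOD_KINDS)) {
    stop("unknown modification kind: ",
         paste(setdiff(mods$kind, MOD_KINDS), collapse = ", "))
  }
  n <- length(seq$chars)
  j <- mods$step_index
  ok <- j >= 1L & j <= n - 1L & seq$chars[j] == "C" & seq$chars[pmin(j + 1L, n)] == "G"
  if (!all(ok)) {
    stop("modification records must sit on CpG steps; offending step_index: ",
         paste(j[!ok], collapse = ", "))
  }
  invisible(seq)
}

#' Coerce to mod_sequence
#' @param x a `mod_sequence` or a character string (plain or extended dialect).
#' @return A `mod_sequence`.
#' @export
as_mod_sequence <- function(x) {
  if (inherits(x, "mod_sequence")) return(x)
  mod_sequence(x)
}

#' @export
print.mod_sequence <- function(x, ...) {
  n <- length(x$chars)
  cat(sprintf("mod_sequence: %d bp, %d CpG step(s), %d modified\n",
              n, count_cpg(x), nrow(x$mods)))
  show <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(" ", show, "\n")
  invisible(x)
}

#' @export
length.mod_sequence <- function(x) length(x$chars)

#' @export
as.character.mod_sequence <- function(x, ...) extended_string(x)

#' Junction positions of CpG steps
#' @param seq a `mod_sequence` (or string).
#' @return Integer vector of 1-based junction indices `j` with
#'   `bases[j..j+1] == "CG"`.
#' @export
cpg_positions <- function(seq) {
  seq <- as_mod_sequence(seq)
  ch <- seq$chars
  n <- length(ch)
  if (n < 2) return(integer(0))
  which(ch[-n] == "C" & ch[-1] == "G")
}

#' Count CpG dinucleotide steps
#'
#' Counts every junction reading `CG` on the Watson strand, whether or not the
#' step carries an epigenetic modification.
#'
#' @inheritParams cpg_positions
#' @return Non-negative integer.
#' @export
count_cpg <- function(seq) length(cpg_positions(seq))

#' Symmetrically modify all CpG steps
#'
#' Marks every CpG step of the sequence as symmetrically methylated (`MpN`)
#' or hydroxymethylated (`HpK`), modifying the cytosines on both strands.
#'
#' @inheritParams cpg_positions
#' @param kind `"methyl"` or `"hydroxymethyl"`.
#' @return A `mod_sequence` whose modification count equals `count_cpg(seq)`.
#' @export
apply_symmetric_modification <- function(seq, kind = c("methyl", "hydroxymethyl")) {
  kind <- match.arg(kind)
  seq <- as_mod_sequence(seq)
  if (nrow(seq$mods) > 0 && any(seq$mods$kind != kind)) {
    stop("sequence already carries modifications of a different kind; ",
         "mixed-kind annotation is not supported")
  }
  pos <- cpg_positions(seq)
  mods <- data.frame(step_index = pos,
                     kind = rep(kind, length(pos)),
                     stringsAsFactors = FALSE)
  mod_sequence(seq$bases, mods)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement
#'
#' Watson/Crick strand swap. A modified CpG step at junction `j` maps to a
#' modified CpG step at junction `n - j` (CpG steps are self-complementary),
#' and `reverse_complement` is an involution.
#'
#' @inheritParams cpg_positions
#' @return A `mod_sequence`.
#' @export
reverse_complement <- function(seq) {
  seq <- as_mod_sequence(seq)
  n <- length(seq$chars)
  rc <- rev(unname(COMPLEMENT[seq$chars]))
  mods <- seq$mods
  if (nrow(mods) > 0) mods$step_index <- n - mods$step_index
  mod_sequence(paste(rc, collapse = ""), mods)
}

#' Random sequence with a target CpG-step count range
#'
#' Draws bases i.i.d. uniformly over \{A, C, G, T\}, then adjusts the CpG
#' count by randomised edits until it falls in `[cpg_min, cpg_max]`:
#' insertion overwrites a uniformly chosen non-CpG junction with `CG`;
#' removal replaces the C of a uniformly chosen CpG step by a uniform draw
#' from \{A, T, G\}. The count is recomputed after every edit.
#'
#' @param n_bp sequence length in base pairs.
#' @param cpg_min,cpg_max inclusive CpG-count bounds,
#'   `0 <= cpg_min <= cpg_max <= floor(n_bp/2)`.
#' @param rng_seed optional integer seed for reproducibility.
#' @return A `mod_sequence` with `count_cpg` in the requested range.
#' @export
random_sequence_with_cpg_range <- function(n_bp, cpg_min, cpg_max,
                                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (cpg_min < 0 || cpg_min > cpg_max) stop("need 0 <= cpg_min <= cpg_max")
  if (cpg_max > floor(n_bp / 2) || cpg_min > floor(n_bp / 2)) {
    stop("infeasible CpG target: at most floor(n_bp/2) = ",
         floor(n_bp / 2), " CpG steps fit in ", n_bp, " bp")
  }
  ch <- sample(c("A", "C", "G", "T"), n_bp, replace = TRUE)
  count_in <- function(ch) sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  guard <- 0L
  repeat {
    cnt <- count_in(ch)
    if (cnt >= cpg_min && cnt <= cpg_max) break
    guard <- guard + 1L
    if (guard > 10000L * n_bp) stop("CpG adjustment failed to converge")
    if (cnt < cpg_min) {
      is_cg <- ch[-n_bp] == "C" & ch[-1] == "G"
      j <- sample(which(!is_cg), 1L)
      ch[j] <- "C"; ch[j + 1L] <- "G"
    } else {
      is_cg <- ch[-n_bp] == "C" & ch[-1] == "G"
      j <- sample(which(is_cg), 1L)
      ch[j] <- sample(c("A", "T", "G"), 1L)
    }
  }
  mod_sequence(paste(ch, collapse = ""))
}

#' @noRd
all_dimer_labels <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(b, b, paste0)))
}

#' Dinucleotide step counts
#'
#' @inheritParams cpg_positions
#' @return Named integer vector over the 16 dinucleotide steps; entries sum
#'   to `n - 1`.
#' @export
dinucleotide_counts <- function(seq) {
  seq <- as_mod_sequence(seq)
  ch <- seq$chars
  n <- length(ch)
  if (n < 2) stop("dinucleotide_counts needs a sequence of length >= 2")
  steps <- paste0(ch[-n], ch[-1])
  out <- integer(16)
  names(out) <- all_dimer_labels()
  tab <- table(steps)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Altschul-Erickson dinucleotide shuffle
#'
#' Produces a uniform random permutation of the sequence that preserves all
#' 16 dinucleotide-step counts exactly (hence also the first and last base),
#' using the Eulerian-path construction: a random last-exit edge is drawn for
#' every vertex and accepted only if the chosen edges form an arborescence
#' into the final base, after which the remaining edge lists are permuted
#' uniformly and the path is walked.
#'
#' @param seq a `mod_sequence` or string without modifications (callers
#'   re-apply modifications afterwards).
#' @param rng_seed optional integer seed.
#' @return A `mod_sequence` with identical [dinucleotide_counts()].
#' @export
altschul_erickson_shuffle <- function(seq, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  seq <- as_mod_sequence(seq)
  if (nrow(seq$mods) > 0) {
    stop("shuffle operates on unmodified sequences; drop modifications first")
  }
  ch <- seq$chars
  n <- length(ch)
  if (n < 2) stop("shuffle needs a sequence of length >= 2")
  if (n == 2) return(seq)
  s1 <- ch[1]; sn <- ch[n]
  out_edges <- split(ch[-1], ch[-n])  # multiset of successors per vertex
  verts <- names(out_edges)
  for (attempt in seq_len(10000L)) {
    last <- vapply(verts, function(v) {
      tv <- out_edges[[v]]
      tv[sample.int(length(tv), 1L)]
    }, character(1))
    last[sn] <- NA_character_  # terminal vertex keeps no reserved last edge
    # check: following last-exit edges from every vertex reaches sn
    ok <- TRUE
    for (v in verts) {
      if (v == sn) next
      cur <- v
      for (hop in seq_len(length(verts) + 1L)) {
        cur <- last[[cur]]
        if (is.na(cur) || cur == sn) break
      }
      if (is.na(cur) || cur != sn) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == 10000L) stop("failed to sample a valid last-edge arborescence")
  }
  ordered <- lapply(verts, function(v) {
    tv <- out_edges[[v]]
    if (v != sn) {
      # remove one instance of the reserved last edge, permute, re-append
      drop <- match(last[[v]], tv)
      rest <- tv[-drop]
      c(rest[sample.int(length(rest))], last[[v]])
    } else {
      tv[sample.int(length(tv))]
    }
  })
  names(ordered) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- s1
  cur <- s1
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  mod_sequence(paste(res, collapse = ""))
}

#' Tetramer flanking-context counts around CpG steps
#'
#' For every CpG step with at least four bases on each side, tallies the four
#' upstream and four downstream flanking bases. Steps too close to the
#' sequence ends are skipped and counted.
#'
#' @param seqs a `mod_sequence`/string or a list of them.
#' @return A list with `upstream` and `downstream` 4x4 count matrices (rows
#'   A/C/G/T, columns positions -4..-1 and +1..+4 relative to the step),
#'   `n_tallied`, and `n_skipped`. Column sums equal `n_tallied`.
#' @export
tetramer_context_counts <- function(seqs) {
  if (inherits(seqs, "mod_sequence") || is.character(seqs)) seqs <- list(seqs)
  bases <- c("A", "C", "G", "T")
  up <- matrix(0L, 4, 4, dimnames = list(bases, paste0("m", 4:1)))
  dn <- matrix(0L, 4, 4, dimnames = list(bases, paste0("p", 1:4)))
  tallied <- 0L; skipped <- 0L
  for (s in seqs) {
    s <- as_mod_sequence(s)
    ch <- s$chars
    n <- length(ch)
    for (j in cpg_positions(s)) {
      if (j - 4L < 1L || j + 5L > n) { skipped <- skipped + 1L; next }
      tallied <- tallied + 1L
      upb <- ch[(j - 4L):(j - 1L)]
      dnb <- ch[(j + 2L):(j + 5L)]
      for (k in 1:4) {
        up[upb[k], k] <- up[upb[k], k] + 1L
        dn[dnb[k], k] <- dn[dnb[k], k] + 1L
      }
    }
  }
  list(upstream = up, downstream = dn, n_tallied = tallied, n_skipped = skipped)
}

## ---- extended-FASTA dialect ----

#' @noRd
parse_extended_string <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "M", "N", "H", "K"))
  if (length(bad) > 0) {
    stop("unsupported letters in extended sequence: ", paste(bad, collapse = ", "))
  }
  n <- length(ch)
  step_index <- integer(0); kind <- character(0)
  i <- 1L
  while (i <= n) {
    if (ch[i] == "M" || ch[i] == "H") {
      partner <- if (ch[i] == "M") "N" else "K"
      if (i == n || ch[i + 1L] != partner) {
        stop("malformed modified step at position ", i, ": ", ch[i],
             " must be immediately followed by ", partner)
      }
      step_index <- c(step_index, i)
      kind <- c(kind, if (ch[i] == "M") "methyl" else "hydroxymethyl")
      ch[i] <- "C"; ch[i + 1L] <- "G"
      i <- i + 2L
    } else if (ch[i] == "N" || ch[i] == "K") {
      stop("stray ", ch[i], " at position ", i,
           " (must be preceded by ", if (ch[i] == "N") "M" else "H", ")")
    } else {
      i <- i + 1L
    }
  }
  list(chars = ch,
       mods = data.frame(step_index = step_index, kind = kind,
                         stringsAsFactors = FALSE))
}

#' @noRd
extended_string <- function(seq) {
  seq <- as_mod_sequence(seq)
  ch <- seq$chars
  if (nrow(seq$mods) > 0) {
    for (r in seq_len(nrow(seq$mods))) {
      j <- seq$mods$step_index[r]
      if (seq$mods$kind[r] == "methyl") {
        ch[j] <- "M"; ch[j + 1L] <- "N"
      } else {
        ch[j] <- "H"; ch[j + 1L] <- "K"
      }
    }
  }
  paste(ch, collapse = "")
}

#' Read sequences in the extended-FASTA dialect
#'
#' Plain A/C/G/T FASTA is accepted; a symmetrically modified CpG step may be
#' written `MN` (methyl) or `HK` (hydroxymethyl). Any other letter is an
#' error.
#'
#' @param path FASTA file path.
#' @return Named list of `mod_sequence` objects.
#' @export
read_mod_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(as.character(ss), mod_sequence)
  names(out) <- names(ss)
  out
}

#' Write sequences in the extended-FASTA dialect
#'
#' @param seqs a `mod_sequence` or a (optionally named) list of them.
#' @param path output FASTA path.
#' @export
write_mod_fasta <- function(seqs, path) {
  if (inherits(seqs, "mod_sequence")) seqs <- list(seqs)
  strs <- vapply(seqs, extended_string, character(1))
  if (is.null(names(strs)) || any(names(strs) == "")) {
    names(strs) <- paste0("seq", seq_along(strs))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(strs), path)
  invisible(path)
}
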
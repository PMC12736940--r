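# Reproduction workflow for externally published model inputs. The trained
# parameter set and the bound-phosphate constraint file used for the
# published nucleosome wrapping-energy benchmarks are distributed by their
# authors, not with this package; given converted copies, this workflow
# recomputes the benchmark energies.

#' Recompute benchmark wrapping energies from external published inputs
#'
#' Loads an externally obtained trained parameter set (converted to the
#' portable container schema of [save_parameter_set()]), the matching
#' bound-phosphate constraint file, and a FASTA of benchmark sequences
#' (e.g. Widom 601, 5S, poly-A, sampled genomic fragments), then runs
#' [minimize_wrap()] on each sequence.
#'
#' @param parameter_file path to the converted parameter-set container.
#' @param constraint_file path to the constraint set
#'   ([read_constraint_set()] format).
#' @param fasta_file path to benchmark sequences (extended-FASTA dialect).
#' @param tol gradient tolerance passed to the minimiser.
#' @return data.frame with one row per sequence: `name`, `wrap_energy` (kT),
#'   `penalty`, `log_density`, `converged`.
#' @export
reproduce_published_benchmarks <- function(parameter_file, constraint_file,
                                           fasta_file, tol = 1e-6) {
  for (f in c(parameter_file, constraint_file, fasta_file)) {
    if (!file.exists(f)) {
      stop("external input not available: ", f,
           " (the trained parameter set, bound-phosphate constraint file ",
           "and benchmark sequences are distributed by their authors and ",
           "are not shipped with this package)")
    }
  }
  params <- load_parameter_set(parameter_file)
  constraints <- read_constraint_set(constraint_file)
  seqs <- read_mod_fasta(fasta_file)
  rows <- lapply(names(seqs), function(nm) {
    res <- minimize_wrap(seqs[[nm]], params, constraints, tol = tol)
    data.frame(name = nm, wrap_energy = res$wrap_energy,
               penalty = res$penalty_value, log_density = res$log_density,
               converged = res$converged)
  })
  do.call(rbind, rows)
}
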
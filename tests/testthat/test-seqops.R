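test_that("CpG steps are counted at every CG junction", {
  expect_equal(count_cpg("ACGT"), 1)
  expect_equal(count_cpg("CGCG"), 2)
  alt <- paste(rep(c("C", "G"), length.out = 147), collapse = "")
  expect_equal(count_cpg(alt), 73)
  expect_equal(count_cpg("AATT"), 0)
})

test_that("symmetric modification annotates exactly the CpG steps", {
  s <- apply_symmetric_modification("ACGT", "methyl")
  expect_equal(s$mods$step_index, 2L)
  expect_equal(s$mods$kind, "methyl")
  expect_equal(nrow(apply_symmetric_modification("AATT", "methyl")$mods), 0)
  h <- apply_symmetric_modification("CGCG", "hydroxymethyl")
  expect_equal(h$mods$step_index, c(1L, 3L))
  expect_error(apply_symmetric_modification(h, "methyl"), "mixed-kind")
  # modification never changes the CpG count
  for (seed in 1:5) {
    s0 <- random_sequence_with_cpg_range(60, 0, 30, rng_seed = seed)
    expect_equal(count_cpg(apply_symmetric_modification(s0, "methyl")),
                 count_cpg(s0))
  }
})

test_that("modification records must sit on CpG steps and be unique", {
  expect_error(mod_sequence("ACGT", data.frame(step_index = 1, kind = "methyl")),
               "CpG")
  expect_error(mod_sequence("ACGT", data.frame(step_index = c(2, 2),
                                               kind = "methyl")),
               "duplicate")
  expect_error(mod_sequence("ANCGT"), "stray|outside")
})

test_that("reverse complement is an involution mapping modified steps to n - j", {
  expect_equal(reverse_complement("ACG")$bases, "CGT")
  p <- apply_symmetric_modification("ACGT", "methyl")
  rc <- reverse_complement(p)
  expect_equal(rc$bases, "ACGT")
  expect_equal(rc$mods$step_index, 2L)
  set.seed(11)
  for (i in 1:20) {
    s <- random_sequence_with_cpg_range(40, 0, 20)
    sm <- apply_symmetric_modification(s, "hydroxymethyl")
    expect_equal(count_cpg(reverse_complement(sm)), count_cpg(sm))
    back <- reverse_complement(reverse_complement(sm))
    expect_equal(back$bases, sm$bases)
    expect_equal(sort(back$mods$step_index), sort(sm$mods$step_index))
  }
})

test_that("random sequences land in the requested CpG range, reproducibly", {
  b <- cpg_count_bins()
  for (i in seq_len(nrow(b))) {
    s <- random_sequence_with_cpg_range(147, b[i, 1], b[i, 2], rng_seed = i)
    expect_gte(count_cpg(s), b[i, 1])
    expect_lte(count_cpg(s), b[i, 2])
  }
  s1 <- random_sequence_with_cpg_range(147, 15, 24, rng_seed = 99)
  s2 <- random_sequence_with_cpg_range(147, 15, 24, rng_seed = 99)
  expect_identical(s1$bases, s2$bases)
  expect_error(random_sequence_with_cpg_range(147, 74, 74), "infeasible")
})

test_that("unconstrained random sequences have near-uniform letter frequencies", {
  set.seed(5)
  ch <- unlist(lapply(1:60, function(i)
    random_sequence_with_cpg_range(147, 0, 73)$chars))
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("dinucleotide counts sum to n - 1 and respect complement folding", {
  dc <- dinucleotide_counts("AATT")
  expect_equal(unname(dc[c("AA", "AT", "TT")]), c(1L, 1L, 1L))
  expect_equal(sum(dc), 3L)
  expect_error(dinucleotide_counts("A"), "length")
  set.seed(2)
  for (i in 1:10) {
    s <- random_sequence_with_cpg_range(30, 0, 15)
    expect_equal(sum(dinucleotide_counts(s)), 29L)
  }
  # complement-pair folding: counts of a step and its reverse complement swap
  # under reverse_complement (verified by brute force over all 4-mers)
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b), 1, paste, collapse = "")
  for (s in all4) {
    dc <- dinucleotide_counts(s)
    dr <- dinucleotide_counts(reverse_complement(s))
    for (lab in names(dc)) {
      expect_equal(unname(dr[rc_step_label(lab)]), unname(dc[lab]))
    }
  }
})

test_that("AE shuffle preserves dinucleotide counts exactly", {
  expect_equal(altschul_erickson_shuffle("AATT", rng_seed = 1)$bases, "AATT")
  expect_equal(length(enumerate_shuffles("AATT")), 1L)
  set.seed(3)
  for (i in 1:200) {
    s <- random_sequence_with_cpg_range(147, 0, 73)
    sh <- altschul_erickson_shuffle(s)
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_equal(substr(sh$bases, 1, 1), substr(s$bases, 1, 1))
    expect_equal(substr(sh$bases, 147, 147), substr(s$bases, 147, 147))
  }
  expect_error(altschul_erickson_shuffle(
    apply_symmetric_modification("ACGT", "methyl")), "unmodified")
})

test_that("AE shuffle draws uniformly over the valid shuffles", {
  # a string with several distinct valid shuffles (checked by enumeration)
  s <- "AGATGCATGA"
  valid <- enumerate_shuffles(s)
  expect_gt(length(valid), 2)
  set.seed(7)
  draws <- replicate(4000, altschul_erickson_shuffle(s)$bases)
  expect_true(all(draws %in% valid))
  tab <- table(factor(draws, levels = valid))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("tetramer flanking context tallies steps with full context", {
  tc <- tetramer_context_counts(list("AAAACGAAAA"))
  expect_equal(tc$n_tallied, 1L)
  expect_equal(tc$n_skipped, 0L)
  expect_equal(unname(tc$upstream["A", ]), rep(1L, 4))
  expect_equal(unname(tc$downstream["A", ]), rep(1L, 4))
  tc2 <- tetramer_context_counts(list("ACGT"))
  expect_equal(tc2$n_tallied, 0L)
  expect_equal(tc2$n_skipped, 1L)
  set.seed(8)
  seqs <- lapply(1:10, function(i) random_sequence_with_cpg_range(50, 2, 20))
  tc3 <- tetramer_context_counts(seqs)
  expect_true(all(colSums(tc3$upstream) == tc3$n_tallied))
  expect_true(all(colSums(tc3$downstream) == tc3$n_tallied))
})

test_that("extended-FASTA dialect round-trips modifications", {
  s <- mod_sequence("AMNTTHKA")
  expect_equal(s$bases, "ACGTTCGA")
  expect_equal(s$mods$kind, c("methyl", "hydroxymethyl"))
  expect_equal(as.character(s), "AMNTTHKA")
  expect_error(mod_sequence("AMTT"), "followed by")
  path <- tempfile(fileext = ".fasta")
  seqs <- list(one = s, two = apply_symmetric_modification("TTCGTT", "methyl"))
  write_mod_fasta(seqs, path)
  back <- read_mod_fasta(path)
  expect_equal(back$one$bases, s$bases)
  expect_equal(back$one$mods, s$mods)
  expect_equal(as.character(back$two), "TTMNTT")
})
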
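gr1 <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end)
}

test_that("four-way CGI x NMI classification follows interval arithmetic", {
  cls <- classify_regions(gr1("chr1", 100, 500), gr1("chr1", 300, 700),
                          gr1("chr1", 0, 1000))
  df <- data.frame(start = GenomicRanges::start(cls) - 1,
                   end = GenomicRanges::end(cls),
                   class = S4Vectors::mcols(cls)$region_class)
  df <- df[order(df$start), ]
  expect_equal(df$start, c(0, 100, 300, 500, 700))
  expect_equal(df$end, c(100, 300, 500, 700, 1000))
  expect_equal(df$class, c("D", "C", "A", "B", "D"))
  # disjoint CGI and NMI leave class A empty
  cls2 <- classify_regions(gr1("chr1", 0, 100), gr1("chr1", 200, 300),
                           gr1("chr1", 0, 400))
  expect_false("A" %in% S4Vectors::mcols(cls2)$region_class)
  expect_error(classify_regions(gr1("chr1", 50, 40), gr1("chr1", 0, 10),
                                gr1("chr1", 0, 100)), "malformed")
})

test_that("classification agrees with brute-force per-bp labelling", {
  set.seed(41)
  L <- 3000
  rand_regions <- function(k) {
    st <- sort(sample(0:(L - 20), k))
    gr1("chrT", st, pmin(st + sample(5:200, k, replace = TRUE), L))
  }
  for (rep in 1:5) {
    cgi <- rand_regions(6)
    nmi <- rand_regions(6)
    cls <- classify_regions(cgi, nmi, gr1("chrT", 0, L))
    # brute-force per-bp labels
    inc <- function(df) {
      v <- logical(L)
      for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
      v
    }
    cg <- inc(cgi); nm <- inc(nmi)
    brute <- ifelse(cg & nm, "A", ifelse(nm, "B", ifelse(cg, "C", "D")))
    got <- rep(NA_character_, L)
    for (i in seq_along(cls)) {
      got[GenomicRanges::start(cls)[i]:GenomicRanges::end(cls)[i]] <-
        S4Vectors::mcols(cls)$region_class[i]
    }
    expect_equal(got, brute)
    # classes pairwise disjoint: no bp assigned twice
    tot <- sum(GenomicRanges::width(cls))
    expect_equal(tot, sum(!is.na(got)))
  }
})

test_that("central windows are centred with floor rounding and short regions skip", {
  w <- central_window(gr1("chr1", 0, 147))
  expect_equal(GenomicRanges::start(w) - 1, 0)
  expect_equal(GenomicRanges::end(w), 147)
  w2 <- central_window(gr1("chr1", 0, 200))
  expect_equal(GenomicRanges::start(w2) - 1, 26)
  expect_equal(GenomicRanges::end(w2), 173)
  expect_warning(w3 <- central_window(gr1("chr1", 0, 100)), "skipped")
  expect_length(w3, 0)
})

test_that("CpG-count bins are inclusive with an explicit overflow bucket", {
  mk <- function(k) {
    # sequence with exactly k CpGs: k "CG" blocks padded with A
    paste0(paste(rep("CG", k), collapse = "AA"), "AAA")
  }
  seqs <- lapply(c(4, 5, 14, 15, 24, 25, 34, 35), mk)
  g <- group_by_cpg_count(seqs)
  expect_equal(g$bin, c("0-4", "5-14", "5-14", "15-24", "15-24",
                        "25-34", "25-34", "overflow"))
  expect_length(g$overflow, 1)
  expect_equal(length(unlist(g$bins, recursive = FALSE)) +
                 length(g$overflow), length(seqs))
})

test_that("ensemble statistics match closed forms and brute force", {
  st <- ensemble_stats(c(1, 1, 1, 0, 2), c("a", "a", "a", "b", "b"))
  expect_equal(st$mean[st$group == "a"], 1)
  expect_equal(st$sd[st$group == "a"], 0)
  expect_equal(st$mean[st$group == "b"], 1)
  expect_equal(st$sd[st$group == "b"], sqrt(2))
  set.seed(42)
  v <- rnorm(50)
  g <- sample(letters[1:4], 50, replace = TRUE)
  st2 <- ensemble_stats(v, g)
  for (l in unique(g)) {
    expect_equal(st2$mean[st2$group == l], mean(v[g == l]))
    expect_equal(st2$sd[st2$group == l], sd(v[g == l]))
  }
})

test_that("window scans emit L - width + 1 windows with correct offsets", {
  s147 <- random_sequence_with_cpg_range(147, 0, 73, rng_seed = 1)
  expect_equal(nrow(scan_windows(s147)), 1)
  s150 <- random_sequence_with_cpg_range(150, 0, 75, rng_seed = 2)
  win <- scan_windows(s150)
  expect_equal(nrow(win), 4)
  expect_equal(win$start, 1:4)
  s3k <- random_sequence_with_cpg_range(3000, 0, 1500, rng_seed = 3)
  expect_equal(nrow(scan_windows(s3k)), 3000 - 146)
  expect_warning(w0 <- scan_windows(random_sequence_with_cpg_range(50, 0, 25)),
                 "shorter")
  expect_equal(nrow(w0), 0)
  # windows carry modifications re-indexed
  sm <- apply_symmetric_modification(s150, "methyl")
  pos <- cpg_positions(sm)
  w5 <- window_at(sm, 5, 140)
  expect_equal(w5$mods$step_index, pos[pos >= 5 & pos <= 143] - 4L)
})

test_that("track scores average per bp with coverage flags", {
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 101), c(100, 200)),
                                  score = c(3, 3))
  items <- gr1("chr1", c(10, 150), c(50, 250))
  sc <- attach_scores(items, track)
  expect_equal(sc$mean_score[1], 3)
  expect_false(sc$flagged[1])
  # second item covers 150-200 of 100 bp -> exactly half covered
  expect_equal(sc$covered_fraction[2], 0.5)
  expect_false(sc$flagged[2])   # at threshold, not below
  sc2 <- attach_scores(gr1("chr1", 150, 260), track)
  expect_true(sc2$flagged[1])
  expect_error(attach_scores(gr1("chr9", 0, 10), track), "chr9")
  # brute-force per-bp mean on a variable track
  track2 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1, 11, 31), c(10, 30, 60)),
                                   score = c(1, 5, -2))
  item <- gr1("chr1", 5, 40)
  perbp <- c(rep(1, 10), rep(5, 20), rep(-2, 30))[6:40]
  expect_equal(attach_scores(item, track2)$mean_score, mean(perbp))
})

test_that("BED and bedGraph files round-trip through the readers", {
  dir <- tempfile(); dir.create(dir)
  bed <- file.path(dir, "x.bed")
  write_bed(gr1("chr2", c(10, 500), c(200, 900)), bed)
  gr <- read_bed(bed)
  expect_equal(GenomicRanges::start(gr) - 1, c(10, 500))
  expect_equal(GenomicRanges::end(gr), c(200, 900))
  bg <- file.path(dir, "x.bedGraph")
  write_bedgraph("chr2", c(0, 147), c(147, 294), c(-12.5, 4.25), bg)
  tr <- read_bedgraph(bg)
  expect_equal(tr$score, c(-12.5, 4.25))
  expect_equal(GenomicRanges::width(tr), c(147, 147))
})

test_that("windows are assigned to region classes by centre or containment", {
  regions <- classify_regions(gr1("chr1", 100, 500), gr1("chr1", 300, 700),
                              gr1("chr1", 0, 1000))
  win <- gr1("chr1", c(250, 320, 920, 80), c(397, 467, 1067, 227))
  ctr <- assign_windows_to_regions(win, regions, "center")
  # centres at 0-based 323, 393, 993, 153 -> classes A, A, D, C
  expect_equal(ctr, c("A", "A", "D", "C"))
  cont <- assign_windows_to_regions(win, regions, "containment")
  expect_equal(cont[2], "A")        # [320,467) inside A [300,500)
  expect_true(is.na(cont[1]))       # [250,397) straddles C/A
})

test_that("the respect-NMI policy methylates only non-NMI classes", {
  seqs <- list("ACGTCG", "ACGTCG", "ACGTCG", "ACGTCG")
  out <- methylate_by_region_class(seqs, c("A", "B", "C", "D"))
  n_mods <- vapply(out, function(s) nrow(s$mods), numeric(1))
  expect_equal(n_mods, c(0, 0, 2, 2))
  expect_true(all(vapply(out[3:4], function(s)
    all(s$mods$kind == "methyl"), logical(1))))
  none <- methylate_by_region_class(seqs, c("A", "B", "C", "D"), mode = "none")
  expect_true(all(vapply(none, function(s) nrow(s$mods) == 0, logical(1))))
})
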
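# Genomic-interval layer: CGI x NMI four-way classification, representative
# 147-bp windows, CpG-count stratified ensembles, 1-bp-shift window scans,
# and score-track grouping. All coordinates are 0-based half-open (BED
# semantics); conversion to 1-based sequence positions happens only at the
# FASTA boundary.

#' @noRd
as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  df <- as.data.frame(x)
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("regions need columns chrom, start, end (0-based half-open)")
  }
  if (any(df$start < 0 | df$start >= df$end)) {
    stop("malformed interval: need 0 <= start < end")
  }
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Read a BED file as genomic regions
#' @param path BED file (0-based half-open).
#' @return A `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Write genomic regions to BED
#' @param regions a `GRanges` (or data.frame with chrom/start/end).
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  rtracklayer::export(as_granges(regions), path, format = "BED")
  invisible(path)
}

#' Four-way CGI x NMI region classification
#'
#' Splits the analysed universe into (A) intersection of CGIs and NMIs,
#' (B) NMI minus CGI, (C) CGI minus NMI, and (D) regions in the universe
#' intersecting neither. Interval arithmetic is per base pair, so partial
#' overlaps are split; the four classes are pairwise disjoint.
#'
#' @param cgi,nmi,universe region sets (`GRanges` or data.frames with
#'   `chrom`, `start`, `end` in 0-based half-open coordinates).
#' @return A sorted `GRanges` with metadata column `region_class` in
#'   `c("A","B","C","D")`.
#' @export
classify_regions <- function(cgi, nmi, universe) {
  cgi <- GenomicRanges::reduce(as_granges(cgi))
  nmi <- GenomicRanges::reduce(as_granges(nmi))
  universe <- GenomicRanges::reduce(as_granges(universe))
  a <- GenomicRanges::intersect(cgi, nmi)
  b <- GenomicRanges::setdiff(nmi, cgi)
  cc <- GenomicRanges::setdiff(cgi, nmi)
  d <- GenomicRanges::setdiff(universe, GenomicRanges::union(cgi, nmi))
  lab <- function(gr, l) {
    if (length(gr)) S4Vectors::mcols(gr)$region_class <- l
    gr
  }
  out <- c(lab(a, "A"), lab(b, "B"), lab(cc, "C"), lab(d, "D"))
  GenomicRanges::sort(out)
}

#' Central fixed-width window of each region
#'
#' `start' = start + floor((len - width)/2)`; regions shorter than `width`
#' are skipped with a warning reporting the count.
#'
#' @param regions `GRanges` or data.frame regions.
#' @param width window width in bp (147 for nucleosome work).
#' @return A `GRanges` of width-`width` windows (metadata preserved).
#' @export
central_window <- function(regions, width = 147) {
  gr <- as_granges(regions)
  if (methods::is(regions, "GRanges")) gr <- regions
  keep <- GenomicRanges::width(gr) >= width
  if (any(!keep)) {
    warning(sum(!keep), " region(s) shorter than ", width, " bp skipped")
  }
  gr <- gr[keep]
  off <- floor((GenomicRanges::width(gr) - width) / 2)
  GenomicRanges::narrow(gr, start = off + 1, width = width)
}

#' CpG-count bins used for ensemble stratification
#' @return 4 x 2 matrix of inclusive `[lo, hi]` bounds.
#' @export
cpg_count_bins <- function() {
  matrix(c(0, 4, 5, 14, 15, 24, 25, 34), ncol = 2, byrow = TRUE,
         dimnames = list(c("0-4", "5-14", "15-24", "25-34"), c("lo", "hi")))
}

#' Group sequences into CpG-count sub-ensembles
#'
#' Bins are inclusive `[0,4], [5,14], [15,24], [25,34]`; sequences above the
#' last bin are returned in an `overflow` bucket, never silently dropped.
#'
#' @param seqs list of `mod_sequence`s (or character vector).
#' @return List with `bins` (named list of four sub-ensembles), `overflow`,
#'   `counts` (per-sequence CpG counts) and `bin` (per-sequence bin label or
#'   `"overflow"`).
#' @export
group_by_cpg_count <- function(seqs) {
  if (is.character(seqs)) seqs <- as.list(seqs)
  seqs <- lapply(seqs, as_mod_sequence)
  counts <- vapply(seqs, count_cpg, numeric(1))
  b <- cpg_count_bins()
  lab <- rep("overflow", length(seqs))
  for (i in seq_len(nrow(b))) {
    lab[counts >= b[i, "lo"] & counts <= b[i, "hi"]] <- rownames(b)[i]
  }
  bins <- lapply(rownames(b), function(l) seqs[lab == l])
  names(bins) <- rownames(b)
  list(bins = bins, overflow = seqs[lab == "overflow"],
       counts = counts, bin = lab)
}

#' Per-group mean and standard deviation
#'
#' @param values numeric vector of per-sequence scalars (e.g. wrapping
#'   energies).
#' @param groups grouping vector of the same length.
#' @return data.frame with `group`, `n`, `mean`, `sd` (sample sd; `NA` for
#'   singleton groups); groups absent from `values` are reported with
#'   `n = 0` and missing statistics.
#' @export
ensemble_stats <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  out <- data.frame(group = lev,
                    n = vapply(lev, function(l) sum(groups == l), numeric(1)))
  out$mean <- vapply(lev, function(l) mean(values[groups == l]), numeric(1))
  out$sd <- vapply(lev, function(l) stats::sd(values[groups == l]), numeric(1))
  out
}

#' Sliding windows over a long sequence
#'
#' All `L - width + 1` windows at 1-bp shifts (or coarser `step`), each
#' carrying its offset. Windows containing the full sequence's modifications
#' inherit the records that fall inside them.
#'
#' @param seq a `mod_sequence` (or string).
#' @param width window width (147 default).
#' @param step shift between windows (1 default).
#' @return data.frame with `start` (1-based), `end`; extract a window with
#'   [window_at()]. Zero rows (with a warning) if the sequence is shorter
#'   than `width`.
#' @export
scan_windows <- function(seq, width = 147, step = 1) {
  seq <- as_mod_sequence(seq)
  L <- length(seq)
  if (L < width) {
    warning("sequence shorter than window width; no windows")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- seq.int(1L, L - width + 1L, by = step)
  data.frame(start = start, end = start + width - 1L)
}

#' Extract one window of a sequence (modifications included)
#'
#' @param seq a `mod_sequence`.
#' @param start 1-based start position.
#' @param width window width.
#' @return A `mod_sequence` of length `width`; modification records whose
#'   CpG step lies fully inside the window are kept (re-indexed).
#' @export
window_at <- function(seq, start, width = 147) {
  seq <- as_mod_sequence(seq)
  end <- start + width - 1L
  stopifnot(start >= 1, end <= length(seq))
  bases <- substr(seq$bases, start, end)
  mods <- seq$mods[seq$mods$step_index >= start &
                     seq$mods$step_index <= end - 1L, , drop = FALSE]
  if (nrow(mods)) mods$step_index <- mods$step_index - start + 1L
  mod_sequence(bases, mods)
}

#' Assign scan windows to classified regions
#'
#' For region-mean summaries of window scans, a window belongs to a region
#' either when its central bp lies inside it (`"center"`, the default) or
#' when it is fully contained (`"containment"`).
#'
#' @param windows `GRanges` (or data.frame) of windows.
#' @param regions `GRanges` with a `region_class` metadata column (from
#'   [classify_regions()]).
#' @param rule `"center"` or `"containment"`.
#' @return Character vector of region classes per window (`NA` when
#'   unassigned).
#' @export
assign_windows_to_regions <- function(windows, regions,
                                      rule = c("center", "containment")) {
  rule <- match.arg(rule)
  win <- as_granges(windows)
  if (methods::is(windows, "GRanges")) win <- windows
  qry <- if (rule == "center") {
    mid <- GenomicRanges::start(win) + floor((GenomicRanges::width(win) - 1) / 2)
    GenomicRanges::GRanges(GenomicRanges::seqnames(win),
                           IRanges::IRanges(mid, mid))
  } else win
  hits <- GenomicRanges::findOverlaps(qry, regions,
                                      type = if (rule == "center") "any" else "within")
  out <- rep(NA_character_, length(win))
  out[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(regions)$region_class[S4Vectors::subjectHits(hits)]
  out
}

#' Apply the methylation policy implied by NMI membership
#'
#' Under the "respect NMI" policy, CpG steps of sequences drawn from
#' non-NMI regions (classes C: CGI-not-NMI, and D: neither) are symmetrically
#' methylated, while NMI sequences (classes A and B) stay unmodified.
#'
#' @param seqs list of `mod_sequence`s.
#' @param classes per-sequence region class in `c("A","B","C","D")`.
#' @param mode `"respect-nmi"` (methylate C and D) or `"none"`.
#' @return List of `mod_sequence`s.
#' @export
methylate_by_region_class <- function(seqs, classes,
                                      mode = c("respect-nmi", "none")) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) == length(classes))
  if (mode == "none") return(lapply(seqs, as_mod_sequence))
  mapply(function(s, cl) {
    s <- as_mod_sequence(s)
    if (cl %in% c("C", "D")) apply_symmetric_modification(s, "methyl") else s
  }, seqs, classes, SIMPLIFY = FALSE)
}

#' Read a bedGraph score track
#' @param path bedGraph file.
#' @return A `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path) rtracklayer::import(path, format = "bedGraph")

#' Write a per-window score table as bedGraph
#'
#' @param chrom chromosome name.
#' @param start 0-based window starts.
#' @param end half-open window ends.
#' @param score numeric scores.
#' @param path output path.
#' @export
write_bedgraph <- function(chrom, start, end, score, path) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Mean track score over regions or windows
#'
#' Arithmetic mean of per-bp scores over each item's span; items with less
#' than half their span covered by the track are flagged.
#'
#' @param items `GRanges` (or data.frame) of regions/windows.
#' @param track `GRanges` with a `score` column (e.g. from
#'   [read_bedgraph()]).
#' @param min_coverage flag items whose covered fraction falls below this.
#' @return data.frame with `mean_score` (over covered bp), `covered_fraction`
#'   and `flagged`.
#' @export
attach_scores <- function(items, track, min_coverage = 0.5) {
  gr <- as_granges(items)
  if (methods::is(items, "GRanges")) gr <- items
  miss <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                  as.character(unique(GenomicRanges::seqnames(track))))
  if (length(miss) > 0) {
    stop("track has no coverage for chromosome(s): ",
         paste(miss, collapse = ", "))
  }
  hits <- GenomicRanges::findOverlaps(gr, track)
  qi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr[qi], track[ti])
  wbp <- GenomicRanges::width(ov)
  sc <- track$score[ti]
  tot <- rep(0, length(gr)); cov <- rep(0, length(gr))
  for (k in seq_along(qi)) {
    tot[qi[k]] <- tot[qi[k]] + wbp[k] * sc[k]
    cov[qi[k]] <- cov[qi[k]] + wbp[k]
  }
  frac <- cov / GenomicRanges::width(gr)
  data.frame(mean_score = ifelse(cov > 0, tot / cov, NA_real_),
             covered_fraction = frac,
             flagged = frac < min_coverage)
}
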
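#' Greedy genomic annotation of a PPS set
#'
#' Each PPS is labelled with *every* genomic class whose annotation it
#' overlaps by at least one nucleotide, and each such class counts the PPS
#' exactly once regardless of overlap extent (so a PPS spanning a miRNA
#' embedded in a CDS increments both tallies). PPSs overlapping nothing are
#' tallied as `intergenic`.
#'
#' @param ppss `GRanges` of PPSs.
#' @param space named list of `GRanges`, one per genomic class
#'   (e.g. `utr5`, `cds`, `utr3`, `intron`, `mirna`).
#' @return list with `labels` (per-PPS character vector of classes) and
#'   `tally` (named counts including `intergenic`).
#' @export
annotate_greedy <- function(ppss, space) {
  stopifnot(length(space) > 0, !is.null(names(space)))
  hit <- vapply(space, function(gr)
    GenomicRanges::countOverlaps(ppss, gr, minoverlap = 1L) > 0,
    logical(length(ppss)))
  hit <- matrix(hit, nrow = length(ppss),
                dimnames = list(NULL, names(space)))
  labels <- apply(hit, 1L, function(row) names(space)[row],
                  simplify = FALSE)
  tally <- colSums(hit)
  tally <- c(tally, intergenic = sum(rowSums(hit) == 0))
  list(labels = labels, tally = tally)
}

#' Matched random background intervals
#'
#' Draws one mock interval per input PPS, preserving its chromosome, length
#' and strand, placed uniformly at random inside the allowed annotation
#' space (each mock must fit entirely within one allowed interval) while
#' overlapping neither any excluded interval nor any previously placed mock,
#' by rejection sampling. Deterministic for a given `seed`.
#'
#' @param ppss `GRanges` of PPSs to mimic.
#' @param space `GRanges` of allowed placement regions (UTR/CDS/exon/intron).
#' @param excluded `GRanges` that mocks must not touch (typically every PPS
#'   called in any sample).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per interval.
#' @return `GRanges` of mock intervals, parallel to `ppss`.
#' @export
shuffle_background <- function(ppss, space, excluded = ppss, seed = 1L,
                               max_attempts = 10000L) {
  set.seed(seed)
  chroms <- as.character(GenomicRanges::seqnames(ppss))
  widths <- GenomicRanges::width(ppss)
  strands <- as.character(GenomicRanges::strand(ppss))
  sp_chrom <- as.character(GenomicRanges::seqnames(space))
  sp_start <- GenomicRanges::start(space)      # 1-based closed
  sp_width <- GenomicRanges::width(space)
  ex_chrom <- as.character(GenomicRanges::seqnames(excluded))
  ex_start <- GenomicRanges::start(excluded)
  ex_end <- GenomicRanges::end(excluded)
  out_start <- integer(length(ppss))
  for (i in seq_along(ppss)) {
    fits <- which(sp_chrom == chroms[i] & sp_width >= widths[i])
    if (length(fits) == 0L) {
      stop("no allowed interval on ", chroms[i], " can fit a ", widths[i],
           "-nt mock for ", chroms[i], ":", GenomicRanges::start(ppss[i]))
    }
    # start slots: one per admissible start position, across space intervals
    slot_n <- sp_width[fits] - widths[i] + 1L
    avoid <- which(ex_chrom == chroms[i])
    prev <- which(chroms[seq_len(i - 1L)] == chroms[i])
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      j <- fits[sample.int(length(fits), 1L, prob = slot_n)]
      s <- sp_start[j] + sample.int(sp_width[j] - widths[i] + 1L, 1L) - 1L
      e <- s + widths[i] - 1L
      clash <- any(s <= ex_end[avoid] & e >= ex_start[avoid]) ||
        any(s <= out_start[prev] + widths[prev] - 1L & e >= out_start[prev])
      if (!clash) {
        out_start[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place mock for interval ", i, " (", chroms[i], ":",
           GenomicRanges::start(ppss[i]) - 1L, "-",
           GenomicRanges::end(ppss[i]), strands[i], ") after ",
           max_attempts, " attempts")
    }
  }
  gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start = out_start, width = widths),
    strand = strands)
  S4Vectors::mcols(gr)$name <- sprintf("bg_%05d", seq_along(gr))
  gr
}

#' Overlap enrichment of external sites in PPSs versus background
#'
#' Fraction of `sites` (e.g. CLIP peaks) overlapping a PPS by >= 1 nt,
#' against the same fraction for matched background intervals, with a
#' chi-squared test (1 df, no continuity correction) on the 2x2
#' overlap-by-set table.
#'
#' @param sites `GRanges` of external sites.
#' @param ppss `GRanges` of PPSs.
#' @param background `GRanges` of matched mock intervals.
#' @param ignore_strand compare without strand (some site sets are
#'   unstranded); default `FALSE`.
#' @return list with `pct_real`, `pct_bg`, `chi2`, `chi2_p`, `table`.
#' @export
overlap_enrichment <- function(sites, ppss, background,
                               ignore_strand = FALSE) {
  if (length(sites) == 0L) stop("empty site set")
  n_real <- sum(IRanges::overlapsAny(sites, ppss,
                                     ignore.strand = ignore_strand))
  n_bg <- sum(IRanges::overlapsAny(sites, background,
                                   ignore.strand = ignore_strand))
  n <- length(sites)
  tab <- matrix(c(n_real, n - n_real, n_bg, n - n_bg), nrow = 2,
                dimnames = list(c("overlap", "no_overlap"),
                                c("real", "background")))
  p <- if (n_real == n_bg) 1 else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  chi2 <- if (n_real == n_bg) 0 else
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  list(pct_real = 100 * n_real / n, pct_bg = 100 * n_bg / n,
       chi2 = chi2, chi2_p = p, table = tab)
}

#' Log2 enrichment of PPS base coverage per genomic class
#'
#' `log2((pps_bases_c / sum(pps_bases)) / (genome_bases_c /
#' sum(genome_bases)))` per class; classes absent from the genome are
#' dropped with a warning.
#'
#' @param pps_class_bases named numeric: PPS-covered bases per class.
#' @param genome_class_bases named numeric: genomic bases per class.
#' @return named numeric of log2 enrichments.
#' @export
class_log2_enrichment <- function(pps_class_bases, genome_class_bases) {
  stopifnot(sum(pps_class_bases) > 0, sum(genome_class_bases) > 0)
  cls <- names(genome_class_bases)
  bad <- cls[genome_class_bases == 0]
  if (length(bad)) {
    warning("dropping classes with zero genomic bases: ",
            paste(bad, collapse = ", "))
    cls <- setdiff(cls, bad)
  }
  pps <- pps_class_bases[cls]
  pps[is.na(pps)] <- 0
  log2((pps / sum(pps_class_bases)) /
         (genome_class_bases[cls] / sum(genome_class_bases)))
}

#' Conservation of PPSs relative to equal-sized flanks
#'
#' For each PPS, the mean conservation over the site is compared with the
#' mean over its two flanking regions of the same length (immediately up-
#' and downstream, averaged together); a two-sample Kolmogorov-Smirnov test
#' contrasts the two per-PPS distributions. Flanks running past the start of
#' a contig are truncated and flagged.
#'
#' @param ppss `GRanges` of PPSs.
#' @param cons a [coverage_track()]-like real-valued track (e.g. PhastCons),
#'   typically unstranded: values are looked up on the PPS strand first and
#'   fall back to "+".
#' @return list with `mean_pps`, `mean_flank`, `ks_d`, `ks_p`, and the
#'   per-PPS data frame `per_pps` (columns `pps_mean`, `flank_mean`,
#'   `truncated`).
#' @export
conservation_flank_compare <- function(ppss, cons) {
  stopifnot(length(ppss) > 0)
  track_mean <- function(chrom, strand, from, to) {   # half-open, 0-based
    if (to <= from) {
      return(NA_real_)
    }
    pos <- seq.int(from, to - 1L)
    v <- cov_values(cons, chrom, strand, pos)
    if (all(v == 0) && strand != "+") {
      v <- cov_values(cons, chrom, "+", pos)
    }
    mean(v)
  }
  n <- length(ppss)
  pps_mean <- flank_mean <- numeric(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(ppss[i]))
    strand <- as.character(GenomicRanges::strand(ppss[i]))
    s <- GenomicRanges::start(ppss[i]) - 1L
    e <- GenomicRanges::end(ppss[i])
    w <- e - s
    pps_mean[i] <- track_mean(chrom, strand, s, e)
    up_from <- max(0L, s - w)
    truncated[i] <- up_from > s - w
    up <- track_mean(chrom, strand, up_from, s)
    down <- track_mean(chrom, strand, e, e + w)
    flank_mean[i] <- mean(c(up, down), na.rm = TRUE)
  }
  ks <- if (n >= 1 && !all(pps_mean == flank_mean)) {
    suppressWarnings(stats::ks.test(pps_mean, flank_mean))
  } else {
    list(statistic = c(D = 0), p.value = 1)
  }
  list(mean_pps = mean(pps_mean), mean_flank = mean(flank_mean),
       ks_d = unname(ks$statistic), ks_p = ks$p.value,
       per_pps = data.frame(pps_mean = pps_mean, flank_mean = flank_mean,
                            truncated = truncated))
}

#' PPS density metagene around the start or stop codon
#'
#' Per offset from the anchor, the fraction of transcripts whose spliced
#' position at that offset is covered by at least one PPS; the profile is
#' rescaled so its maximum is exactly 1. An all-zero profile is returned
#' unscaled with a warning.
#'
#' @param ppss `GRanges` of PPSs.
#' @param txs named list of [transcript_model()]s.
#' @param anchor `"start"` or `"stop"`.
#' @param flank half-window (nt).
#' @return a `metagene_profile` data frame (`offset`, `mean`, `sem`, `n`);
#'   `mean` is the max-normalized density.
#' @export
density_profile <- function(ppss, txs, anchor = c("start", "stop"),
                            flank = 400L) {
  anchor <- match.arg(anchor)
  offs <- seq.int(-flank, flank - 1L)
  covered <- nvec <- numeric(length(offs))
  for (tx in txs) {
    a <- tx_anchor(tx, anchor)
    if (is.na(a)) next
    pos <- a + offs
    ok <- pos >= 0L & pos < tx$spliced_length
    if (!any(ok)) next
    gpos <- transcript_to_genomic(tx, pos[ok])
    gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(start = gpos + 1L, width = 1L),
      strand = tx$strand)
    covered[ok] <- covered[ok] +
      (GenomicRanges::countOverlaps(gr, ppss) > 0)
    nvec[ok] <- nvec[ok] + 1
  }
  dens <- ifelse(nvec > 0, covered / nvec, NA_real_)
  mx <- max(dens, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) {
    dens <- dens / mx
  } else {
    warning("all-zero density profile left unnormalized")
  }
  out <- data.frame(offset = offs, mean = dens, sem = 0, n = nvec)
  attr(out, "anchor") <- anchor
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Percent of each spliced transcript covered by PPSs
#'
#' The union of PPS-covered exonic bases, mapped to spliced coordinates, as
#' a percentage of spliced length; transcripts are then ranked into deciles
#' of coverage (nearest-rank; decile 10 = most covered).
#'
#' @param ppss `GRanges` of PPSs.
#' @param txs named list of [transcript_model()]s.
#' @return data frame with `transcript_id`, `percent`, `decile`.
#' @export
transcript_pps_coverage <- function(ppss, txs) {
  pct <- vapply(txs, function(tx) {
    gpos <- transcript_to_genomic(tx, seq.int(0L, tx$spliced_length - 1L))
    gr <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(start = gpos + 1L, width = 1L),
      strand = tx$strand)
    100 * sum(GenomicRanges::countOverlaps(gr, ppss) > 0) /
      tx$spliced_length
  }, numeric(1))
  n <- length(pct)
  decile <- as.integer(ceiling(10 * rank(pct, ties.method = "first") / n))
  data.frame(transcript_id = names(txs), percent = unname(pct),
             decile = decile, row.names = NULL)
}

#' Sliding-window correlation between two coverage tracks
#'
#' RPKM-like abundance (reads per window per million mapped reads,
#' length-fixed windows) in non-overlapping windows, correlated (Pearson)
#' across windows with at least one read in either track.
#'
#' @param covA,covB [coverage_track()]s on the same contigs.
#' @param window window size (nt), default 1000.
#' @return Pearson correlation coefficient.
#' @export
sliding_window_correlation <- function(covA, covB, window = 1000L) {
  keys <- cov_keys(covA, covB)
  a <- b <- numeric(0)
  for (k in keys) {
    va <- covA$counts[[k]]
    vb <- covB$counts[[k]]
    n <- max(length(va), length(vb))
    va <- c(va, numeric(n - length(va)))
    vb <- c(vb, numeric(n - length(vb)))
    nw <- ceiling(n / window)
    idx <- rep(seq_len(nw), each = window, length.out = n)
    a <- c(a, as.numeric(tapply(va, idx, sum)))
    b <- c(b, as.numeric(tapply(vb, idx, sum)))
  }
  use <- (a + b) > 0
  if (sum(use) < 2L) stop("fewer than 2 usable windows")
  # per-library depth normalization (RPKM-like; window length is constant)
  an <- a[use] / max(1, sum(a)) * 1e6
  bn <- b[use] / max(1, sum(b)) * 1e6
  stats::cor(an, bn)
}

#' Select PPSs within a 3'UTR window downstream of stop codons
#'
#' Returns PPSs overlapping by >= 1 nt the spliced interval
#' `[stop + offset_start, stop + offset_end)` of any transcript, where
#' `stop` is the first base after the CDS.
#'
#' @param ppss `GRanges` of PPSs.
#' @param txs named list of [transcript_model()]s.
#' @param offset_start,offset_end half-open window downstream of the stop
#'   (nt), `0 <= offset_start < offset_end`.
#' @return subset of `ppss` (unique, original order).
#' @export
select_pps_in_utr_window <- function(ppss, txs, offset_start, offset_end) {
  stopifnot(offset_start >= 0, offset_start < offset_end)
  windows <- lapply(txs, function(tx) {
    stop_tx <- tx_anchor(tx, "stop")
    if (is.na(stop_tx)) {
      return(GenomicRanges::GRanges())
    }
    transcript_window_granges(tx, stop_tx + offset_start,
                              stop_tx + offset_end)
  })
  win <- do.call(c, unname(windows))
  if (length(win) == 0L) {
    return(ppss[integer(0)])
  }
  ppss[IRanges::overlapsAny(ppss, win, minoverlap = 1L)]
}

#' Nucleotide composition of PPS sequences
#'
#' Emits both readings of per-base composition: pooled base counts over all
#' sequences, and per-sequence base fractions (one row per PPS, suitable for
#' a boxplot).
#'
#' @param seqs character vector of PPS sequences (ACGU/T, case-insensitive).
#' @return list with `pooled` (named counts over A,C,G,U) and `per_pps`
#'   (data frame of per-sequence fractions).
#' @export
nucleotide_composition <- function(seqs) {
  seqs <- chartr("acgutT", "ACGUUU", seqs)
  tab_one <- function(s) {
    v <- strsplit(s, "")[[1]]
    counts <- vapply(c("A", "C", "G", "U"), function(b) sum(v == b),
                     numeric(1))
    counts
  }
  mat <- t(vapply(seqs, tab_one, numeric(4)))
  pooled <- colSums(mat)
  frac <- mat / pmax(1, rowSums(mat))
  list(pooled = pooled,
       per_pps = data.frame(A = frac[, 1], C = frac[, 2], G = frac[, 3],
                            U = frac[, 4], row.names = NULL))
}
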
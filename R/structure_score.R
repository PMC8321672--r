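#' Generalized log ratio transform
#'
#' `glog(x) = log2(x + sqrt(1 + x^2))`. Unlike `log2`, it is defined at 0
#' (`glog(0) = 0`), which matters for bases covered by only one of the two
#' nuclease digests, and it approaches `log2(2x)` for large `x`, so the
#' difference of two glogs behaves like an ordinary log ratio at high
#' coverage.
#'
#' @param x non-negative numeric vector.
#' @return `log2(x + sqrt(1 + x^2))`, same length as `x`.
#' @export
glog <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("glog() is defined for x >= 0 only")
  log2(x + sqrt(1 + x^2))
}

#' Coverage-length normalized digest coverage
#'
#' Rescales a per-base count from one digest so the two digests are
#' comparable despite different library footprints:
#' `n * max(L_self, L_other) / L_self`, where `L` is the library-wide number
#' of covered bases. The digest with the larger footprint passes through
#' unchanged.
#'
#' @param n per-base read count(s) from this digest.
#' @param L_self covered length (nt) of this digest's library.
#' @param L_other covered length (nt) of the other digest's library.
#' @return normalized coverage, same length as `n`.
#' @export
normalized_digest_coverage <- function(n, L_self, L_other) {
  if (L_self == 0) {
    if (any(n > 0)) {
      stop("nonzero counts with zero covered length are inconsistent")
    }
    return(rep(0, length(n)))
  }
  n * max(L_self, L_other) / L_self
}

#' Per-base structure score of a spliced transcript
#'
#' For each spliced position `i`, `S_i = glog(ds_i) - glog(ss_i)` where
#' `ds_i`/`ss_i` are the [normalized_digest_coverage()] of the dsRNase and
#' ssRNase structure-only libraries (sense strand only). Positive scores mark
#' bases more likely paired, negative more likely unpaired. The `normalized`
#' component subtracts the transcript mean, so scores are comparable across
#' transcripts of different overall structure.
#'
#' @param ds,ss [coverage_track()]s of the dsRNase and ssRNase structure-only
#'   libraries.
#' @param tx a [transcript_model()].
#' @param L_ds,L_ss library-wide covered lengths; default to the tracks'
#'   totals. Pass explicitly when scoring a transcript subset of a larger
#'   library.
#' @return object of class `structure_score_track` with fields
#'   `transcript_id`, `raw`, `normalized`, `ds`, `ss` (per spliced position).
#' @export
structure_score <- function(ds, ss, tx,
                            L_ds = covered_length(ds),
                            L_ss = covered_length(ss)) {
  if (L_ds == 0 && L_ss == 0) {
    stop("no structure-only signal: both libraries have zero covered length")
  }
  gpos <- transcript_to_genomic(tx, seq.int(0L, tx$spliced_length - 1L))
  n_ds <- cov_values(ds, tx$chrom, tx$strand, gpos)
  n_ss <- cov_values(ss, tx$chrom, tx$strand, gpos)
  ds_i <- normalized_digest_coverage(n_ds, L_ds, L_ss)
  ss_i <- normalized_digest_coverage(n_ss, L_ss, L_ds)
  raw <- glog(ds_i) - glog(ss_i)
  structure(
    list(transcript_id = tx$transcript_id, raw = raw,
         normalized = raw - mean(raw), ds = ds_i, ss = ss_i),
    class = "structure_score_track")
}

#' @export
print.structure_score_track <- function(x, ...) {
  cat(sprintf(
    "<structure_score_track> %s: %d positions, raw mean %.4f, range [%.3f, %.3f]\n",
    x$transcript_id, length(x$raw), mean(x$raw),
    min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' Metagene profile of structure scores around the start or stop codon
#'
#' Averages transcript-normalized scores at each offset from the anchor
#' (`"start"` = first CDS base; `"stop"` = first base after the CDS).
#' Transcripts contribute only at offsets their spliced extent covers, so `n`
#' varies along the window.
#'
#' @param scores list of [structure_score()] tracks.
#' @param txs named list of [transcript_model()]s (names = transcript ids).
#' @param anchor `"start"` or `"stop"`.
#' @param flank half-window (nt); offsets run `-flank .. flank-1`.
#' @return object of class `metagene_profile`: data frame with `offset`,
#'   `mean`, `sem`, `n`.
#' @export
metagene <- function(scores, txs, anchor = c("start", "stop"), flank = 400L) {
  anchor <- match.arg(anchor)
  stopifnot(flank >= 1L)
  offs <- seq.int(-flank, flank - 1L)
  sum_x <- sum_x2 <- nvec <- numeric(length(offs))
  for (sc in scores) {
    tx <- txs[[sc$transcript_id]]
    if (is.null(tx)) stop("no transcript model for ", sc$transcript_id)
    a <- tx_anchor(tx, anchor)
    if (is.na(a)) next
    pos <- a + offs
    ok <- pos >= 0L & pos < tx$spliced_length
    v <- sc$normalized[pos[ok] + 1L]
    sum_x[ok] <- sum_x[ok] + v
    sum_x2[ok] <- sum_x2[ok] + v^2
    nvec[ok] <- nvec[ok] + 1
  }
  mean_v <- ifelse(nvec > 0, sum_x / nvec, NA_real_)
  var_v <- ifelse(nvec > 1,
                  pmax(0, (sum_x2 - nvec * mean_v^2) / (nvec - 1)), 0)
  sem <- ifelse(nvec > 0, sqrt(var_v / pmax(nvec, 1)), NA_real_)
  out <- data.frame(offset = offs, mean = mean_v, sem = sem, n = nvec)
  attr(out, "anchor") <- anchor
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' @export
plot.metagene_profile <- function(x, ..., col = "steelblue",
                                  ylab = "mean signal") {
  ok <- !is.na(x$mean)
  plot(x$offset[ok], x$mean[ok], type = "l", col = col,
       xlab = sprintf("offset from %s codon (nt)", attr(x, "anchor")),
       ylab = ylab, ...)
  lo <- x$mean[ok] - x$sem[ok]
  hi <- x$mean[ok] + x$sem[ok]
  polygon(c(x$offset[ok], rev(x$offset[ok])), c(lo, rev(hi)),
          border = NA, col = grDevices::adjustcolor(col, alpha.f = 0.25))
  abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Rank-sum comparison of per-transcript window means
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test between two sets of
#' per-transcript window means (e.g. the +/-100 nt around the start codon in
#' two conditions). Uses the exact distribution for small untied samples and
#' the tie-corrected normal approximation otherwise; two identical degenerate
#' samples give p = 1.
#'
#' @param a,b numeric vectors (non-empty).
#' @return two-sided p-value.
#' @export
compare_windows <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty")
  }
  if (length(unique(c(a, b))) == 1L) {
    return(1)
  }
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}
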
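#' Transcript model
#'
#' An exon chain with CDS boundaries in spliced coordinates. All coordinates
#' are 0-based half-open (BED convention); exons are stored in ascending
#' genomic order and interpreted 5'->3' according to `strand`.
#'
#' @param transcript_id character scalar.
#' @param chrom chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of 0-based half-open exon
#'   coordinates, ascending and non-overlapping.
#' @param cds_start_tx,cds_end_tx CDS boundaries in spliced-transcript
#'   coordinates: `cds_start_tx` is the first CDS base, `cds_end_tx` the
#'   exclusive end. `NA` for non-coding models.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start_tx = NA_integer_,
                             cds_end_tx = NA_integer_) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts))
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("exons of ", transcript_id, " overlap")
  }
  spliced_length <- sum(exon_ends - exon_starts)
  if (!is.na(cds_start_tx)) {
    stopifnot(cds_start_tx >= 0, cds_start_tx < cds_end_tx,
              cds_end_tx <= spliced_length)
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         exon_starts = as.integer(exon_starts),
         exon_ends = as.integer(exon_ends),
         cds_start_tx = as.integer(cds_start_tx),
         cds_end_tx = as.integer(cds_end_tx),
         spliced_length = as.integer(spliced_length)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start_tx)) "non-coding" else
    sprintf("CDS [%d,%d)", x$cds_start_tx, x$cds_end_tx)
  cat(sprintf("<transcript_model> %s %s:%s %d exon(s), %d nt spliced, %s\n",
              x$transcript_id, x$chrom, x$strand,
              length(x$exon_starts), x$spliced_length, cds))
  invisible(x)
}

#' Map genomic positions to spliced-transcript coordinates
#'
#' Offsets count 5'->3' in transcript orientation; on the minus strand the
#' rightmost exonic base is position 0. Intronic or outside positions map to
#' `NA`.
#'
#' @param tx a [transcript_model()].
#' @param gpos 0-based genomic positions (vectorized).
#' @return integer vector of spliced positions in `[0, spliced_length)`, or
#'   `NA` where `gpos` is not exonic.
#' @export
genomic_to_transcript <- function(tx, gpos) {
  cum <- cumsum(c(0L, tx$exon_ends - tx$exon_starts))
  out <- rep(NA_integer_, length(gpos))
  idx <- findInterval(gpos, tx$exon_starts)
  ok <- idx >= 1L & gpos < tx$exon_ends[pmax(idx, 1L)]
  plus_pos <- cum[idx[ok]] + (gpos[ok] - tx$exon_starts[idx[ok]])
  out[ok] <- as.integer(plus_pos)
  if (tx$strand == "-") out <- tx$spliced_length - 1L - out
  out
}

#' Map spliced-transcript positions to genomic coordinates
#'
#' Inverse of [genomic_to_transcript()].
#'
#' @param tx a [transcript_model()].
#' @param tpos 0-based spliced positions in `[0, spliced_length)`.
#' @return integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(tx, tpos) {
  stopifnot(all(tpos >= 0 & tpos < tx$spliced_length, na.rm = TRUE))
  plus_pos <- if (tx$strand == "-") tx$spliced_length - 1L - tpos else tpos
  cum <- cumsum(c(0L, tx$exon_ends - tx$exon_starts))
  idx <- findInterval(plus_pos, cum, rightmost.closed = FALSE)
  as.integer(tx$exon_starts[idx] + (plus_pos - cum[idx]))
}

#' Genomic footprint of a spliced-coordinate window
#'
#' Converts the half-open spliced interval `[tx_start, tx_end)` (clipped to
#' the transcript) into the corresponding genomic ranges, split at exon
#' junctions.
#'
#' @param tx a [transcript_model()].
#' @param tx_start,tx_end half-open spliced window.
#' @return a [GenomicRanges::GRanges] (possibly empty) on the transcript's
#'   strand.
#' @export
transcript_window_granges <- function(tx, tx_start, tx_end) {
  tx_start <- max(0L, tx_start)
  tx_end <- min(tx$spliced_length, tx_end)
  if (tx_end <= tx_start) {
    return(GenomicRanges::GRanges())
  }
  gpos <- transcript_to_genomic(tx, seq.int(tx_start, tx_end - 1L))
  gpos <- sort(gpos)
  brk <- c(TRUE, diff(gpos) != 1L)
  run <- cumsum(brk)
  starts <- tapply(gpos, run, min)
  ends <- tapply(gpos, run, max) + 1L
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(start = starts + 1L, end = ends),
                         strand = tx$strand)
}

# spliced anchor position: "start" = first CDS base, "stop" = first base
# after the CDS (half-open CDS end)
tx_anchor <- function(tx, anchor = c("start", "stop")) {
  anchor <- match.arg(anchor)
  if (is.na(tx$cds_start_tx)) {
    return(NA_integer_)
  }
  if (anchor == "start") tx$cds_start_tx else tx$cds_end_tx
}

# spliced half-open [start,end) ranges of the three transcript regions
tx_regions <- function(tx) {
  if (is.na(tx$cds_start_tx)) {
    return(list(utr5 = c(0L, 0L), cds = c(0L, 0L),
                utr3 = c(0L, tx$spliced_length)))
  }
  list(utr5 = c(0L, tx$cds_start_tx),
       cds = c(tx$cds_start_tx, tx$cds_end_tx),
       utr3 = c(tx$cds_end_tx, tx$spliced_length))
}
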
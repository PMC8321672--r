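#' Read BED6 intervals or BED12 transcript models
#'
#' Coordinates are preserved 0-based half-open; the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed representation
#' internally, so `start(gr) == BED start + 1`.
#'
#' @param path BED file.
#' @param dialect `"bed6"` (stranded intervals) or `"bed12"` (transcript
#'   models with exon blocks and thickStart/thickEnd CDS).
#' @return for `"bed6"`, a `GRanges` with `name` and `score` columns; for
#'   `"bed12"`, a named list of [transcript_model()] objects.
#' @export
read_bed <- function(path, dialect = c("bed6", "bed12")) {
  dialect <- match.arg(dialect)
  need <- if (dialect == "bed6") 6L else 12L
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|#|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < need)
  if (length(bad)) {
    stop("malformed ", dialect, " line ", lineno[bad[1L]], " in ", path,
         ": expected >= ", need, " fields")
  }
  fld <- function(i) vapply(f, `[[`, character(1), i)
  chrom <- fld(1L)
  start <- as.integer(fld(2L))
  end <- as.integer(fld(3L))
  name <- fld(4L)
  score <- suppressWarnings(as.numeric(fld(5L)))
  strand <- fld(6L)
  bad <- which(is.na(start) | is.na(end) | end <= start |
                 !(strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed ", dialect, " line ", lineno[bad[1L]], " in ", path,
         ": bad coordinates or strand")
  }
  if (dialect == "bed6") {
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = start + 1L, end = end),
      strand = strand)
    S4Vectors::mcols(gr)$name <- name
    S4Vectors::mcols(gr)$score <- score
    return(gr)
  }
  thick_start <- as.integer(fld(7L))
  thick_end <- as.integer(fld(8L))
  n_block <- as.integer(fld(10L))
  sizes <- lapply(strsplit(fld(11L), ",", fixed = TRUE), as.integer)
  offs <- lapply(strsplit(fld(12L), ",", fixed = TRUE), as.integer)
  out <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    sz <- sizes[[i]]
    of <- offs[[i]]
    if (length(sz) != n_block[i] || length(of) != n_block[i]) {
      stop("malformed bed12 line ", lineno[i], " in ", path,
           ": blockCount disagrees with blockSizes/blockStarts")
    }
    ex_start <- start[i] + of
    ex_end <- ex_start + sz
    if (of[1L] != 0L || ex_end[n_block[i]] != end[i]) {
      stop("malformed bed12 line ", lineno[i], " in ", path,
           ": blocks inconsistent with chromStart/chromEnd")
    }
    tx <- transcript_model(name[i], chrom[i], strand[i], ex_start, ex_end)
    if (thick_end[i] > thick_start[i]) {
      # first/last CDS base in genomic coords -> spliced coords
      lo <- genomic_to_transcript(tx, c(thick_start[i], thick_end[i] - 1L))
      if (anyNA(lo)) {
        stop("bed12 line ", lineno[i], " in ", path,
             ": thickStart/thickEnd not exonic")
      }
      tx$cds_start_tx <- min(lo)
      tx$cds_end_tx <- max(lo) + 1L
    }
    out[[i]] <- tx
  }
  names(out) <- name
  out
}

#' Write intervals or transcript models to BED
#'
#' Inverse of [read_bed()]: BED6 for a `GRanges`, BED12 for a list of
#' [transcript_model()]s. Round-trips coordinates exactly.
#'
#' @param x a `GRanges` (with optional `name`/`score` columns) or a list of
#'   `transcript_model` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "GRanges")) {
    nm <- S4Vectors::mcols(x)$name
    if (is.null(nm)) nm <- rep(".", length(x))
    sc <- S4Vectors::mcols(x)$score
    if (is.null(sc)) sc <- rep(0, length(x))
    sc <- ifelse(is.na(sc), "0", format(sc, trim = TRUE, digits = 10))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       as.character(GenomicRanges::seqnames(x)),
                       GenomicRanges::start(x) - 1L,
                       GenomicRanges::end(x), nm, sc,
                       as.character(GenomicRanges::strand(x))), path)
    return(invisible(path))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                   "transcript_model")))
  rows <- vapply(x, function(tx) {
    chrom_start <- tx$exon_starts[1L]
    chrom_end <- tx$exon_ends[length(tx$exon_ends)]
    if (is.na(tx$cds_start_tx)) {
      thick <- c(chrom_start, chrom_start)
    } else {
      g <- transcript_to_genomic(tx, c(tx$cds_start_tx, tx$cds_end_tx - 1L))
      thick <- c(min(g), max(g) + 1L)
    }
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            tx$chrom, chrom_start, chrom_end, tx$transcript_id, tx$strand,
            thick[1L], thick[2L], length(tx$exon_starts),
            paste0(paste(tx$exon_ends - tx$exon_starts, collapse = ","), ","),
            paste0(paste(tx$exon_starts - chrom_start, collapse = ","), ","))
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
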
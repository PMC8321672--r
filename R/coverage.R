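#' Per-base strand-specific coverage track
#'
#' Sparse per-base signal stored densely per (contig, strand). Positions are
#' 0-based; absent positions read as 0. For read-count tracks the covered
#' length `L` (number of positions with signal > 0) and the total read count
#' are the library-wide normalizers used by the structure score.
#'
#' @param chrom,strand,pos,value parallel vectors: contig name, strand
#'   (`"+"`/`"-"`), 0-based position, and non-negative signal. Duplicated
#'   positions are summed.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom = character(), strand = character(),
                           pos = integer(), value = numeric()) {
  stopifnot(length(pos) == length(value))
  if (any(value < 0)) stop("coverage values must be non-negative")
  if (length(chrom) == 1L && length(pos) > 0L) {
    chrom <- rep(chrom, length(pos))
  }
  if (length(strand) == 1L && length(pos) > 0L) {
    strand <- rep(strand, length(pos))
  }
  if (length(pos) == 0L) {
    return(new_coverage_track(list()))
  }
  stopifnot(length(chrom) == length(pos), length(strand) == length(pos))
  key <- paste0(chrom, "|", strand)
  counts <- list()
  for (k in unique(key)) {
    sel <- key == k
    p <- pos[sel]
    v <- value[sel]
    vec <- numeric(max(p) + 1L)
    agg <- rowsum(v, p)                       # sum duplicates/overlaps
    vec[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    counts[[k]] <- vec
  }
  new_coverage_track(counts)
}

new_coverage_track <- function(counts) {
  structure(
    list(counts = counts,
         total_reads = sum(vapply(counts, sum, numeric(1))),
         covered_length = sum(vapply(counts, function(v) sum(v > 0),
                                     numeric(1)))),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %d contig-strand(s), total signal %.6g, L = %d covered bases\n",
    length(x$counts), x$total_reads, as.integer(x$covered_length)))
  invisible(x)
}

#' @rdname coverage_track
#' @param x a `coverage_track`.
#' @export
covered_length <- function(x) x$covered_length

#' @rdname coverage_track
#' @export
total_reads <- function(x) x$total_reads

# vectorized getter: values at 0-based positions on one contig-strand
cov_values <- function(x, chrom, strand, pos) {
  vec <- x$counts[[paste0(chrom, "|", strand)]]
  if (is.null(vec)) {
    return(numeric(length(pos)))
  }
  out <- numeric(length(pos))
  ok <- pos >= 0L & pos < length(vec)
  out[ok] <- vec[pos[ok] + 1L]
  out
}

# keys ("chrom|strand") present in a set of tracks
cov_keys <- function(...) {
  unique(unlist(lapply(list(...), function(t) names(t$counts))))
}

#' Pool coverage tracks by summation
#'
#' @param ... `coverage_track` objects (e.g. replicate libraries).
#' @return a single pooled `coverage_track`.
#' @export
pool_tracks <- function(...) {
  tracks <- list(...)
  counts <- list()
  for (t in tracks) {
    for (k in names(t$counts)) {
      v <- t$counts[[k]]
      if (is.null(counts[[k]])) {
        counts[[k]] <- v
      } else {
        n <- max(length(counts[[k]]), length(v))
        a <- c(counts[[k]], numeric(n - length(counts[[k]])))
        a[seq_along(v)] <- a[seq_along(v)] + v
        counts[[k]] <- a
      }
    }
  }
  new_coverage_track(counts)
}

#' Read a strand's bedGraph into a coverage track
#'
#' bedGraph records are expanded to per-base values; overlapping records sum,
#' which makes replicate pooling by file concatenation well defined.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param strand strand to assign to every record (`"+"` or `"-"`).
#' @return a [coverage_track()].
#' @export
coverage_from_bedgraph <- function(path, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#|browser)", lines)]
  if (length(lines) == 0L) {
    return(coverage_track())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 4L)) {
    stop("malformed bedGraph line ", which(nf < 4L)[1L], " in ", path)
  }
  chrom <- vapply(f, `[[`, character(1), 1L)
  start <- as.integer(vapply(f, `[[`, character(1), 2L))
  end <- as.integer(vapply(f, `[[`, character(1), 3L))
  val <- as.numeric(vapply(f, `[[`, character(1), 4L))
  if (anyNA(start) || anyNA(end) || anyNA(val)) {
    stop("non-numeric coordinates or value in bedGraph ", path)
  }
  if (any(val < 0)) stop("negative value in bedGraph ", path)
  if (any(end <= start)) stop("empty or inverted interval in bedGraph ", path)
  w <- end - start
  coverage_track(chrom = rep(chrom, w), strand = strand,
                 pos = unlist(lapply(seq_along(start), function(i)
                   seq.int(start[i], end[i] - 1L))),
                 value = rep(val, w))
}

#' Write a coverage track's strand to bedGraph
#'
#' @param x a [coverage_track()].
#' @param path output file.
#' @param strand which strand to emit.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, strand = "+") {
  keys <- names(x$counts)
  keys <- keys[endsWith(keys, paste0("|", strand))]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in sort(keys)) {
    chrom <- sub("\\|.$", "", k)
    v <- x$counts[[k]]
    nz <- which(v != 0)
    if (length(nz) == 0L) next
    brk <- c(TRUE, diff(nz) != 1L | diff(v[nz]) != 0)
    run <- cumsum(brk)
    s <- tapply(nz, run, min) - 1L
    e <- tapply(nz, run, max)
    val <- v[tapply(nz, run, min)]
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, s, e, val), con)
  }
  invisible(path)
}
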
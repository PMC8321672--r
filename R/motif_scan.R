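#' Position weight matrix for RNA motif scanning
#'
#' A position-probability matrix over A/C/G/U with a background model. A
#' pseudocount is added to every cell and rows renormalized on construction
#' so no log-odds is `-Inf`.
#'
#' @param probs W x 4 numeric matrix of position probabilities, columns
#'   A, C, G, U (rows need not be exactly normalized on input).
#' @param motif_id label.
#' @param background length-4 background probabilities (default uniform).
#' @param pseudocount added to every cell before renormalization.
#' @return object of class `pwm_model`.
#' @export
pwm_model <- function(probs, motif_id = "motif",
                      background = rep(0.25, 4), pseudocount = 0.001) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, all(probs >= 0), length(background) == 4,
            abs(sum(background) - 1) < 1e-6)
  probs <- probs + pseudocount
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("A", "C", "G", "U")
  structure(list(motif_id = motif_id, probs = probs,
                 background = stats::setNames(background,
                                              c("A", "C", "G", "U"))),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  consensus <- paste(colnames(x$probs)[max.col(x$probs)], collapse = "")
  cat(sprintf("<pwm_model> %s: %d positions, consensus %s\n",
              x$motif_id, nrow(x$probs), consensus))
  invisible(x)
}

#' Read a PWM from HOMER `.motif` or plain TSV format
#'
#' HOMER format: a `>` header line (consensus, name, threshold) followed by
#' one probability row per position (A C G T). TSV dialect: optional header
#' `A C G U`, then one row per position.
#'
#' @param path input file.
#' @param format `"homer"` or `"tsv"`.
#' @param ... passed to [pwm_model()] (e.g. `background`, `pseudocount`).
#' @return a [pwm_model()].
#' @export
read_pwm <- function(path, format = c("homer", "tsv"), ...) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "homer") {
    hdr <- which(startsWith(lines, ">"))
    if (length(hdr) != 1L) stop("expected exactly one '>' header in ", path)
    id <- strsplit(sub("^>", "", lines[hdr]), "[\t ]+")[[1]]
    id <- if (length(id) >= 2) id[2] else id[1]
    rows <- lines[-hdr]
  } else {
    id <- sub("\\.[^.]*$", "", basename(path))
    rows <- lines
    if (grepl("^[ACGUTacgut \t]+$", rows[1])) rows <- rows[-1]  # header
  }
  mat <- do.call(rbind, lapply(rows, function(l)
    as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])))
  if (ncol(mat) != 4 || anyNA(mat)) {
    stop("malformed PWM rows in ", path)
  }
  pwm_model(mat, motif_id = id, ...)
}

#' Log-odds score of one window against a PWM
#'
#' `sum_j log2(probs[j, base_j] / background[base_j])` in bits; ambiguous
#' bases (anything outside ACGU/T) contribute 0 at their position.
#'
#' @param window character scalar of length-W sequence (T read as U).
#' @param pwm a [pwm_model()].
#' @return log-odds score (bits).
#' @export
log_odds <- function(window, pwm) {
  w <- nrow(pwm$probs)
  if (nchar(window) != w) {
    stop("window length ", nchar(window), " != PWM length ", w)
  }
  bases <- strsplit(chartr("acgutT", "ACGUUU", window), "")[[1]]
  idx <- match(bases, c("A", "C", "G", "U"))
  ok <- !is.na(idx)
  if (!any(ok)) {
    return(0)
  }
  j <- which(ok)
  sum(log2(pwm$probs[cbind(j, idx[j])] / pwm$background[idx[j]]))
}

#' Scan sequences for PWM matches above a log-odds threshold
#'
#' Slides the PWM over every window of each sequence (sense strand only —
#' the libraries are strand-specific) and reports offsets whose log-odds
#' reaches `min_bits`. Overlapping matches are all reported.
#'
#' @param sequences named character vector of sequences (ACGU/T).
#' @param pwm a [pwm_model()].
#' @param min_bits score threshold (bits); use `-Inf` to enumerate all
#'   windows.
#' @return data frame (class `motif_hits`) with `id`, `offset` (0-based),
#'   `strand`, `log_odds`, sorted by `(id, offset)`.
#' @export
scan_pwm <- function(sequences, pwm, min_bits) {
  stopifnot(is.finite(min_bits) || min_bits == -Inf)
  w <- nrow(pwm$probs)
  lo_base <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  out <- list()
  for (id in names(sequences)) {
    s <- chartr("acgutT", "ACGUUU", sequences[[id]])
    n <- nchar(s)
    if (n < w) next
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
    # offsets 0..n-w, score(o) = sum_j lo_base[j, base_{o+j}]; NA base -> 0
    scores <- numeric(n - w + 1L)
    for (j in seq_len(w)) {
      b <- idx[seq.int(j, j + n - w)]
      contrib <- numeric(n - w + 1L)
      okb <- !is.na(b)
      contrib[okb] <- lo_base[j, b[okb]]
      scores <- scores + contrib
    }
    hit <- which(scores >= min_bits)
    if (length(hit)) {
      out[[id]] <- data.frame(id = id, offset = hit - 1L, strand = "+",
                              log_odds = scores[hit])
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(id = character(), offset = integer(),
                      strand = character(), log_odds = numeric())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$id, res$offset), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("motif_hits", "data.frame")
  res
}

#' Keep the top fraction of motif hits by log-odds
#'
#' The best `ceiling(n * fraction)` hits; ties with the boundary score are
#' all included, so the result can exceed that count when scores tie.
#'
#' @param hits a [scan_pwm()] result (or any data frame with `log_odds`).
#' @param fraction fraction to keep, in `(0, 1]` (default 0.10).
#' @return subset of `hits`, original order.
#' @export
top_fraction <- function(hits, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(hits)
  if (n == 0L) {
    return(hits)
  }
  k <- nr_rank(fraction, n)
  threshold <- sort(hits$log_odds, decreasing = TRUE)[k]
  hits[hits$log_odds >= threshold, , drop = FALSE]
}

#' Write motif hits as BED6
#'
#' Score column = log-odds x 100, rounded.
#'
#' @param hits a [scan_pwm()] result.
#' @param pwm the [pwm_model()] used (for the match width).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(hits, pwm, path) {
  w <- nrow(pwm$probs)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t+",
                     hits$id, hits$offset, hits$offset + w,
                     pwm$motif_id, round(100 * hits$log_odds)), path)
  invisible(path)
}
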
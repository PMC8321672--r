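#' Mean normalized structure score in an anchored window
#'
#' Arithmetic mean of the transcript-normalized scores over the spliced
#' positions `[anchor - halfwidth, anchor + halfwidth)` that exist (the
#' window is clipped at transcript ends, so a short 5'UTR simply contributes
#' fewer positions). `NA` when no position is defined, so the transcript can
#' be excluded downstream.
#'
#' @param score a [structure_score()] track.
#' @param tx the matching [transcript_model()].
#' @param anchor `"start"` (default, the 200-nt window around the start
#'   codon) or `"stop"`.
#' @param halfwidth half-window (nt), default 100.
#' @return mean score, or `NA_real_`.
#' @export
window_mean <- function(score, tx, anchor = c("start", "stop"),
                        halfwidth = 100L) {
  anchor <- match.arg(anchor)
  a <- tx_anchor(tx, anchor)
  if (is.na(a)) {
    return(NA_real_)
  }
  pos <- seq.int(a - halfwidth, a + halfwidth - 1L)
  pos <- pos[pos >= 0L & pos < tx$spliced_length]
  if (length(pos) == 0L) {
    return(NA_real_)
  }
  mean(score$normalized[pos + 1L])
}

#' Structure-change table across time points
#'
#' Joins per-transcript window means across time points and computes the
#' change `delta = window_mean(tB) - window_mean(tA)` for each consecutive
#' and each against-baseline pair.
#'
#' @param means named list (one element per time point, in order) of named
#'   numeric vectors of per-transcript window means.
#' @return data frame with one row per transcript present at *all* time
#'   points: the window means plus `delta_<tB>_<tA>` columns versus the
#'   first time point.
#' @export
delta_structure <- function(means) {
  stopifnot(length(means) >= 2, !is.null(names(means)))
  ids <- Reduce(intersect, lapply(means, names))
  ids <- ids[!is.na(ids)]
  mat <- vapply(means, function(m) m[ids], numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, names(means)))
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  out <- data.frame(transcript_id = rownames(mat), mat, row.names = NULL,
                    check.names = FALSE)
  base <- names(means)[1L]
  for (tp in names(means)[-1L]) {
    out[[paste0("delta_", tp, "_", base)]] <- mat[, tp] - mat[, base]
  }
  out
}

#' Partition transcripts by percentile of structure change
#'
#' Ranks transcripts by `delta` (ties broken deterministically by name) and
#' returns the nearest-rank percentile groups: `bottom10` (ranks up to the
#' 10th percentile), `top10` (ranks above the 90th), and `control` (ranks in
#' the 45th-55th band, the little-change set).
#'
#' @param deltas named numeric vector (>= 10 transcripts).
#' @return list of character vectors `top10`, `bottom10`, `control`.
#' @export
percentile_partition <- function(deltas) {
  n <- length(deltas)
  if (n < 10L) stop("need at least 10 transcripts, got ", n)
  if (is.null(names(deltas))) names(deltas) <- as.character(seq_len(n))
  ord <- order(deltas, names(deltas))     # ascending; name breaks ties
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  r10 <- nr_rank(0.10, n)
  r45 <- nr_rank(0.45, n)
  r55 <- nr_rank(0.55, n)
  r90 <- nr_rank(0.90, n)
  list(top10 = names(deltas)[rk > r90],
       bottom10 = names(deltas)[rk <= r10],
       control = names(deltas)[rk > r45 & rk <= r55])
}

#' Hierarchical clustering of structure-change trajectories
#'
#' Agglomerative clustering (Euclidean distance, complete linkage — the
#' defaults of R's built-in `hclust`) of the transcripts-by-timepoints
#' window-mean matrix, cut into `k` clusters. Optionally z-scores each row
#' first so only the trajectory shape is clustered.
#'
#' @param mat numeric matrix, rows = transcripts (no missing values),
#'   columns = time points.
#' @param k number of clusters (default 6).
#' @param zscore_rows standardize each row before clustering.
#' @return integer cluster labels `1..k`, named by rownames.
#' @export
hcluster_changes <- function(mat, k = 6L, zscore_rows = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must have no missing values")
  if (k > nrow(mat)) stop("k (", k, ") exceeds number of rows (",
                          nrow(mat), ")")
  if (zscore_rows) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    mat <- (mat - mu) / sdv
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  stats::cutree(hc, k = k)
}
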
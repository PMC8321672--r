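#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation: probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counted 1/2.
#'
#' @param score numeric vector of scores (higher = more positive-like).
#' @param label logical or 0/1 vector; `TRUE`/1 marks positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc() needs at least one positive and one negative")
  }
  r <- rank(score)                      # midranks handle ties
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# nearest-rank index: ceiling(p * n), guarded against floating-point fuzz
# (0.45 * 100 is 45 + 7e-15 in binary, which must still rank as 45)
nr_rank <- function(p, n) {
  as.integer(max(1L, min(n, ceiling(p * n - 1e-9))))
}

# nearest-rank percentile threshold: value at rank ceiling(p * n) of sorted x
nearest_rank <- function(x, p) {
  sort(x)[nr_rank(p, length(x))]
}

#' Transcripts per million
#'
#' Length-normalized relative abundance: `rate_i = count_i / length_i`,
#' `TPM_i = 1e6 * rate_i / sum(rate)`. All-zero counts yield all-zero TPM.
#'
#' @param counts non-negative integer vector of per-transcript read counts.
#' @param lengths positive transcript lengths (nt), same length as `counts`.
#' @return numeric vector summing to 1e6 (or all zero).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    return(rep(0, length(counts)))
  }
  1e6 * rate / tot
}
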
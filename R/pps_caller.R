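#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, evaluated through the survival
#' function so that very small tail probabilities are computed without
#' catastrophic cancellation.
#'
#' @param k observed count(s), non-negative integer.
#' @param lam expected rate(s), > 0.
#' @return upper-tail probability, vectorized over `k`/`lam`.
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Order-preserving wrapper around the BH adjustment:
#' `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call protein-protected sites by Poisson enrichment
#'
#' Per base `b`, the footprint count is tested against the rate
#' `lam_b = r * (max(so_b, local_mean_b) + pseudo)` expected from the
#' structure-only library, where `r` is the footprint/structure-only
#' library-size ratio, `local_mean_b` is the mean structure-only coverage in
#' a `local_window`-nt window around `b`, and `pseudo` regularizes
#' uncovered control bases. Taking the larger of the point and local rates
#' guards against single-base control dropouts (a control base at 0 by
#' sampling chance would otherwise fabricate astronomically small
#' p-values), while leaving true protected sites untouched — the control
#' library is protein-stripped, so footprint enrichment never deflates the
#' local control mean. Candidate regions are maximal runs
#' of bases with `p <= enter_p`, allowing internal gaps up to `max_gap` nt.
#' A candidate is reported as a PPS when it passes two
#' Benjamini-Hochberg-controlled filters at the requested `fdr`:
#' \enumerate{
#'   \item its best member base survives BH adjustment of the per-base
#'     p-values across *all* scored bases genome-wide, and
#'   \item its aggregate count test — the exact conditional comparison of
#'     the region's footprint and structure-only totals (binomial given
#'     their sum, the classic two-sample Poisson test) — survives a
#'     Bonferroni bound over all scored bases.
#' }
#' The per-base filter anchors the region in at least one genome-wide
#' significant base (adjusting only within pre-selected candidates would
#' pass essentially any candidate under the null); the aggregate filter is
#' calibrated regardless of local coverage and removes regions carried by
#' chance opposite fluctuations of the two libraries. The reported
#' `q_value` is the larger of the two adjusted values, i.e. the threshold
#' at which the region would first be called.
#'
#' An optional label-swap mode estimates the FDR empirically instead:
#' regions are formed identically, and each region's p-value is compared
#' with the candidate-region p-values obtained after exchanging the two
#' libraries' roles (q = swapped-count / real-count at that threshold).
#'
#' @param fp footprint [coverage_track()].
#' @param so structure-only [coverage_track()] from the same RNase arm.
#' @param fdr false discovery rate (default 0.05).
#' @param pseudo pseudo-count added to the control rate (nt^-1).
#' @param enter_p per-base p-value required to enter a candidate region.
#' @param max_gap largest internal gap (nt) bridged within a region.
#' @param min_len minimum reported region length (nt).
#' @param local_window width (nt) of the centered window for the local
#'   control rate; 0 disables the local component.
#' @param rnase,sample labels stored on the calls.
#' @param fdr_method `"bh"` (default) or `"permutation"` (label swap).
#' @return a [GenomicRanges::GRanges] of PPSs with metadata columns `name`,
#'   `score` (-log10 q), `enrichment` (max per-base -log10 p), `p_value`,
#'   `q_value`, `rnase`, `sample`.
#' @export
call_pps <- function(fp, so, fdr = 0.05, pseudo = 0.5, enter_p = 0.01,
                     max_gap = 10L, min_len = 5L, local_window = 25L,
                     rnase = "ss", sample = "sample",
                     fdr_method = c("bh", "permutation")) {
  fdr_method <- match.arg(fdr_method)
  if (total_reads(so) == 0) {
    if (total_reads(fp) == 0) {
      return(empty_pps())
    }
    stop("no control library: structure-only track has zero reads")
  }
  r <- total_reads(fp) / total_reads(so)
  scored <- score_bases(fp, so, r, pseudo, local_window)
  if (nrow(scored) == 0L) {
    return(empty_pps())
  }
  scored$q <- bh_fdr(scored$p)
  regions <- segment_regions(scored, enter_p, max_gap)
  if (nrow(regions) == 0L) {
    return(empty_pps())
  }
  regions <- aggregate_region_test(regions, fp, so, r, pseudo)
  if (fdr_method == "permutation") {
    swapped <- score_bases(so, fp, 1 / r, pseudo, local_window)
    null_regions <- segment_regions(swapped, enter_p, max_gap)
    if (nrow(null_regions) > 0L) {
      null_regions <- aggregate_region_test(null_regions, so, fp, 1 / r,
                                            pseudo)
    }
    # empirical FDR: expected false regions at threshold / observed regions
    regions$q <- vapply(regions$agg_p, function(p0) {
      min(1, sum(null_regions$agg_p <= p0) /
            max(1, sum(regions$agg_p <= p0)))
    }, numeric(1))
  } else {
    # candidate regions are selected for small per-base p, so their
    # aggregate p-values are not uniform under the null and BH across
    # candidates would be anti-conservative; a Bonferroni bound over all
    # scored bases is immune to the selection and true protected sites
    # clear it by many orders of magnitude
    regions$q <- pmax(regions$q, pmin(1, regions$agg_p * nrow(scored)))
  }
  keep <- regions$q <= fdr & (regions$end - regions$start) >= min_len
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0L) {
    return(empty_pps())
  }
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = regions$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("pps_%s_%s_%04d", sample, rnase, seq_len(nrow(regions))),
    score = -log10(pmax(regions$q, 1e-300)),
    enrichment = -log10(pmax(regions$p, 1e-300)),
    p_value = regions$p, q_value = regions$q,
    rnase = rnase, sample = sample)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

empty_pps <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(), score = numeric(), enrichment = numeric(),
    p_value = numeric(), q_value = numeric(), rnase = character(),
    sample = character())
  gr
}

# centered running mean (window w) via cumulative sums, edges truncated
running_mean <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# per-base Poisson p-values over all bases covered in either track; the
# control rate is max(point count, local mean) to resist control dropouts
score_bases <- function(fp, so, r, pseudo, local_window = 25L) {
  keys <- cov_keys(fp, so)
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    vf <- fp$counts[[k]]
    vs <- so$counts[[k]]
    n <- max(length(vf), length(vs))
    if (is.null(vf)) vf <- numeric(0)
    if (is.null(vs)) vs <- numeric(0)
    vf <- c(vf, numeric(n - length(vf)))
    vs <- c(vs, numeric(n - length(vs)))
    idx <- which(vf > 0 | vs > 0)
    if (length(idx) == 0L) next
    ctrl <- vs
    if (local_window > 1L) {
      ctrl <- pmax(vs, running_mean(vs, as.integer(local_window)))
    }
    p <- poisson_upper_tail(vf[idx], r * (ctrl[idx] + pseudo))
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    out[[i]] <- data.frame(chrom = parts[1L], strand = parts[2L],
                           pos = idx - 1L, p = p)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), p = numeric()))
  }
  do.call(rbind, out)
}

# maximal runs of seed bases (p <= enter_p) bridging gaps <= max_gap
segment_regions <- function(scored, enter_p, max_gap) {
  seeds <- scored[scored$p <= enter_p, , drop = FALSE]
  if (nrow(seeds) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), p = numeric(),
                      q = numeric()))
  }
  seeds <- seeds[order(seeds$chrom, seeds$strand, seeds$pos), , drop = FALSE]
  new_run <- c(TRUE, diff(seeds$pos) > max_gap + 1L |
                 seeds$chrom[-1L] != seeds$chrom[-nrow(seeds)] |
                 seeds$strand[-1L] != seeds$strand[-nrow(seeds)])
  run <- cumsum(new_run)
  data.frame(
    chrom = tapply(seeds$chrom, run, `[`, 1L),
    strand = tapply(seeds$strand, run, `[`, 1L),
    start = as.integer(tapply(seeds$pos, run, min)),
    end = as.integer(tapply(seeds$pos, run, max)) + 1L,
    p = as.numeric(tapply(seeds$p, run, min)),
    q = if (!is.null(seeds$q)) as.numeric(tapply(seeds$q, run, min))
        else NA_real_,
    row.names = NULL)
}

# region-aggregate test: exact conditional comparison of the two Poisson
# totals — given n = fp_sum + so_sum, fp_sum ~ Binomial(n, r/(1+r)) under
# the null of equal per-base rates (the classic two-sample Poisson test).
# Unlike the per-base plug-in rate, this is calibrated regardless of the
# local coverage level.
aggregate_region_test <- function(regions, fp, so, r, pseudo) {
  p0 <- r / (1 + r)
  regions$agg_p <- vapply(seq_len(nrow(regions)), function(i) {
    pos <- seq.int(regions$start[i], regions$end[i] - 1L)
    fp_sum <- sum(cov_values(fp, regions$chrom[i], regions$strand[i], pos))
    so_sum <- sum(cov_values(so, regions$chrom[i], regions$strand[i], pos))
    n <- fp_sum + so_sum
    if (n == 0) {
      return(1)
    }
    stats::pbinom(fp_sum - 1, n, p0, lower.tail = FALSE)
  }, numeric(1))
  regions
}

#' Remove PPSs in the ribosome footprint size range
#'
#' Footprinting cannot distinguish ribosomes from other RNA-binding
#' proteins, so sites between 20 and 40 nt (inclusive), the typical ribosome
#' footprint size, are excluded.
#'
#' @param ppss `GRanges` of PPSs.
#' @param min_nt,max_nt inclusive length bounds of the excluded range.
#' @return the surviving PPSs, in input order.
#' @export
ribosome_filter <- function(ppss, min_nt = 20L, max_nt = 40L) {
  w <- GenomicRanges::width(ppss)
  ppss[!(w >= min_nt & w <= max_nt)]
}

#' High-confidence PPSs reproduced across replicates
#'
#' Keeps the PPSs of `repA` that overlap, by at least one nucleotide on the
#' same strand, a PPS called in the other biological replicate; the first
#' overlapping partner's name is recorded.
#'
#' @param repA,repB `GRanges` of PPSs from the two replicates.
#' @return subset of `repA` with a `partner` metadata column.
#' @export
high_confidence <- function(repA, repB) {
  hits <- GenomicRanges::findOverlaps(repA, repB, minoverlap = 1L)
  keep <- unique(S4Vectors::queryHits(hits))
  out <- repA[keep]
  partner <- S4Vectors::mcols(repB)$name[
    S4Vectors::subjectHits(hits)[match(keep, S4Vectors::queryHits(hits))]]
  if (is.null(partner)) partner <- rep(NA_character_, length(out))
  S4Vectors::mcols(out)$partner <- partner
  out
}

#' Full PPS-calling pipeline over time points and replicates
#'
#' For each time point: calls PPSs per RNase arm and replicate with
#' [call_pps()], keeps the [high_confidence()] calls reproduced in both
#' replicates of each arm (when two or more replicates are present), unions
#' the two arms with [merge_arms()], and optionally applies the
#' [ribosome_filter()].
#'
#' @param libs nested list `libs[[timepoint]][[replicate]]` of
#'   [coverage_track()]s named `fp_ss`, `fp_ds`, `so_ss`, `so_ds`, as
#'   produced by [simulate_libraries()].
#' @param fdr false discovery rate passed to [call_pps()].
#' @param drop_ribosome apply the 20-40 nt ribosome filter (default `TRUE`).
#' @param ... further arguments to [call_pps()].
#' @return named list (per time point) of merged PPS `GRanges`.
#' @export
pps_pipeline <- function(libs, fdr = 0.05, drop_ribosome = TRUE, ...) {
  out <- vector("list", length(libs))
  names(out) <- names(libs)
  for (tp in names(libs)) {
    reps <- libs[[tp]]
    arm_calls <- lapply(c(ss = "ss", ds = "ds"), function(arm) {
      calls <- lapply(names(reps), function(r)
        call_pps(reps[[r]][[paste0("fp_", arm)]],
                 reps[[r]][[paste0("so_", arm)]],
                 fdr = fdr, rnase = arm,
                 sample = paste0(tp, "_", r), ...))
      if (length(calls) >= 2L) {
        high_confidence(calls[[1L]], calls[[2L]])
      } else {
        calls[[1L]]
      }
    })
    merged <- merge_arms(arm_calls$ss, arm_calls$ds)
    out[[tp]] <- if (drop_ribosome) ribosome_filter(merged) else merged
  }
  out
}

#' Merge ssRNase- and dsRNase-arm PPS calls
#'
#' Unions the two arms' calls: overlapping same-strand intervals are merged
#' and labelled `rnase = "merged"`; arm-specific calls keep their label. The
#' reported q-value of a merged interval is the best (smallest) among its
#' members.
#'
#' @param pps_ss,pps_ds `GRanges` of PPSs from the two arms.
#' @return merged `GRanges` with `rnase`, `q_value` and `score` columns.
#' @export
merge_arms <- function(pps_ss, pps_ds) {
  all <- c(GenomicRanges::granges(pps_ss), GenomicRanges::granges(pps_ds))
  if (length(all) == 0L) {
    return(empty_pps())
  }
  merged <- GenomicRanges::reduce(all, min.gapwidth = 0L)
  from_ss <- GenomicRanges::countOverlaps(merged, pps_ss) > 0
  from_ds <- GenomicRanges::countOverlaps(merged, pps_ds) > 0
  q <- rep(NA_real_, length(merged))
  for (src in list(pps_ss, pps_ds)) {
    if (length(src) == 0L) next
    h <- GenomicRanges::findOverlaps(merged, src)
    qs <- tapply(S4Vectors::mcols(src)$q_value[S4Vectors::subjectHits(h)],
                 S4Vectors::queryHits(h), min)
    i <- as.integer(names(qs))
    q[i] <- pmin(q[i], as.numeric(qs), na.rm = TRUE)
  }
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    name = sprintf("pps_merged_%04d", seq_along(merged)),
    score = -log10(pmax(q, 1e-300)),
    q_value = q,
    rnase = ifelse(from_ss & from_ds, "merged", ifelse(from_ss, "ss", "ds")))
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}
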
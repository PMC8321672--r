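#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a set of spliced
#' mRNAs with 5'UTR/CDS/3'UTR architecture, a hidden per-base pairing state,
#' planted RBP-bound sites, and the four-library design (footprint and
#' structure-only, each digested with ssRNase or dsRNase) sampled per time
#' point and replicate.
#'
#' @param n_transcripts number of transcripts (each on its own contig).
#' @param utr5_mean,cds_mean,utr3_mean mean region lengths (nt).
#' @param paired_fraction probability a base is paired before smoothing.
#' @param site_rate planted RBP sites per kb of spliced transcript.
#' @param site_length planted site length (nt).
#' @param protection_factor multiplicative footprint enrichment at bound
#'   bases (>= 1; 1 = null, no protection).
#' @param depth mean reads per base per library.
#' @param digestion_bias probability a paired base yields a dsRNase rather
#'   than an ssRNase read (and symmetrically for unpaired bases).
#' @param n_timepoints,n_replicates libraries simulated per arm.
#' @param structure_drift per-timepoint probability a base flips pairing
#'   state.
#' @param site_turnover fraction of sites resampled at each later time
#'   point (resampled sites are the "developmental" sites).
#' @param overdispersion `NULL` for Poisson counts, or a negative-binomial
#'   size parameter to stress-test overdispersion robustness.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 60L, utr5_mean = 150, cds_mean = 1200,
                       utr3_mean = 500, paired_fraction = 0.5, site_rate = 1,
                       site_length = 60L, protection_factor = 5, depth = 30,
                       digestion_bias = 0.85, n_timepoints = 3L,
                       n_replicates = 2L, structure_drift = 0.05,
                       site_turnover = 0.3, overdispersion = NULL,
                       seed = 1L) {
  cfg <- list(n_transcripts = n_transcripts, utr5_mean = utr5_mean,
              cds_mean = cds_mean, utr3_mean = utr3_mean,
              paired_fraction = paired_fraction, site_rate = site_rate,
              site_length = site_length,
              protection_factor = protection_factor, depth = depth,
              digestion_bias = digestion_bias, n_timepoints = n_timepoints,
              n_replicates = n_replicates,
              structure_drift = structure_drift,
              site_turnover = site_turnover,
              overdispersion = overdispersion, seed = as.integer(seed))
  probs <- c(cfg$paired_fraction, cfg$digestion_bias, cfg$structure_drift,
             cfg$site_turnover)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$protection_factor >= 1,
            cfg$depth > 0, cfg$site_length >= 1)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d transcripts, %d timepoint(s) x %d replicate(s), depth %gx, protection %gx, seed %d\n",
    x$n_transcripts, x$n_timepoints, x$n_replicates, x$depth,
    x$protection_factor, x$seed))
  invisible(x)
}

# majority filter on a 0/1 vector, window size k (ties keep the original)
majority_smooth <- function(x, k = 10L) {
  n <- length(x)
  if (n == 0L) {
    return(x)
  }
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- cumsum(c(0L, x))
  lo <- pmax(0L, seq_len(n) - 1L - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  cnt <- cs[hi + 1L] - cs[lo + 1L]
  w <- hi - lo
  out <- x
  out[cnt * 2L > w] <- 1L
  out[cnt * 2L < w] <- 0L
  out
}

# place n_sites non-overlapping site_length-nt sites inside single exons;
# sites are data.frames of 0-based half-open genomic coordinates. `avoid`
# adds further forbidden intervals (e.g. sites from earlier time points)
place_sites <- function(tx, n_sites, site_length, existing = NULL,
                        avoid = NULL, max_attempts = 10000L) {
  placed <- if (is.null(existing)) {
    data.frame(start = integer(), end = integer())
  } else {
    existing
  }
  if (n_sites == 0L) {
    return(placed)
  }
  forbid <- rbind(placed, avoid)
  ex_ok <- which((tx$exon_ends - tx$exon_starts) >= site_length)
  if (length(ex_ok) == 0L) {
    stop("no exon of ", tx$transcript_id, " can hold a ", site_length,
         "-nt site")
  }
  slots <- tx$exon_ends[ex_ok] - tx$exon_starts[ex_ok] - site_length + 1L
  for (s in seq_len(n_sites)) {
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      e <- ex_ok[sample.int(length(ex_ok), 1L, prob = slots)]
      start <- tx$exon_starts[e] +
        sample.int(tx$exon_ends[e] - tx$exon_starts[e] - site_length + 1L,
                   1L) - 1L
      end <- start + site_length
      if (all(end <= forbid$start | start >= forbid$end)) {
        placed <- rbind(placed, data.frame(start = start, end = end))
        forbid <- rbind(forbid, data.frame(start = start, end = end))
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("site_rate too high: cannot place ", n_sites, " sites on ",
           tx$transcript_id, " without overlap")
    }
  }
  placed
}

#' Simulate ground truth: transcripts, pairing states, planted sites
#'
#' Transcript region lengths are Poisson-distributed around the configured
#' means (with small floors); each transcript gets 1-4 exons on its own
#' contig. Pairing states are i.i.d. Bernoulli(`paired_fraction`) smoothed
#' by a 10-nt majority filter into realistic helix-like runs; later time
#' points flip bases with probability `structure_drift` and re-smooth.
#' Sites are placed uniformly without overlap within single exons at
#' `site_rate` per spliced kb; at later time points a `site_turnover`
#' fraction is replaced by newly placed ("developmental") sites.
#'
#' @param cfg a [sim_config()].
#' @return object of class `ground_truth`: list with `cfg`, `transcripts`
#'   (named list of [transcript_model()]), `pairing` (per timepoint, per
#'   transcript 0/1 vector over spliced positions) and `sites` (per
#'   timepoint `GRanges` with a `born` column naming the time point each
#'   site first appeared in).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  txs <- vector("list", cfg$n_transcripts)
  for (i in seq_len(cfg$n_transcripts)) {
    utr5 <- max(30L, stats::rpois(1, cfg$utr5_mean))
    cds <- max(150L, stats::rpois(1, cfg$cds_mean))
    utr3 <- max(60L, stats::rpois(1, cfg$utr3_mean))
    total <- utr5 + cds + utr3
    n_ex <- sample.int(4L, 1L)
    cuts <- sort(sample.int(total - 1L, n_ex - 1L))
    sizes <- diff(c(0L, cuts, total))
    introns <- stats::rpois(n_ex - 1L, 200) + 50L
    starts <- cumsum(c(100L, utils::head(sizes, -1L) + introns))
    tx <- transcript_model(sprintf("tx%04d", i), sprintf("ctg%04d", i),
                           sample(c("+", "-"), 1L), starts, starts + sizes,
                           cds_start_tx = utr5, cds_end_tx = utr5 + cds)
    txs[[i]] <- tx
  }
  names(txs) <- vapply(txs, `[[`, character(1), "transcript_id")

  pairing <- vector("list", cfg$n_timepoints)
  sites <- vector("list", cfg$n_timepoints)
  tp_names <- paste0("t", seq_len(cfg$n_timepoints) - 1L)
  # time point 1
  pairing[[1]] <- lapply(txs, function(tx) majority_smooth(
    stats::rbinom(tx$spliced_length, 1L, cfg$paired_fraction)))
  site_list <- lapply(txs, function(tx) {
    n_sites <- stats::rpois(1, cfg$site_rate * tx$spliced_length / 1000)
    place_sites(tx, n_sites, cfg$site_length)
  })
  born <- lapply(site_list, function(d) rep(tp_names[1L], nrow(d)))
  ever <- site_list                       # every location ever protected
  sites[[1]] <- collect_sites(site_list, born, txs, tp_names[1L])

  if (cfg$n_timepoints > 1L) {
    for (t in 2L:cfg$n_timepoints) {
      pairing[[t]] <- lapply(pairing[[t - 1L]], function(p) {
        flip <- stats::rbinom(length(p), 1L, cfg$structure_drift) == 1L
        majority_smooth(as.integer(xor(p == 1L, flip)))
      })
      for (i in seq_along(txs)) {
        tx <- txs[[i]]
        prev <- site_list[[i]]
        keep <- stats::runif(nrow(prev)) >= cfg$site_turnover
        kept <- prev[keep, , drop = FALSE]
        # new sites avoid every location ever protected, so a site born at
        # this time point is genuinely developmental
        placed <- place_sites(tx, sum(!keep), cfg$site_length,
                              existing = kept, avoid = ever[[i]])
        site_list[[i]] <- placed
        new_rows <- placed[seq_len(nrow(placed)) > nrow(kept), ,
                           drop = FALSE]
        ever[[i]] <- rbind(ever[[i]], new_rows)
        born[[i]] <- c(born[[i]][keep],
                       rep(tp_names[t], nrow(placed) - sum(keep)))
      }
      sites[[t]] <- collect_sites(site_list, born, txs, tp_names[t])
    }
  }
  names(pairing) <- names(sites) <- tp_names
  structure(list(cfg = cfg, transcripts = txs, pairing = pairing,
                 sites = sites),
            class = "ground_truth")
}

collect_sites <- function(site_list, born_list, txs, tp) {
  n <- vapply(site_list, nrow, integer(1))
  chrom <- rep(vapply(txs, `[[`, character(1), "chrom"), n)
  strand <- rep(vapply(txs, `[[`, character(1), "strand"), n)
  starts <- unlist(lapply(site_list, `[[`, "start"), use.names = FALSE)
  ends <- unlist(lapply(site_list, `[[`, "end"), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts + 1, end = ends),
    strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("site_%s_%04d", tp, seq_along(gr)),
    born = unlist(born_list, use.names = FALSE))
  gr
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d transcripts, %d timepoint(s), %s planted sites\n",
    length(x$transcripts), length(x$pairing),
    paste(vapply(x$sites, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Simulate the four coverage libraries per time point and replicate
#'
#' Structure-only expected rate at a base: `depth * digestion_bias` for the
#' matching digest (dsRNase at paired bases, ssRNase at unpaired bases) and
#' `depth * (1 - digestion_bias)` for the mismatched digest. Footprint rates
#' equal the structure-only rates multiplied by `protection_factor` inside
#' planted sites, unchanged outside. Counts are Poisson (or negative
#' binomial when `overdispersion` is set); replicates are independent draws
#' from the same rates.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()] (defaults to `truth$cfg`).
#' @return nested list `libs[[timepoint]][[replicate]]` of four
#'   [coverage_track()]s: `fp_ss`, `fp_ds`, `so_ss`, `so_ds`.
#' @export
simulate_libraries <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(cfg$seed + 1L)
  draw <- function(lam) {
    if (is.null(cfg$overdispersion)) {
      stats::rpois(length(lam), lam)
    } else {
      stats::rnbinom(length(lam), size = cfg$overdispersion, mu = lam)
    }
  }
  tp_names <- names(truth$pairing)
  libs <- vector("list", length(tp_names))
  names(libs) <- tp_names
  for (tp in tp_names) {
    reps <- vector("list", cfg$n_replicates)
    names(reps) <- paste0("rep", seq_len(cfg$n_replicates))
    # per-base rates are fixed for the time point; replicates redraw counts
    lam <- list(so_ss = numeric(0), so_ds = numeric(0),
                fp_ss = numeric(0), fp_ds = numeric(0))
    chrom <- character(0)
    strand <- character(0)
    gpos <- integer(0)
    for (tx in truth$transcripts) {
      p <- truth$pairing[[tp]][[tx$transcript_id]]
      g <- transcript_to_genomic(tx, seq.int(0L, tx$spliced_length - 1L))
      lam_ds <- cfg$depth * ifelse(p == 1L, cfg$digestion_bias,
                                   1 - cfg$digestion_bias)
      lam_ss <- cfg$depth * ifelse(p == 1L, 1 - cfg$digestion_bias,
                                   cfg$digestion_bias)
      site_gr <- truth$sites[[tp]]
      sel <- as.character(GenomicRanges::seqnames(site_gr)) == tx$chrom
      in_site <- rep(FALSE, length(g))
      if (any(sel)) {
        s0 <- GenomicRanges::start(site_gr)[sel] - 1L
        e0 <- GenomicRanges::end(site_gr)[sel]
        for (k in seq_along(s0)) {
          in_site[g >= s0[k] & g < e0[k]] <- TRUE
        }
      }
      prot <- ifelse(in_site, cfg$protection_factor, 1)
      lam$so_ss <- c(lam$so_ss, lam_ss)
      lam$so_ds <- c(lam$so_ds, lam_ds)
      lam$fp_ss <- c(lam$fp_ss, lam_ss * prot)
      lam$fp_ds <- c(lam$fp_ds, lam_ds * prot)
      chrom <- c(chrom, rep(tx$chrom, length(g)))
      strand <- c(strand, rep(tx$strand, length(g)))
      gpos <- c(gpos, g)
    }
    for (r in seq_len(cfg$n_replicates)) {
      reps[[r]] <- lapply(lam, function(l)
        coverage_track(chrom = chrom, strand = strand, pos = gpos,
                       value = draw(l)))
    }
    libs[[tp]] <- reps
  }
  libs
}

#' Write simulated fixtures to plain-text files
#'
#' Emits `transcripts.bed12`, one `truth_sites_<tp>.bed` per time point,
#' `truth_pairing.tsv` (transcript, spliced position, 0/1 pairing per time
#' point), one bedGraph per library/replicate/time point
#' (`<tp>_<rep>_<lib>.bedgraph`, both strands; strand is recoverable from
#' the transcript models since each contig carries one transcript), and a
#' `manifest.json` recording the configuration. Re-running with the same
#' configuration reproduces byte-identical files.
#'
#' @param truth a [simulate_truth()] result.
#' @param libs a [simulate_libraries()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fixtures <- function(truth, libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "transcripts.bed12")
  write_bed(truth$transcripts, p)
  paths <- c(paths, p)
  for (tp in names(truth$sites)) {
    p <- file.path(dir, sprintf("truth_sites_%s.bed", tp))
    write_bed(truth$sites[[tp]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth_pairing.tsv")
  rows <- c(paste(c("transcript_id", "pos", names(truth$pairing)),
                  collapse = "\t"))
  for (id in names(truth$transcripts)) {
    n <- truth$transcripts[[id]]$spliced_length
    mat <- vapply(truth$pairing, function(tp) tp[[id]], integer(n))
    rows <- c(rows, paste(id, seq_len(n) - 1L,
                          apply(matrix(mat, nrow = n), 1L, paste,
                                collapse = "\t"),
                          sep = "\t"))
  }
  writeLines(rows, p)
  paths <- c(paths, p)
  for (tp in names(libs)) {
    for (r in names(libs[[tp]])) {
      for (lib in names(libs[[tp]][[r]])) {
        p <- file.path(dir, sprintf("%s_%s_%s.bedgraph", tp, r, lib))
        write_bedgraph_all(libs[[tp]][[r]][[lib]], p)
        paths <- c(paths, p)
      }
    }
  }
  p <- file.path(dir, "manifest.json")
  cfg <- truth$cfg
  cfg$overdispersion <- if (is.null(cfg$overdispersion)) NA else
    cfg$overdispersion
  jsonlite::write_json(
    list(config = unclass(cfg), files = basename(paths),
         n_bedgraphs = sum(grepl("bedgraph$", paths))),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

# all contig-strands of a track into one bedGraph (deterministic order)
write_bedgraph_all <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in sort(names(x$counts))) {
    chrom <- sub("\\|.$", "", k)
    v <- x$counts[[k]]
    nz <- which(v != 0)
    if (length(nz) == 0L) next
    brk <- c(TRUE, diff(nz) != 1L | diff(v[nz]) != 0)
    run <- cumsum(brk)
    s <- as.integer(tapply(nz, run, min)) - 1L
    e <- as.integer(tapply(nz, run, max))
    val <- v[as.integer(tapply(nz, run, min))]
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, s, e, val), con)
  }
  invisible(path)
}
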
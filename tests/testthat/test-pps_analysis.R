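test_that("greedy annotation counts every overlapped class once", {
  space <- list(mirna = gi("chr1", 100L, 130L),
                cds = gi("chr1", 120L, 300L),
                intron = gi("chr1", 400L, 600L))
  res <- annotate_greedy(gi("chr1", 110L, 140L), space)
  expect_setequal(res$labels[[1]], c("mirna", "cds"))
  expect_equal(unname(res$tally[c("mirna", "cds")]), c(1, 1))

  res <- annotate_greedy(gi("chr1", 450L, 460L), space)
  expect_equal(res$labels[[1]], "intron")

  res <- annotate_greedy(gi("chr1", 900L, 950L), space)
  expect_length(res$labels[[1]], 0L)
  expect_equal(unname(res$tally["intergenic"]), 1)
})

test_that("background shuffle preserves chrom/length/strand and avoids exclusions", {
  set.seed(5)
  ppss <- gi(rep(c("chr1", "chr2"), each = 10),
             seq(0, 1900, by = 100), seq(0, 1900, by = 100) + 50,
             strand = rep(c("+", "-"), 10))
  space <- gi(c("chr1", "chr2"), c(0L, 0L), c(10000L, 10000L))
  bg <- shuffle_background(ppss, space, excluded = ppss, seed = 99)
  key <- function(g) sort(paste(GenomicRanges::seqnames(g),
                                GenomicRanges::width(g),
                                GenomicRanges::strand(g)))
  expect_equal(key(bg), key(ppss))
  ov <- GenomicRanges::findOverlaps(bg, ppss, ignore.strand = TRUE)
  expect_length(ov, 0L)
  self <- GenomicRanges::findOverlaps(bg, ignore.strand = TRUE,
                                      drop.self = TRUE)
  expect_length(self, 0L)
  expect_identical(
    GenomicRanges::start(shuffle_background(ppss, space, seed = 99)),
    GenomicRanges::start(bg))
  # impossible placements are reported, not silently skipped
  expect_error(
    shuffle_background(gi("chr1", 0L, 50L), gi("chr1", 0L, 40L), seed = 1),
    "fit")
})

test_that("overlap enrichment computes fractions and an uncorrected chi-square", {
  sites <- gi("chr1", seq(0L, 990L, by = 10L), seq(0L, 990L, by = 10L) + 2L)
  ppss <- gi("chr1", 0L, 900L)        # covers the first 90 sites
  bg <- gi("chr1", 900L, 1000L)       # covers the last 10
  res <- overlap_enrichment(sites, ppss, bg)
  expect_equal(res$pct_real, 90)
  expect_equal(res$pct_bg, 10)
  expect_equal(res$chi2, 128, tolerance = 1e-9)
  expect_lt(res$chi2_p, 1e-28)

  res <- overlap_enrichment(sites, ppss, ppss)
  expect_equal(res$chi2_p, 1)
  expect_error(overlap_enrichment(ppss[0], ppss, bg), "empty")
})

test_that("class enrichment is the log2 ratio of base-coverage fractions", {
  expect_equal(
    unname(class_log2_enrichment(c(a = 10, b = 30), c(a = 100, b = 300))),
    c(0, 0))
  expect_equal(
    unname(class_log2_enrichment(c(a = 50, b = 50),
                                 c(a = 25, b = 75))["a"]),
    1)
  expect_equal(
    unname(class_log2_enrichment(c(a = 10, b = 90),
                                 c(a = 40, b = 60))["a"]),
    -2)
  expect_warning(
    class_log2_enrichment(c(a = 10, b = 10), c(a = 20, b = 0)),
    "zero genomic")
})

test_that("conservation compares PPS means with averaged flank means", {
  ppss <- gi("chr1", 100L, 110L)
  const <- coverage_track("chr1", "+", 0:299, rep(0.7, 300))
  res <- conservation_flank_compare(ppss, const)
  expect_equal(res$mean_pps, res$mean_flank)
  expect_equal(res$ks_d, 0)

  # 0.5 inside, 0.2 upstream flank, 0.3 downstream flank
  v <- rep(0, 300)
  v[(90:99) + 1] <- 0.2
  v[(100:109) + 1] <- 0.5
  v[(110:119) + 1] <- 0.3
  tr <- coverage_track("chr1", "+", 0:299, v)
  res <- conservation_flank_compare(ppss, tr)
  expect_equal(res$mean_pps, 0.5)
  expect_equal(res$mean_flank, 0.25)

  # indicator track separates the distributions completely
  many <- gi("chr1", seq(100L, 2000L, by = 100L),
             seq(100L, 2000L, by = 100L) + 10L)
  ind <- local({
    vv <- rep(0, 2500)
    for (i in seq_along(many)) {
      vv[GenomicRanges::start(many[i]):GenomicRanges::end(many[i])] <- 1
    }
    coverage_track("chr1", "+", 0:2499, vv)
  })
  res <- conservation_flank_compare(many, ind)
  expect_equal(res$mean_pps, 1)
  expect_equal(res$mean_flank, 0)
  expect_equal(res$ks_d, 1)
})

test_that("density profile is max-normalized to exactly 1", {
  # two single-exon transcripts, anchor at spliced 100; tx1 covered at
  # offsets [-10,10), both covered at [0,10) -> densities 0.5 and 1.0
  tx1 <- transcript_model("t1", "c1", "+", 0L, 400L, 100L, 300L)
  tx2 <- transcript_model("t2", "c2", "+", 0L, 400L, 100L, 300L)
  txs <- list(t1 = tx1, t2 = tx2)
  ppss <- suppressWarnings(c(gi("c1", 90L, 110L), gi("c2", 100L, 110L)))
  prof <- density_profile(ppss, txs, anchor = "start", flank = 20)
  expect_equal(max(prof$mean), 1)
  expect_equal(prof$mean[prof$offset %in% -10:-1], rep(0.5, 10))
  expect_equal(prof$mean[prof$offset %in% 0:9], rep(1, 10))

  full <- gi("c1", 0L, 400L)
  prof <- density_profile(full, txs["t1"], anchor = "start", flank = 20)
  expect_equal(prof$mean, rep(1, 40))

  expect_warning(
    prof <- density_profile(ppss[0], txs, anchor = "start", flank = 5),
    "unnormalized")
  expect_equal(prof$mean, rep(0, 10))
})

test_that("transcript coverage is the spliced union percent, with deciles", {
  tx <- transcript_model("t1", "c1", "+", 0L, 100L)
  txs <- list(t1 = tx)
  # spliced [0,50) and [25,75): union 75 of 100 spliced nt
  ppss <- c(gi("c1", 0L, 50L), gi("c1", 25L, 75L))
  expect_equal(transcript_pps_coverage(ppss, txs)$percent, 75)
  expect_equal(transcript_pps_coverage(ppss[0], txs)$percent, 0)
  spliced_tx <- transcript_model("t1", "c1", "+", c(0L, 200L),
                                 c(100L, 300L))
  intronic <- gi("c1", 120L, 180L)
  expect_equal(transcript_pps_coverage(intronic,
                                       list(t1 = spliced_tx))$percent, 0)

  set.seed(2)
  many_tx <- lapply(1:20, function(i)
    transcript_model(sprintf("t%02d", i), sprintf("c%02d", i), "+",
                     0L, 100L))
  names(many_tx) <- vapply(many_tx, `[[`, character(1), "transcript_id")
  covs <- lapply(1:20, function(i)
    gi(sprintf("c%02d", i), 0L, as.integer(5 * i)))
  cov <- suppressWarnings(do.call(c, covs))
  d <- suppressWarnings(transcript_pps_coverage(cov, many_tx))
  expect_equal(sort(unique(d$decile)), 1:10)
  expect_equal(d$decile[order(d$percent)], rep(1:10, each = 2))
})

test_that("window correlation behaves like Pearson on window abundances", {
  a <- flat_track(3000, base = 0,
                  boxes = list(list(start = 0, end = 1000, value = 1),
                               list(start = 1000, end = 2000, value = 2),
                               list(start = 2000, end = 3000, value = 3)))
  b <- flat_track(3000, base = 0,
                  boxes = list(list(start = 0, end = 1000, value = 3),
                               list(start = 1000, end = 2000, value = 2),
                               list(start = 2000, end = 3000, value = 1)))
  expect_equal(sliding_window_correlation(a, a), 1)
  a2 <- a
  a2$counts <- lapply(a2$counts, `*`, 2)
  a2$total_reads <- a2$total_reads * 2
  expect_equal(sliding_window_correlation(a, a2), 1)
  expect_equal(sliding_window_correlation(a, b), -1)
  expect_error(sliding_window_correlation(flat_track(500), flat_track(500)),
               "windows")
})

test_that("3'UTR window selection is half-open downstream of the stop", {
  tx <- transcript_model("t1", "c1", "+", 0L, 1000L, 100L, 700L)
  txs <- list(t1 = tx)
  # stop anchor at spliced 700 = genomic 700 on this single-exon model
  expect_length(select_pps_in_utr_window(gi("c1", 760L, 780L), txs, 50, 100),
                1L)
  expect_length(select_pps_in_utr_window(gi("c1", 800L, 820L), txs, 50, 100),
                0L)
  # 3'UTR shorter than the window start contributes nothing
  short <- transcript_model("t2", "c2", "+", 0L, 730L, 100L, 700L)
  expect_length(select_pps_in_utr_window(gi("c2", 740L, 760L),
                                         list(t2 = short), 50, 100), 0L)
})

test_that("nucleotide composition reports pooled counts and per-PPS fractions", {
  res <- nucleotide_composition(c("AACG", "UUUU"))
  expect_equal(unname(res$pooled), c(2, 1, 1, 4))
  expect_equal(res$per_pps$A, c(0.5, 0))
  expect_equal(res$per_pps$U, c(0, 1))
})
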
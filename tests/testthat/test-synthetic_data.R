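test_that("ground truth is deterministic and respects degenerate settings", {
  cfg <- sim_config(n_transcripts = 5, seed = 21)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$pairing, t2$pairing)
  expect_equal(GenomicRanges::start(t1$sites$t0),
               GenomicRanges::start(t2$sites$t0))

  unpaired <- simulate_truth(sim_config(n_transcripts = 3,
                                        paired_fraction = 0, seed = 1))
  expect_true(all(unlist(unpaired$pairing) == 0))
  paired <- simulate_truth(sim_config(n_transcripts = 3,
                                      paired_fraction = 1, seed = 1))
  expect_true(all(unlist(paired$pairing) == 1))

  nosites <- simulate_truth(sim_config(n_transcripts = 3, site_rate = 0,
                                       seed = 1))
  expect_true(all(vapply(nosites$sites, length, integer(1)) == 0L))
})

test_that("planted sites sit inside exons and pairing covers every base", {
  truth <- simulate_truth(sim_config(n_transcripts = 8, seed = 13))
  exons <- suppressWarnings(do.call(c, unname(lapply(
    truth$transcripts, function(tx)
      GenomicRanges::GRanges(tx$chrom,
                             IRanges::IRanges(start = tx$exon_starts + 1L,
                                              end = tx$exon_ends),
                             strand = tx$strand)))))
  for (tp in names(truth$sites)) {
    s <- truth$sites[[tp]]
    within <- GenomicRanges::countOverlaps(s, exons, type = "within")
    expect_true(all(within >= 1L))
  }
  for (id in names(truth$transcripts)) {
    expect_length(truth$pairing$t0[[id]],
                  truth$transcripts[[id]]$spliced_length)
  }
})

test_that("sites born after baseline never touch previously protected bases", {
  truth <- simulate_truth(sim_config(n_transcripts = 10, seed = 33))
  born <- S4Vectors::mcols(truth$sites$t2)$born
  dev <- truth$sites$t2[born == "t2"]
  earlier <- c(GenomicRanges::granges(truth$sites$t0),
               GenomicRanges::granges(truth$sites$t1))
  expect_false(any(IRanges::overlapsAny(dev, earlier)))
})

test_that("library rates follow the digestion-bias and protection model", {
  cfg <- sim_config(n_transcripts = 6, paired_fraction = 1, site_rate = 0,
                    depth = 50, n_timepoints = 1, n_replicates = 1,
                    seed = 5)
  libs <- simulate_libraries(simulate_truth(cfg))
  l <- libs$t0$rep1
  ratio <- total_reads(l$so_ds) / total_reads(l$so_ss)
  expect_equal(ratio, 0.85 / 0.15, tolerance = 0.05)

  cfg <- sim_config(n_transcripts = 12, depth = 30, protection_factor = 5,
                    seed = 6, n_timepoints = 1)
  truth <- simulate_truth(cfg)
  l <- simulate_libraries(truth)$t0$rep1
  fp_in <- fp_out <- 0
  n_in <- n_out <- 0
  for (tx in truth$transcripts) {
    g <- transcript_to_genomic(tx, seq.int(0L, tx$spliced_length - 1L))
    s <- truth$sites$t0
    sel <- as.character(GenomicRanges::seqnames(s)) == tx$chrom
    inside <- rep(FALSE, length(g))
    for (k in which(sel)) {
      inside[g >= GenomicRanges::start(s)[k] - 1L &
               g < GenomicRanges::end(s)[k]] <- TRUE
    }
    fp <- cov_values(l$fp_ds, tx$chrom, tx$strand, g) +
      cov_values(l$fp_ss, tx$chrom, tx$strand, g)
    fp_in <- fp_in + sum(fp[inside])
    fp_out <- fp_out + sum(fp[!inside])
    n_in <- n_in + sum(inside)
    n_out <- n_out + sum(!inside)
  }
  expect_gt(n_in, 500)
  expect_equal((fp_in / n_in) / (fp_out / n_out), 5, tolerance = 0.1)
})

test_that("replicates are independent draws from identical rates", {
  cfg <- sim_config(n_transcripts = 4, n_timepoints = 1, seed = 8)
  libs <- simulate_libraries(simulate_truth(cfg))
  r1 <- libs$t0$rep1$so_ds
  r2 <- libs$t0$rep2$so_ds
  expect_false(identical(r1$counts, r2$counts))
  expect_equal(total_reads(r1) / total_reads(r2), 1, tolerance = 0.05)
})

test_that("fixtures are written deterministically with the full library grid", {
  cfg <- sim_config(n_transcripts = 3, seed = 17)
  truth <- simulate_truth(cfg)
  libs <- simulate_libraries(truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(truth, libs, d1)
  expect_equal(sum(grepl("bedgraph$", list.files(d1))), 24L)
  expect_true(file.exists(file.path(d1, "transcripts.bed12")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_length(read_bed(file.path(d1, "transcripts.bed12"), "bed12"), 3L)

  truth2 <- simulate_truth(cfg)
  libs2 <- simulate_libraries(truth2)
  write_fixtures(truth2, libs2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  one <- sim_config(n_transcripts = 1, seed = 2)
  t1 <- simulate_truth(one)
  d3 <- withr::local_tempdir()
  write_fixtures(t1, simulate_libraries(t1), d3)
  expect_length(readLines(file.path(d3, "transcripts.bed12")), 1L)
})

test_that("a null protection factor gives footprint == structure-only rates", {
  cfg <- sim_config(n_transcripts = 5, protection_factor = 1,
                    n_timepoints = 1, seed = 12)
  libs <- simulate_libraries(simulate_truth(cfg))
  l <- libs$t0$rep1
  expect_equal(total_reads(l$fp_ss) / total_reads(l$so_ss), 1,
               tolerance = 0.05)
  expect_equal(total_reads(l$fp_ds) / total_reads(l$so_ds), 1,
               tolerance = 0.05)
})
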
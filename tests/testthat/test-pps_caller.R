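# direct-summation oracle for the Poisson upper tail
pois_tail_oracle <- function(k, lam) {
  if (k == 0) {
    return(1)
  }
  # direct summation of the upper-tail pmf (terms vanish well before 400)
  j <- k:(k + 400)
  sum(exp(-lam + j * log(lam) - lgamma(j + 1)))
}

test_that("Poisson upper tail matches direct summation", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(10, 2), pois_tail_oracle(10, 2),
               tolerance = 1e-10)
  expect_equal(poisson_upper_tail(10, 2), 4.6498075e-5, tolerance = 1e-6)
  expect_equal(poisson_upper_tail(2, 2), 1 - exp(-2) * 3, tolerance = 1e-12)
  expect_error(poisson_upper_tail(3, 0), "lam")
  for (k in c(1, 3, 17, 50)) {
    for (lam in c(0.1, 1, 7, 20)) {
      expect_equal(poisson_upper_tail(k, lam), pois_tail_oracle(k, lam),
                   tolerance = 1e-10)
    }
  }
})

test_that("BH step-up reproduces hand-computed q-values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("an enriched box is called as exactly one PPS, and only at a sane FDR", {
  so <- flat_track(1000, base = 2)
  fp <- flat_track(1000, base = 2,
                   boxes = list(list(start = 100, end = 160, value = 10)))
  pps <- call_pps(fp, so)
  expect_length(pps, 1L)
  expect_equal(GenomicRanges::start(pps) - 1L, 100L)
  expect_equal(GenomicRanges::end(pps), 160L)
  expect_true(all(S4Vectors::mcols(pps)$q_value <= 0.05))
  expect_true(all(S4Vectors::mcols(pps)$q_value >=
                    S4Vectors::mcols(pps)$p_value))

  expect_length(call_pps(fp, so, fdr = 1e-12), 0L)
  expect_length(call_pps(so, so), 0L)
  expect_error(call_pps(fp, coverage_track()), "no control library")
})

test_that("calling is stable under joint scaling of both libraries", {
  so <- flat_track(2000, base = 3)
  fp <- flat_track(2000, base = 3,
                   boxes = list(list(start = 200, end = 260, value = 30),
                                list(start = 900, end = 960, value = 15)))
  scale_track <- function(t, f) {
    t$counts <- lapply(t$counts, `*`, f)
    t$total_reads <- t$total_reads * f
    t
  }
  p1 <- call_pps(fp, so)
  p3 <- call_pps(scale_track(fp, 3L), scale_track(so, 3L))
  expect_equal(GenomicRanges::start(p1), GenomicRanges::start(p3))
  expect_equal(GenomicRanges::end(p1), GenomicRanges::end(p3))
  expect_equal(order(S4Vectors::mcols(p1)$q_value),
               order(S4Vectors::mcols(p3)$q_value))
})

test_that("the label-swap FDR mode agrees with BH on a clear signal", {
  so <- flat_track(1000, base = 2)
  fp <- flat_track(1000, base = 2,
                   boxes = list(list(start = 100, end = 160, value = 10)))
  pps <- call_pps(fp, so, fdr_method = "permutation")
  expect_length(pps, 1L)
  expect_equal(GenomicRanges::start(pps) - 1L, 100L)
})

test_that("ribosome filter removes lengths 20-40 inclusive", {
  lens <- c(15L, 25L, 41L, 30L, 100L)
  gr <- gi("chr1", cumsum(lens + 50) - lens, cumsum(lens + 50))
  expect_equal(GenomicRanges::width(ribosome_filter(gr)), c(15L, 41L, 100L))
  gr2 <- gi("chr1", c(0L, 100L), c(20L, 140L))
  expect_length(ribosome_filter(gr2), 0L)
  expect_length(ribosome_filter(gr[0]), 0L)
})

test_that("replicate intersection needs >= 1 nt same-strand overlap", {
  a <- gi("chr1", 100L, 150L, "+")
  expect_length(high_confidence(a, gi("chr1", 149L, 200L, "+")), 1L)
  expect_length(high_confidence(a, gi("chr1", 150L, 200L, "+")), 0L)
  expect_length(high_confidence(a, gi("chr1", 120L, 130L, "-")), 0L)
})

test_that("arm merging unions overlapping calls and labels provenance", {
  ss <- gi("chr1", c(100L, 500L), c(160L, 550L), "+")
  S4Vectors::mcols(ss)$q_value <- c(1e-4, 1e-3)
  ds <- gi("chr1", 140L, 200L, "+")
  S4Vectors::mcols(ds)$q_value <- 1e-6
  m <- merge_arms(ss, ds)
  expect_length(m, 2L)
  expect_equal(S4Vectors::mcols(m)$rnase, c("merged", "ss"))
  expect_equal(GenomicRanges::start(m) - 1L, c(100L, 500L))
  expect_equal(GenomicRanges::end(m), c(200L, 550L))
  expect_equal(S4Vectors::mcols(m)$q_value, c(1e-6, 1e-3))
})
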
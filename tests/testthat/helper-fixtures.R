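# shared in-code fixtures

# flat coverage on one contig/strand with optional boxed enrichment
flat_track <- function(n = 1000L, base = 2, boxes = NULL, chrom = "chr1",
                       strand = "+") {
  v <- rep(base, n)
  if (!is.null(boxes)) {
    for (b in boxes) v[seq.int(b$start + 1L, b$end)] <- b$value
  }
  coverage_track(chrom = chrom, strand = strand, pos = seq_len(n) - 1L,
                 value = v)
}

# the two-exon plus-strand model used across coordinate tests:
# exons [1000,1100) and [1200,1300), CDS thick [1050,1250)
two_exon_tx <- function(strand = "+") {
  tx <- transcript_model("txA", "chr1", strand,
                         exon_starts = c(1000L, 1200L),
                         exon_ends = c(1100L, 1300L))
  tx$cds_start_tx <- 50L
  tx$cds_end_tx <- 150L
  tx
}

# bare score track for metagene tests (only id + normalized are consumed)
score_track <- function(id, normalized) {
  structure(list(transcript_id = id, raw = normalized,
                 normalized = normalized),
            class = "structure_score_track")
}

gi <- function(chrom, start, end, strand = "+", name = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L,
                                                end = end),
                               strand = strand)
  S4Vectors::mcols(gr)$name <-
    if (is.null(name)) sprintf("iv%03d", seq_along(gr)) else name
  gr
}

# 6-protein x (4 probes x 3 timepoints) iBAQ toy: at each time point every
# column holds one strong protein (9999) and five background proteins (99),
# so all columns share a value multiset and fold changes are exact by hand:
# strong = 10000/100 = 100, others = 100/mean(10000,100,100) = 100/3400.
# Strong assignments: d0 m1->P1 m2->F4 m3->F5 m4->F6; d2 m1->P1 m2->P2
# m3->F5 m4->F6; d4 m1->P1 m2->P2 m3->P3 m4->F6. A keratin row rides along
# and must be filtered.
toy_ibaq <- function() {
  probes <- rep(c("m1", "m2", "m3", "m4"), times = 3)
  tps <- rep(c("d0", "d2", "d4"), each = 4)
  prot <- c("P1", "P2", "P3", "F4", "F5", "F6", "Krt1")
  strong <- list(
    d0 = c(m1 = "P1", m2 = "F4", m3 = "F5", m4 = "F6"),
    d2 = c(m1 = "P1", m2 = "P2", m3 = "F5", m4 = "F6"),
    d4 = c(m1 = "P1", m2 = "P2", m3 = "P3", m4 = "F6"))
  vals <- matrix(99, nrow = length(prot), ncol = 12,
                 dimnames = list(prot, NULL))
  for (j in seq_len(12)) {
    vals[strong[[tps[j]]][[probes[j]]], j] <- 9999
  }
  ibaq_matrix(vals, probe = probes, timepoint = tps)
}
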
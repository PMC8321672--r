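---
title: "Structure scores and protein-protected sites from paired nuclease footprinting"
author: "pipstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure scores and protein-protected sites from paired nuclease footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipstruct)
```

## The experimental design this package models

Protein interaction profile sequencing digests cross-linked RNA twice per
sample: once with a single-strand-specific RNase and once with a
double-strand-specific RNase, each in two conditions — a *footprint*
condition in which bound proteins are still attached and shield their
binding sites from digestion, and a *structure-only* condition in which
proteins are stripped first, so read coverage reflects only the RNA's
base-pairing state. Four libraries per sample therefore carry two
orthogonal signals:

* the **ratio of dsRNase to ssRNase coverage** in the structure-only
  libraries encodes per-base pairing state, and
* the **excess of footprint over structure-only coverage** (within a
  digestion arm) marks protein-protected sites (PPSs).

In the murine erythroleukemia (MEL) differentiation setting that motivates
the defaults, this design is applied at three time points (day 0, 2, 4
after DMSO induction) with two biological replicates — 24 libraries.

## The structure score

For a base $i$ with structure-only counts $n_{ds}$ and $n_{ss}$:

$$ S_i \;=\; \mathrm{glog}(ds_i) - \mathrm{glog}(ss_i), \qquad
   \mathrm{glog}(x) = \log_2\!\left(x + \sqrt{1 + x^2}\right), $$

with coverage-length normalization
$ds_i = n_{ds}\,\max(L_{ds}, L_{ss})/L_{ds}$ (and symmetrically for
$ss_i$), where $L$ is the number of bases covered by the whole library —
the working assumption being that the transcriptome as a whole has
comparable amounts of paired and unpaired sequence, so the two digests
should occupy comparable footprints. The generalized log tolerates zero
counts (`glog(0) = 0`) and converges to `log2(2x)` for large `x`, so $S_i$
behaves like an ordinary log-ratio at high coverage. Raw scores are
centered by the transcript mean (`normalized = raw - mean(raw)`), which
preserves the glog scale and the sign convention (positive = more likely
paired); we interpret "normalized to the average structure score of the
spliced transcript" as exactly this centering and apply no further
per-window rescaling. Bases with no structure-only signal in either digest
score 0 and are included in the mean.

Coordinate conventions: all intervals are 0-based half-open (BED); the
start-codon anchor is the first CDS base in spliced coordinates and the
stop anchor is the first base *after* the CDS (the exclusive CDS end), so
negative stop-anchored offsets lie in the CDS and non-negative ones in the
3'UTR. Metagene profiles (`metagene()`, default ±400 nt) are gap-aware:
transcripts contribute only at offsets their spliced extent covers, and the
per-offset `n` reflects that.

## Calling protein-protected sites

Within one digestion arm, each base's footprint count $fp_b$ is tested
against the rate expected from the structure-only library,

$$ \lambda_b = r\,\bigl(\max(so_b,\ \bar{so}_b^{(w)}) + \text{pseudo}\bigr),
   \qquad r = \frac{\text{fp total}}{\text{so total}}, $$

with an upper-tail Poisson p-value. Two numerical choices matter here:

* **Local control rate.** $\bar{so}_b^{(w)}$ is the running mean of the
  control in a `local_window` = 25 nt window. A single control base that
  drops to zero by sampling chance would otherwise imply an absurdly small
  expected rate and fabricate p-values around $10^{-10}$; taking the larger
  of the point and local estimates (the same guard peak callers apply to
  their background rates) removes these artifacts. It cannot mask true
  sites, because protection acts on the footprint library only — the
  control is protein-stripped, so footprint enrichment never deflates the
  local control mean.
* **pseudo = 0.5** keeps the rate positive where the control is empty.

Candidate regions are maximal runs of bases with $p \le$ `enter_p` (0.01),
bridging internal gaps of at most `max_gap` (10 nt). A candidate is
reported when it passes **two** filters at the requested FDR (5%):

1. its best member base survives Benjamini–Hochberg adjustment of the
   per-base p-values across *all* scored bases genome-wide, and
2. its aggregate count test — the exact conditional comparison of the
   region's footprint and structure-only totals, i.e.
   $fp_\Sigma \sim \mathrm{Binomial}(fp_\Sigma + so_\Sigma,\ r/(1+r))$
   under the null, the classic two-sample Poisson test — survives a
   Bonferroni bound over the number of scored bases.

Adjusting only within the pre-selected candidates would pass essentially
any candidate under the null (they are selected for small p), and a BH
pass across candidate aggregate p-values inherits the same selection bias;
the genome-wide per-base BH plus the family-wise aggregate guard keep the
null discovery rate at or below nominal while true sites — whose aggregate
p-values sit tens of orders of magnitude below the bound — are unaffected.
Regions shorter than `min_len` = 5 nt are dropped as single-base
artifacts. An optional `fdr_method = "permutation"` estimates the FDR
empirically by exchanging the two libraries' roles and comparing candidate
p-value counts; the deterministic path is the default and the tested one.

Arms are called separately and unioned (`merge_arms()`), with overlapping
intervals labelled `merged` — the combination rule is a package choice, as
is genome-wide (rather than per-chromosome) FDR control. Downstream the
pipeline applies the **ribosome filter** (drop lengths 20–40 nt inclusive,
the typical ribosome footprint) and keeps **high-confidence** calls
reproduced across both biological replicates with ≥ 1 nt of same-strand
overlap (`pps_pipeline()` wires these steps together).

## Downstream analyses

* `annotate_greedy()`: a PPS increments *every* genomic class it overlaps
  by one, matching the stated greedy convention.
* `shuffle_background()`: matched mocks preserving chromosome, length and
  strand, placed uniformly in the allowed annotation space by rejection
  sampling (10,000 attempts per interval), overlapping neither any
  excluded interval nor one another; deterministic per seed.
* `overlap_enrichment()`: χ² on the 2×2 overlap table, 1 df, no continuity
  correction (matching R's behaviour for large tables; configurable
  upstream by calling `chisq.test` directly).
* `conservation_flank_compare()`: each PPS against its two equal-length
  flanks, averaged together — the aggregation across the two flanks is not
  dictated by the design, and averaging was chosen for symmetry; a
  two-sample Kolmogorov–Smirnov test contrasts the per-PPS distributions.
* `sliding_window_correlation()`: non-overlapping 1,000-nt windows (the
  stride is a package choice), depth-normalized counts, Pearson across
  windows with any signal.
* `percentile_partition()`: nearest-rank percentiles on ranks with
  deterministic tie-breaking by transcript id; `top10` = ranks above the
  90th percentile, `bottom10` = ranks up to the 10th, control = the
  45th–55th band.
* `hcluster_changes()`: Euclidean distance + complete linkage (the
  defaults of the environment's built-in hierarchical clustering), cut at
  k = 6; rows are raw window means by default with an optional per-row
  z-score.
* `scan_pwm()` / `top_fraction()`: sense-strand log-odds scanning in bits
  against a background model, PWM rows regularized with a 0.001
  pseudocount on load; ambiguous bases contribute 0. The "top fraction"
  keeps the best `ceiling(n * fraction)` hits with boundary ties included
  — a match threshold is always an explicit input, since none is implied
  by the data.
* `fold_enrichment()`: iBAQ values are zero-filled, contaminants
  (keratin/ribosomal name patterns, configurable) removed, `log10(x+1)`
  transformed and column-centered; fold changes are computed on the
  de-logged normalized scale so that "10-fold" keeps its ordinary meaning,
  and bead-only columns are excluded from the comparison mean by default.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: 60 transcripts with
Poisson-distributed region lengths around 150/1200/500 nt
(5'UTR/CDS/3'UTR, a mouse mRNA-like geometry), 1–4 exons each, half the
bases paired with 10-nt majority-filter smoothing into helix-like runs,
one 60-nt bound site per spliced kb, 5× footprint protection, 30× mean
depth, 0.85 digestion bias (probability a paired base yields a dsRNase
rather than an ssRNase read), three time points × two replicates, 5%
per-time-point pairing drift and 30% site turnover. Sites born after
baseline avoid every location previously protected, so "developmental"
sites are genuinely new. Counts are Poisson per base (a negative-binomial
switch, `overdispersion`, exists for stress testing); replicates are
independent draws from identical rates.

The simulator does **not** model sequence-dependent digestion or coverage
bias, read-length effects, alignment artifacts, isoform mixtures, or
cross-linking chemistry. Passing recovery tests therefore demonstrates
that the statistics behave as designed under their own assumptions — not
that real libraries satisfy those assumptions; on real data the
overdispersion switch and the permutation FDR mode are the first knobs to
reach for.

## Problem sizes and determinism

The shipped tests and the acceptance script run the default scenario
(60 transcripts ≈ 120 kb of exonic sequence, 24 libraries), a 100-contig
null calibration at protection 1, and a 30-transcript 50× run for
structure-score discrimination — sizes chosen so the whole suite completes
in well under a minute on one CPU while leaving hundreds of planted sites
and tens of thousands of labelled bases per check. Every random step
(truth, libraries, shuffles) is seed-controlled; `write_fixtures()` output
is byte-identical across reruns of the same configuration.

## Known limitations

* The per-base Poisson test treats bases as independent; neighbouring
  bases share fragments in real data, which the region-level aggregate
  test only partly absorbs.
* FDR is controlled at the base level (BH) with a family-wise aggregate
  guard; the emitted *region count* error rate is bounded empirically (see
  the null-calibration test), not analytically.
* Structure scores are coverage ratios, not pairing probabilities; no
  thermodynamic model is involved, and scores from shallow transcripts are
  noisy in proportion to depth.
* BED12 is the only transcript-model dialect read; supply conversions from
  GTF/GFF externally.
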
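---
title: "Detecting cell-type-specific alternative polyadenylation from 3' tag scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-type-specific alternative polyadenylation from 3' tag scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatag)
```

## The measurement model

3' tag single-cell protocols prime reverse transcription with oligo-dT at the
poly(A) tail. The captured cDNA fragment therefore ends at the
cleavage/polyadenylation (pA) site, and the sequenced read — the fragment's
5'-most ~100 nt — sits a fragment-length's reach upstream of it. Over many
molecules the strand-aware 3' ends of reads pile up just upstream of each pA
site, and the peak's 3' edge approaches the site itself (the minimum fragment
length observed sets how closely). Two consequences drive the design:

* a gene with two used pA sites shows either two coverage peaks or, when the
  sites are closer than roughly a fragment length, one merged peak whose
  3'-end positions are bimodal;
* oligo-dT also anneals to genomically encoded A-rich stretches inside
  transcripts, creating artifact peaks whose *downstream* genomic sequence is
  A-rich — the signature the internal-priming filter keys on.

Because per-cell coverage is shallow, reads from all cells of a cluster are
pooled (pseudobulk) and clusters are treated as samples. Cluster assignment,
alignment and UMI deduplication are inputs, not concerns of this package.

## Stages and their parameters

**Region building.** Annotated per-transcript 3' UTRs are merged per gene
into maximal disjoint regions. When a transcript's 3' UTR spans several
exons, it is truncated to its last (3'-most) exon *before* the per-gene
merge; the truncation is per transcript because the spanning is a
per-transcript property. Introns are per-transcript inter-exon gaps, merged
per gene, then clipped by any overlap with any gene's UTR region
(strand-blind, matching common interval-intersection practice). Clipping
rather than discarding keeps intronic sequence far from any UTR; a discarded
intron would silently delete true intronic pA candidates. Internally all
coordinates are 1-based closed, the native convention of the R/Bioconductor
interval stack used for the arithmetic; BED output converts at the boundary.

**Peak calling** (`min_reads = 5`, `max_gap = 0`). Peaks are maximal
strand-specific intervals of footprint coverage ≥ 1, with gaps ≤ `max_gap`
merged and intervals under `min_reads` members dropped. This
coverage-interval formulation reproduces what a fixed-window caller followed
by interval merging converges to, while keeping the member reads of each
peak — the quantity every later stage consumes. Both knobs are exposed;
`min_reads = 5` suppresses scattered single-read noise at pseudobulk depth.

**Peak-to-region assignment.** Overlap of ≥ 1 nt on the same strand, no
clipping of peak coordinates (tag peaks genuinely spill into coding
sequence upstream of the UTR). Peaks in a region are indexed 5'→3' in
transcript orientation; index 1 is the proximal peak on either strand. A
peak overlapping regions of two genes goes to the larger overlap, ties to
the lexicographically lower region ID so reruns are deterministic.

**Bimodal splitting** (`min_split_reads = 20`, `min_distance = 75 nt`,
`sd_factor = 3`). For each peak with enough members, a two-component 1-D
Gaussian mixture is fitted by EM to the member 3'-end positions: means
initialised at the 25th/75th percentiles, equal weights, a shared starting
SD, log-likelihood tolerance 1e-6, at most 500 iterations, no random
restarts — the fit is deterministic. The peak is split only when the fitted
modes are more than `sd_factor · max(σ₁, σ₂)` *and* at least 75 nt apart;
the larger SD is the conservative reading of "separated by more than three
standard deviations". The split point is the coordinate between the means
where the weighted component densities are equal (solved by root finding;
midpoint fallback if the densities do not cross). Members partition exactly,
sub-peak intervals are the span of their members, and sub-peaks are
re-examined recursively so one peak merging three sites resolves in two
rounds. Fits on fewer than 20 points are unstable, so smaller peaks are
never split; degenerate (σ < 1e-6) or non-converged fits leave the peak
unsplit, with a log line. The 3'-end positions — not footprint centres — are
fitted because the 3' end is the quantity mechanistically tied to the pA
site.

**Counting.** A read is counted to a peak its footprint overlaps on the same
strand; a read overlapping several peaks goes to the one containing its 3'
end (ties to the proximal peak, reported), so each read is counted once and
reads straddling freshly split sub-peaks land with the site that generated
them.

**Filtering.** Usage first, then artifacts, per peak class: UTR peaks keep a
summed CPM > 10 over clusters (strict inequality); intronic peaks keep ≥ 50
total counts *and* ≥ 10 summed CPM. Then the internal-priming scan removes
peaks whose sense-strand genomic sequence downstream of the 3' edge contains
an adenine run: ≥ 8 A within 10–140 nt for UTR peaks, and the stricter ≥ 7 A
within 1–200 nt for intronic peaks, where the artifact fraction is much
higher. Window offsets are inclusive 1-based distances from the edge. CPM
denominators are the per-cluster totals of the peak set being filtered; the
UTR and intron sets are normalised independently, which keeps the two
filters decoupled and makes filtering idempotent (column totals only shrink,
summed CPMs only grow, so survivors keep passing). Removal reasons
(`low_cpm`, `low_count`, `a_run`) are returned with the filtered matrix.

**Differential usage.** Per multi-peak UTR, a Pearson chi-squared test of
independence on the raw peaks × clusters table — raw counts, not CPM,
because the test's sampling model is multinomial counts. No continuity
correction; tables with an expected cell below 1 are flagged but still
tested, as no small-count rule is imposed. Clusters contributing zero counts
to a UTR are dropped; UTRs left with under two non-zero peak rows or two
clusters are untestable and excluded from the Benjamini–Hochberg correction,
which runs across all tested UTRs at FDR 0.05. Direction calls (shortening
vs lengthening) are restricted to two-peak UTRs, where the proximal PUI
comparison is unambiguous — in practice the large majority of dynamic UTRs;
UTRs with more peaks instead get per-peak 2 × K tests (each peak against the
sum of its siblings, BH within the UTR). The global direction excess uses a
one-tailed binomial test; PUI distribution comparisons use rank tests
(Wilcoxon for two groups, Kruskal–Wallis beyond), one-tailed only when a
direction is pre-registered by the caller. Results expose both the
significant subset and all multi-peak UTRs, so either population can feed
the distribution comparisons.

**Indices.** For a UTR with peak counts `C` (proximal first),
`proximal PUI = log2((C1+1) / geomean(C+1))`; the pseudocount keeps zeros
finite, and for two peaks the index reduces to
`0.5·log2((C1+1)/(C2+1))`. For an intronic peak,
`intronic PUI = log2((Ci+1)/(CU+1))` with `CU` the summed counts of the same
gene's 3' UTR peaks *downstream* of the intronic peak in transcript
orientation. Expression per UTR is the peak-count sum, CPM-transformed and
quantile-normalised (ties averaged over tied ranks; the target distribution
is the row-wise mean of sorted columns). The per-cell summary averages the
proximal PUI over all multi-peak UTRs with at least one read in that cell.

## The synthetic-data generator

`sim_config()` defaults define the study conditions used throughout the
tests: 60 genes (alternating strand, ~25 per chromosome), each with one
intron and a 3' UTR carrying two pA sites 400 nt apart; two clusters of 100
cells at a mean 1050 reads per cell (about 210k reads in total); fragment
lengths truncated-normal N(250, 50²) in [100, 400] nt — the 200–300 bp
libraries and ~100 nt reads typical of tag protocols, with the upper bound
playing the role of size selection; proximal/distal usage 0.3/0.7 in the
first cluster versus 0.7/0.3 in the second; 5% internal-priming reads drawn
at a planted A₁₂ decoy 500 nt past the distal site; a quarter of genes with
an intronic pA site used at 0.15 vs 0.30 of reads. AATAAA is planted ending
20 nt upstream of every true site, and the background sequence is scrubbed
of A- and T-runs of five or more, so the only A-rich stretches are the
planted decoys — which makes the internal-priming filter's false-removal
rate on true peaks interpretable as exactly zero by construction.

With these geometry choices the two true sites of a UTR merge into one
coverage peak (the distal site's longest fragments reach the proximal site),
so the mixture splitter is exercised on essentially every gene, while the
decoy stays a separate peak that must be caught by the A-run filter, not by
the splitter. Reads are emitted as already-aligned SAM records (the
pipeline's input contract starts at alignments); one RNG stream per run
makes output byte-identical for a given seed.

What the generator does *not* emulate: sequencing errors, UMI collisions,
ambient RNA, doublets, spliced 3' UTRs, overlapping genes, non-uniform gene
expression, or biological within-cluster heterogeneity. Passing tests
therefore demonstrate the correctness and calibration of the algorithms
under the stated library model, not performance on the full messiness of
real data.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent oracle:
interval arithmetic against per-base set operations; the peak caller against
a per-base coverage scan; chi-squared statistics against the expected-count
formula; BH against a from-scratch step-up; the PUI against direct formula
evaluation; A-run detection against a run-length scan; quantile
normalisation against a rank/mean oracle; and the EM against mclust's
mixture fit on the same data. Calibration checks use 1000 null count tables
(type-I control), 100 shifted tables at 500 reads per cluster (power and
direction), 200 unimodal and 200 bimodal position sets (split specificity
and sensitivity), a spacing series at 100/200/300/500 nt (resolution is
monotone and near-total at wide spacing — adjacent sites below ~150 nt merge
irretrievably at these fragment SDs), and a 20% downsampling rerun (peak
recovery above 90%). These sizes keep the whole suite and the acceptance
script within a few minutes while leaving each binomial check with narrow
enough error bars to be meaningful.

## Known limitations

* Single-block alignments only; spliced reads crossing a UTR intron are
  counted by their footprint interval, not split by CIGAR.
* The splitter fits exactly two components per round; heavily multimodal
  peaks rely on recursion, and modes closer than the 75 nt / 3-SD rule are
  deliberately left merged.
* The binomial direction test treats UTRs as independent draws; co-regulated
  genes violate that assumption, as they do in any such global test.
* Per-cell PUI means are shallow-coverage estimates; they rank cells well
  but their absolute values are biased toward whichever peaks capture reads
  first at low counts.
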
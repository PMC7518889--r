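---
title: "Methods: spike-calibrated comparison of chromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-calibrated comparison of chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

CUT&RUN profiles of histone modifications are not directly comparable
across samples: antibody efficiency, cell input and library depth all move
the raw counts. When the biology itself changes the *global* amount of a
mark — as the K27M oncohistone does for H3K27me3 — per-sample
normalization to library size actively hides the effect. The remedy is a
heterologous spike-in: every reaction receives the same quantity of
foreign chromatin (fly cells at a 1:20 cell ratio to the primary cells),
so the number of reads mapping to the spike genome measures the overall
recovery of each reaction, and

$$ f_s = \frac{C}{N^{\text{spike}}_s}, \qquad C = 10{,}000 $$

is a per-sample factor that puts primary-genome signal on a common
absolute scale. Multiplying sample $s$'s coverage (or region counts) by
$f_s$ makes a 10-fold genuine loss of the mark appear as a 10-fold drop,
regardless of sequencing depth.

`spikedomains` implements this calibration together with the downstream
comparison workflow: binned coverage, a simplified sparse-enrichment
domain caller, replicate merging, partition of merged domain lists into
disjoint segments, dominant-segment length filtering into a
differential-domain list, k-means clustering with knee-based selection of
k, and fragments-per-kilobase (FPK) quantification — plus a seeded
simulator that generates fragment data with planted ground truth for all
of it.

## Coordinate and unit conventions

All intervals are BED-standard 0-based half-open at every interface; a
fragment's length is `end - start`. The unit of signal is the *fragment*
(a sequenced paired-end insert), not the read. Strand is ignored
throughout: nucleosomal fragments and methylation domains are
strand-less. Spike fragments are recognized by chromosome-name membership
in the spike genome's `chrom_sizes`, so a single combined fragment BED
per sample carries both genomes.

## Coverage and the ranked-bin view

`binned_coverage()` sums fragment *base pairs* per fixed-width bin
(default 5 kb), attributing a boundary-spanning fragment to each bin
pro-rata by overlap, so the genome-wide sum equals total fragment bp
exactly. `ranked_bin_counts()` sorts bins by descending value with ties
broken by genomic position. The shape of that ranked curve is a
deposition signature: promoter-turnover marks concentrate signal in a
steep head of bins, while replication-coupled deposition gives a flat
curve. The suite summarizes the shape as mean(top 1% of bins) / median
bin — a head-versus-body ratio that is near 1 for uniform signal.

## Domain calling and its scope

`call_domains()` is deliberately minimal: candidate blocks are maximal
runs of strictly positive per-bp (or fine-binned) coverage, scored by
area under the curve, and kept when the score exceeds the maximum block
score of a control track (or, without a control, when the block is in the
top quantile by score). This keeps the core idea of sparse-enrichment
callers without their empirical-FDR machinery; externally called peak
BEDs can be substituted at any point via `read_region_bed()`, and that is
the recommended path when exact reproduction of a published peak list
matters.

Two practical constraints follow from the block definition and should be
respected in experimental design as in simulation:

* data must be *sparse* — if background coverage approaches saturation,
  positive runs chain across the genome and blocks lose meaning. Our
  simulated depths keep background occupancy below roughly 60–95%
  (fragment starts at ≲0.02/bp), which is where real CUT&RUN operates;
* the control must be sequenced to at least the signal's *background*
  density, since the threshold is the control's maximum block. A control
  much shallower than the signal background lets background blocks pass;
  a control far deeper than the signal merges into giant blocks and
  suppresses everything.

## Differential domains: partition and dominant-segment filtering

Merged per-condition domain lists are compared by presence, not by
signal. `partition_regions()` cuts the union of all lists at every
interval boundary, yielding maximal disjoint segments of constant
set-membership; segments abut exactly where membership changes, and those
shared boundaries are recorded as adjacency flags. `filter_dominant()`
then applies two length rules: a segment adjacent to another partitioned
segment survives only at ≥ 10 kb — selecting the dominant segment of each
overlap neighborhood and avoiding double-mapping of adjacent slivers —
and a free-standing segment survives only at ≥ 3 kb. Decisions taken
where the rules are underdetermined:

* "adjacent" means sharing an exact boundary coordinate on either side
  (the only reading compatible with partition output, where adjacency
  arises precisely at membership changes);
* "less than N kb" is a strict inequality: a segment of exactly 10,000 bp
  (or 3,000 bp free-standing) is kept;
* in chains of three or more mutually adjacent segments the 10 kb rule is
  applied to every segment independently, and both members of an adjacent
  pair may be dropped;
* membership labels are carried through filtering as annotation, so
  downstream clustering can report per-source provenance.

## Clustering and the knee criterion

The clustering features are spike-scaled fragment counts per
differential region (one column per condition), log2(x+1) transformed;
`transform = "none"` is available. FPK is deliberately *not* applied
before clustering — it is a quantification scale, applied later. K-means
is Lloyd's algorithm (via `stats::kmeans`) with 25 random restarts by
default, keeping the best within-cluster sum of squares; restarts that
abandon with an empty cluster are skipped. Everything is deterministic
given the seed.

`select_k_knee()` scans k over [2, 15] by default, prepends the k = 1
total sum of squares, and selects the k with the largest discrete second
difference of the within-cluster distance curve — the point of maximum
curvature. Ties go to the smaller k, and a non-monotone curve (possible
under sampling noise) is reported but still resolved by maximum
curvature.

## Quantification

`signal_matrix()` counts fragments overlapping each region by ≥ 1 bp
(configurable), the convention of the standard intersect utilities.
`fpk_scale()` multiplies each entry by `1000 / region_length` and then by
a per-sample constant proportional to `1 / spike_reads` — the same
calibration as the coverage tracks, now at region resolution.
`cluster_region_stats()` reports five-number summaries (type-7 quartiles)
per cluster and sample. `overlap_fraction()` reports the percentage of
query intervals touching a reference set, rounded half-up at the printed
precision, and `tss_window_correlation()` computes Pearson $R^2$ between
log2(x+1) promoter-window counts and expression counts (the transform is
a package decision; the comparison it supports did not state one).

## The simulator and what it does (not) emulate

`make_truth()` encodes four regimes as piecewise-constant fragment
intensities: broad silenced domains (10–200 kb, default 20× background)
for a Polycomb-like mark; promoter peaks (1 kb, per-peak multipliers
drawn log-uniformly up to 50× to emulate expression-graded turnover) over
a low background; a uniform genome-wide rate for replication-coupled
deposition; and a flat background for IgG. The spike-in is a uniform
intensity over the spike genome whose share follows from the 1:20
spike:primary cell ratio and the genome sizes; `spike_rate` scales the
spike chromatin's per-bp reactivity relative to primary background
(quantitative examples use 50, emulating an antibody whose epitope is
abundant on the spike chromatin — as for H3K27me3 on the fly genome —
which yields the few-percent spike read fractions seen in practice).
`simulate_sample()` draws fragment starts from that intensity, lengths
from a normal(170, 25) truncated at 50 bp, and is byte-reproducible given
its seed.

The default toy genome is two 5 Mb chromosomes plus a 500 kb spike
chromosome; the end-to-end suites use four 10 Mb chromosomes so that
hundreds of 12–25 kb domains fit with realistic spacing. These sizes, and
simulated depths of 10⁵–10⁶ fragments, are chosen so background sparsity,
bin widths and the 10 kb/3 kb filters are all in their operating regimes
while a full run takes seconds.

The simulator does **not** model GC or mappability bias, PCR duplicates,
fragment-length dependence on chromatin state, heterogeneous spike-in
chromatin, or sequence-level effects. Passing tests therefore demonstrate
the correctness and calibration behavior of the *computations*, not
robustness to those real-data artifacts.

## What the planted-truth suites check

* **Calibration**: the spike factor is exact arithmetic; across a
  titration series (fly cells fixed, human input varied 5–40×),
  spike-scaled domain signal is linear in human input (R² > 0.99) and
  constant per cell-equivalent.
* **Partition**: against a per-bp brute-force membership scan on 1,000
  random three-set inputs, segment membership and exact cover hold
  bit-for-bit.
* **Clustering**: on matrices with four planted well-separated row
  clusters the knee criterion selects k = 4 in ≥ 95/100 seeded runs.
* **End to end**: a three-class design (shared / A-only / B-only domains,
  20× enrichment, two replicates per condition plus an IgG control)
  recovers the planted classes with adjusted Rand index ≥ 0.9 after the
  full call → merge → partition → filter → matrix → knee-k-means chain.
* **Quantification**: a planted 10× per-domain contrast between samples
  of deliberately unequal depth and spike fraction is recovered as a
  10× ± 20% ratio of FPK+spike-scaled medians — the mechanism that lets
  calibrated profiling report "percent of wild-type levels" claims.

## Known limitations

The domain caller is a stand-in, not a SEACR reimplementation; for
published peak lists use the BED import path. Partition adjacency is
defined within the partition output only — domains that merely come close
(without sharing a boundary) are free-standing. The knee criterion needs
the within-cluster curve at k−1 and k+1, so it cannot select `k_max`
itself. Per-bp coverage tracks of very large genomes are run-length
encoded, but the simulator and caller are designed for desk-scale
genomes, not full mammalian ones.
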
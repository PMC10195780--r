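---
title: "Methods: building a replicable DHS atlas from per-sample peak calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a replicable DHS atlas from per-sample peak calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsatlas)
```

## The problem

DNase-seq consortia release peak calls per sample. Three things stand
between those files and a usable cross-sample annotation of open chromatin:
the same regulatory site has slightly different coordinates in every sample
(peak callers see different read pileups); a substantial fraction of called
peaks are artifacts that no replicate supports; and the −log10 p
accessibility scores are not comparable across generating centers.
`dhsatlas` addresses the three in order: graph-based cross-sample alignment,
a replication test per aligned site, and rank-based intensity normalization.
This vignette explains each model, its assumptions, the tunable parameters,
and what the synthetic benchmark does and does not demonstrate.

## Peak alignment by Markov clustering

Peaks from all QC-passed samples on one chromosome form a weighted graph:
an edge joins every overlapping pair, weighted by the bp-level Jaccard
similarity (intersection length over union length, both computed with
0-based half-open arithmetic). Disjoint peaks get no edge, so connected
components are small islands of mutually overlapping peaks; MCL partitions
each component. We run MCL with its classical defaults — expansion 2
(matrix squaring), inflation 2.0, self-loop weight 1.0, pruning threshold
1e-5, convergence tolerance 1e-6 — because the method was published with
"default parameters" and these are what the canonical implementation
defaults to. Inflation is the resolution knob: lower values (e.g. 1.4)
merge more aggressively and never produce more clusters than 2.0 on the
same graph.

Two implementation details matter for reproducibility. First, nodes are
canonically ordered (start, end, sample, significance) before the transition
matrix is built, which makes the partition invariant to input row order.
Second, MCL's attractor systems can in principle overlap; we resolve
overlaps to a hard partition by assigning each node to the system with the
largest total attraction weight, ties to the smallest cluster index. A
cluster's span is the union extent of its members, members may come from
the same sample more than once (the intensity step later takes the maximum
significance), and singleton components skip MCL entirely.

## The replication test

The quality question for an aligned cluster is: does its presence pattern
respect replicate structure? For one run we draw, per cell type with at
least two replicates, an unordered pair of replicate samples (uniformly over
all pairs), and pool a 2×2 presence table over cell types: present in the
first replicate, the second, both, neither. The Pearson chi-squared
statistic of that table (no continuity correction),

$$X^2 = \frac{T\,(n_{11} n_{00} - n_{10} n_{01})^2}
{(n_{11}+n_{10})(n_{01}+n_{00})(n_{11}+n_{01})(n_{10}+n_{00})},$$

is asymptotically χ²(1) under the null of no concordance; with T around 160
paired cell types the asymptotics are excellent (maximum-likelihood df fits
on null simulations return 1.00 ± 0.03). Degenerate tables are scored by
convention: all-present clusters get the Pearson maximum T — a site open in
every cell type is maximal evidence of replication, and constitutively open
sites must not be lost; all-absent clusters and other constant-margin tables
get 0 (association unidentifiable). The statistic is two-sided: a strongly
anti-concordant table also scores high. We accept this because genuine
anti-concordance essentially does not occur in peak presence data; a
one-sided truncation would destroy the χ²(1) null calibration.

Pairings are redrawn K = 10 times (run k seeded by `seed XOR k`), the
statistics summed and referred to χ²(10); clusters with p ≤ 0.05
(inclusive) are replicable. Cell types with exactly two replicates
contribute the same pair every run — the reference distribution is used
regardless, as published.

**Known limitation: the χ²(K) reference is approximate.** Runs reuse the
same replicate samples: with four replicates per cell type, two runs draw
the identical pair with probability 1/6, so the per-run statistics are
positively correlated (pairwise correlation ≈ 1/36 of the squared
statistics). The sum then has mean K but variance ≈ 25 rather than 2K = 20,
and the realized type-I error at the 0.05 threshold is ≈ 0.06 rather than
0.05 (more inflation when many cell types have exactly two replicates,
since those runs are perfectly correlated). The ML df fitted to the sum
remains ≈ 9.9, so the reference is a good description of the bulk; it is the
extreme tail that is slightly heavy. We deliberately do not correct for
this (e.g. by moment-matching an effective df): the published procedure
uses χ²(10), and the filter's purpose is enrichment of real sites, not
exact error control. The acceptance suite reports the honest rejection
rate; users who need calibrated error control should treat alpha as nominal.

The number of runs is itself checkable: `stability_analysis()` combines up
to 20 runs, takes the 20-run replicable set as reference labels, and
computes the AUC of the N-run p-values against them; AUC rises quickly with
N, supporting ~10 runs as the operating point. With `count_in_window()` one
can report how few clusters sit just above the threshold (the published
analysis found essentially none between 0.05 and 0.0505).

## Intensities, batch correction, activity filter

A replicable cluster's intensity in a sample is the −log10 p of its most
significant member peak from that sample, and 0 when the sample contributes
none — zero means "inaccessible" throughout, and the whole normalization
chain preserves zeros exactly. Per-sample scaling divides each column by its
maximum rather than min–max scaling the non-zero range: min–max would map
the weakest detected peak to 0 and conflate it with absence.

Quantile normalization across samples is estimated on a random subsample of
10,000 non-zero sites per sample (sampling non-zero sites only, as absences
carry no distributional information). The reference distribution is the
rank-wise mean of the sorted subsamples — the standard convention; when
subsample sizes differ across samples the sorted vectors are aligned on a
common quantile grid by linear interpolation first. Sampled values map to
the reference at their rank; the remaining non-zero values map through
monotone piecewise-linear interpolation of the sampled (original →
normalized) pairs, clipped to [0, 1] at the extremes. With full subsampling
this reduces exactly to textbook rank-wise-mean quantile normalization
(verified against `limma::normalizeQuantiles` in the tests). Because the
correction is purely rank-based, it removes any monotone per-batch
distortion of intensities — which is also precisely the class of batch
effect the synthetic generator injects, so the batch-removal tests
demonstrate removal of monotone distortions, not of arbitrary batch
structure.

Cell-type values are medians over all samples of the cell type, zeros
included (a site absent in most replicates of a cell type should not look
active there); R's even-count convention (mean of the two middle values)
applies. Finally, sites whose best cell-type median does not exceed 0.25
are dropped — strictly greater, matching the published "higher than 0.25".

## The synthetic benchmark

`simulate_dataset()` emulates what the pipeline assumes about real data:
true regulatory sites (default 2,000) with log-normal lengths (median
310 bp, the published median replicable-DHS length), each active in a
random ~30% of 20 cell types (at least one); every replicate of an active
cell type carries a peak, minus 5% dropout, with boundaries jittered by
N(0, 25 bp) per end; base intensities are uniform on [10, 25] on the
−log10 p scale with 10% multiplicative log-normal noise; each of two
generating centers applies a monotone power/scale distortion
(center 1: identity; center 2: 0.6·x^1.4); replicates alternate centers
round-robin within each cell type so most cell types span batches; and
2,000 spurious peaks per sample are placed at globally non-overlapping
positions, each present in exactly one sample. Chromosome lengths default
to two 60-Mb autosomes, sized so that ~120,000 spurious peaks still fit
without overlap. Everything derives from one master seed; the same
configuration always yields byte-identical files.

What the generator does *not* emulate: correlated neighboring sites,
heavy-tailed intensity distributions, copy-number or mappability artifacts,
partially overlapping composite sites, and non-monotone batch effects.
Passing the end-to-end test (recall ≥ 0.9 of true sites, spurious pass rate
≤ 2×alpha at the default configuration) therefore shows the machinery is
correct under the model's assumptions, not that real consortium data would
behave as cleanly.

## Numerical and design choices

- **Coordinates.** BED-style 0-based half-open internally; GFF3 export
  converts to 1-based inclusive (`start + 1`, `end`). Chromosome names are
  normalized to the `chr` prefix on read; non-autosomal peaks are dropped by
  default.
- **narrowPeak significance.** Column 8 (−log10 p) is the intensity source;
  a `-1` sentinel or a missing column falls back to column 7 (signalValue),
  then 0. Peak counts for QC are taken after autosome filtering.
- **QC boundaries.** Strict inequalities; a sample with exactly 40,000 or
  500,000 peaks is retained.
- **MCL convergence.** Largest entrywise change < 1e-6, capped at 100
  iterations (warning and current partition on cap). Two-node components
  use a scalar reduction of the same iteration (the 2×2 stochastic matrix
  stays symmetric), verified against the dense path.
- **Seeding.** One master seed; stages and runs derive theirs by XOR with a
  fixed offset, so every artifact is bit-reproducible and independent
  stages do not share RNG streams.
- **Problem sizes in the checks.** Calibration tests use 5,000 null
  clusters (df fits, KS) and 20,000 (type-I rate) over 161 cell types × 4
  replicates; the end-to-end check runs the full default configuration
  (~59 samples, ~150,000 peaks). These sizes give Monte-Carlo error well
  below the assertion tolerances while keeping a full test run in ~1-2
  minutes.

```{r calibration, eval = FALSE}
# the acceptance computation, condensed
null <- simulate_null_presence(5000, n_cell_types = 161, n_replicates = 4,
                               seed = 1)
res <- replication_test_presence(null$presence, null$metadata,
                                 n_runs = 10, seed = 2)
fit_chisq_df(res$results$S, interval = c(1, 40)) # ~9.9
```

## Limitations

Beyond the χ²(K) tail approximation discussed above: the per-run statistic
pools presence over cell types and is calibrated when a cluster's presence
probability is exchangeable across cell types; strong per-cell-type margin
heterogeneity within a cluster inflates the pooled statistic (a Simpson-type
effect), which in practice makes the test more willing to keep sites with
structured cell-type activity — acceptable for an enrichment filter,
important to know for error-rate interpretation. The activity filter
operates on normalized medians, so its 0.25 threshold is relative to each
study's intensity distribution, not an absolute accessibility level. MCL on
very long chains of partially overlapping peaks can produce clusters whose
span exceeds a typical site; downstream consumers should treat spans as
union extents, not footprints.
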
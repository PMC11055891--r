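---
title: "rdcscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rdcscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Replication stress concentrates DNA double-strand breaks (DSBs) into
recurrent DNA break clusters (RDCs), preferentially at loci where the
replication fork meets transcription. `rdcscan` implements the computational
chain that connects three measurements into one statistical statement about
those collisions:

1. **Oriented translocation junctions** (LAM-HTGTS). A CRISPR-induced bait
   DSB captures prey DSB ends genome-wide; linear amplification preserves
   whether a prey end was centromere-connected (`Dcen`) or
   telomere-connected (`Dtel`). Single-ended breaks at stalled forks are
   oriented by the fork: rightward-moving forks leave `Dcen` ends,
   leftward-moving forks leave `Dtel` ends.
2. **16-fraction high-resolution Repli-seq.** Sorting S phase into sixteen
   consecutive fractions gives each 50-kb bin a replication-timing profile,
   from which initiation zones (IZ), termination zones (TZ), timing
   transition regions (TTR) and constant timing regions (CTR) are called,
   and fork direction is reconstructed.
3. **Transcription and DNA:RNA hybrid annotation** (GRO-seq RPKM, DRIPc-seq
   strand-specific peaks) to orient collisions and stratify RDCs by hybrid
   load.

The head-on proportion `P_HO` is the fraction of matched-orientation DSBs
falling in compartments where fork and transcription oppose each other;
`P_CD = 100 - P_HO`. A seeded synthetic-data generator plants every ground
truth the pipeline is supposed to recover, and the test suite measures that
recovery.

# RDC calling

Junctions from the non-viewpoint chromosomes (the bait chromosome is
excluded: its `Dcen`/`Dtel` recovery is biased by up to 15--25%, and the
package excludes rather than corrects, matching the source protocol) are
extended symmetrically by 50 kb and piled up on a 1-kb grid, separately for
`Dcen`, `Dtel` and all junctions. The pileup grid is deliberately much finer
than the 50-kb extension: the joining rules below operate at 10-kb
granularity, and a 1-kb grid makes them exact.

For each (chromosome, condition, orientation) stratum a negative binomial
background is fitted by the method of moments: `mu` is the sample mean and
the size parameter solves `var = mu + mu^2/size`. Moments are deterministic,
robust at genomic scale, and recover the simulation truth to within 2%
(mean) and 10% (dispersion) at 10^5 bins. When the sample variance does not
exceed the mean the negative binomial degenerates and a Poisson background
is used. The fit uses *all* bins of the stratum, including candidate peaks;
with RDCs occupying a few percent of the genome the inflation is negligible,
and the choice keeps the background independent of the calling outcome.

Each bin then gets an upper-tail p-value `P(X >= observed)`. Calling applies
the rules in order:

* bins with `p < 0.01`, joined across gaps of at most 10 kb, form **seeds**;
* seeds joined across gaps of at most 100 kb form **islands**;
* islands are extended outward through contiguous bins with `p < 0.1`;
* islands from the three orientation tracks that overlap (or touch
  end-to-start) are merged;
* a merged candidate is kept when it contains at least 100 kb of
  `p < 0.01` bins (in any orientation) and spans at least 300 kb; the call
  is the broadest range of its merged islands.

All gap rules are strict "at most" comparisons in base pairs. No
multiple-testing correction is applied: the thresholds are on raw p-values
by design. The test suite checks every call against an independent
brute-force implementation of the same rules built on boolean bin arrays,
and measures the null behavior empirically: on simulated background-only
100-Mb genomes at the generator's pooled five-condition depth (~10
junctions per 50-kb bin), negative binomial tail clumps spanning several
consecutive bins occasionally chain across the 100-kb island join and
survive the 100-kb/300-kb filters, at a rate of roughly 0.1 calls per
genome. Raw-p thresholding buys sensitivity at the cost of such rare
chance clusters; at single-library depth the same thresholds produce
essentially no null calls but also lack power for 3x enrichments, which is
why the pipeline pools conditions before calling.

A numerical note on verifying the background fit: upper-tail p-values of a
*discrete* distribution are never exactly uniform, so goodness-of-fit is
asserted on the randomized probability integral transform
`u = P(X > x) + V * P(X = x)` (`V ~ U(0,1)`), which is exactly Uniform(0,1)
precisely when the fitted distribution is correct. The caller itself keeps
the conservative non-randomized p-value.

# Corrected S-phase fractions and timing features

Raw Repli-seq matrices are normalized in three steps: per-fraction scaling
to a common depth (reads-per-50M equivalent), Gaussian smoothing along the
genome within each fraction (default s.d. of 1 bin), and per-bin scaling to
unit column sum. All-zero columns mark unmappable bins and stay zero.

Bins are clustered by their 16-vectors into 80 clusters with a BIRCH-style
two-phase procedure written for this package: a single sequential pass in
genomic order absorbs each bin into the nearest leaf centroid within a
distance threshold (the threshold starts at half the median non-zero
distance between adjacent bins and grows only if the leaf budget is
exceeded), then Ward agglomeration of the leaf centroids reduces the leaves
to the requested cluster count. The procedure is deterministic given genomic
input order, which the package fixes. Each cluster's **corrected fraction**
is the argmax over its centroid's 16 components (ties resolve to the
earliest fraction), and every member bin inherits it. Corrected fractions
depend on centroids only, never on cluster labels.

Features are called from the corrected-fraction track:

* **IZ**: a local-minimum plateau (both neighbors later-replicating).
* **small TZ**: a local-maximum plateau of at most 100 kb. Broader maxima
  are left to the neural predictor below -- centroid clustering cannot
  resolve termination zones wider than ~100 kb.
* **late CTR**: a constant run longer than 3 bins at corrected fraction >=
  12 of 16. The "late" cut is configurable; 12 corresponds to the final
  quarter of S phase.
* **TTR**: a maximal monotone chain of plateaus in which any plateau of at
  most 3 equal-fraction bins is tolerated. A 4-bin plateau (or a claimed
  extremum) breaks the chain; the fragment's fraction span extends into the
  breaking plateau when its value continues the trend, so
  `3,4,5,5,5,5,6` yields TTR(3→5), a CTR candidate, and TTR(5→6).
  Ascending chains are rightward TTRs (early→late implies a rightward
  fork), descending chains leftward.

Missing bins break all features. Where definitions overlap, extrema win
over late CTR, which wins over TTR, so the output intervals are disjoint.

# Termination prediction

Reference labels come from OK-seq: replication fork directionality
`RFD = (R - F)/(R + F)` rises through zero at initiation and falls through
zero at termination. A LOESS fit (span default 0.02 of the track, about 20
bins of context on a 1000-bin chromosome) smooths the raw ratio; ascending
zero-crossings anchor IZs, descending crossings anchor TZs, and only IZs
flanked by TZs on both sides are kept. Descending-crossing TZ anchors stand
in for an external OK-seq HMM segmentation: the descending crossing is the
standard termination signature, and on synthetic fork programs the anchors
land within one bin of the planted meeting points.

The predictor itself is a small fully convolutional network over the
16-channel Repli-seq signal: an inception block with 5-, 7- and 9-wide
kernels plus a width-3 max-pool branch, each behind a 1x1 reduction;
concatenation; then 1x1, 1x1 and 1x9 convolutions; SELU activations
throughout and a sigmoid per-bin output. Training minimizes the Dice loss
(the natural choice for the extreme class imbalance of single-bin labels)
with Adam at learning rate 0.001, mini-batches of 32, and 90% dropout on
the concatenated inception features. Windows span 30 bins, tiled with
stride 24 at both the native 50-kb and a 2x-merged 100-kb scale; adjacent
windows share 6 bins of context and the loss is masked to the central 24
bins, so every bin is *scored* exactly once while the network still sees
its neighborhood. Windows qualify for training only when they contain at
least one labeled IZ and one TZ. The forward/backward passes and the Adam
optimizer are implemented in base R linear algebra; training is
bit-reproducible given a seed on single-threaded BLAS.

Default training runs 60 epochs (the cross-validation in the acceptance
suite uses 80); on the synthetic genome used by the tests (a 150-Mb
chromosome, origins every ~2 Mb with firing fractions 1--8, Poisson depth
200 per bin, ~130 windows) 10-fold cross-validation reaches ~0.90 recall
and ~0.96 precision at a 1-bin (50-kb) tolerance, comfortably above the
0.8/0.8 bar the suite asserts. Prediction is fully convolutional: any track
of >= 30 bins is processed in one pass, and meeting points are reported as
local probability maxima above a 0.5 threshold.

# Fork assembly and RDC classification

Each IZ edge connects to the nearest termination anchor on its side: the
interval from the IZ's right edge to the next anchor is a rightward fork
segment, and symmetrically leftward. TTR features contribute segments with
their own direction. Segments shorter than one 50-kb bin are unresolvable
and dropped; an IZ missing an anchor on one side assembles one-sided with a
warning. Technical repeats are intersected base-pair-wise keeping only
same-direction positions ("consensus forks"); the operation is commutative
and again drops sub-bin leftovers.

An RDC is classified by the consensus segments overlapping it by at least
one bin: exactly one rightward and one leftward segment converging =
**inward**; a single direction = **unidirectional**; diverging pair =
**outward**; three or more segments = **complex**; no usable overlap =
**undetermined**. Flags record whether the RDC contains a TTR and whether
it contains a late CTR broader than 500 kb. A heuristic biphasic flag
(two disjoint S-phase bands in >= 20% of RDC bins, local maxima >= 4
fractions apart) is available but off by default -- no formula exists for
it in the source material and it is documented as a heuristic.

# Transcription--replication conflict statistics

Within an RDC, every fork-covered interval overlapping a gene transcribed
at >= 0.05 RPKM is a compartment: **head-on** when fork and transcription
directions oppose, **co-directional** when they agree. The junction
evidence for a compartment is its *matched orientation* -- `Dcen` under
rightward forks, `Dtel` under leftward forks -- because those are the
single-ended breaks that fork direction predicts. Then

```
P_HO = 100 * N_HO / (N_HO + N_CD),   P_CD = 100 - P_HO
```

with junction counts optionally weighted by the off-target library-size
weights (`weight_c = mean off-target count / off-target count of condition
c`, computed over dose-invariant CRISPR off-target regions). Counts
aggregate over all compartments of an RDC before dividing; with equal
matched counts in both compartment classes, `P_HO = P_CD = 50` exactly.

Relative replication speed of a compartment is `Rs = bins / distinct
corrected fractions spanned` -- a geometry-only quantity independent of
junction density. Relative DSB counts across the five aphidicolin doses are
`log2(P_RDC / (sum(P_RDC)/5))` per condition, with a 0.5 pseudocount for
zero numerators (the denominator keeps the true sum). RDC stratification by
co-transcriptional hybrids counts dual-strand DRIPc peaks (a plus-strand
and a minus-strand peak that positionally overlap): the low group is the
0--2 boundary; among all stratified RDCs the upper tertile of counts
(type-7 quantile at 2/3) splits mid from high. Only the 0--2 boundary is
anchored in the source data; the tertile rule is this package's choice and
is configurable. Peak-density comparisons (peaks per 100 kb of gene length,
RDC genes versus active non-RDC genes > 100 kb) use the two-sided
Mann-Whitney test; group comparisons default to the unpaired two-tailed
Student's t-test with pooled variance. Two degenerate t-test inputs are
resolved by continuity: equal constant groups give p = 1, distinct constant
groups (perfect separation) give p = 0.

# The synthetic-data generator

`sim_config()` fixes the study conditions. Defaults: one 100-Mb chromosome
plus a 10-Mb bait chromosome; replication origins every ~2 Mb with firing
fractions drawn once (seeded) from 1--8; fork speed 100 kb per S fraction
(1.8 kb/min over a ~55-minute fraction); 16-fraction signal built as a
Gaussian band of s.d. 1.5 fractions around the true timing, depth 200
Poisson reads per bin; OK-seq depth 100 per bin with expected |RFD| 0.9;
junction background negative binomial with mean 2 and dispersion 5 per
50-kb bin (roughly the per-bin rate of a pooled multi-library experiment);
five dose conditions with per-condition depth factors and fold enrichments
(3x at the top dose); planted RDCs whose junction orientations follow the
local true fork direction with head-on bias theta (head-on compartments
receive `theta/(1-theta)` times the co-directional rate); genes with
configured strand and RPKM; DRIPc dual-strand peak pairs planted per gene;
dose-invariant off-target counts on the bait chromosome. The generator
emits the true timing, fork directions, origin and termination positions
(closed form: the meeting point of two origins is the firing-time-weighted
midpoint), and all planted intervals in a machine-readable truth bundle.

What the generator does *not* emulate: mappability gaps, copy-number
variation, chromatin-state-dependent junction recovery, sequence-level
signal (no reads or alignments -- the pipeline operates on binned signal),
biological replicate variation beyond Poisson/NB sampling noise, and
distance-dependent translocation capture bias. Passing tests therefore
demonstrate the correctness of the algorithms under the stated stochastic
model, not robustness to every artifact of real libraries.

# Problem sizes and runtime choices

The test suite runs at desk scale by choice of problem size, not by
changing any model constant: the RDC recovery property uses three planted
100-Mb genomes and fifty null 100-Mb genomes; the network cross-validation
uses one 150-Mb synthetic chromosome (~130 windows, 80 epochs, 10 folds,
about two minutes on one core); the head-on bias property uses fifty RDCs
with 10^4 junctions each. The pipeline driver (`run_pipeline`) chains all
stages on a synthetic dataset, optionally caching stage outputs keyed by an
input checksum; cached and recomputed results are identical, and reruns
with the same configuration are deterministic.

# Known limitations

* The corrected-fraction clusterer is order-dependent by construction (as
  is classic BIRCH); determinism is guaranteed by fixing genomic order, but
  a different input ordering could shift cluster boundaries slightly.
* TTR fragment boundaries at long plateaus follow the documented
  chain-with-span-extension convention; other conventions (e.g. including
  half the plateau) would shift boundaries by up to the plateau length.
* The biphasic flag is a heuristic and off by default.
* The network's zero-padding means predictions within ~9 bins of a contig
  edge see partial context; the tiling scheme only scores interior bins
  during training, but edge bins of short contigs are genuinely less
  reliable.
* `P_HO` aggregates junctions over all compartments of an RDC before
  forming the proportion (aggregate-then-divide); per-compartment averaging
  is a defensible alternative that weights short compartments more.
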
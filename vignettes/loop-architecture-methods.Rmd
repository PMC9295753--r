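---
title: "Methods: loop architecture statistics and their synthetic test bed"
author: "loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop architecture statistics and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

## Scope and model

`loopscape` analyzes chromatin loops downstream of loop calling. A loop is
an ordered pair of genomic intervals (anchors) on one chromosome, labelled
by the histone mark that directed the conformation-capture pulldown
(H3K27me3 for Polycomb loops, H3K27ac for enhancer-associated loops). All
coordinates are 0-based, half-open (BED convention); a shared endpoint is
not an overlap, zero-length intervals are rejected at parse time rather
than silently dropped, and strand is ignored throughout — none of the
supported analyses is stranded.

The package answers five families of questions:

1. How far apart are loop anchors, and how do the distance and
   TAD-crossing distributions differ between loop classes?
2. Are PRC2 features (EZH2 peaks, nucleation points) enriched at anchors,
   and does that enrichment grow with loop span?
3. What does a single viewpoint's interaction profile look like in a
   binned contact map (virtual 4C), and how concordant or conserved are
   two loop sets?
4. At single-cell resolution, how often are two imaged loci in contact,
   and does a genotype change the distance distribution?
5. After an anchor deletion, which differential histone-signal sites lose
   signal, and how does loss stratify by EZH2 occupancy and A/B
   compartment?

## Conventions that needed a decision

**Anchor distance.** Published loop tables rarely state whether "distance
between anchors" is midpoint-to-midpoint or edge-to-edge. Both are
implemented (`anchor_distance(convention =)`); midpoint is the default and
the convention is carried in every summary object, so it is always logged.
For equal-width, non-overlapping anchors the midpoint distance is never
smaller than the inner-edge distance.

**TADs "between" anchors.** `tads_crossed()` counts TADs fully contained
in the interior `[end1, start2)`. Containment is the only reading that is
reproducible across TAD callers: a TAD straddling an anchor would be
counted by some overlap rules and not others, while "between" naturally
means the interior. The rule is recorded in the summary metadata
(`tad_rule`).

**Top percentile.** "Top percentile of loops ranked by X" is the
`ceiling(p * n)` loops with the largest X, with `p = 0.01` by default and
the distance and TAD rankings computed independently. Medians of
even-length samples use the midpoint rule.

**Nucleation classification.** Restricted to loops spanning strictly more
than `min_distance` (default 1 Mb, the scale above which Polycomb loops
distinguish themselves). Reported are the fraction of loops with at least
one nucleation-point anchor and, among those, the fraction with exactly
one — both readings of "X% had a nucleation point at only one anchor" are
therefore recoverable.

**Contact.** Imaging contact is strictly `distance < 150 nm`; a cell at
exactly the threshold is not a contact. Only cells with both barcodes
localized enter a pair's statistics (pairwise-complete, no imputation);
the informative and excluded counts are both reported so either
denominator can be audited.

**Differential significance.** Strict on both sides: `|log2FC| > fc_cut`
and `padj < p_cut`. A site at exactly the cutoff is not significant, and a
missing adjusted p (independence-filtered row) is never significant. The
same code path serves histone-signal tables (`fc_cut = 1`) and
differential EZH2 peak tables (`fc_cut = 0.5`).

## Statistical machinery

**Wilcoxon rank-sum.** `rank_sum_test()` is self-contained. When
`choose(n1 + n2, n1)` is at most 2e5 it enumerates every assignment of the
pooled average ranks to the first sample — valid under ties — and doubles
the smaller tail (capped at 1), so fully tied data give p = 1 exactly.
Larger samples use the normal approximation with tie-corrected variance
and a 0.5 continuity correction. The exact path is verified in the test
suite against full enumeration for all `n1 + n2 <= 10` and against
`stats::wilcox.test` on tie-free data; the normal path is calibrated on
1,000 null simulations at `alpha = 0.05`.

**Loess.** The overlap-versus-distance trend is a degree-1 local
regression with tricube weights over the nearest `ceiling(span * n)`
points (span 0.6 by default), implemented directly so that fits are
bit-reproducible and exactly equal ordinary least squares at span 1 on
linear data. Overlap is fit on log10 distance; fitted fractions are
clamped to [0, 1]. The 95% CI is a percentile bootstrap over loops
(default 200 seeded resamples) — the CI method is a package choice, since
figure captions of the kind this analysis reproduces state a CI but not
its construction.

**Fisher exact test.** Stratified 2x2 summaries (significant-down versus
not, EZH2-occupied versus not) use `stats::fisher.test` (two-sided,
point-probability method); the test suite checks it against direct
hypergeometric enumeration.

**Enrichment units.** `aggregate_profile()` divides the per-bin signal
mass by the per-bin covered base pairs and by library depth in millions,
yielding normalized library depth per base pair per anchor. Windows
truncated at chromosome ends contribute only covered bases; the profile is
invariant to how the bedGraph fragments its runs, and doubling the library
depth exactly halves the values.

**Virtual 4C.** Rows of the sparse symmetric matrix over all viewpoint
bins are summed cis-only and scaled by 1e6 / total filtered read pairs.
Self-interaction bins are reported but flagged. Optional smoothing is a
centered running mean over an odd number of bins with partial windows at
the ends; with smoothing off, profile mass exactly equals the scaled row
sum.

**Loop matching.** Two loops match when both anchor pairs overlap after
symmetric extension by `slack_bp` (default one 10-kb bin, matching typical
loop-calling resolution). Assignment is greedy one-to-one by ascending
combined midpoint offset, ties broken by leftmost coordinate, so shared
fractions are well-defined; the same machinery serves caller concordance
and cross-species conservation (coordinate mapping between genomes is
upstream of this package).

## The synthetic test bed

The generators produce every input the pipeline consumes, plus
ground-truth manifests, so downstream statistics are tested by parameter
recovery rather than against fixtures.

* **Genome.** Six chromosomes, ~1 Gb total. The scale is a deliberate
  compromise: large enough that independently placed anchors rarely
  collide (planted anchor flags stay recoverable by overlap; on a toy
  ~100 Mb genome the collision bias is substantial), small enough that
  everything runs in seconds. Locus-scale analyses (contact matrices) use
  a dedicated 40-Mb region genome at 25-kb bins so that cis bin-pair
  enumeration stays in the low millions.
* **Loops.** H3K27ac-class distances are log-normal (median 200 kb,
  sdlog 0.6 — enhancer-promoter scale); H3K27me3-class distances mix a
  log-normal body (median 500 kb, sdlog 0.8) with a 15% Pareto tail
  (minimum 1 Mb, shape 2), giving the asymmetric, long-tailed distribution
  characteristic of Polycomb loops, with the realized top-percentile
  median several-fold above the short class's. Anchors are 10 kb wide and
  placed uniformly subject to fitting on a length-weighted chromosome;
  the realized midpoint distance equals the drawn distance exactly, so
  summary medians can be checked against the manifest to the bit.
  Nucleation flags are planted on the H3K27me3 class only (they are PRC2
  features), with P(both anchors) = 0.25 and P(exactly one) = 0.37 —
  echoing the observation that ~62% of Polycomb loops over 1 Mb carry at
  least one nucleation point.
* **TADs and compartments.** Gamma-distributed TAD sizes (shape 4) around
  1 Mb tile each chromosome without gaps; A/B compartments alternate over
  whole TADs, so every compartment boundary is a TAD boundary.
* **Contact maps.** Expected counts decay as `(1 + |i − j|)^-1` with an
  8x multiplicative dot at planted anchor bin pairs; counts are Poisson
  with the depth parameter as expected total, and the realized total
  filtered read pairs is recorded on the object.
* **Signal tracks.** Constant background plus a symmetric triangular bump
  per peak, discretized into an even number of steps so the bump integral
  is exactly `height x width / 2`; Poisson noise is optional.
* **ORCA traces.** Per cell, a 3D Gaussian-step polymer over the ordered
  barcodes (per-axis step sd 600 nm, giving WT pair distances in the
  hundreds-of-nanometres range of real chromatin tracing); designated
  pairs are resampled uniformly inside the 150-nm contact ball with their
  planted probability; barcodes drop out independently. The demo cohort
  sizes (2,190 WT and 520 mutant cells) and planted WT contact
  probability (0.4) mirror the imaging experiment this pipeline is built
  to analyze.
* **Differential tables.** Sites lacking EZH2 occupancy and sharing the
  deletion's compartment receive `-effect_size` plus N(0, 0.25) noise and
  small adjusted p; all others are null with uniform adjusted p. This is a
  post-fit table — replicate-level counts and the negative-binomial fit
  itself are out of scope.

What the generators do **not** emulate: correlated barcode dropout,
ChIP/pulldown efficiency, matrix-balancing artifacts, read-level noise,
genuine evolutionary coordinate mapping (conservation tests jitter loops
in one coordinate system), or dependence between a loop's distance and its
nucleation status. Passing recovery tests therefore demonstrates that the
statistics measure what they claim under the stated sampling models — not
that real data meet those models.

All generators pin the RNG (Mersenne-Twister, inversion normals, rejection
sampling) so a fixed seed is bit-reproducible across platforms.

## Numerical and degenerate-input choices

* Interval queries run against exhaustive nested-loop oracles in the test
  suite (and against GenomicRanges as an independent implementation).
* Empty loop sets refuse to summarize; overlap curves with fewer than 10
  points return raw points without a fit; zero informative ORCA cells are
  an error rather than NaN.
* Loess grid points with zero bandwidth (duplicated x) fall back to the
  local mean; a degenerate weighted regression falls back to slope 0.
* A deletion spanning a compartment boundary takes the label at its
  midpoint, with a warning.
* Abutting anchors have inner-edge distance 0 and cross 0 TADs.

## Pipeline and problem sizes

`run_pipeline()` drives generation and every analysis stage, writing
per-stage tables, `summary.json` and a manifest (seed, package version,
all parameters, input checksums). Stage seeds derive from the master seed
by fixed offsets; identical config and seed give byte-identical output.
The demo configuration (1,000 loops per class, 5e6 read pairs at 25 kb
over a 40-Mb region, 2,710 imaged cells, 300 differential sites, 50
bootstrap resamples) was chosen so a full run takes tens of seconds on one
CPU; the class contrasts it measures are already decisive at that scale,
and the acceptance checks are recovery-based rather than dependent on
large n.

## Known limitations

* Greedy one-to-one matching is not maximum bipartite matching; in dense
  loop sets where several loops fall within one slack radius, the shared
  fraction can be slightly conservative.
* The per-anchor mode of the overlap-distance curve deduplicates anchors
  by exact coordinates; anchors that differ by a few base pairs between
  loops are treated as distinct.
* Virtual 4C is cis-only by design; trans contacts in the input are
  ignored.
* The contact-matrix generator enumerates all cis bin pairs, which bounds
  practical resolution (use region genomes for fine bins).
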
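---
title: "Methods: integrating and classifying differential chromatin loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating and classifying differential chromatin loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopweaver)
```

## Scope and assumptions

`loopweaver` starts where the upstream callers stop.  It assumes

* differential loop calls per resolution (1/5/10 kb) with per-loop
  p-values and signed fold-changes, produced by a differential-contact
  model run on matched contact maps;
* Hi-ChIP loop calls at 1 kb for the *control* condition only — which is
  why only knockdown-*lost* (downregulated) loops can be classified as
  direct or indirect: there is no Hi-ChIP evidence to interrogate for
  loops that appear after depletion;
* balanced contact matrices (any matrix-level normalization is assumed
  done upstream).

All interval arithmetic is 0-based half-open; "overlap" always means at
least one shared base pair.  Loop records are cis by construction (trans
rows are rejected at parse time), canonically ordered
(`start1 <= start2`), and deduplicated on the coordinate 5-tuple, keeping
the smallest p-value among metadata ties.

## The conventions that matter

### Harmonized 10 kb windows

Anchors called at different resolutions cannot be intersected directly: a
1 kb anchor of the same underlying contact would almost never touch its
10 kb counterpart's boundaries.  Every cross-set comparison therefore
widens anchors symmetrically to a common window — `(window − width)/2` of
slop per side, i.e. ±4500 bp for 1 kb and ±2500 bp for 5 kb anchors at the
default 10 kb window, clipped at chromosome ends.  We apply the same
widening to the 1 kb Hi-ChIP anchors so that both sides of the comparison
use 10 kb windows; widening only one side would make the direct/indirect
call asymmetric in a way that is hard to justify.  The choice is
switchable (`slop_hichip = FALSE`).

### Consensus merging across resolutions

`merge_multiresolution()` expands all anchors to the *coarsest* input
resolution, connects loops whose expanded windows overlap at both ends
(in either orientation), and takes connected components as consensus
clusters.  Expansion-to-coarsest makes the overlap relation symmetric
across resolutions and reuses the same windowing logic as classification.
Each cluster is represented by its finest-resolution member — the most
precise available coordinates — with ties broken by smallest p-value,
then leftmost coordinates.  The exact tie-breaking of merge tools in
circulation varies; ours is deterministic and documented, and the merge
result is invariant to the order in which the input sets are given
(property-tested).

### Loop size

Loop size is the distance between anchor midpoints, in bp.  The
alternative — outer span `end2 − start1` — systematically adds one anchor
width and makes sets called at different resolutions incomparable, so
midpoint distance is the default and the outer span is available behind
`loop_span(..., method = "ospan")` for sensitivity checks.

### Direct vs indirect

A downregulated loop is *direct* when at least one Hi-ChIP loop of the
same factor matches it under the both-ends predicate on harmonized
windows, *indirect* otherwise.  The rule is monotone (more Hi-ChIP
evidence can only promote loops to direct), is invariant to anchor order
on either side, and partitions the input exactly.  Upregulated loops are
never classified.

### RDD normalization

roX2-RDD loops have variable anchor widths (kb to tens of kb), so before
any comparison both sides are snapped to a uniform 5 kb grid: each anchor
is replaced by the grid bin containing its midpoint (grid anchored at
coordinate 0, matching binned-matrix conventions).  Loops whose two
midpoints collapse into one bin are dropped and counted; duplicates
created by snapping are collapsed and counted.  Snapping is idempotent at
the target resolution.

### Chromatin states

State annotation is restricted to 1 kb loop calls (wider anchors span
several segments of the ~kb-scale segmentation and make "the anchor's
state" meaningless); `force = TRUE` overrides with eyes open.  Two
conventions are provided: either-anchor association (a loop counts once
per distinct state any anchor touches) and unordered anchor state *pairs*
(the Cartesian product of the two anchors' state sets, stored min-first —
orientation of a cis pair carries no information here).  Anchors covering
no segment receive an explicit reserved label (state 0, "unassigned")
rather than being dropped silently.  A loop is assigned to chrX when both
anchors are on chrX, which the cis invariant makes total.

## Statistics

* **Fisher exact (2×2), two-sided** by the probability-mass rule: the sum
  of hypergeometric probabilities not exceeding the observed table's
  (with the conventional 1 + 1e-7 relative slack); a doubling-rule
  variant is available.  Raw p-values are primary — the integration
  tables threshold raw p — with Benjamini–Hochberg q-values always
  co-reported.
* **Mann–Whitney U** from midranks.  The p-value is exact whenever
  n₁·n₂ ≤ 400, via the distribution of the rank sum over all
  C(n₁+n₂, n₁) group assignments, computed by a Streitberg–Røhmel-style
  generating-function recursion on doubled midranks (ties handled
  exactly); otherwise a normal approximation with tie and continuity
  correction.  The exact two-sided p doubles the smaller tail (capped at
  1).
* **Printed percentages** use half-away-from-zero rounding, which is what
  reproduces values like 85.71 or 31.62 from their integer counts;
  banker's rounding does not.

## Aggregate peak analysis

Windows of (2·flank+1)² pixels are extracted around loop pixels (or
around all same-chromosome site pairs within a separation band), skipped
— never zero-padded — when they would cross the matrix edge, optionally
normalized pixel-wise by expected contact at each pixel's own separation,
and averaged.  The enrichment score is the central pixel of the mean
window over the mean of its four corner blocks (default 3×3), the least
loop-contaminated region of the window; both the raw ratio and its
natural log are reported, since both conventions circulate.

**Expected model.**  The per-diagonal *median* is the default expected
estimator, not the mean.  On desk-scale matrices (hundreds of bins) the
planted or real loop pixels occupy a non-negligible fraction of a
diagonal, and the mean is inflated by exactly those pixels the pile-up is
trying to measure, biasing obs/exp downward.  The median of a diagonal is
exact under the noise-free decay model whenever enriched pixels are a
minority, and nearly unbiased under Poisson noise.  The per-diagonal mean
remains available (`expected_stat = "mean"`) and is the better choice for
genome-scale matrices where the loop fraction per diagonal is vanishing.

## The synthetic study

`simulate_study()` generates every input the pipeline consumes, with
recorded ground truth.  Default conditions: two 2 Mb chromosomes (chrX
and chr2L), two factors, 100 significant loops per resolution per
direction per factor (300 down-loops per factor), 40% of down-loops
direct, 30 non-significant decoys per comparison, a 9-state tiling with
2–10 kb segments and state 5 restricted to chrX, 200 genes with 40% of
chrX genes planted on state-5 segments, 24 HAS (half at direct-loop
anchors), a 20% planted RDD overlap among chrX direct loops plus 60
background RDD loops with 2–12 kb anchors, and 5 kb contact matrices with
contact `base·(1+|i−j|)^(−α)` (α = 0.85, base = 1000) times a planted
factor e = 3 at loop pixels, with optional Poisson resampling.

**Geometry.**  Anchors sit on per-chromosome lattice "sites" spaced
11–11.8 kb; loops connect nearby sites (spans ~11–35 kb, matching the
kb-scale medians typical of TF-anchored loops).  Because harmonized
windows are 10 kb wide and centred on anchors, sites further apart than
the pitch can never produce a spurious both-ends overlap, so consensus
counts equal planted counts exactly.  Direct loops receive a Hi-ChIP twin
jittered by < 4.5 kb per anchor plus a ChIP peak inside an anchor;
indirect loops are placed at least two pitches (> 22 kb) away from every
Hi-ChIP anchor and peak.  This 15 kb-plus exclusion makes label recovery
exact by construction, which is what turns classification, DC-gene and
state-pair recovery into sharp tests (`hard = TRUE` shrinks the gap for
stress testing).  RDD partners are planted bin-identical to a chosen
subset of direct loops, and background RDD loops are rejection-sampled
away from every down-loop bin pair, so the planted overlap fraction is
recovered with zero tolerance.

**What it does not emulate.**  Read-level noise and caller variability
(p-values are drawn, not estimated); loop-density heterogeneity —
real genomes are not lattices, and at this density (four 300-loop sets on
4 Mb) *cross-factor* union overlaps are necessarily large, unlike the
sparse overlaps seen genome-wide; distance-dependent loop strength;
biological loop extrusion.  Passing tests therefore demonstrate the
correctness of the integration conventions, not the biology of any real
dataset.

A separate APA fixture (`simulate_apa_fixture()`) plants loops at a fixed
separation with stride exceeding the pile-up flank, so no window contains
another loop's pixel; with noise off the recovered central-pixel ratio
equals the planted enrichment exactly, which the default study — where
chained loops share anchors and contaminate each other's windows — cannot
and should not guarantee.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: the default 300-down-loop
study, a 100-loop three-resolution merge fixture, 200-window APA fixtures
on 1 kb/2 Mb matrices, exhaustive Fisher validation over all 2×2 tables
with N ≤ 40 (~135k tables), Mann–Whitney enumeration up to n₁ = n₂ = 8,
and 1,000 null simulations at n = 20 + 20 for type-I calibration.  These
sizes keep a full run in minutes on one core while leaving every
guarantee sharp (exact recovery, exhaustive enumeration).

## Known limitations

* `pair_to_bed`/`pair_to_pair` are backed by interval trees via
  GenomicRanges; worst-case quadratic output (everything overlapping
  everything) is inherent to the operation, not the implementation.
* The Fisher 2×2 universe for cross-factor overlap tables is the pooled
  consensus loop count; other universes (all tested bin pairs) are
  defensible and would change p-values, though not the overlap
  percentages.
* Mann–Whitney exact enumeration is capped at n₁·n₂ ≤ 400; beyond that
  the corrected normal approximation is used.
* Contact-matrix I/O covers the dense per-chromosome TSV dialect;
  cooler-container input should be converted upstream (e.g.
  `cooler dump`).
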
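---
title: "Broad epigenomic domains: models, parameters, and design choices"
author: "broadomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broad epigenomic domains: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadomains)
```

This vignette is the package's own account of the methods it implements:
what each stage computes, which parameters matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## Coordinates and interval algebra

All file formats consumed and emitted (BED3/6, narrowPeak, broadPeak,
bedGraph) are 0-based half-open; in memory every region is an ordinary
`GRanges` (1-based closed), and conversion happens only at the I/O
boundary. Chromosome names are opaque strings — `"chr1"` and `"1"` are
different chromosomes — because silent alias resolution is a common source
of irreproducibility. Merging uses a `gap` rule: two intervals join when
the space between them is at most `gap` bp, so bookended intervals merge
at `gap = 0`; the rule is transitive. Overlap requires at least 1 shared
base by default (`min_overlap` is configurable); under the half-open
convention, intervals that merely touch do not overlap.

## Super-enhancer calling

The caller follows the ranked-ordering recipe: stitch H3K27ac peaks,
score stitched regions by input-corrected signal area, rank, and place a
cutoff where the ranked curve turns upward.

* **`stitch_gap`** (bp, default 12 500). Two stitching windows are in
  common use for this analysis, 5 000 and 12 500 bp, and the underlying
  literature is not consistent about which was used where. The package
  privileges neither: 12 500 is the default and 5 000 is one argument
  away. On the synthetic panel the planted regions are separated by twice
  the stitch gap, so the choice does not affect recovery there.
* **TSS exclusion** is off by default; when a TSS set is supplied, peaks
  fully inside TSS ± `tss_flank` (default 2 500 bp) are removed before
  stitching. Promoter-proximal H3K27ac otherwise inflates stitched-region
  scores.
* **Scoring**: `max(0, area(treat) − area(input))`. Clipping at zero keeps
  ranks meaningful when input exceeds treatment (unsequenced or blacklisted
  regions); the clip affects only regions that would rank at the bottom
  anyway.
* **Cutoff**: with scores ascending, both axes are scaled to [0, 1] and
  the discrete slope between consecutive points is scanned from the left;
  the cutoff is the (unscaled) score at the first segment with slope > 1,
  and super-enhancers score strictly above it. This construction is
  invariant under positive rescaling of the scores and fully
  deterministic; no tangency optimization is attempted, matching common
  reimplementations. A flat curve (all scores equal) yields no
  super-enhancers and a warning. Cutoffs are computed per sample: a single
  global cutoff across samples would mix library depths, and nothing in
  the method requires one.

## Broad H3K4me3 domains

The width-percentile rule keeps exactly `ceiling(top_fraction × n)` peaks
(default `top_fraction = 0.05`, the "top 5% by domain size" convention).
Ties at the threshold width are broken by chromosome and start coordinate,
ascending, so the output is reproducible; the count law holds for every
`n ≥ 1`.

## Grade classification across a panel

Union regions are the merged concatenation of all samples' domain sets at
`merge_gap = 0` — a larger gap would chain unrelated domains into one
union region and distort occupancy. A region is **common** when every
sample overlaps it. For grade-unique calls the field's phrase "unique to"
a group is genuinely ambiguous, so the rule is parameterized: present in
at least `min_in_group` samples of the group (`"all"` by default, the
strictest reading) and at most `max_in_other` (default 0) of the other.
Relabeling the groups swaps HGU and LGU exactly, which the tests assert.
Cross-type overlap (broad H3K4me3 × super-enhancer, per category) uses
≥ 1 bp, as no overlap fraction is standard here.

## Differential enrichment

The package deliberately uses a transparent plumbing statistic rather than
wrapping a count-model package: replicates are pooled per condition and
each region's pooled counts (tᵢ, cᵢ) are tested with an exact two-sided
binomial test of tᵢ successes in tᵢ + cᵢ trials against a null treated
proportion p₀.

The choice of p₀ is the one place where a naive reading fails. Setting
p₀ = T/(T+C) from the pooled totals is correct only when enrichment
changes are balanced between directions: a minority of genuinely changed
regions shifts T, biasing *every* null region's test and inflating the
false-discovery proportion well beyond its nominal level. The default is
therefore a robust estimate, `p₀ = m/(1+m)` with
`m = exp(median(log(tᵢ/cᵢ)))` over regions with counts in both conditions
— the same median-of-ratios idea used for library-size estimation in
count-based differential expression, insensitive to a minority of changed
regions. The median is taken on the log scale so that swapping the
condition labels maps the estimate to exactly `1 − p₀` for any number of
regions, which makes label-swap antisymmetry of the fold-changes and
invariance of the p-values exact. `normalization = "library-size"`
restores the pooled-totals null for externally calibrated designs.

The fold-change is `log2(((t+1)/(c+1)) / (p₀/(1−p₀)))`: pseudocount 1 in
the fold-change only, never in the test, so zero counts cannot produce
infinite estimates while inference stays exact. FDR is Benjamini–Hochberg;
direction is assigned only below the FDR threshold (default 0.1, the
conventional cutoff for this analysis). A region with no counts at all is
reported unchanged with p = 1.

Location labels follow the precedence promoter > intragenic > distal
intergenic, with a strand-aware promoter window of −2 000/+500 bp around
the TSS (no standard window exists; both bounds are arguments). Gene
assignment links every TSS within 100 kb of the region's edges, distance 0
when the TSS is inside. Expression comparisons between categories use
Welch's unequal-variance *t*-test on per-gene log₂ fold-changes, with the
degenerate constant-vector cases defined explicitly (equal constants:
p = 1; unequal constants: p = 0).

## TAD calling and boundary enrichment

The caller is a simplified diamond-statistic method in the TopDom style.
For each inter-bin gap the **bin signal** is the mean of the w×w diamond
of contacts spanning the gap (default `w = 5`, TopDom's own default; the
value used in the source analyses of this kind is typically unreported).
Candidate boundaries are strict local minima; each must additionally pass
a one-sided rank-sum test of its diamond cells against the pooled diamond
cells of the `w` flanking gaps on each side at p < 0.05. The original
method's piecewise-linear fitting step is intentionally not reproduced:
the simplified caller is fully specified, testable, and recovers planted
block structure, at the cost of occasionally splitting a very wide domain
under noise (the permutation machinery downstream is insensitive to an
extra boundary or two).

Domains shorter than `min_domain_bins` (default 2) are absorbed into a
neighbor. The absorption removes the *weaker* of the short domain's two
junctions — the one with the larger bin signal, i.e. the shallower
minimum — keeping the better-supported boundary. Matrix bins are 40 kb by
default, the conventional resolution for boundary analyses of this kind.

Boundary **enrichment** compares the number of features overlapping any
boundary region (boundary bin ± 20 kb flank; the flank is anchored on the
bin's outer edges, `[bin_start − flank, bin_end + flank)`, stated
explicitly because the anchor is ambiguous in prose descriptions) against
permutations that draw the same number of bins uniformly without
replacement and flank them identically. The number of drawn bins defaults
to the number of boundary bins ("auto"): drawing a dataset-specific
constant such as 8 354 bins only makes sense for the dataset it came from,
but any fixed count remains available via `n_bins_drawn`. The empirical p
uses the add-one rule, `(1 + #{perm ≥ obs})/(n_perm + 1)`, which is never
zero and unbiased; 1 000 permutations give a resolution floor of
1/1001 ≈ 10⁻³. The z-score is reported alongside for effect size. All
permutations derive from a single seed and restore the caller's RNG state.

## The synthetic-data generator

`simulate_panel()` emulates a seven-sample panel (3 High-Grade, 4
Low-Grade) with planted common/HGU/LGU regions for both domain types,
background typical peaks per sample, and multiplicative log-normal signal
noise (`noise_sd` on the log scale; ratio-scaled noise is the natural
model for ChIP enrichment). Key guarantees:

* placements sit on a slot grid separated by at least twice the stitch
  gap, so stitching can never merge two distinct planted truths and
  recovery tests are well-posed;
* a configurable number of planted regions per category coincide across
  the two domain types (for cross-type overlap analysis); all other
  placements are disjoint;
* planted regions are wide (8–20 kb) with `signal_contrast` × baseline
  signal (default 20), background peaks narrow (0.8–2.5 kb) at baseline;
* every generator is bit-reproducible given its seed and emits standard
  formats re-readable by the package's own readers.

`simulate_contact_matrix()` plants block-constant TADs with a
within:between contrast (default 10) and log-normal noise, symmetrized.
`simulate_treatment()` draws Poisson counts per region and replicate with
planted fold-changes in configurable fractions of regions;
`simulate_expression()` shifts per-gene log₂ fold-changes by category.

What the generator does **not** emulate: read-level sampling and
fragment-size effects, mappability and blacklist artifacts, copy-number
variation between cell lines, peak-edge uncertainty (planted edges are
exact), distance-decay within TADs, and correlated replicate noise.
Passing recovery tests on this generator therefore demonstrates the
correctness of the algorithms under their stated models — not robustness
to every artifact of real ChIP-seq or Hi-C data.

## Problem sizes and numerical choices

The bundled test-and-acceptance configuration uses panels of ~2 400
placed regions, 2 000-region count tables with two replicates per
condition, 100–140-bin contact matrices, and 200–1 000 permutations;
these sizes make every planted structure recoverable while keeping a full
run in seconds on one core. Scores and signal values are doubles
throughout; counts are integers; the contact-matrix symmetry tolerance is
10⁻⁶ (inputs are averaged with their transpose after validation). Ranking
ties anywhere are broken by genomic coordinate. The exact binomial test is
`stats::binom.test`; rank-sum filtering uses `stats::wilcox.test` with its
normal approximation when ties occur.

## Known limitations

* The differential statistic models pooled counts; it does not estimate
  per-region overdispersion, so biological replicate variability beyond
  Poisson is not propagated (a count-model package should be used when
  replicate variance matters).
* The TAD caller reports a single segmentation; nested or overlapping
  domain hierarchies are out of scope, as are inter-chromosomal contacts
  and matrix normalization itself (a normalized matrix is the input
  contract).
* Enrichment permutations randomize bins uniformly; they do not preserve
  feature clustering or chromosome-end effects beyond the bin grid.
* Gene assignment is distance-based (100 kb windows), not
  regulatory-domain-based; it will link genes across insulated
  neighborhoods.
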
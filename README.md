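# broadomains

Analysis of **broad epigenomic domains** across tumor-grade cell-line
panels: super-enhancer calling, broad H3K4me3 domain calling,
grade-specific domain classification, differential ChIP-seq enrichment
under drug treatment, TAD detection from chromatin-contact matrices, and
permutation enrichment of features at TAD boundaries. A seeded
synthetic-data generator with planted structure makes the entire pipeline
testable end-to-end without any external downloads.

The package is aimed at epigenomics analysts working with panels of cell
lines (for example pancreatic ductal adenocarcinoma lines split into
High-Grade, mesenchymal, and Low-Grade, epithelial groups) who have peak
calls and signal tracks in BED-family formats and a normalized
intra-chromosomal contact matrix, and who want a deterministic, scriptable
re-implementation of the standard broad-domain toolchain.

## Methods at a glance

- **Super-enhancers** (ranked ordering of stitched enhancers). H3K27ac
  peaks within a stitching window *g* (default 12.5 kb; 5 kb also in common
  use) are merged; each stitched region is scored by input-corrected signal
  area, `s = max(0, area(treat) − area(input))`. With scores sorted
  ascending and both axes scaled to [0, 1] (`x = rank/n`,
  `y = s/max(s)`), the cutoff is the score at the first segment of the
  ranked curve whose discrete slope Δy/Δx exceeds 1; regions above the
  cutoff are super-enhancers.
- **Broad H3K4me3 domains**: the top 5% of peaks by width (exactly
  `ceil(0.05 n)`, ties broken by coordinate).
- **Grade classification**: union regions across the panel (merged at gap
  0) with binary occupancy per sample; a region is *common* when present in
  every sample, *HGU*/*LGU* (High-/Low-Grade unique) when present in the
  required number of one group's samples and at most `max_in_other` of the
  other's. The two domain types are then overlapped per category (≥ 1 bp).
- **Differential enrichment**: replicates pooled per condition; for region
  *i* with pooled counts (tᵢ, cᵢ), an exact two-sided binomial test of tᵢ
  in tᵢ+cᵢ trials against a null treated proportion p₀ estimated by a
  robust median-of-log-ratios rule (library-size pooling available as an
  option), Benjamini–Hochberg FDR, direction called at FDR < 0.1.
  Genomic-location labels (promoter > intragenic > distal intergenic),
  gene assignment within 100 kb of region edges, and Welch's *t*-test
  between per-category expression log₂ fold-changes complete the module.
- **TADs**: a simplified TopDom-style caller — the mean contact frequency
  in a w×w diamond at each inter-bin gap (default 40-kb bins, w = 5),
  strict local minima filtered by a one-sided rank-sum test against the
  flanking diamonds, domains as maximal runs between boundaries.
- **Boundary enrichment**: observed feature count at boundary bins ± 20 kb
  versus a null built by drawing the same number of random bins (without
  replacement) 1000 times; empirical p via the add-one rule
  `(1 + #{perm ≥ obs}) / (n_perm + 1)` and a permutation z-score.

## Worked example

```r
library(broadomains)

panel <- simulate_panel(n_common = 12, n_hgu = 10, n_lgu = 16,
                        n_background = 60, seed = 42)

rrs <- call_super_enhancers(panel$marks$H3K27ac$peaks$High1,
                            panel$marks$H3K27ac$tracks$High1)
rrs
#> RankedRegionSet: 82 regions, 22 super-enhancers (cutoff score 2497)
head(ranked_table(rrs), 3)
#>    chrom    start      end    score rank is_super
#> 19  chrD  3105000  3124809 507480.0   82     TRUE
#> 82  chrB 57375000 57392999 493820.7   81     TRUE
#> 15  chrC 55980000 55999287 475599.8   80     TRUE

mm <- build_membership(sample_panel(panel$marks$H3K27ac$peaks, panel$groups))
table(classify_regions(mm))
#> common    HGU    LGU  other
#>     12     10     16    420
```

The 22 super-enhancers are the planted high-signal clusters present in a
High-Grade sample (12 common + 10 HGU); the classification across all
seven samples recovers the planted 12/10/16 common/HGU/LGU design, with
the 420 per-sample background peaks labelled `other`.

```r
sim  <- simulate_contact_matrix(tad_sizes = c(12, 8, 20, 10, 15), seed = 42)
tads <- call_tads(sim$cm)
tads
#> TADSet: 6 domains, 5 boundaries on chr1 ( 65 bins of 40000 bp )
ctcf_like <- GenomicRanges::GRanges("chr1",
  IRanges::IRanges(tads$boundary_bins * 40000 + 1001,
                   tads$boundary_bins * 40000 + 3000))
boundary_enrichment(ctcf_like, tads, seed = 1)
#> EnrichmentResult: observed 5 vs expected 0.76 (sd 0.74), z = 5.76,
#>   empirical p = 0.000999 (1000 permutations of 5 bins, seed 1)
```

All four planted domain junctions (bins 12, 20, 40, 50) are recovered; the
widest domain is additionally split once by noise, a known behavior of
diamond-statistic callers. Boundary-placed features reach the smallest
attainable empirical p at 1000 permutations, 1/1001 ≈ 0.000999.

The same stages run from the shell via the bundled wrapper:

```sh
Rscript inst/scripts/broadomains-cli.R all --outdir out --seed 1
```

which writes super-enhancer and broad-domain BEDs, the membership matrix
and category counts, the differential-region table, TAD and boundary BEDs,
and the enrichment table, plus the resolved YAML config; reruns with the
same config and seed are byte-identical.

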
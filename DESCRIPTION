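Package: broadomains
Title: Broad Epigenomic Domain Analysis Across Tumor-Grade Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls super-enhancers by ranked ordering of stitched H3K27ac
    regions and broad H3K4me3 domains by width percentile, classifies domains
    across a multi-sample cell-line panel into common and grade-unique sets,
    tests regions for differential ChIP-seq enrichment under drug treatment
    with gene assignment and expression comparison, detects topologically
    associated domains (TADs) from binned contact matrices with a simplified
    diamond-statistic caller, and measures feature enrichment at TAD
    boundaries by random-bin permutation. Ships a seeded synthetic-data
    generator with planted structure so the full pipeline is testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
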
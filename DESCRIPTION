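Package: spliceclip
Title: Downstream Analysis of Differential Alternative Splicing with
    CLIP-Tag and Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of differential alternative
    pre-mRNA splicing results. Reads rMATS-style differential exon inclusion
    tables and differential gene-expression tables; filters events by false
    discovery rate and inclusion-level difference; tallies event types,
    threshold sweeps and gene-set overlaps; builds three genomic region groups
    (significant alternatively spliced exons, non-significant exons under a
    mixed-gene exclusion rule, and random genomic background regions) with
    flank expansion, sorting and deduplication; tests CLIP-tag intersection
    enrichment between groups with Pearson's chi-squared test; and scores
    degenerate-motif (YCAY) and k-mer enrichment in region sequences. A
    seeded synthetic-data generator with known planted parameters supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
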
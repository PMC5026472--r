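# spliceclip

Downstream analysis of differential alternative pre-mRNA splicing:
event-table filtering and summaries, genomic region-group construction,
CLIP-tag intersection enrichment, and degenerate-motif (YCAY) scoring.

## What it is for

After an rMATS-style differential-splicing comparison, a recurring
question is whether a candidate RNA-binding splicing factor plausibly
drives the observed exon inclusion/exclusion changes. The standard
genomic-interval answer is: take the regulated exons (with their flanking
intronic sequence, where splicing regulators bind), take matched control
regions, and ask whether in-vivo binding evidence — CLIP-seq tags — piles
up on the regulated set. spliceclip packages that analysis for R users
working with bulk or single-cell transcriptomics output:

* **Event tables** — read rMATS-style TSVs; filter to the regulated
  stratum (strict `FDR < 0.05` and `|ΔInc| > 0.1`); tally event types
  (SE, MXE, RI, A5SS, A3SS); sweep threshold grids; collapse to gene sets
  and compute Venn-style overlap percentages.
* **Region groups** — (1) significant exons, (2) non-significant exons
  (`FDR ≥ 0.05`, excluding exons of genes that also contain a significant
  exon), (3) random genomic background regions (100 bp, n = 10,000 by
  default); exon groups expanded by 500 bp on each side, all groups
  sorted and deduplicated.
* **CLIP enrichment** — per group, the count and percentage of regions
  intersecting ≥ 1 tag (0-based half-open BED semantics), with Pearson's
  chi-squared test on the 2×2 with/without table for significant-vs-each
  control:

  `X² = N·(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, df = 1,

  uncorrected by default, Yates correction by flag.
* **Motif enrichment** — pooled k-mer counts in foreground vs background
  sequences, per-k-mer chi-squared, Benjamini–Hochberg q-values, with
  k-mers flagged when they match an IUPAC element (default `YCAY`, the
  NOVA binding site; Y = C or T).
* **Synthetic data** — a seeded generator that plants known strata, tag
  overlap probabilities and motif densities, so the whole pipeline can be
  validated against ground truth.

Everything is tibble-in/tibble-out and pipe-friendly; enrichment results
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a small synthetic dataset with known truth (80 regulated + 150
null events, tags planted in 56% of regulated and 30% of control
regions), then run the analysis:

```r
library(spliceclip)

cfg <- synthetic_config(n_chromosomes = 2, chrom_length = 3e5,
                        n_sig_events = 80, n_null_events = 150, seed = 42)
d <- generate_dataset(cfg, file.path(tempdir(), "demo"),
                      write_sequences = FALSE)

events <- read_events(d$paths$events)
sig    <- filter_significant(events)          # recovers the 80 planted events
tally_event_types(sig)
#>   event_type     n
#> 1 SE            46
#> 2 MXE           11
#> 3 RI            10
#> 4 A5SS           4
#> 5 A3SS           9

groups <- build_region_groups(events, d$genome,
                              group_config(random_n = 300, seed = 1))
run_enrichment(groups, d$tags)
#> CLIP-tag intersection enrichment
#>
#>      group_name n_with n_without pct_with
#>     significant     42        38     52.5
#>  nonsignificant     44       106     29.3
#>          random      7       293      2.3
#>
#>                     comparison statistic df p_display warning
#>  significant vs nonsignificant  11.96121  1 0.0005432    <NA>
#>          significant vs random 141.51460  1 < 2.2e-16    <NA>
```

The tally counts each filtered event once per splicing class. In the
enrichment table, 52.5% of the regulated regions carry at least one tag —
within binomial error of the planted 56% — versus 29.3% of control exon
regions, and the chi-squared comparisons quantify that difference
(`p_display` floors at `< 2.2e-16`; the numeric p-value is kept
alongside). The random group is near zero here because tags were planted
only in exon-derived regions.

Gene-set overlap uses half-away-from-zero integer rounding:

```r
set_overlap(paste0("g", 1:1249), c(paste0("g", 1:323), paste0("x", 1:627)))
#>     n_a   n_b n_shared pct_of_a pct_of_b
#>    1249   950      323       26       34
```

i.e. the 323 shared genes are 26% of the first set and 34% of the second.

A one-call end-to-end run (simulate → filter → regions → enrich → motifs
→ report) with a single seed and byte-reproducible outputs:

```r
res <- run_pipeline(pipeline_config(
  synthetic = list(n_chromosomes = 2, chrom_length = 60000,
                   n_sig_events = 25, n_null_events = 45),
  group = list(random_n = 300), seed = 5
), "out_dir")
render_report("out_dir", "out_dir/report.md")
```

A thin command-line wrapper with the same stages as subcommands is
installed at `inst/cli/spliceclip`.

## Documentation

The methods vignette (`vignettes/splicing-clip-enrichment.Rmd`) describes
the model and its assumptions, the generator's design, every tunable
parameter, numerical conventions, and known limitations.
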
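write_native_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

native_rows <- function(...) {
  tibble::tibble(...)
}

test_that("native event tables parse row-for-row and round-trip", {
  df <- native_rows(
    event_id = c("e1", "e2"), event_type = c("SE", "RI"),
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
    strand = c("+", "-"), exonStart_0base = c(100L, 200L),
    exonEnd = c(250L, 380L), IncLevelDifference = c(0.2, -0.05),
    FDR = c(0.01, 0.6)
  )
  ev <- read_events(write_native_tsv(df))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start, c(100, 200))
  expect_equal(ev$inc_level_diff, c(0.2, -0.05))

  out <- tempfile(fileext = ".tsv")
  write_events(ev, out)
  expect_equal(read_events(out), ev)

  # header-only file gives an empty collection
  empty <- read_events(write_native_tsv(df[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("rMATS dialect maps its columns onto half-open exon coordinates", {
  df <- tibble::tibble(
    ID = 7L, GeneID = "ENSMUSG1", geneSymbol = "Abc", chr = "chr5",
    strand = "+", exonStart_0base = 1000L, exonEnd = 1150L,
    IncLevelDifference = -0.3, FDR = 0.002, PValue = 1e-5
  )
  ev <- read_events(write_native_tsv(df), dialect = "rmats",
                    event_type = "MXE")
  expect_equal(ev$event_id, "7")
  expect_equal(ev$event_type, "MXE")
  expect_equal(c(ev$start, ev$end), c(1000, 1150))
})

test_that("event parsing surfaces format and validation errors", {
  good <- native_rows(
    event_id = "e1", event_type = "SE", gene_id = "g", chrom = "chr1",
    strand = "+", exonStart_0base = 1L, exonEnd = 10L,
    IncLevelDifference = 0.3, FDR = 0.01
  )
  expect_error(read_events(write_native_tsv(good[, -9])),
               "FDR", class = "spliceclip_format_error")
  expect_error(read_events(write_native_tsv(dplyr::mutate(good, FDR = 1.5))),
               "row", class = "spliceclip_validation_error")
  expect_error(
    read_events(write_native_tsv(dplyr::mutate(good, event_type = "XX"))),
    class = "spliceclip_validation_error"
  )
  dup <- dplyr::bind_rows(good, good)
  expect_error(read_events(write_native_tsv(dup)),
               "duplicate", class = "spliceclip_validation_error")
})

test_that("significance filter uses strict inequalities on both thresholds", {
  ev <- random_events(4, seed = 1)
  ev$fdr <- c(0.05, 0.01, 0.01, 0.049)
  ev$inc_level_diff <- c(0.5, 0.10, -0.11, 0.2)
  kept <- filter_significant(ev)
  # fdr exactly at the cutoff and |dInc| exactly at the cutoff are excluded;
  # the sign of dInc is irrelevant
  expect_equal(kept$event_id, ev$event_id[3:4])
  expect_equal(filter_significant(kept), kept)
})

test_that("DE gene filter applies strict thresholds on q and |log2fc|", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(0.75, -0.8, 2, 0.9),
    q_value = c(0.04, 0.04, 0.05, 0.01)
  )
  expect_equal(filter_de_genes(de), c("b", "d"))
  expect_equal(filter_de_genes(de[0, ]), character(0))
  conflicting <- dplyr::bind_rows(de, dplyr::mutate(de[1, ], log2fc = 3))
  expect_error(filter_de_genes(conflicting),
               class = "spliceclip_validation_error")
})

test_that("threshold sweep matches the per-cell brute force and is monotone", {
  ev <- random_events(500, seed = 33)
  fdrs <- c(0.05, 0.01, 0.001, 0.0001)
  dincs <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75)
  sweep <- threshold_sweep(ev, fdrs, dincs)
  mat <- tidyr::pivot_wider(sweep, names_from = "min_abs_dinc",
                            values_from = "n_events")
  got <- as.matrix(mat[, -1])
  expect_equal(unname(got), unname(oracle_sweep(ev, fdrs, dincs)))
  # nested predicates force monotone rows and columns
  expect_true(all(apply(got, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(apply(got, 2, function(r) all(diff(r) <= 0))))
  # default cell equals the default filter
  expect_equal(sweep$n_events[sweep$fdr_max == 0.05 &
                                sweep$min_abs_dinc == 0.1],
               nrow(filter_significant(ev)))
  expect_error(threshold_sweep(ev, numeric(0)),
               class = "spliceclip_validation_error")
})

test_that("a single event fills exactly the cells its statistics force", {
  ev <- random_events(1, seed = 2)
  ev$fdr <- 0.0005
  ev$inc_level_diff <- 0.3
  sweep <- threshold_sweep(ev)
  expected <- as.integer(sweep$fdr_max > 0.0005 & sweep$min_abs_dinc < 0.3)
  expect_equal(sweep$n_events, expected)
})

test_that("event-type tallies count every event exactly once", {
  ev <- random_events(3, seed = 9)
  ev$event_type <- c("SE", "SE", "RI")
  tal <- tally_event_types(ev)
  expect_equal(tal$n[tal$event_type == "SE"], 2L)
  expect_equal(tal$n[tal$event_type == "RI"], 1L)
  expect_equal(sum(tal$n), 3L)
  expect_equal(sum(tally_event_types(ev[0, ])$n), 0L)
})

test_that("gene collapse returns distinct gene ids", {
  ev <- random_events(50, genes = 20, seed = 14)
  expect_setequal(collapse_to_genes(ev), unique(ev$gene_id))
  expect_length(collapse_to_genes(ev[0, ]), 0)
  two <- random_events(2, seed = 3)
  two$gene_id <- c("gX", "gX")
  expect_equal(collapse_to_genes(two), "gX")
})

test_that("set overlap reproduces the printed worked example and is symmetric", {
  a <- paste0("a", 1:1249)
  b <- c(a[1:323], paste0("b", 1:627))
  ov <- set_overlap(a, b)
  expect_equal(ov$n_shared, 323)
  expect_equal(ov$pct_of_a, 26)
  expect_equal(ov$pct_of_b, 34)

  swapped <- set_overlap(b, a)
  expect_equal(swapped$n_a, ov$n_b)
  expect_equal(swapped$pct_of_a, ov$pct_of_b)

  disjoint <- set_overlap(c("x"), c("y"))
  expect_equal(c(disjoint$n_shared, disjoint$pct_of_a, disjoint$pct_of_b),
               c(0, 0, 0))
  same <- set_overlap(letters, letters)
  expect_equal(c(same$pct_of_a, same$pct_of_b), c(100, 100))
  empty <- set_overlap(character(0), letters)
  expect_equal(empty$n_shared, 0)
  expect_true(is.na(empty$pct_of_a))
  expect_equal(empty$pct_of_b, 0)
})

test_that("percentage rounding is half away from zero", {
  # 25/200 of a 50-gene set: 12.5% must round to 13, not banker's 12
  a <- paste0("g", 1:200)
  b <- a[1:25]
  expect_equal(set_overlap(b, a)$pct_of_b, 13)
})

test_that("PSI is the length-normalised inclusion fraction", {
  expect_equal(compute_psi(10, 0), 1)
  expect_equal(compute_psi(10, 10), 0.5)
  expect_equal(compute_psi(20, 10, inclusion_eff_len = 2,
                           skipping_eff_len = 1), 0.5)
  expect_error(compute_psi(0, 0), class = "spliceclip_validation_error")
  expect_error(compute_psi(1, 1, inclusion_eff_len = 0),
               class = "spliceclip_validation_error")
})
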
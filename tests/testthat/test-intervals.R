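test_that("flank expansion does forced arithmetic and clamps at bounds", {
  g <- toy_genome(c(chr1 = 1e6))
  x <- as_intervals(data.frame(chrom = "chr1", start = 1000, end = 1200))
  out <- expand_flanks(x, g, 500)
  expect_equal(c(out$start, out$end), c(500, 1700))

  clamped <- expand_flanks(
    as_intervals(data.frame(chrom = "chr1", start = 100, end = 200)), g, 500
  )
  expect_equal(c(clamped$start, clamped$end), c(0, 700))

  ident <- expand_flanks(x, g, 0)
  expect_equal(ident[c("start", "end")], x[c("start", "end")])

  expect_error(
    expand_flanks(as_intervals(data.frame(chrom = "chrX", start = 0, end = 1)),
                  g),
    class = "spliceclip_lookup_error"
  )
})

test_that("flank expansion never leaves chromosome bounds or empties intervals", {
  g <- toy_genome(c(chr1 = 5000, chr2 = 800))
  withr::with_seed(11, {
    x <- random_intervals(200, max_pos = 700, max_len = 90)
  })
  out <- expand_flanks(x, g, 400)
  len <- g$length[match(out$chrom, g$chrom)]
  expect_true(all(out$start >= 0))
  expect_true(all(out$end <= len))
  expect_true(all(out$start < out$end))
})

test_that("sort_dedup removes exact duplicates only and is idempotent", {
  x <- as_intervals(tibble::tribble(
    ~chrom, ~start, ~end,
    "chr2", 50, 150,
    "chr1", 0, 100,
    "chr1", 0, 100,
    "chr1", 50, 150
  ))
  out <- sort_dedup(x)
  expect_equal(nrow(out), 3)
  # overlapping-but-unequal intervals are both retained: dedup is not merge
  expect_true(all(c(0, 50) %in% out$start[out$chrom == "chr1"]))
  expect_true(!is.unsorted(out$start[out$chrom == "chr1"]))
  expect_equal(sort_dedup(out), out)
  expect_equal(out$chrom, sort(out$chrom))
})

test_that("dedup keeps the first contributor's provenance", {
  x <- as_intervals(tibble::tibble(
    chrom = "chr1", start = c(10, 10), end = c(20, 20), id = c("a", "b")
  ))
  expect_equal(sort_dedup(x)$id, "a")
})

test_that("overlap uses half-open semantics with a one-base threshold", {
  q <- as_intervals(data.frame(chrom = "chr1", start = 0, end = 100))
  adjacent <- as_intervals(data.frame(chrom = "chr1", start = 100, end = 200))
  touching <- as_intervals(data.frame(chrom = "chr1", start = 99, end = 150))
  expect_false(intersects_any(q, adjacent)$hit)
  expect_true(intersects_any(q, touching)$hit)
  # other chromosome never overlaps
  expect_false(intersects_any(q, dplyr::mutate(touching, chrom = "chr2"))$hit)
})

test_that("stranded mode requires matching strands", {
  q <- as_intervals(data.frame(chrom = "chr1", start = 0, end = 100,
                               strand = "+"))
  t_minus <- as_intervals(data.frame(chrom = "chr1", start = 50, end = 60,
                                     strand = "-"))
  t_plus <- dplyr::mutate(t_minus, strand = "+")
  expect_false(intersects_any(q, t_minus, stranded = TRUE)$hit)
  expect_true(intersects_any(q, t_plus, stranded = TRUE)$hit)
  expect_true(intersects_any(q, t_minus, stranded = FALSE)$hit)
})

test_that("interval-index intersection agrees with the all-pairs oracle", {
  withr::with_seed(202, {
    for (i in 1:25) {
      q <- as_intervals(random_intervals(sample.int(300, 1)))
      tg <- as_intervals(random_intervals(sample.int(300, 1)))
      stranded <- i %% 2 == 0
      expect_equal(intersects_any(q, tg, stranded = stranded)$hit,
                   oracle_overlap(q, tg, stranded = stranded))
    }
  })
  # empty sets allowed on both sides
  empty <- as_intervals(tibble::tibble(chrom = character(), start = double(),
                                       end = double()))
  some <- as_intervals(random_intervals(5))
  expect_equal(nrow(intersects_any(empty, some)), 0)
  expect_false(any(intersects_any(some, empty)$hit))
})

test_that("random region sampling respects n, length, bounds and seed", {
  g <- toy_genome(c(chrA = 1000, chrB = 5000))
  expect_equal(nrow(sample_random_regions(g, n = 0)), 0)

  x <- sample_random_regions(g, n = 500, region_length = 100, seed = 5)
  expect_true(all(x$end - x$start == 100))
  len <- g$length[match(x$chrom, g$chrom)]
  expect_true(all(x$start >= 0 & x$end <= len))
  expect_equal(x, sample_random_regions(g, n = 500, region_length = 100,
                                        seed = 5))

  expect_error(sample_random_regions(toy_genome(c(chr1 = 50)), n = 10,
                                     region_length = 100),
               class = "spliceclip_capacity_error")
})

test_that("random region starts are uniform over the valid range", {
  g <- toy_genome(c(chr1 = 1000))
  x <- sample_random_regions(g, n = 10000, region_length = 100, seed = 99)
  # starts live on the integers 0..900; bin and test goodness of fit
  breaks <- seq(0, 901, length.out = 11)
  counts <- table(cut(x$start, breaks, right = FALSE))
  probs <- table(cut(0:900, breaks, right = FALSE)) / 901
  gof <- chisq.test(counts, p = as.numeric(probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("BED and chrom.sizes files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  x <- as_intervals(tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(0, 10), end = c(5, 40),
    strand = c("+", "-"), name = c("a", "b")
  ))
  write_bed(x, tmp)
  back <- read_bed(tmp)
  expect_equal(back[, c("chrom", "start", "end", "strand", "name")],
               x[, c("chrom", "start", "end", "strand", "name")])

  bed3 <- withr::local_tempfile(fileext = ".bed")
  write_bed(x[, c("chrom", "start", "end")], bed3)
  expect_equal(read_bed(bed3)$strand, c(".", "."))

  sizes <- withr::local_tempfile(fileext = ".sizes")
  write_chrom_sizes(toy_genome(), sizes)
  expect_equal(read_chrom_sizes(sizes), toy_genome())
})

test_that("interval validation rejects malformed tables", {
  expect_error(as_intervals(data.frame(chrom = "chr1", start = 10, end = 10)),
               class = "spliceclip_validation_error")
  expect_error(as_intervals(data.frame(chrom = "chr1", start = -1, end = 5)),
               class = "spliceclip_validation_error")
  expect_error(as_intervals(data.frame(start = 1, end = 5)),
               class = "spliceclip_format_error")
})
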
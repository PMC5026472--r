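#' Genomic intervals as tibbles
#'
#' Throughout the package a set of genomic intervals is an ordinary tibble
#' with columns `chrom` (character), `start` and `end` (0-based half-open:
#' `start` inclusive, `end` exclusive) and `strand` (`"+"`, `"-"` or `"."`).
#' `as_intervals()` coerces a data frame to this shape and validates the
#' invariants (`0 <= start < end`, non-empty `chrom`). Extra columns (names,
#' provenance ids, scores) are carried through untouched.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @return A tibble with validated interval columns; `strand` is added
#'   (as `"."`) when absent.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
as_intervals <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("interval table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "spliceclip_format_error"
    )
  }
  if (!"strand" %in% names(x)) x$strand <- "."
  x$chrom <- as.character(x$chrom)
  x$start <- as.double(x$start)
  x$end <- as.double(x$end)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort("interval chrom names must be non-empty",
          class = "spliceclip_validation_error")
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(
      paste0("invalid interval(s) at row(s) ",
             paste(head(bad, 5), collapse = ", "),
             ": need 0 <= start < end"),
      class = "spliceclip_validation_error"
    )
  }
  if (any(!x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'",
          class = "spliceclip_validation_error")
  }
  invisible(x)
}

#' Read a chromosome-sizes table
#'
#' Reads a two-column tab-separated `chrom.sizes` file (chromosome name,
#' length in bases), the standard carrier of genome extent used to clamp
#' flank expansion and to sample random background regions.
#'
#' @param path Path to a headerless two-column TSV.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  validate_genome(g)
  g
}

#' Write a chromosome-sizes table
#' @param genome Tibble with `chrom`, `length` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  validate_genome(genome)
  readr::write_tsv(genome[, c("chrom", "length")], path, col_names = FALSE)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome))) {
    abort("genome must have columns chrom and length",
          class = "spliceclip_format_error")
  }
  if (anyDuplicated(genome$chrom) > 0) {
    abort("genome chrom names must be unique",
          class = "spliceclip_validation_error")
  }
  if (any(genome$length <= 0)) {
    abort("genome chromosome lengths must be > 0",
          class = "spliceclip_validation_error")
  }
  invisible(genome)
}

#' Read and write BED intervals
#'
#' `read_bed()` reads BED3/BED6 (tab-separated, 0-based half-open, optional
#' name/score/strand in columns 4-6). `write_bed()` writes BED6 when a
#' `name` or non-`.` strand is present, BED3 otherwise.
#'
#' @param path File path.
#' @return `read_bed()`: an interval tibble (with `name` and `score` when
#'   the file has six columns).
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    return(as_intervals(tibble(chrom = character(), start = double(),
                               end = double(), strand = character())))
  }
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol >= 6) {
    x <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         col_types = "cddcdc", progress = FALSE)
  } else {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cdd", progress = FALSE)
  }
  as_intervals(x)
}

#' @param x An interval tibble.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  if ("name" %in% names(x) || any(x$strand != ".")) {
    out <- tibble(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if ("name" %in% names(x)) x$name else ".",
      score = if ("score" %in% names(x)) x$score else 0,
      strand = x$strand
    )
  } else {
    out <- x[, c("chrom", "start", "end")]
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Expand intervals by a fixed flank, clamped to chromosome bounds
#'
#' Adds `flank` bases of sequence on both the 5' and 3' side of each
#' interval, truncating at position 0 and at the chromosome length so the
#' result never leaves the genome.
#'
#' @param x An interval tibble.
#' @param genome Chromosome sizes tibble (`chrom`, `length`).
#' @param flank Bases to add on each side (default 500).
#' @return The interval tibble with expanded `start`/`end`; other columns
#'   unchanged.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", length = 1e6)
#' expand_flanks(as_intervals(data.frame(chrom = "chr1", start = 1000,
#'                                       end = 1200)), g)
#' @export
expand_flanks <- function(x, genome, flank = 500) {
  x <- as_intervals(x)
  validate_genome(genome)
  if (flank < 0) {
    abort("flank must be >= 0", class = "spliceclip_validation_error")
  }
  unknown <- setdiff(unique(x$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) not in genome: ",
                 paste(unknown, collapse = ", ")),
          class = "spliceclip_lookup_error")
  }
  len <- genome$length[match(x$chrom, genome$chrom)]
  x$start <- pmax(0, x$start - flank)
  x$end <- pmin(len, x$end + flank)
  x
}

#' Sort intervals and drop exact duplicates
#'
#' Orders intervals by (chrom lexicographic, start, end) and collapses rows
#' identical in `(chrom, start, end)` to the first occurrence. Overlapping
#' but unequal intervals are both retained: deduplication is not merging.
#'
#' @param x An interval tibble.
#' @return A sorted, deduplicated interval tibble.
#' @export
sort_dedup <- function(x) {
  x <- as_intervals(x)
  x |>
    arrange(.data$chrom, .data$start, .data$end) |>
    distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

#' Flag queries that intersect at least one tag
#'
#' Half-open overlap semantics: query `q` and tag `t` overlap iff they share
#' a chromosome and `q.start < t.end` and `t.start < q.end` (>= 1 shared
#' base; adjacent intervals do not overlap). When `stranded = TRUE` strands
#' must also match. The fast path uses an interval index
#' ([IRanges::findOverlaps()]) per chromosome.
#'
#' @param queries,tags Interval tibbles.
#' @param stranded Require matching strand (default `FALSE`, mirroring
#'   strandless `bedtools intersect` defaults).
#' @return `queries` with a logical `hit` column; the number of queries with
#'   at least one overlap is `sum(result$hit)`.
#' @export
intersects_any <- function(queries, tags, stranded = FALSE) {
  queries <- as_intervals(queries)
  tags <- as_intervals(tags)
  hit <- rep(FALSE, nrow(queries))
  if (nrow(queries) > 0 && nrow(tags) > 0) {
    qkey <- if (stranded) paste(queries$chrom, queries$strand) else queries$chrom
    tkey <- if (stranded) paste(tags$chrom, tags$strand) else tags$chrom
    for (key in intersect(unique(qkey), unique(tkey))) {
      qi <- which(qkey == key)
      ti <- which(tkey == key)
      qr <- IRanges::IRanges(start = queries$start[qi] + 1,
                             end = queries$end[qi])
      tr <- IRanges::IRanges(start = tags$start[ti] + 1, end = tags$end[ti])
      hit[qi] <- IRanges::overlapsAny(qr, tr, minoverlap = 1)
    }
  }
  queries$hit <- hit
  queries
}

#' Sample random genomic background regions
#'
#' Draws `n` fixed-length regions uniformly from the genome: the chromosome
#' is chosen with probability proportional to its number of valid start
#' positions (`length - region_length + 1`) and the start uniformly among
#' them. Regions may overlap each other; no masking is applied. Strand is
#' reported as `"."`.
#'
#' @param genome Chromosome sizes tibble.
#' @param n Number of regions (default 10000).
#' @param region_length Region length in bases (default 100).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A sorted interval tibble of `n` rows (before any deduplication).
#' @export
sample_random_regions <- function(genome, n = 10000, region_length = 100,
                                  seed = NULL) {
  validate_genome(genome)
  if (n < 0) abort("n must be >= 0", class = "spliceclip_validation_error")
  eligible <- genome$length >= region_length
  if (n > 0 && !any(eligible)) {
    abort("no chromosome is long enough for the requested region length",
          class = "spliceclip_capacity_error")
  }
  draw <- function() {
    if (n == 0) {
      return(tibble(chrom = character(), start = double(), end = double(),
                    strand = character()))
    }
    g <- genome[eligible, ]
    npos <- g$length - region_length + 1
    ci <- sample.int(nrow(g), n, replace = TRUE, prob = npos)
    start <- floor(runif(n, min = 0, max = npos[ci]))
    tibble(chrom = g$chrom[ci], start = start,
           end = start + region_length, strand = ".")
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  as_intervals(out) |> arrange(.data$chrom, .data$start, .data$end)
}
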
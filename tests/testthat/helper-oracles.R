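# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths wherever they check one.

# all-pairs O(n*m) overlap check, half-open semantics
oracle_overlap <- function(queries, tags, stranded = FALSE) {
  n <- nrow(queries)
  m <- nrow(tags)
  if (n == 0) return(logical(0))
  if (m == 0) return(rep(FALSE, n))
  same_chrom <- outer(queries$chrom, tags$chrom, `==`)
  ov <- outer(queries$start, tags$end, `<`) &
    t(outer(tags$start, queries$end, `<`))
  hit <- same_chrom & ov
  if (stranded) {
    hit <- hit & outer(queries$strand, tags$strand, `==`)
  }
  rowSums(hit) > 0
}

# algebraic closed form of the uncorrected Pearson 2x2 statistic
oracle_chi2x2 <- function(a, b, c, d) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# per-cell double loop over raw predicates, independent of filter_significant
oracle_sweep <- function(events, fdr_levels, dinc_levels) {
  out <- matrix(0L, length(fdr_levels), length(dinc_levels))
  for (i in seq_along(fdr_levels)) {
    for (j in seq_along(dinc_levels)) {
      k <- 0L
      for (r in seq_len(nrow(events))) {
        if (events$fdr[r] < fdr_levels[i] &&
            abs(events$inc_level_diff[r]) > dinc_levels[j]) {
          k <- k + 1L
        }
      }
      out[i, j] <- k
    }
  }
  out
}

# brute-force per-gene scan for non-significant-group membership
oracle_nonsig_members <- function(events, fdr_sig = 0.05,
                                  exclusion_fdr = 0.05) {
  keep <- character(0)
  for (r in seq_len(nrow(events))) {
    if (events$fdr[r] < fdr_sig) next
    gene <- events$gene_id[r]
    mixed <- FALSE
    for (s in seq_len(nrow(events))) {
      if (events$gene_id[s] == gene && events$fdr[s] < exclusion_fdr) {
        mixed <- TRUE
        break
      }
    }
    if (!mixed) keep <- c(keep, events$event_id[r])
  }
  keep
}

# random event-table fixture; multi-exon genes when genes < n
random_events <- function(n, genes = n, chrom = "chr1", seed = 1) {
  withr::with_seed(seed, {
    start <- sort(sample.int(1e6, n)) * 10
    tibble::tibble(
      event_id = sprintf("ev%04d", seq_len(n)),
      event_type = sample(c("SE", "MXE", "RI", "A5SS", "A3SS"), n,
                          replace = TRUE),
      gene_id = sprintf("g%04d", sample.int(genes, n, replace = TRUE)),
      chrom = chrom,
      start = start,
      end = start + sample(50:300, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      inc_level_diff = round(runif(n, -1, 1), 3),
      fdr = round(runif(n), 4)
    )
  })
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    strand = sample(c("+", "-", "."), n, replace = TRUE)
  )
}

toy_genome <- function(lengths = c(chr1 = 1e6, chr2 = 1e6)) {
  tibble::tibble(chrom = names(lengths), length = unname(lengths))
}

# small but non-trivial synthetic dataset shared across tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 3e5, n_sig_events = 80,
         n_null_events = 150, seed = 42),
    list(...)
  )
  do.call(synthetic_config, args)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(unname(tools::md5sum(files)),
                  sub(paste0("^", dir, "/"), "", files))
}
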
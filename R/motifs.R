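IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

validate_motif <- function(pattern) {
  if (!nzchar(pattern)) {
    abort("motif pattern must be non-empty",
          class = "spliceclip_validation_error")
  }
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% IUPAC_LETTERS)) {
    abort("motif pattern must use IUPAC nucleotide codes",
          class = "spliceclip_validation_error")
  }
  invisible(toupper(pattern))
}

as_dna <- function(sequences, what = "sequence") {
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    abort(paste0("invalid character in ", what, " ",
                 paste(head(which(bad), 5), collapse = ", "),
                 " (allowed: A, C, G, T, N)"),
          class = "spliceclip_validation_error")
  }
  Biostrings::DNAStringSet(sequences)
}

#' Count degenerate-motif occurrences in sequences
#'
#' Counts the positions at which an IUPAC pattern (default `"YCAY"`,
#' Y = C or T — the NOVA binding element) matches each sequence.
#' Overlapping occurrences are all counted; an `N` in the sequence matches
#' nothing.
#'
#' @param sequences Character vector of nucleotide strings over
#'   A/C/G/T/N (case-insensitive).
#' @param pattern IUPAC pattern (default `"YCAY"`).
#' @return Integer vector of per-sequence occurrence counts.
#' @examples
#' count_motif("TCATCCAC")  # 2: TCAT at offset 0, CCAC at offset 4
#' @export
count_motif <- function(sequences, pattern = "YCAY") {
  pattern <- validate_motif(pattern)
  dna <- as_dna(sequences)
  vapply(seq_along(dna), function(i) {
    Biostrings::countPattern(pattern, dna[[i]], fixed = "subject")
  }, integer(1))
}

#' Extract region sequences from a genome
#'
#' Pulls out one nucleotide string per region (length `end - start`).
#' With `strand_aware = TRUE`, minus-strand regions are
#' reverse-complemented.
#'
#' @param regions An interval tibble.
#' @param fasta Path to a FASTA file with one record per chromosome, or a
#'   [Biostrings::DNAStringSet].
#' @param strand_aware Reverse-complement minus-strand regions (default
#'   `FALSE`).
#' @return Character vector of sequences, one per region.
#' @export
extract_sequences <- function(regions, fasta, strand_aware = FALSE) {
  regions <- as_intervals(regions)
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else {
    Biostrings::readDNAStringSet(fasta)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  unknown <- setdiff(unique(regions$chrom), names(seqs))
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) not in FASTA: ",
                 paste(unknown, collapse = ", ")),
          class = "spliceclip_lookup_error")
  }
  lens <- Biostrings::width(seqs)[match(regions$chrom, names(seqs))]
  bad <- which(regions$end > lens)
  if (length(bad) > 0) {
    abort(paste0("region(s) beyond sequence end: row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "spliceclip_bounds_error")
  }
  out <- vapply(seq_len(nrow(regions)), function(i) {
    s <- Biostrings::subseq(seqs[[regions$chrom[i]]],
                            start = regions$start[i] + 1,
                            end = regions$end[i])
    if (strand_aware && regions$strand[i] == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, character(1))
  out
}

# does a k-mer contain a full match of the IUPAC pattern?
kmer_matches_motif <- function(kmers, pattern) {
  pattern <- validate_motif(pattern)
  if (nchar(kmers[1]) < nchar(pattern)) {
    return(rep(FALSE, length(kmers)))
  }
  vapply(kmers, function(km) {
    Biostrings::countPattern(pattern, Biostrings::DNAString(km),
                             fixed = "subject") > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' k-mer enrichment of foreground over background sequences
#'
#' Counts every k-mer (overlapping positions; windows containing `N` are
#' skipped) pooled over the foreground and background sequence sets, tests
#' each k-mer's this-k-mer-vs-all-others split between the two pools with
#' the uncorrected Pearson chi-squared test, and adjusts p-values across
#' all `4^k` k-mers with Benjamini-Hochberg. Each row is flagged when the
#' k-mer contains a match of the degenerate motif of interest, so the
#' motif's standing in the ranking can be read off directly.
#'
#' Odds ratios with a zero cell use a Haldane-Anscombe 0.5 pseudo-count on
#' all four cells; the raw counts are reported unchanged.
#'
#' @param fg_seqs,bg_seqs Character vectors of nucleotide sequences.
#' @param k k-mer length (default 4, the length of YCAY).
#' @param motif IUPAC pattern to flag (default `"YCAY"`).
#' @return A tibble of class `"kmer_enrichment"`, sorted by ascending
#'   `q_value` (ties by `p_value`, then k-mer), with columns `kmer`,
#'   `count_fg`, `count_bg`, `odds_ratio`, `statistic`, `p_value`,
#'   `q_value`, `matches_motif`.
#' @export
kmer_enrichment <- function(fg_seqs, bg_seqs, k = 4, motif = "YCAY") {
  if (k < 1) abort("k must be >= 1", class = "spliceclip_validation_error")
  fg <- as_dna(fg_seqs, "foreground sequence")
  bg <- as_dna(bg_seqs, "background sequence")
  if (all(Biostrings::width(fg) < k) || all(Biostrings::width(bg) < k)) {
    abort("k is longer than every sequence in a group",
          class = "spliceclip_validation_error")
  }
  count_fg <- colSums(Biostrings::oligonucleotideFrequency(fg, width = k))
  count_bg <- colSums(Biostrings::oligonucleotideFrequency(bg, width = k))
  total_fg <- sum(count_fg)
  total_bg <- sum(count_bg)

  kmers <- names(count_fg)
  test_one <- function(a, c) {
    b <- total_fg - a
    d <- total_bg - c
    m <- rbind(c(a, b), c(c, d))
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected == 0)) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    c(unname(ct$statistic), unname(ct$p.value))
  }
  stats_mat <- vapply(seq_along(kmers),
                      function(i) test_one(count_fg[i], count_bg[i]),
                      numeric(2))
  odds <- vapply(seq_along(kmers), function(i) {
    a <- count_fg[i]; b <- total_fg - a
    c_ <- count_bg[i]; d <- total_bg - c_
    if (any(c(a, b, c_, d) == 0)) {
      ((a + 0.5) / (b + 0.5)) / ((c_ + 0.5) / (d + 0.5))
    } else {
      (a / b) / (c_ / d)
    }
  }, numeric(1))

  out <- tibble(
    kmer = kmers,
    count_fg = as.integer(count_fg),
    count_bg = as.integer(count_bg),
    odds_ratio = odds,
    statistic = stats_mat[1, ],
    p_value = stats_mat[2, ],
    q_value = p.adjust(stats_mat[2, ], method = "BH"),
    matches_motif = kmer_matches_motif(kmers, motif)
  ) |>
    arrange(.data$q_value, .data$p_value, .data$kmer)
  structure(out, class = c("kmer_enrichment", class(out)))
}

#' Volcano-style plot of a k-mer enrichment table
#'
#' @param object A `"kmer_enrichment"` tibble.
#' @param ... Unused.
#' @return A ggplot object; motif-matching k-mers are highlighted.
#' @export
autoplot.kmer_enrichment <- function(object, ...) {
  d <- object |>
    mutate(neg_log_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$odds_ratio),
                                  y = .data$neg_log_q,
                                  colour = .data$matches_motif)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 odds ratio (foreground / background)",
                  y = "-log10 q", colour = "matches motif") +
    ggplot2::theme_minimal()
}
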
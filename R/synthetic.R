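#' Configuration for the synthetic splicing dataset generator
#'
#' Bundles and validates the planted parameters of the generator. The
#' defaults describe a genome-scale differential-splicing comparison: 1631
#' significantly regulated exons against 11490 non-significant exons, CLIP
#' tags planted in 56% of significant and 30% of control regions, 500 bp
#' flanks and 100 bp random background regions.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of every chromosome, bases.
#' @param n_sig_events Events in the significant stratum (FDR drawn below
#'   0.05, |dInc| uniform on `[dinc_sig_min, 1]`).
#' @param n_null_events Events in the null stratum (FDR uniform on
#'   `[0.05, 1]`, |dInc| uniform on `[0, 0.1]`).
#' @param n_genes Genes to spread events over; `NULL` (default) assigns one
#'   gene per event so the mixed-gene exclusion rule is vacuous by
#'   construction.
#' @param frac_de_genes Fraction of genes drawn as differentially expressed
#'   in the companion DE table.
#' @param planted_overlap_sig,planted_overlap_ctrl Probability that a
#'   significant (resp. control) region receives one CLIP tag.
#' @param tag_length CLIP-tag length, bases (default 32; CLIP tags are
#'   short and are placed fully inside their target region).
#' @param motif_density_sig,motif_density_bg Additional planted YCAY
#'   occurrences per kb in significant regions / genome-wide background
#'   (uniform-random sequence already contains YCAY at about 15.6 matches
#'   per kb; densities are planted on top of that floor).
#' @param dinc_sig_min Lower bound of |dInc| in the significant stratum;
#'   must exceed 0.1 so every planted significant event passes the default
#'   filter.
#' @param exon_length Exon length, bases.
#' @param flank Flank used to space exons (and to plant tags in the
#'   flank-expanded regions), bases.
#' @param seed Integer seed; the generator consumes one RNG stream in a
#'   fixed documented order, so identical config gives identical output.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_chromosomes = 4,
                             chrom_length = 2e8,
                             n_sig_events = 1631,
                             n_null_events = 11490,
                             n_genes = NULL,
                             frac_de_genes = 0.25,
                             planted_overlap_sig = 0.56,
                             planted_overlap_ctrl = 0.30,
                             tag_length = 32,
                             motif_density_sig = 20,
                             motif_density_bg = 2,
                             dinc_sig_min = 0.2,
                             exon_length = 150,
                             flank = 500,
                             seed = 1L) {
  cfg <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    n_sig_events = n_sig_events, n_null_events = n_null_events,
    n_genes = n_genes, frac_de_genes = frac_de_genes,
    planted_overlap_sig = planted_overlap_sig,
    planted_overlap_ctrl = planted_overlap_ctrl,
    tag_length = tag_length,
    motif_density_sig = motif_density_sig,
    motif_density_bg = motif_density_bg,
    dinc_sig_min = dinc_sig_min,
    exon_length = exon_length, flank = flank,
    seed = as.integer(seed)
  )
  counts <- c("n_chromosomes", "chrom_length", "n_sig_events",
              "n_null_events", "tag_length", "exon_length", "flank")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0(f, " must be a single non-negative number"),
            class = "spliceclip_validation_error")
    }
  }
  probs <- c("frac_de_genes", "planted_overlap_sig", "planted_overlap_ctrl")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0(f, " must lie in [0,1]"),
            class = "spliceclip_validation_error")
    }
  }
  if (cfg$dinc_sig_min <= 0.1 || cfg$dinc_sig_min > 1) {
    abort("dinc_sig_min must lie in (0.1, 1] so planted significant events pass the default filter",
          class = "spliceclip_validation_error")
  }
  if (cfg$chrom_length < 2 * (cfg$flank + cfg$exon_length)) {
    abort("chrom_length must be at least 2*(flank + exon_length)",
          class = "spliceclip_validation_error")
  }
  if (cfg$motif_density_sig < 0 || cfg$motif_density_bg < 0) {
    abort("motif densities must be >= 0",
          class = "spliceclip_validation_error")
  }
  structure(cfg, class = "synthetic_config")
}

# exon slot layout: non-overlapping grid with >= 2*flank + 100 spacing so
# flank-expanded regions of distinct exons never share a coordinate triple
exon_slots <- function(cfg) {
  stride <- cfg$exon_length + 2 * cfg$flank + 100
  last_start <- cfg$chrom_length - cfg$flank - cfg$exon_length
  if (last_start < cfg$flank) {
    return(tibble(chrom = character(), start = double()))
  }
  starts <- seq(cfg$flank, last_start, by = stride)
  tidyr::expand_grid(
    chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
    start = starts
  )
}

#' Plant CLIP tags inside a set of regions
#'
#' Each region independently receives one tag with probability `prob`; the
#' tag is placed uniformly at random, fully contained in the region, so the
#' one-base-overlap intersection rule is unambiguous.
#'
#' @param regions An interval tibble; every region must be at least
#'   `tag_length` wide.
#' @param prob Per-region planting probability.
#' @param tag_length Tag length in bases.
#' @param seed Optional seed (caller RNG untouched when supplied; when
#'   `NULL` the current RNG stream is consumed, as inside
#'   [generate_dataset()]).
#' @return A list with `tags` (interval tibble, one row per planted tag,
#'   with `source` giving the originating region's row index) and `planted`
#'   (logical vector over regions).
#' @export
plant_clip_tags <- function(regions, prob, tag_length = 32, seed = NULL) {
  regions <- as_intervals(regions)
  if (prob < 0 || prob > 1) {
    abort("prob must lie in [0,1]", class = "spliceclip_validation_error")
  }
  if (nrow(regions) > 0 && any(regions$end - regions$start < tag_length)) {
    abort("every region must be at least tag_length wide",
          class = "spliceclip_validation_error")
  }
  draw <- function() {
    planted <- runif(nrow(regions)) < prob
    idx <- which(planted)
    start <- floor(runif(length(idx),
                         min = regions$start[idx],
                         max = regions$end[idx] - tag_length + 1))
    list(
      tags = tibble(chrom = regions$chrom[idx], start = start,
                    end = start + tag_length, strand = ".", source = idx),
      planted = planted
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Random DNA sequences with planted degenerate motifs
#'
#' Generates uniform-random ACGT strings and overwrites a Poisson number of
#' positions per sequence (rate `motif_rate_per_kb` per kb) with a random
#' realisation of the IUPAC `pattern`. Useful as foreground/background
#' material for motif-enrichment checks; note random sequence already
#' contains matches of short degenerate patterns at its combinatorial floor.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence, bases.
#' @param motif_rate_per_kb Planted occurrences per kb (default 0).
#' @param pattern IUPAC pattern to plant (default `"YCAY"`).
#' @param seed Optional seed.
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, length, motif_rate_per_kb = 0, pattern = "YCAY",
                       seed = NULL) {
  draw <- function() {
    purrr::map_chr(seq_len(n), function(i) {
      chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      k <- nchar(pattern)
      n_plant <- if (motif_rate_per_kb > 0 && length >= k) {
        rpois(1, motif_rate_per_kb * length / 1000)
      } else 0L
      if (n_plant > 0) {
        pos <- floor(runif(n_plant, min = 1, max = length - k + 2))
        for (p in pos) {
          chars[p:(p + k - 1)] <- realise_iupac(pattern)
        }
      }
      paste(chars, collapse = "")
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# one concrete ACGT realisation of an IUPAC pattern (random choice per
# degenerate position)
realise_iupac <- function(pattern) {
  codes <- Biostrings::IUPAC_CODE_MAP
  vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- strsplit(codes[[toupper(ch)]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a complete synthetic splicing dataset
#'
#' Writes a self-consistent bundle of inputs for the downstream pipeline —
#' chromosome sizes, a differential-splicing event table with two planted
#' strata, an exon catalog, a DE-gene table, CLIP-tag intervals and genome
#' sequences — together with the ground truth of every planted draw.
#'
#' The RNG is seeded once from `config$seed` and consumed in a fixed order:
#' (1) exon slot assignment and stratum shuffle, (2) event types, strands,
#' FDR and dInc draws, (3) DE-gene draws, (4) CLIP-tag planting in the
#' flank-expanded significant then control regions, (5) sequence and motif
#' draws. Identical config therefore gives byte-identical files.
#'
#' The two strata are separable by construction: significant events have
#' FDR uniform on `[0, 0.05)` and |dInc| uniform on `[dinc_sig_min, 1]`
#' with `dinc_sig_min > 0.1`; null events have FDR uniform on `[0.05, 1]`
#' and |dInc| uniform on `[0, 0.1]`. Applying the default significance
#' filter to the written table recovers the significant stratum exactly.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param write_sequences Write the FASTA genome and plant motifs (default
#'   `TRUE`; sequence synthesis dominates runtime at genome scale).
#' @return A list with the written `paths`, the in-memory `genome`,
#'   `events`, `de_genes`, `tags` tibbles, and `truth`: one row per event
#'   (`event_id`, `stratum`, flank-expanded region coordinates,
#'   `tag_planted`) plus the config echoed as an attribute.
#' @export
generate_dataset <- function(config, dir, write_sequences = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_events <- config$n_sig_events + config$n_null_events

  genome <- tibble(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    length = config$chrom_length
  )
  slots <- exon_slots(config)
  if (nrow(slots) < n_events) {
    abort(paste0("genome too small: ", nrow(slots),
                 " exon slots available for ", n_events, " events"),
          class = "spliceclip_capacity_error")
  }

  out <- withr::with_seed(config$seed, {
    chosen <- slots[sort(sample.int(nrow(slots), n_events)), ]
    stratum <- sample(rep(c("significant", "null"),
                          c(config$n_sig_events, config$n_null_events)))
    type_weights <- c(SE = 1052, MXE = 144, RI = 160, A5SS = 123, A3SS = 152)
    sig <- stratum == "significant"
    fdr <- ifelse(sig, runif(n_events, 0, 0.05), runif(n_events, 0.05, 1))
    abs_dinc <- ifelse(sig,
                       runif(n_events, config$dinc_sig_min, 1),
                       runif(n_events, 0, 0.1))
    dinc <- abs_dinc * sample(c(-1, 1), n_events, replace = TRUE)
    gene_id <- if (is.null(config$n_genes)) {
      sprintf("gene%05d", seq_len(n_events))
    } else {
      sprintf("gene%05d", sample.int(config$n_genes, n_events, replace = TRUE))
    }
    events <- tibble(
      event_id = sprintf("ev%05d", seq_len(n_events)),
      event_type = sample(names(type_weights), n_events, replace = TRUE,
                          prob = type_weights),
      gene_id = gene_id,
      chrom = chosen$chrom,
      start = chosen$start,
      end = chosen$start + config$exon_length,
      strand = sample(c("+", "-"), n_events, replace = TRUE),
      inc_level_diff = dinc,
      fdr = fdr
    )

    gene_universe <- sort(unique(events$gene_id))
    is_de <- runif(length(gene_universe)) < config$frac_de_genes
    de_genes <- tibble(
      gene_id = gene_universe,
      log2fc = ifelse(is_de,
                      runif(length(gene_universe), 0.75, 3) *
                        sample(c(-1, 1), length(gene_universe), replace = TRUE),
                      runif(length(gene_universe), -0.75, 0.75)),
      q_value = ifelse(is_de,
                       runif(length(gene_universe), 0, 0.05),
                       runif(length(gene_universe), 0.05, 1))
    )

    regions <- expand_flanks(events, genome, config$flank)
    sig_idx <- which(sig)
    null_idx <- which(!sig)
    planted_sig <- plant_clip_tags(regions[sig_idx, ],
                                   config$planted_overlap_sig,
                                   config$tag_length)
    planted_null <- plant_clip_tags(regions[null_idx, ],
                                    config$planted_overlap_ctrl,
                                    config$tag_length)
    tag_planted <- logical(n_events)
    tag_planted[sig_idx] <- planted_sig$planted
    tag_planted[null_idx] <- planted_null$planted
    tags <- bind_rows(
      planted_sig$tags |> mutate(source = events$event_id[sig_idx[.data$source]]),
      planted_null$tags |> mutate(source = events$event_id[null_idx[.data$source]])
    ) |>
      arrange(.data$chrom, .data$start, .data$end)

    sequences <- NULL
    if (write_sequences) {
      sequences <- synthesise_genome(genome, regions[sig_idx, ], config)
    }

    truth <- tibble(
      event_id = events$event_id,
      stratum = stratum,
      region_chrom = regions$chrom,
      region_start = regions$start,
      region_end = regions$end,
      tag_planted = tag_planted
    )
    list(events = events, de_genes = de_genes, tags = tags,
         truth = truth, sequences = sequences)
  })

  paths <- list(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    events = file.path(dir, "events.tsv"),
    exon_catalog = file.path(dir, "exon_catalog.tsv"),
    de_genes = file.path(dir, "de_genes.tsv"),
    clip_tags = file.path(dir, "clip_tags.bed"),
    fasta = if (write_sequences) file.path(dir, "genome.fa") else NULL
  )
  write_chrom_sizes(genome, paths$chrom_sizes)
  write_events(out$events, paths$events)
  readr::write_tsv(
    out$events |>
      select("event_id", "gene_id", "chrom", "start", "end", "strand"),
    paths$exon_catalog
  )
  readr::write_tsv(out$de_genes, paths$de_genes)
  write_bed(out$tags |> rename(name = "source"), paths$clip_tags)
  if (write_sequences) {
    Biostrings::writeXStringSet(out$sequences, paths$fasta, width = 80)
  }

  truth <- out$truth
  attr(truth, "config") <- config
  list(paths = paths, genome = genome, events = out$events,
       de_genes = out$de_genes, tags = out$tags, truth = truth,
       config = config)
}

# random genome with YCAY planted genome-wide at motif_density_bg per kb
# and additionally inside significant regions at motif_density_sig per kb
synthesise_genome <- function(genome, sig_regions, config) {
  seqs <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    k <- 4L
    n_bg <- if (config$motif_density_bg > 0) {
      rpois(1, config$motif_density_bg * len / 1000)
    } else 0L
    if (n_bg > 0) {
      pos <- floor(runif(n_bg, min = 1, max = len - k + 2))
      for (p in pos) chars[p:(p + k - 1)] <- realise_iupac("YCAY")
    }
    regs <- sig_regions[sig_regions$chrom == genome$chrom[i], ]
    if (nrow(regs) > 0 && config$motif_density_sig > 0) {
      n_per <- rpois(nrow(regs),
                     config$motif_density_sig *
                       (regs$end - regs$start) / 1000)
      for (j in which(n_per > 0)) {
        pos <- floor(runif(n_per[j], min = regs$start[j] + 1,
                           max = regs$end[j] - k + 2))
        for (p in pos) chars[p:(p + k - 1)] <- realise_iupac("YCAY")
      }
    }
    paste(chars, collapse = "")
  })
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- genome$chrom
  x
}
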
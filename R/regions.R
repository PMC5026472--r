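#' Configuration for region-group construction
#'
#' Holds the constants of the three-group extraction: 500 bp flanks around
#' exons, FDR and |dInc| thresholds defining significance, the exclusion
#' FDR for mixed genes, and the size/count of the random background group.
#'
#' @param flank Bases of flanking sequence added on both sides of each exon
#'   (default 500).
#' @param fdr_significant Significance threshold on FDR (default 0.05;
#'   strict `<` for group 1, `>=` defines group-2 candidacy).
#' @param dinc_min Absolute inclusion-difference threshold for group 1
#'   (default 0.1, strict `>`).
#' @param exclusion_fdr Mixed-gene exclusion threshold: a group-2 candidate
#'   is dropped when its gene also has an exon with `fdr < exclusion_fdr`
#'   (default 0.05).
#' @param random_n Number of random background regions (default 10000).
#' @param random_length Length of each random region, bases (default 100).
#' @param seed Seed for the random group.
#' @return A validated list of class `"group_config"`.
#' @export
group_config <- function(flank = 500, fdr_significant = 0.05,
                         dinc_min = 0.1, exclusion_fdr = 0.05,
                         random_n = 10000, random_length = 100,
                         seed = 1L) {
  cfg <- list(flank = flank, fdr_significant = fdr_significant,
              dinc_min = dinc_min, exclusion_fdr = exclusion_fdr,
              random_n = random_n, random_length = random_length,
              seed = as.integer(seed))
  if (cfg$flank < 0) {
    abort("flank must be >= 0", class = "spliceclip_validation_error")
  }
  for (f in c("fdr_significant", "dinc_min", "exclusion_fdr")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0(f, " must lie in [0,1]"),
            class = "spliceclip_validation_error")
    }
  }
  if (cfg$random_n < 0 || cfg$random_length <= 0) {
    abort("random_n must be >= 0 and random_length > 0",
          class = "spliceclip_validation_error")
  }
  structure(cfg, class = "group_config")
}

new_region_group <- function(name, regions) {
  structure(list(name = name, regions = regions),
            class = "region_group")
}

#' @export
print.region_group <- function(x, ...) {
  cat("<region_group '", x$name, "': ", nrow(x$regions), " regions>\n",
      sep = "")
  invisible(x)
}

#' Build the significant-exon region group
#'
#' Group 1 of the three-group extraction: exons of events passing the
#' significance filter (`fdr < fdr_significant` and
#' `|dInc| > dinc_min`), expanded by `flank` bases on both sides, sorted,
#' and deduplicated on exact coordinates. The originating `event_id` is
#' kept as per-region provenance (first contributor wins on duplicates).
#'
#' @param events A splice-event tibble.
#' @param genome Chromosome sizes tibble.
#' @param config A [group_config()].
#' @return A `region_group` (list with `name` and a sorted interval tibble
#'   `regions` carrying `event_id` provenance).
#' @export
build_significant_group <- function(events, genome, config = group_config()) {
  validate_events(events)
  sig <- filter_significant(events, config$fdr_significant, config$dinc_min)
  regions <- sig |>
    select("chrom", "start", "end", "strand", "event_id") |>
    expand_flanks(genome, config$flank) |>
    sort_dedup()
  new_region_group("significant", regions)
}

#' Build the non-significant-exon region group
#'
#' Group 2: exons with `fdr >= fdr_significant` (candidacy uses FDR only).
#' A candidate is then excluded when its gene also contains at least one
#' exon with `fdr < exclusion_fdr` — genes mixing significant and
#' non-significant exons contribute nothing to the control group.
#' Survivors are flank-expanded, sorted and deduplicated.
#'
#' @inheritParams build_significant_group
#' @return A `region_group` named `"nonsignificant"`.
#' @export
build_nonsignificant_group <- function(events, genome,
                                       config = group_config()) {
  validate_events(events)
  candidates <- events |> filter(.data$fdr >= config$fdr_significant)
  mixed_genes <- events |>
    filter(.data$fdr < config$exclusion_fdr) |>
    pull("gene_id") |>
    unique()
  survivors <- candidates |> filter(!.data$gene_id %in% mixed_genes)
  regions <- survivors |>
    select("chrom", "start", "end", "strand", "event_id") |>
    expand_flanks(genome, config$flank) |>
    sort_dedup()
  new_region_group("nonsignificant", regions)
}

#' Build the random background region group
#'
#' Group 3: fixed-length regions sampled uniformly from the genome (see
#' [sample_random_regions()]), sorted and deduplicated. These regions are
#' sampled at their final length and are not flank-expanded.
#'
#' @inheritParams build_significant_group
#' @return A `region_group` named `"random"` with `"random_k"` provenance
#'   ids.
#' @export
build_random_group <- function(genome, config = group_config()) {
  regions <- sample_random_regions(genome, n = config$random_n,
                                   region_length = config$random_length,
                                   seed = config$seed)
  regions$event_id <- sprintf("random_%d", seq_len(nrow(regions)))
  new_region_group("random", sort_dedup(regions))
}

#' Build all three region groups
#'
#' @inheritParams build_significant_group
#' @return A named list of three `region_group`s: `significant`,
#'   `nonsignificant`, `random`.
#' @export
build_region_groups <- function(events, genome, config = group_config()) {
  list(
    significant = build_significant_group(events, genome, config),
    nonsignificant = build_nonsignificant_group(events, genome, config),
    random = build_random_group(genome, config)
  )
}

#' Write region groups as BED6 plus provenance TSV
#'
#' @param groups A named list of `region_group`s.
#' @param dir Output directory.
#' @return Tibble of written paths, invisibly.
#' @export
write_region_groups <- function(groups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map(groups, function(g) {
    bed <- file.path(dir, paste0("group_", g$name, ".bed"))
    prov <- file.path(dir, paste0("group_", g$name, ".provenance.tsv"))
    write_bed(g$regions |> rename(name = "event_id"), bed)
    readr::write_tsv(
      g$regions |> select("event_id", "chrom", "start", "end", "strand"),
      prov
    )
    tibble(group = g$name, bed = bed, provenance = prov)
  })
  invisible(bind_rows(paths))
}

#' Read region groups written by [write_region_groups()]
#'
#' @param dir Directory holding `group_<name>.bed` files.
#' @param names Group names to read.
#' @return Named list of `region_group`s.
#' @export
read_region_groups <- function(dir,
                               names = c("significant", "nonsignificant",
                                         "random")) {
  groups <- lapply(names, function(nm) {
    path <- file.path(dir, paste0("group_", nm, ".bed"))
    if (!file.exists(path)) {
      abort(paste0("missing region group file: ", path),
            class = "spliceclip_validation_error")
    }
    x <- read_bed(path)
    if ("name" %in% names(x)) x <- x |> rename(event_id = "name")
    new_region_group(nm, sort_dedup(x))
  })
  setNames(groups, names)
}
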
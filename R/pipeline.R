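#' Pipeline configuration
#'
#' One validated object driving the end-to-end analysis. Either a
#' `synthetic` section ([synthetic_config()] arguments) or a full set of
#' `inputs` paths must be supplied.
#'
#' @param synthetic `NULL`, or a list of [synthetic_config()] arguments;
#'   when present the pipeline generates its own inputs.
#' @param inputs `NULL`, or a named list of paths: `events`, `de_genes`,
#'   `tags`, `genome` (chrom.sizes) and optionally `fasta` and `events_b`
#'   (a second event table; when present the significant gene sets of the
#'   two tables are also overlapped).
#' @param group List of [group_config()] arguments (flank, thresholds,
#'   random group size).
#' @param stranded Strand-aware tag intersection (default `FALSE`).
#' @param correction Yates correction for the chi-squared tests (default
#'   `FALSE`).
#' @param motif List with `k` (default 4), `pattern` (default `"YCAY"`)
#'   and `background` (`"nonsignificant"` or `"random"`).
#' @param seed Integer seed propagated to every stochastic stage.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            group = list(), stranded = FALSE,
                            correction = FALSE,
                            motif = list(), seed = 1L) {
  if (is.null(synthetic) && is.null(inputs)) {
    abort("config needs either a synthetic section or an inputs section",
          class = "spliceclip_validation_error")
  }
  if (is.null(synthetic)) {
    needed <- c("events", "de_genes", "tags", "genome")
    missing_paths <- setdiff(needed, names(inputs))
    if (length(missing_paths) > 0) {
      abort(paste0("inputs section is missing: ",
                   paste(missing_paths, collapse = ", ")),
            class = "spliceclip_validation_error")
    }
  }
  motif <- utils::modifyList(
    list(k = 4L, pattern = "YCAY", background = "nonsignificant"), motif
  )
  if (!motif$background %in% c("nonsignificant", "random")) {
    abort("motif background must be 'nonsignificant' or 'random'",
          class = "spliceclip_validation_error")
  }
  cfg <- list(
    synthetic = synthetic, inputs = inputs, group = group,
    stranded = isTRUE(stranded), correction = isTRUE(correction),
    motif = motif, seed = as.integer(seed)
  )
  # fail fast on bad sub-configs
  if (!is.null(synthetic)) do.call(synthetic_config, synthetic)
  do.call(group_config, group)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  result <- tryCatch(
    force(expr),
    error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "spliceclip_stage_error", parent = e)
    }
  )
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (optional), read and
#' filter event tables, summarise (type tallies, threshold sweep, gene-set
#' overlaps), build the three region groups, CLIP-tag enrichment, and
#' motif enrichment (when sequences are available) — writing every result
#' as TSV/BED under `out_dir` plus a `manifest.tsv` of per-file MD5
#' checksums. All randomness derives from `config$seed`, so a repeated run
#' with the same config is byte-identical. Progress is logged to stderr.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return A list: `manifest` (tibble stage/file/md5), `config_hash`,
#'   `outputs` (the in-memory results), `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  outputs <- list()

  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    syn_args$seed <- syn_args$seed %||% config$seed
    dataset <- run_stage("simulate", generate_dataset(
      do.call(synthetic_config, syn_args),
      file.path(out_dir, "synthetic")
    ))
    inputs <- list(events = dataset$paths$events,
                   de_genes = dataset$paths$de_genes,
                   tags = dataset$paths$clip_tags,
                   genome = dataset$paths$chrom_sizes,
                   fasta = dataset$paths$fasta)
    outputs$truth <- dataset$truth
    files$simulate <- unlist(dataset$paths, use.names = FALSE)
  } else {
    inputs <- config$inputs
  }

  loaded <- run_stage("load", {
    list(
      events = read_events(inputs$events),
      de = read_de_genes(inputs$de_genes),
      tags = read_bed(inputs$tags),
      genome = read_chrom_sizes(inputs$genome),
      events_b = if (!is.null(inputs$events_b)) read_events(inputs$events_b)
    )
  })

  gcfg_args <- config$group
  gcfg_args$seed <- gcfg_args$seed %||% config$seed
  gcfg <- do.call(group_config, gcfg_args)

  outputs$summaries <- run_stage("filter", {
    sig <- filter_significant(loaded$events, gcfg$fdr_significant,
                              gcfg$dinc_min)
    tally <- tally_event_types(sig)
    sweep <- threshold_sweep(loaded$events)
    de_ids <- filter_de_genes(loaded$de)
    spliced_genes <- collapse_to_genes(sig)
    overlaps <- set_overlap(spliced_genes, de_ids) |>
      mutate(comparison = "spliced_genes_vs_de_genes", .before = 1)
    if (!is.null(loaded$events_b)) {
      sig_b <- filter_significant(loaded$events_b, gcfg$fdr_significant,
                                  gcfg$dinc_min)
      overlaps <- bind_rows(
        overlaps,
        set_overlap(spliced_genes, collapse_to_genes(sig_b)) |>
          mutate(comparison = "spliced_genes_a_vs_b", .before = 1)
      )
    }
    f <- list(
      filtered_events = file.path(out_dir, "filtered_events.tsv"),
      tally = file.path(out_dir, "event_type_tally.tsv"),
      sweep = file.path(out_dir, "threshold_sweep.tsv"),
      overlaps = file.path(out_dir, "overlap_summary.tsv")
    )
    write_events(sig, f$filtered_events)
    readr::write_tsv(tally, f$tally)
    readr::write_tsv(sweep, f$sweep)
    readr::write_tsv(overlaps, f$overlaps)
    files$filter <- unlist(f, use.names = FALSE)
    list(significant = sig, tally = tally, sweep = sweep,
         overlaps = overlaps)
  })

  outputs$groups <- run_stage("regions", {
    groups <- build_region_groups(loaded$events, loaded$genome, gcfg)
    written <- write_region_groups(groups, file.path(out_dir, "regions"))
    files$regions <- c(written$bed, written$provenance)
    groups
  })

  outputs$enrichment <- run_stage("enrich", {
    enr <- run_enrichment(outputs$groups, loaded$tags,
                          stranded = config$stranded,
                          correction = config$correction)
    f1 <- file.path(out_dir, "enrichment_groups.tsv")
    f2 <- file.path(out_dir, "enrichment_tests.tsv")
    write_enrichment(enr, f1, f2)
    files$enrich <- c(f1, f2)
    enr
  })

  if (!is.null(inputs$fasta)) {
    outputs$motifs <- run_stage("motifs", {
      fasta <- Biostrings::readDNAStringSet(inputs$fasta)
      fg <- extract_sequences(outputs$groups$significant$regions, fasta)
      bg <- extract_sequences(
        outputs$groups[[config$motif$background]]$regions, fasta
      )
      km <- kmer_enrichment(fg, bg, k = config$motif$k,
                            motif = config$motif$pattern)
      f <- file.path(out_dir, "motif_enrichment.tsv")
      readr::write_tsv(km, f)
      files$motifs <- f
      km
    })
  }

  manifest <- run_stage("manifest", {
    m <- purrr::imap(files, function(fs, stage) {
      tibble(stage = stage, file = sub(paste0("^", out_dir, "/?"), "", fs),
             md5 = unname(tools::md5sum(fs)))
    }) |> bind_rows()
    readr::write_tsv(m, file.path(out_dir, "manifest.tsv"))
    m
  })

  list(manifest = manifest, config_hash = rlang::hash(unclass(config)),
       outputs = outputs, out_dir = out_dir)
}

report_section <- function(title, body) {
  paste0("## ", title, "\n\n", body, "\n")
}

tsv_or_missing <- function(path, render) {
  if (file.exists(path)) {
    render(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  } else {
    "MISSING"
  }
}

md_table <- function(df) {
  df <- as.data.frame(df)
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  rows <- apply(df, 1, function(r) paste(r, collapse = " | "))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a human-readable pipeline report
#'
#' Collects the written pipeline outputs into one markdown document: event
#' type tallies, the threshold-sweep matrix, gene-set overlap percentages,
#' the per-group CLIP enrichment table with chi-squared comparisons, and
#' the top motif rows. Sections whose output file is absent are rendered
#' with an explicit `MISSING` marker.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @param path Optional path to also write the report to.
#' @return The report as a single character string, invisibly when `path`
#'   is given.
#' @export
render_report <- function(out_dir, path = NULL) {
  sweep_render <- function(x) {
    wide <- x |>
      tidyr::pivot_wider(names_from = "min_abs_dinc",
                         values_from = "n_events",
                         names_prefix = "dInc>")
    md_table(wide)
  }
  overlap_render <- function(x) {
    lines <- apply(x, 1, function(r) {
      sprintf("- %s: |A|=%s, |B|=%s, shared=%s (%s%% of A, %s%% of B)",
              r[["comparison"]], r[["n_a"]], r[["n_b"]], r[["n_shared"]],
              r[["pct_of_a"]], r[["pct_of_b"]])
    })
    paste(lines, collapse = "\n")
  }
  sections <- c(
    report_section("Event type tally",
                   tsv_or_missing(file.path(out_dir, "event_type_tally.tsv"),
                                  md_table)),
    report_section("Threshold sweep",
                   tsv_or_missing(file.path(out_dir, "threshold_sweep.tsv"),
                                  sweep_render)),
    report_section("Gene-set overlaps",
                   tsv_or_missing(file.path(out_dir, "overlap_summary.tsv"),
                                  overlap_render)),
    report_section("CLIP-tag enrichment", paste0(
      tsv_or_missing(file.path(out_dir, "enrichment_groups.tsv"), md_table),
      "\n\n",
      tsv_or_missing(file.path(out_dir, "enrichment_tests.tsv"), md_table)
    )),
    report_section("Top motif k-mers",
                   tsv_or_missing(file.path(out_dir, "motif_enrichment.tsv"),
                                  function(x) md_table(head(x, 10))))
  )
  report <- paste(c("# Splicing analysis report\n", sections),
                  collapse = "\n")
  if (!is.null(path)) {
    writeLines(report, path)
    return(invisible(report))
  }
  report
}
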
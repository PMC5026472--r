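EVENT_TYPES <- c("SE", "MXE", "RI", "A5SS", "A3SS")

NATIVE_EVENT_COLS <- c("event_id", "event_type", "gene_id", "chrom",
                       "strand", "exonStart_0base", "exonEnd",
                       "IncLevelDifference", "FDR")

#' Read a differential-splicing event table
#'
#' Reads a per-event table of differential exon inclusion results into a
#' tibble of splice events. Two dialects are supported:
#'
#' * `"native"`: the package's own TSV with columns `event_id`,
#'   `event_type` (SE/MXE/RI/A5SS/A3SS), `gene_id`, `chrom`, `strand`,
#'   `exonStart_0base`, `exonEnd`, `IncLevelDifference`, `FDR`.
#' * `"rmats"`: an rMATS `*.MATS` output table (one event type per file;
#'   pass `event_type`), using its `ID`, `GeneID`, `chr`, `strand`,
#'   `exonStart_0base`, `exonEnd`, `IncLevelDifference`, `FDR` columns.
#'
#' Exon coordinates are interpreted 0-based half-open in both dialects
#' (rMATS documents 0-based starts and 1-based-inclusive = half-open ends).
#'
#' @param path Path to a TSV with a header row.
#' @param dialect `"native"` (default) or `"rmats"`.
#' @param event_type Event type to assign when reading the `"rmats"`
#'   dialect, whose files are split by type.
#' @return A tibble with columns `event_id`, `event_type`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `inc_level_diff`, `fdr`.
#' @export
read_events <- function(path, dialect = c("native", "rmats"),
                        event_type = "SE") {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (dialect == "native") {
    required <- NATIVE_EVENT_COLS
  } else {
    required <- c("ID", "GeneID", "chr", "strand", "exonStart_0base",
                  "exonEnd", "IncLevelDifference", "FDR")
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("event table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spliceclip_format_error")
  }
  x <- if (dialect == "native") {
    tibble(
      event_id = as.character(raw$event_id),
      event_type = as.character(raw$event_type),
      gene_id = as.character(raw$gene_id),
      chrom = as.character(raw$chrom),
      start = as.double(raw$exonStart_0base),
      end = as.double(raw$exonEnd),
      strand = as.character(raw$strand),
      inc_level_diff = as.double(raw$IncLevelDifference),
      fdr = as.double(raw$FDR)
    )
  } else {
    tibble(
      event_id = as.character(raw$ID),
      event_type = event_type,
      gene_id = as.character(raw$GeneID),
      chrom = as.character(raw$chr),
      start = as.double(raw$exonStart_0base),
      end = as.double(raw$exonEnd),
      strand = as.character(raw$strand),
      inc_level_diff = as.double(raw$IncLevelDifference),
      fdr = as.double(raw$FDR)
    )
  }
  validate_events(x)
  x
}

#' Write a splice-event table in the native TSV dialect
#' @param events A splice-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- tibble(
    event_id = events$event_id,
    event_type = events$event_type,
    gene_id = events$gene_id,
    chrom = events$chrom,
    strand = events$strand,
    exonStart_0base = as.integer(events$start),
    exonEnd = as.integer(events$end),
    IncLevelDifference = events$inc_level_diff,
    FDR = events$fdr
  )
  readr::write_tsv(out, path)
  invisible(path)
}

validate_events <- function(x) {
  required <- c("event_id", "event_type", "gene_id", "chrom", "start",
                "end", "strand", "inc_level_diff", "fdr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("event table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spliceclip_format_error")
  }
  if (nrow(x) == 0) return(invisible(x))
  bad_type <- which(!x$event_type %in% EVENT_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown event_type at row(s) ",
                 paste(head(bad_type, 5), collapse = ", "),
                 " (must be one of ", paste(EVENT_TYPES, collapse = ", "), ")"),
          class = "spliceclip_validation_error")
  }
  bad_fdr <- which(is.na(x$fdr) | x$fdr < 0 | x$fdr > 1)
  if (length(bad_fdr) > 0) {
    abort(paste0("FDR outside [0,1] at row(s) ",
                 paste(head(bad_fdr, 5), collapse = ", ")),
          class = "spliceclip_validation_error")
  }
  bad_dinc <- which(is.na(x$inc_level_diff) | abs(x$inc_level_diff) > 1)
  if (length(bad_dinc) > 0) {
    abort(paste0("inclusion-level difference outside [-1,1] at row(s) ",
                 paste(head(bad_dinc, 5), collapse = ", ")),
          class = "spliceclip_validation_error")
  }
  if (anyDuplicated(x$event_id) > 0) {
    abort("duplicate event_id values in event table",
          class = "spliceclip_validation_error")
  }
  validate_intervals(x)
  invisible(x)
}

#' Filter events to the significantly regulated stratum
#'
#' Keeps events with `fdr < fdr_max` and `|inc_level_diff| > min_abs_dinc`,
#' both inequalities strict. The defaults (FDR < 0.05, |dInc| > 0.1) are
#' the conventional thresholds for calling an exon differentially spliced
#' from rMATS output.
#'
#' @param events A splice-event tibble.
#' @param fdr_max FDR threshold (strict `<`), default 0.05.
#' @param min_abs_dinc Absolute inclusion-level-difference threshold
#'   (strict `>`), default 0.1.
#' @return The filtered tibble, same columns.
#' @export
filter_significant <- function(events, fdr_max = 0.05, min_abs_dinc = 0.1) {
  stopifnot(fdr_max >= 0, fdr_max <= 1, min_abs_dinc >= 0, min_abs_dinc <= 1)
  events |>
    filter(.data$fdr < fdr_max, abs(.data$inc_level_diff) > min_abs_dinc)
}

#' Read a differential gene-expression table
#'
#' @param path TSV with header columns `gene_id`, `log2fc`, `q_value`.
#' @return A tibble with those three columns.
#' @export
read_de_genes <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  missing_cols <- setdiff(c("gene_id", "log2fc", "q_value"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("DE table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spliceclip_format_error")
  }
  if (any(x$q_value < 0 | x$q_value > 1, na.rm = TRUE)) {
    abort("q_value outside [0,1]", class = "spliceclip_validation_error")
  }
  as_tibble(x[, c("gene_id", "log2fc", "q_value")])
}

#' Select differentially expressed genes
#'
#' Keeps genes with `q_value < q_max` and `|log2fc| > min_abs_l2fc` (both
#' strict), the conventional cutoffs for calling differential expression
#' from a Cuffdiff-style table. Rows duplicated per gene must agree; a
#' gene appearing with conflicting statistics is an input error.
#'
#' @param de A tibble with `gene_id`, `log2fc`, `q_value`.
#' @param q_max q-value threshold (strict `<`), default 0.05.
#' @param min_abs_l2fc Absolute log2-fold-change threshold (strict `>`),
#'   default 0.75.
#' @return Character vector of gene ids.
#' @export
filter_de_genes <- function(de, q_max = 0.05, min_abs_l2fc = 0.75) {
  dup <- de |>
    distinct(.data$gene_id, .data$log2fc, .data$q_value) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("conflicting rows for gene(s): ",
                 paste(head(dup$gene_id, 5), collapse = ", ")),
          class = "spliceclip_validation_error")
  }
  de |>
    filter(.data$q_value < q_max, abs(.data$log2fc) > min_abs_l2fc) |>
    pull("gene_id") |>
    unique()
}

#' Count significant events across a grid of thresholds
#'
#' For every combination of FDR cutoff and absolute inclusion-difference
#' cutoff, counts the events passing [filter_significant()] at those
#' thresholds. Counts are non-increasing as either threshold tightens.
#'
#' @param events A splice-event tibble.
#' @param fdr_levels FDR cutoffs (default `c(0.05, 0.01, 0.001, 1e-4)`).
#' @param dinc_levels Absolute dInc cutoffs (default
#'   `c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75)`).
#' @return A tibble with columns `fdr_max`, `min_abs_dinc`, `n_events`,
#'   one row per grid cell, of class `"threshold_sweep"`.
#' @export
threshold_sweep <- function(events,
                            fdr_levels = c(0.05, 0.01, 0.001, 0.0001),
                            dinc_levels = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75)) {
  if (length(fdr_levels) == 0 || length(dinc_levels) == 0) {
    abort("threshold level lists must be non-empty",
          class = "spliceclip_validation_error")
  }
  grid <- tidyr::expand_grid(fdr_max = fdr_levels, min_abs_dinc = dinc_levels)
  grid$n_events <- purrr::map2_int(
    grid$fdr_max, grid$min_abs_dinc,
    function(a, b) nrow(filter_significant(events, a, b))
  )
  structure(grid, class = c("threshold_sweep", class(grid)))
}

#' Tally events by splicing event type
#'
#' @param events A splice-event tibble.
#' @return A tibble with one row per event type (SE, MXE, RI, A5SS, A3SS)
#'   and columns `event_type`, `n`; `sum(n)` equals `nrow(events)`.
#' @export
tally_event_types <- function(events) {
  validate_events(events)
  counts <- table(factor(events$event_type, levels = EVENT_TYPES))
  tibble(event_type = EVENT_TYPES, n = as.integer(counts))
}

#' Collapse events to the set of distinct genes
#'
#' @param events A splice-event tibble.
#' @return Character vector of distinct `gene_id` values.
#' @export
collapse_to_genes <- function(events) {
  unique(events$gene_id)
}

#' Summarise the overlap of two gene sets
#'
#' Computes the shared count and the share of each set that is co-regulated,
#' the quantities behind a two-set Venn diagram. Percentages are rounded to
#' the nearest integer, half away from zero, and are `NA` for an empty set.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return A one-row tibble: `n_a`, `n_b`, `n_shared`, `pct_of_a`,
#'   `pct_of_b`.
#' @examples
#' set_overlap(paste0("g", 1:10), paste0("g", 6:20))
#' @export
set_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  n_shared <- length(intersect(a, b))
  tibble(
    n_a = length(a),
    n_b = length(b),
    n_shared = n_shared,
    pct_of_a = if (length(a) == 0) NA_real_ else
      round_half_up(100 * n_shared / length(a)),
    pct_of_b = if (length(b) == 0) NA_real_ else
      round_half_up(100 * n_shared / length(b))
  )
}

#' Percent-spliced-in from junction counts
#'
#' Length-normalised inclusion fraction
#' `psi = (I/lI) / (I/lI + S/lS)` for inclusion junction count `I`,
#' skipping junction count `S` and their effective lengths. This is
#' plumbing for inspecting event tables, not a reimplementation of any
#' differential-splicing statistical model.
#'
#' @param inclusion_count,skipping_count Non-negative junction read counts.
#' @param inclusion_eff_len,skipping_eff_len Positive effective lengths.
#' @return PSI in `[0, 1]`.
#' @export
compute_psi <- function(inclusion_count, skipping_count,
                        inclusion_eff_len = 1, skipping_eff_len = 1) {
  if (any(inclusion_eff_len <= 0) || any(skipping_eff_len <= 0)) {
    abort("effective lengths must be > 0",
          class = "spliceclip_validation_error")
  }
  if (any(inclusion_count < 0) || any(skipping_count < 0)) {
    abort("junction counts must be >= 0",
          class = "spliceclip_validation_error")
  }
  if (any(inclusion_count + skipping_count == 0)) {
    abort("PSI is undefined when both junction counts are 0",
          class = "spliceclip_validation_error")
  }
  i_norm <- inclusion_count / inclusion_eff_len
  s_norm <- skipping_count / skipping_eff_len
  i_norm / (i_norm + s_norm)
}

#' Plot a threshold sweep
#'
#' One line per FDR cutoff showing how the significant-event count decays
#' as the absolute inclusion-difference cutoff grows.
#'
#' @param object A `"threshold_sweep"` tibble from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$min_abs_dinc, y = .data$n_events,
    colour = factor(.data$fdr_max), group = factor(.data$fdr_max)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "absolute inclusion-level difference cutoff",
                  y = "significant events", colour = "FDR <") +
    ggplot2::theme_minimal()
}
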
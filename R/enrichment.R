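#' Tally CLIP-tag intersections for one region group
#'
#' Counts how many regions of the group intersect at least one tag (a
#' region touched by several tags counts once) and expresses it as a
#' percentage of the group, reported to one decimal.
#'
#' @param group A `region_group`.
#' @param tags CLIP-tag interval tibble.
#' @param stranded Require matching strand (default `FALSE`).
#' @return A one-row tibble: `group_name`, `n_with`, `n_without`,
#'   `pct_with` (`NA` for an empty group).
#' @export
tally_intersections <- function(group, tags, stranded = FALSE) {
  stopifnot(inherits(group, "region_group"))
  n <- nrow(group$regions)
  if (n == 0) {
    return(tibble(group_name = group$name, n_with = 0L, n_without = 0L,
                  pct_with = NA_real_))
  }
  hits <- intersects_any(group$regions, tags, stranded = stranded)$hit
  n_with <- sum(hits)
  tibble(
    group_name = group$name,
    n_with = as.integer(n_with),
    n_without = as.integer(n - n_with),
    pct_with = round_half_up(100 * n_with / n, 1)
  )
}

#' Pearson's chi-squared test on a 2x2 with/without table
#'
#' Compares the with-tag/without-tag split of two region groups with the
#' Pearson chi-squared test on the 2x2 contingency table (df = 1). The
#' default is the uncorrected statistic; `correction = TRUE` applies the
#' Yates continuity adjustment (each |O - E| reduced by 0.5). p-values
#' below 2.2e-16 are additionally rendered as the display string
#' `"< 2.2e-16"`; the numeric field keeps the computed double.
#'
#' @param row_a,row_b One-row tibbles from [tally_intersections()] (or any
#'   tibble with `group_name`, `n_with`, `n_without`).
#' @param correction Apply the Yates continuity correction (default
#'   `FALSE`).
#' @return A one-row tibble: `comparison`, `statistic`, `df`, `p_value`,
#'   `p_display`, `continuity_correction`, `warning` (`NA` or a note when
#'   an expected cell is below 5).
#' @export
chi_squared_2x2 <- function(row_a, row_b, correction = FALSE) {
  m <- rbind(c(row_a$n_with, row_a$n_without),
             c(row_b$n_with, row_b$n_without))
  if (any(m < 0) || any(rowSums(m) == 0)) {
    abort("both groups must be non-empty with non-negative counts",
          class = "spliceclip_validation_error")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort("degenerate 2x2 table: an expected cell is 0",
          class = "spliceclip_degenerate_error")
  }
  warning_note <- if (any(expected < 5)) {
    "expected cell count below 5; chi-squared approximation may be poor"
  } else {
    NA_character_
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correction))
  p <- unname(ct$p.value)
  tibble(
    comparison = paste(row_a$group_name, "vs", row_b$group_name),
    statistic = unname(ct$statistic),
    df = 1L,
    p_value = p,
    p_display = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4),
    continuity_correction = correction,
    warning = warning_note
  )
}

#' CLIP-tag enrichment across the three region groups
#'
#' Tallies tag intersections for the significant, non-significant and
#' random groups and tests the significant group's with-tag proportion
#' against each control with Pearson's chi-squared test (two pairwise
#' comparisons, no omnibus test). A degenerate comparison (for example an
#' empty tag set, which zeroes a whole column) is reported as a row with
#' `NA` statistic and an explanatory `warning` rather than an error.
#'
#' @param groups Named list with exactly the `region_group`s
#'   `significant`, `nonsignificant`, `random`.
#' @param tags CLIP-tag interval tibble.
#' @param stranded Require matching strand (default `FALSE`).
#' @param correction Yates continuity correction (default `FALSE`).
#' @return An object of class `"clip_enrichment"`: list with `rows` (three
#'   contingency rows) and `tests` (two chi-squared comparisons). Use
#'   [tidy()], [glance()] and [autoplot()] on it.
#' @export
run_enrichment <- function(groups, tags, stranded = FALSE,
                           correction = FALSE) {
  needed <- c("significant", "nonsignificant", "random")
  if (!all(needed %in% names(groups))) {
    abort(paste0("groups must contain: ", paste(needed, collapse = ", ")),
          class = "spliceclip_validation_error")
  }
  rows <- bind_rows(lapply(groups[needed], tally_intersections,
                           tags = tags, stranded = stranded))
  one_test <- function(a, b) {
    tryCatch(
      chi_squared_2x2(rows[rows$group_name == a, ],
                      rows[rows$group_name == b, ],
                      correction = correction),
      error = function(e) tibble(
        comparison = paste(a, "vs", b),
        statistic = NA_real_, df = 1L, p_value = NA_real_,
        p_display = NA_character_, continuity_correction = correction,
        warning = conditionMessage(e)
      )
    )
  }
  tests <- bind_rows(
    one_test("significant", "nonsignificant"),
    one_test("significant", "random")
  )
  structure(list(rows = rows, tests = tests), class = "clip_enrichment")
}

#' @export
print.clip_enrichment <- function(x, ...) {
  cat("CLIP-tag intersection enrichment\n\n")
  print(as.data.frame(x$rows), row.names = FALSE)
  cat("\n")
  print(as.data.frame(x$tests[, c("comparison", "statistic", "df",
                                  "p_display", "warning")]),
        row.names = FALSE)
  invisible(x)
}

#' Tidy a CLIP enrichment result
#'
#' @param x A `"clip_enrichment"` object.
#' @param ... Unused.
#' @return The two pairwise chi-squared comparisons as a tibble.
#' @export
tidy.clip_enrichment <- function(x, ...) {
  x$tests
}

#' One-row summary of a CLIP enrichment result
#'
#' @param x A `"clip_enrichment"` object.
#' @param ... Unused.
#' @return A one-row tibble with each group's size and with-tag
#'   percentage and the two p-values.
#' @export
glance.clip_enrichment <- function(x, ...) {
  r <- x$rows
  g <- function(nm, col) r[[col]][r$group_name == nm]
  tibble(
    n_significant = g("significant", "n_with") + g("significant", "n_without"),
    n_nonsignificant = g("nonsignificant", "n_with") +
      g("nonsignificant", "n_without"),
    n_random = g("random", "n_with") + g("random", "n_without"),
    pct_significant = g("significant", "pct_with"),
    pct_nonsignificant = g("nonsignificant", "pct_with"),
    pct_random = g("random", "pct_with"),
    p_vs_nonsignificant = x$tests$p_value[1],
    p_vs_random = x$tests$p_value[2]
  )
}

#' Bar chart of with-tag percentages per region group
#'
#' @param object A `"clip_enrichment"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clip_enrichment <- function(object, ...) {
  d <- object$rows |>
    mutate(group_name = factor(.data$group_name,
                               c("significant", "nonsignificant", "random")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_name,
                                  y = .data$pct_with)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% regions with >= 1 CLIP tag") +
    ggplot2::theme_minimal()
}

#' Write an enrichment result as two TSV reports
#'
#' @param x A `"clip_enrichment"` object.
#' @param rows_path Path for the per-group contingency table.
#' @param tests_path Path for the pairwise comparisons.
#' @return `rows_path`, invisibly.
#' @export
write_enrichment <- function(x, rows_path, tests_path) {
  readr::write_tsv(x$rows, rows_path)
  readr::write_tsv(x$tests, tests_path)
  invisible(rows_path)
}
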
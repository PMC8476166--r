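# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a marker assessment into a per-marker table
#'
#' One row per supporting locus (markers with no locus get a single row with
#' NA locus fields) - the long "full table" view of an assessment.
#'
#' @param x A `marker_assessment`.
#' @param ... Unused.
#' @return A tibble: `marker_id`, `status`, `sequence_id`, `env_start`,
#'   `env_end`, `bit_score`, `aligned_length`, `quality`.
#' @export
tidy.marker_assessment <- function(x, ...) {
  rows <- purrr::map(x$per_marker, function(st) {
    if (nrow(st$loci) == 0L) {
      tibble::tibble(
        marker_id = st$marker_id, status = st$status,
        sequence_id = NA_character_, env_start = NA_integer_,
        env_end = NA_integer_, bit_score = NA_real_,
        aligned_length = NA_integer_, quality = NA_character_
      )
    } else {
      tibble::tibble(
        marker_id = st$marker_id, status = st$status,
        sequence_id = st$loci$sequence_id, env_start = st$loci$env_start,
        env_end = st$loci$env_end, bit_score = st$loci$bit_score,
        aligned_length = st$loci$aligned_length, quality = st$loci$quality
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a marker assessment
#'
#' @param x A `marker_assessment`.
#' @param ... Unused.
#' @return A one-row tibble with ids, counts, percentages, marker total,
#'   genetic code and the score string.
#' @export
glance.marker_assessment <- function(x, ...) {
  p <- completeness_pct(x)
  tibble::tibble(
    input_id = x$input_id, dataset = x$dataset_name, mode = x$mode,
    workflow = x$workflow_label,
    C = p[["C"]], S_pct = p[["S"]], D_pct = p[["D"]],
    F_pct = p[["F"]], M_pct = p[["M"]],
    S = unname(x$counts[["S"]]), D = unname(x$counts[["D"]]),
    F = unname(x$counts[["F"]]), M = unname(x$counts[["M"]]), n = x$n,
    genetic_code = x$genetic_code_used, summary = format_summary(x)
  )
}

#' @rdname tidy.marker_assessment
#' @export
tidy.depletion_report <- function(x, ...) x$table

#' Per-level summary of a depletion report
#'
#' @param x A `depletion_report`.
#' @param ... Unused.
#' @return A tibble with one row per (level, mode): mean missing count and
#'   percentage, mean precision, replicate count.
#' @export
glance.depletion_report <- function(x, ...) {
  x$table |>
    dplyr::group_by(.data$level, .data$mode) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mean_missing = mean(.data$M),
      mean_missing_pct = mean(100 * .data$M / .data$n),
      mean_precision = mean(.data$precision, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @rdname tidy.marker_assessment
#' @export
tidy.lineage_decision <- function(x, ...) {
  dplyr::mutate(x$path_scores, chosen = .data$dataset %in% x$path)
}

#' Completeness category bar for an assessment
#'
#' @param object A `marker_assessment`.
#' @param ... Unused.
#' @return A ggplot object: a single stacked bar of the S/D/F/M percentages.
#' @export
autoplot.marker_assessment <- function(object, ...) {
  p <- completeness_pct(object)
  df <- tibble::tibble(
    category = factor(c("Complete (single)", "Complete (duplicated)",
                        "Fragmented", "Missing"),
                      levels = c("Missing", "Fragmented",
                                 "Complete (duplicated)", "Complete (single)")),
    pct = c(p[["S"]], p[["D"]], p[["F"]], p[["M"]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = object$input_id, y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c(
      "Complete (single)" = "#3b82c4", "Complete (duplicated)" = "#1d4f78",
      "Fragmented" = "#f2c45f", "Missing" = "#d1493e"
    )) +
    ggplot2::labs(x = NULL, y = "% of markers", fill = NULL,
                  subtitle = format_summary(object)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Missingness versus depletion level
#'
#' Plots the reported missing percentage per replicate against the depletion
#' level, with the expected (truth) missingness as a reference line.
#'
#' @param object A `depletion_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depletion_report <- function(object, ...) {
  tab <- object$table |>
    dplyr::mutate(missing_pct = 100 * .data$M / .data$n,
                  expected_pct = 100 * .data$n_removed_truth / .data$n)
  ggplot2::ggplot(tab, ggplot2::aes(x = 100 * .data$level, y = .data$missing_pct)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_pct), colour = "red",
                       linewidth = 0.4) +
    ggplot2::geom_jitter(width = 1, height = 0, alpha = 0.7, size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = "% of marker genes removed", y = "% markers reported missing",
                  subtitle = paste("protocol:", object$plan$protocol)) +
    ggplot2::theme_minimal()
}
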
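# Plain-file output interfaces: per-marker full table as TSV, the one-line
# summary as text, and a structured JSON summary.

#' Write assessment outputs to a directory
#'
#' Emits the standard result files for one assessment: `full_table.tsv` (one
#' row per marker locus: marker, status, sequence, envelope, score, length),
#' `short_summary.txt` (the one-line score string plus metadata), and
#' `summary.json` (counts, percentages and configuration echoes).
#'
#' @param result A `marker_assessment`.
#' @param dir Output directory (created if needed).
#' @param config Optional [search_config()] echoed into the JSON summary.
#' @return Named character vector of written paths, invisibly.
#' @export
write_assessment <- function(result, dir, config = NULL) {
  stopifnot(inherits(result, "marker_assessment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    full_table = file.path(dir, "full_table.tsv"),
    summary_txt = file.path(dir, "short_summary.txt"),
    summary_json = file.path(dir, "summary.json")
  )
  tab <- tidy(result)
  utils::write.table(tab, paths[["full_table"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(
    paste0("# input: ", result$input_id),
    paste0("# dataset: ", result$dataset_name),
    paste0("# workflow: ", result$workflow_label),
    format_summary(result)
  ), paths[["summary_txt"]])
  p <- completeness_pct(result)
  payload <- list(
    input_id = result$input_id,
    dataset = result$dataset_name,
    mode = result$mode,
    workflow = result$workflow_label,
    counts = as.list(result$counts),
    n = result$n,
    percentages = as.list(p),
    one_line = format_summary(result),
    genetic_code = if (is.na(result$genetic_code_used)) NULL else result$genetic_code_used,
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(payload, paths[["summary_json"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Write a batch summary table as TSV
#'
#' @param batch The tibble returned by [run_batch()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_batch_summary <- function(batch, path) {
  utils::write.table(dplyr::select(batch, -dplyr::any_of("decision")), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
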
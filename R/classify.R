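# Turning per-marker hits into Complete(Single/Duplicated)/Fragmented/Missing
# statuses and aggregate completeness results.

STATUS_LEVELS <- c("complete_single", "complete_duplicated", "fragmented", "missing")

# Reduce a marker's hits to distinct loci. Hits on different target
# sequences are always distinct; on the same target, two envelopes that
# overlap by at least 50% of the shorter envelope are treated as the same
# locus and only the best-scoring one is kept.
distinct_loci <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$bit_score), .data$sequence_id,
                         .data$env_start)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$sequence_id[j] != hits$sequence_id[i]) next
      ov <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j]) + 1L
      shorter <- min(hits$aligned_length[i], hits$aligned_length[j])
      if (ov >= 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Classify one marker from its search hits
#'
#' Distinct loci are ranked by quality: a locus is *complete-quality* when its
#' bit score reaches the marker's cutoff and its aligned length lies within
#' two standard deviations of the seed length mean (families with zero sigma
#' require an exact length match); *fragment-quality* when the score reaches
#' the cutoff but the length falls outside that band. The marker is
#' `complete_duplicated` with two or more complete-quality loci,
#' `complete_single` with exactly one, `fragmented` with none complete but at
#' least one fragment, and `missing` otherwise.
#'
#' @param hits Tibble of hits for this marker (as returned by
#'   [search_markers()]), possibly empty.
#' @param family The [marker_family()] the hits belong to.
#' @return A list of class `marker_status` with fields `marker_id`, `status`,
#'   and `loci` (tibble of supporting loci with a `quality` column).
#' @export
classify_marker <- function(hits, family) {
  stopifnot(inherits(family, "marker_family"))
  if (nrow(hits) > 0L && !all(hits$marker_id == family$marker_id)) {
    stop("hits for classify_marker must all belong to marker '",
         family$marker_id, "'", call. = FALSE)
  }
  loci <- distinct_loci(hits)
  if (nrow(loci) > 0L) {
    scored <- loci$bit_score >= family$score_cutoff
    in_band <- abs(loci$aligned_length - family$length_mean) <=
      2 * family$length_sigma
    loci$quality <- dplyr::case_when(
      scored & in_band ~ "complete",
      scored ~ "fragment",
      TRUE ~ "weak"
    )
    loci <- loci[loci$quality != "weak", , drop = FALSE]
  } else {
    loci$quality <- character()
  }
  n_complete <- sum(loci$quality == "complete")
  status <- if (n_complete >= 2L) "complete_duplicated"
  else if (n_complete == 1L) "complete_single"
  else if (nrow(loci) >= 1L) "fragmented"
  else "missing"
  if (status == "missing") loci <- loci[0, , drop = FALSE]
  structure(
    list(marker_id = family$marker_id, status = status,
         loci = tibble::as_tibble(loci)),
    class = "marker_status"
  )
}

#' Assess an input against a marker dataset
#'
#' The central entry point: searches the input for every marker of the
#' dataset and aggregates per-marker statuses into Complete (Single +
#' Duplicated), Fragmented and Missing counts.
#'
#' Modes:
#' * `"genome"` - nucleotide input; for bacterial/archaeal/viral datasets the
#'   genetic code is auto-selected from the dataset's candidates by coding
#'   density, then the two-pass ORF workflow runs ([two_pass_genome_search()]).
#' * `"proteins"` - amino-acid gene set, searched directly in one pass.
#' * `"transcriptome"` - nucleotide transcripts, searched via six-frame
#'   translation split at stop codons.
#'
#' @param input Sequences: named character vector, `XStringSet`, or FASTA
#'   path (nucleotide for genome/transcriptome, amino acid for proteins).
#' @param dataset A [marker_dataset()].
#' @param mode `"genome"`, `"proteins"`, or `"transcriptome"`.
#' @param config A [search_config()].
#' @param input_id Identifier recorded in the result; defaults to the file
#'   stem when `input` is a path, else `"input"`.
#' @param sensitivity Sensitivity override for the single-pass modes
#'   (proteins/transcriptome); defaults to the config's first-pass value.
#' @return An object of class `marker_assessment`; see [tidy.marker_assessment()]
#'   and [glance.marker_assessment()] for tabular views and
#'   [format_summary()] for the one-line score string.
#' @export
assess <- function(input, dataset, mode = c("genome", "proteins", "transcriptome"),
                   config = search_config(), input_id = NULL,
                   sensitivity = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "marker_dataset"), inherits(config, "search_config"))
  if (is.null(input_id)) {
    input_id <- if (is.character(input) && length(input) == 1L && file.exists(input)) {
      sub("\\.[^.]*$", "", basename(input))
    } else "input"
  }
  seqs <- as_seq_vector(input, if (mode == "proteins") "AA" else "DNA")
  if (length(seqs) == 0L || all(!nzchar(seqs))) {
    stop("input '", input_id, "' contains no sequences", call. = FALSE)
  }
  genetic_code_used <- NA_integer_
  if (mode == "genome") {
    tp <- two_pass_genome_search(seqs, dataset, config)
    hits <- tp$hits
    genetic_code_used <- tp$genetic_code
    workflow <- "genome (two-pass ORF)"
  } else if (mode == "proteins") {
    s <- sensitivity %||% config$sensitivity_pass1
    hits <- search_markers(dataset, seqs, sensitivity = s)
    workflow <- "proteins"
  } else {
    code <- if (length(dataset$genetic_codes)) dataset$genetic_codes[[1]] else 1L
    peps <- six_frame_peptides(seqs, table = code,
                               min_aa = config$min_orf_nt %/% 3L)
    prots <- stats::setNames(peps$protein, peps$peptide_id)
    s <- sensitivity %||% config$sensitivity_pass1
    hits <- search_markers(dataset, prots, sensitivity = s)
    genetic_code_used <- as.integer(code)
    workflow <- "transcriptome (six-frame)"
  }
  statuses <- lapply(dataset$markers, function(fam) {
    classify_marker(hits[hits$marker_id == fam$marker_id, , drop = FALSE], fam)
  })
  new_assessment(input_id, dataset, mode, workflow, statuses, genetic_code_used)
}

new_assessment <- function(input_id, dataset, mode, workflow, statuses,
                           genetic_code_used = NA_integer_) {
  status_vec <- vapply(statuses, function(s) s$status, character(1))
  counts <- c(
    S = sum(status_vec == "complete_single"),
    D = sum(status_vec == "complete_duplicated"),
    F = sum(status_vec == "fragmented"),
    M = sum(status_vec == "missing")
  )
  structure(
    list(input_id = input_id, dataset_name = dataset$name,
         domain = dataset$domain, mode = mode, workflow_label = workflow,
         counts = counts, n = length(statuses),
         per_marker = statuses,
         genetic_code_used = genetic_code_used),
    class = "marker_assessment"
  )
}

#' Completeness percentages of an assessment
#'
#' Percentages are `100 * count / n`, rounded half-up to one decimal - the
#' rounding used in the printed score string.
#'
#' @param result A `marker_assessment`.
#' @return Named numeric vector `C`, `S`, `D`, `F`, `M`.
#' @export
completeness_pct <- function(result) {
  stopifnot(inherits(result, "marker_assessment"))
  k <- result$counts
  n <- result$n
  pct <- function(x) round_half_up(100 * x / n, 1)
  c(C = pct(k[["S"]] + k[["D"]]), S = pct(k[["S"]]), D = pct(k[["D"]]),
    F = pct(k[["F"]]), M = pct(k[["M"]]))
}

#' One-line completeness score string
#'
#' Renders the canonical one-line summary,
#' `C:<c>%[S:<s>%,D:<d>%],F:<f>%,M:<m>%,n:<n>`, with each percentage rounded
#' half-up to one decimal.
#'
#' @param result A `marker_assessment`.
#' @return A single string.
#' @export
#' @examples
#' # a result with counts S=6, D=0, F=1, M=3 over n=10 markers prints
#' # "C:60.0%[S:60.0%,D:0.0%],F:10.0%,M:30.0%,n:10"
format_summary <- function(result) {
  p <- completeness_pct(result)
  sprintf("C:%.1f%%[S:%.1f%%,D:%.1f%%],F:%.1f%%,M:%.1f%%,n:%d",
          p[["C"]], p[["S"]], p[["D"]], p[["F"]], p[["M"]], result$n)
}

#' @export
print.marker_assessment <- function(x, ...) {
  cat("<marker_assessment>", x$input_id, "vs", x$dataset_name,
      paste0("[", x$workflow_label, "]"), "\n  ", format_summary(x), "\n")
  if (!is.na(x$genetic_code_used)) {
    cat("   genetic code:", x$genetic_code_used, "\n")
  }
  invisible(x)
}

#' Recalculate scores after excluding markers
#'
#' The "parasitic check": markers on a curated exclusion list (e.g. genes
#' systematically absent from genome-reduced parasites) are removed from the
#' result and all counts and percentages are recomputed on the reduced marker
#' total, so their absence no longer counts as incompleteness.
#'
#' @param result A `marker_assessment`.
#' @param exclusion_list Character vector of marker ids; must be a subset of
#'   the result's markers.
#' @return A new `marker_assessment` over `n - length(exclusions)` markers.
#' @export
parasitic_recalculate <- function(result, exclusion_list) {
  stopifnot(inherits(result, "marker_assessment"))
  unknown <- setdiff(exclusion_list, names(result$per_marker))
  if (length(unknown) > 0L) {
    stop("exclusion list contains markers not in the dataset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(result$per_marker), exclusion_list)
  if (length(keep) == 0L) {
    stop("exclusion list removes every marker; nothing left to score", call. = FALSE)
  }
  out <- result
  out$per_marker <- result$per_marker[keep]
  status_vec <- vapply(out$per_marker, function(s) s$status, character(1))
  out$counts <- c(
    S = sum(status_vec == "complete_single"),
    D = sum(status_vec == "complete_duplicated"),
    F = sum(status_vec == "fragmented"),
    M = sum(status_vec == "missing")
  )
  out$n <- length(keep)
  out$workflow_label <- paste0(result$workflow_label, " + parasitic check")
  out
}

#' Screen an input against the domain root datasets
#'
#' Assesses the input with each root (domain-level) dataset and reports the
#' completeness per root. High completeness under an off-domain root may
#' indicate contamination by species from another domain (or horizontal
#' transfer); a configurable advisory threshold flags such roots. A nonzero
#' background level of cross-domain matches is expected and is not by itself
#' evidence of contamination.
#'
#' @param input Sequences as in [assess()].
#' @param root_datasets List of root [marker_dataset()]s (typically the
#'   bacteria, archaea and eukaryota roots), or a [dataset_tree()] whose
#'   roots are used.
#' @param config A [search_config()].
#' @param mode Assessment mode, default `"genome"`.
#' @param advisory_threshold Completeness percentage above which an
#'   off-domain root is flagged (default 40; heuristic and configurable).
#' @return A tibble with one row per root: `dataset`, `domain`,
#'   `complete_pct`, `missing`, `home` (logical, best-scoring root), and
#'   `flagged`.
#' @export
cross_domain_screen <- function(input, root_datasets, config = search_config(),
                                mode = "genome", advisory_threshold = 40) {
  if (inherits(root_datasets, "dataset_tree")) {
    root_datasets <- root_datasets$datasets[root_datasets$roots]
  }
  stopifnot(length(root_datasets) >= 1)
  rows <- purrr::map(root_datasets, function(ds) {
    res <- assess(input, ds, mode = mode, config = config)
    p <- completeness_pct(res)
    tibble::tibble(dataset = ds$name, domain = ds$domain,
                   complete_pct = p[["C"]], missing = unname(res$counts[["M"]]))
  })
  out <- dplyr::bind_rows(rows)
  best <- which.max(out$complete_pct)
  out$home <- seq_len(nrow(out)) == best
  out$flagged <- !out$home & out$complete_pct > advisory_threshold
  out
}
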
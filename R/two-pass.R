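# The two-pass genome workflow: a fast first search, then a more sensitive
# rescue pass restricted to the markers still missing.

#' Two-pass marker search on a genome
#'
#' Pass 1 extracts ORFs at the configured minimum span and searches all
#' markers at the first-pass sensitivity. Markers with at least one hit
#' reaching their full classification cutoff are considered recovered and are
#' not searched again. Pass 2 re-extracts ORFs at half the minimum span and
#' searches only the remaining markers at the (higher) second-pass
#' sensitivity, so short or weakly matching genes missed by the fast pass can
#' still be found.
#'
#' For bacterial, archaeal and viral datasets the genetic code is first
#' auto-selected from the dataset's candidate codes by coding density
#' ([select_genetic_code()]); eukaryotic datasets use the standard code.
#'
#' @param genome Nucleotide sequences (named character vector, `DNAStringSet`,
#'   or FASTA path).
#' @param dataset A [marker_dataset()].
#' @param config A [search_config()].
#' @return A list with `hits` (hit tibble with a `pass` column), `genetic_code`
#'   (table number used), `pass1_recovered` and `pass2_markers` (character
#'   vectors of marker ids).
#' @export
two_pass_genome_search <- function(genome, dataset, config = search_config()) {
  stopifnot(inherits(dataset, "marker_dataset"), inherits(config, "search_config"))
  genome <- as_seq_vector(genome, "DNA")
  code <- if (dataset$domain %in% PROK_DOMAINS) {
    select_genetic_code(genome, dataset$genetic_codes, config$min_orf_nt)
  } else if (length(dataset$genetic_codes)) {
    dataset$genetic_codes[[1]]
  } else {
    1L
  }

  orfs1 <- extract_orfs(genome, code, config$min_orf_nt)
  prots1 <- stats::setNames(orfs1$protein, orfs1$orf_id)
  hits1 <- search_markers(dataset, prots1, sensitivity = config$sensitivity_pass1)
  cutoffs <- vapply(dataset$markers, function(m) m$score_cutoff, numeric(1))
  recovered <- names(which(vapply(names(dataset$markers), function(id) {
    any(hits1$bit_score[hits1$marker_id == id] >= cutoffs[[id]])
  }, logical(1))))
  todo <- setdiff(names(dataset$markers), recovered)

  hits2 <- empty_hit_tibble()
  if (length(todo) > 0L) {
    min2 <- config$min_orf_nt %/% 2L
    min2 <- max(3L, min2 - min2 %% 3L)
    orfs2 <- extract_orfs(genome, code, min2)
    prots2 <- stats::setNames(orfs2$protein, orfs2$orf_id)
    sub <- marker_dataset(
      name = dataset$name, domain = dataset$domain,
      markers = dataset$markers[todo],
      genetic_codes = dataset$genetic_codes, parent = dataset$parent,
      creation_meta = dataset$creation_meta
    )
    hits2 <- search_markers(sub, prots2, sensitivity = config$sensitivity_pass2)
  }

  hits1 <- hits1[hits1$marker_id %in% recovered, , drop = FALSE]
  hits <- dplyr::bind_rows(
    if (nrow(hits1)) dplyr::mutate(hits1, pass = 1L) else NULL,
    if (nrow(hits2)) dplyr::mutate(hits2, pass = 2L) else NULL
  )
  if (nrow(hits) == 0L) hits <- dplyr::mutate(empty_hit_tibble(), pass = integer())
  list(hits = hits, genetic_code = as.integer(code),
       pass1_recovered = recovered, pass2_markers = todo)
}
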
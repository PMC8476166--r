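# Six-frame ORF calling, coding density, and genetic-code auto-selection.
# This is the gene-extraction stage of the genome workflow: a deliberately
# simple maximal start->stop ORF model (one call per stop codon, starting at
# the first start codon after the previous stop). Intron-aware prediction is
# out of scope; genome mode is documented as valid for intron-poor inputs.

#' Extract open reading frames from nucleotide sequences
#'
#' Scans all six reading frames of each input sequence. For every stop codon,
#' the maximal ORF runs from the first start codon after the previous in-frame
#' stop to that stop (inclusive). ORFs shorter than `min_orf_nt` (span
#' including the stop codon) are discarded, as are runs that never reach a
#' stop. Reverse-strand calls are reported in forward-strand coordinates with
#' `nt_start < nt_end`.
#'
#' @param genome Named character vector of nucleotide sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param table Translation table (`translation_table` or NCBI number).
#' @param min_orf_nt Minimum ORF span in nucleotides (start through stop).
#' @return A tibble with one row per ORF: `orf_id`, `sequence_id`, `strand`,
#'   `frame` (0-2 on the scanned strand), `nt_start`, `nt_end` (1-based
#'   inclusive, forward strand), and `protein` (stop excluded; N-containing
#'   codons as `X`).
#' @export
#' @examples
#' extract_orfs(c(chr = "ATGAAATAA"), table = 11, min_orf_nt = 9)
extract_orfs <- function(genome, table = 11, min_orf_nt = 90) {
  table <- as_translation_table(table)
  stopifnot(min_orf_nt >= 3, min_orf_nt %% 3 == 0)
  genome <- as_seq_vector(genome, "DNA")
  if (length(genome) == 0L) {
    return(empty_orf_tibble())
  }
  rows <- purrr::map(names(genome), function(sid) {
    seq_fwd <- genome[[sid]]
    L <- nchar(seq_fwd)
    purrr::map(c("+", "-"), function(strand) {
      s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
      purrr::map(0:2, function(frame) {
        orfs_one_frame(s, sid, strand, frame, L, table, min_orf_nt)
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  if (nrow(out) == 0L) empty_orf_tibble() else out
}

empty_orf_tibble <- function() {
  tibble::tibble(
    orf_id = character(), sequence_id = character(), strand = character(),
    frame = integer(), nt_start = integer(), nt_end = integer(),
    protein = character()
  )
}

# ORFs in one frame of one (possibly reverse-complemented) sequence.
orfs_one_frame <- function(s, sid, strand, frame, L, table, min_orf_nt) {
  n_codons <- (nchar(s) - frame) %/% 3L
  if (n_codons < 2L) return(NULL)
  starts_at <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts_at, starts_at + 2L)
  stop_idx <- which(codons %in% table$stop_codons)
  start_idx <- which(codons %in% table$start_codons)
  if (length(stop_idx) == 0L || length(start_idx) == 0L) return(NULL)
  # governing stop for each start: the nearest stop strictly after it
  gov <- findInterval(start_idx, stop_idx) + 1L
  keep <- gov <= length(stop_idx)
  if (!any(keep)) return(NULL)
  start_idx <- start_idx[keep]
  gov <- gov[keep]
  first_start <- tapply(start_idx, gov, min)
  st <- stop_idx[as.integer(names(first_start))]
  f <- as.integer(first_start)
  span <- 3L * (st - f + 1L)
  ok <- span >= min_orf_nt
  if (!any(ok)) return(NULL)
  f <- f[ok]; st <- st[ok]
  a <- frame + 3L * (f - 1L) + 1L   # local coords on scanned strand
  b <- frame + 3L * st
  prot <- vapply(seq_along(f), function(i) {
    translate_nt(substr(s, a[i], b[i] - 3L), table)
  }, character(1))
  if (strand == "+") {
    nt_start <- a; nt_end <- b
  } else {
    nt_start <- L - b + 1L; nt_end <- L - a + 1L
  }
  tibble::tibble(
    orf_id = sprintf("%s:%d-%d(%s)", sid, nt_start, nt_end, strand),
    sequence_id = sid, strand = strand, frame = as.integer(frame),
    nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
    protein = prot
  )
}

#' Fraction of a genome covered by ORFs
#'
#' Computes the fraction of input positions covered by the union of all ORF
#' spans from both strands under a given translation table. This is the
#' quantity maximised when auto-selecting the genetic code.
#'
#' @inheritParams extract_orfs
#' @return A single number in \[0, 1\].
#' @export
coding_density <- function(genome, table = 11, min_orf_nt = 90) {
  genome <- as_seq_vector(genome, "DNA")
  total <- sum(nchar(genome))
  if (total == 0L) return(0)
  orfs <- extract_orfs(genome, table, min_orf_nt)
  if (nrow(orfs) == 0L) return(0)
  covered <- sum(vapply(split(orfs, orfs$sequence_id), function(d) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$nt_start, d$nt_end))))
  }, numeric(1)))
  covered / total
}

#' Auto-select the genetic code by coding density
#'
#' Evaluates each candidate translation table on the input and returns the
#' identifier of the one yielding the highest coding density. Ties are broken
#' by position in `candidate_tables` (earliest wins), so the dataset's
#' preferred code is kept when the input gives no signal either way.
#'
#' @param genome Nucleotide input (named character vector, `DNAStringSet`, or
#'   FASTA path).
#' @param candidate_tables Ordered vector of NCBI table numbers, typically the
#'   dataset's `genetic_codes`.
#' @param min_orf_nt Minimum ORF span used for the density computation.
#' @return The selected table number (integer).
#' @export
select_genetic_code <- function(genome, candidate_tables, min_orf_nt = 90) {
  stopifnot(length(candidate_tables) >= 1)
  genome <- as_seq_vector(genome, "DNA")
  dens <- vapply(candidate_tables, function(id) {
    coding_density(genome, id, min_orf_nt)
  }, numeric(1))
  as.integer(candidate_tables[[which.max(dens)]])
}

# Six-frame peptides for transcriptome mode: translate every frame fully,
# split at stops, keep fragments of at least min_aa residues. No start-codon
# requirement (transcripts are routinely 5'-truncated).
six_frame_peptides <- function(transcripts, table = 1, min_aa = 30) {
  table <- as_translation_table(table)
  transcripts <- as_seq_vector(transcripts, "DNA")
  rows <- purrr::imap(transcripts, function(seq_fwd, sid) {
    purrr::map(c("+", "-"), function(strand) {
      s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
      purrr::map(0:2, function(frame) {
        n <- nchar(s) - frame
        n <- n - n %% 3L
        if (n < 3L) return(NULL)
        aa <- translate_nt(substr(s, frame + 1L, frame + n), table)
        parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
        parts <- parts[nchar(parts) >= min_aa]
        if (length(parts) == 0L) return(NULL)
        tibble::tibble(
          peptide_id = sprintf("%s|%s%d.%d", sid, strand, frame, seq_along(parts)),
          protein = parts
        )
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  if (nrow(out) == 0L) {
    tibble::tibble(peptide_id = character(), protein = character())
  } else {
    out
  }
}
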
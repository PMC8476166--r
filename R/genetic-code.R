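#' NCBI translation tables
#'
#' Wraps the NCBI genetic-code tables shipped with Biostrings into the small
#' structure the ORF caller needs: a 64-codon map plus the start- and
#' stop-codon sets. Start codons are fixed to the conventional prokaryotic
#' trio ATG/GTG/TTG for every table (the simulator only emits ATG starts, so
#' the exact alternative-start policy does not change fixture results; real
#' inputs with rarer initiators are found from the next canonical start).
#'
#' @param table_id NCBI translation-table number (e.g. 1, 4, 11).
#' @return An object of class `translation_table` with fields `table_id`,
#'   `codon_map` (named character of length 64, stops as `"*"`),
#'   `start_codons`, and `stop_codons`.
#' @export
#' @examples
#' tt <- translation_table(4)
#' tt$codon_map[["TGA"]]   # "W" under table 4
translation_table <- function(table_id) {
  id <- as.character(table_id)
  map <- Biostrings::getGeneticCode(id)
  stops <- names(map)[map == "*"]
  if (length(stops) == 0L) stop("translation table ", id, " has no stop codon", call. = FALSE)
  structure(
    list(
      table_id = as.integer(table_id),
      codon_map = map,
      start_codons = c("ATG", "GTG", "TTG"),
      stop_codons = stops
    ),
    class = "translation_table"
  )
}

as_translation_table <- function(x) {
  if (inherits(x, "translation_table")) x else translation_table(x)
}

#' Translate a nucleotide sequence
#'
#' Translates a codon-multiple nucleotide string under a given translation
#' table. Stop codons render as `"*"`; any codon containing a character
#' outside ACGT (e.g. the ambiguity code N) renders as `"X"`.
#'
#' @param nt A single nucleotide string; length must be divisible by 3.
#' @param table A `translation_table` or an NCBI table number.
#' @return The amino-acid string.
#' @export
#' @examples
#' translate_nt("ATGAAATAA", 11)  # "MK*"
#' translate_nt("TGA", 4)         # "W"
translate_nt <- function(nt, table = 1) {
  table <- as_translation_table(table)
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(table$codon_map[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
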
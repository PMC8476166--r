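# Shared internal helpers.

# Canonical 20-letter amino-acid alphabet, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Round half away from zero
#'
#' Plain decimal rounding where `.5` always rounds up, as used for the
#' percentages of the one-line completeness summary. Base `round()` rounds
#' half to even, which would mis-render some score strings.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 99.0849), c(1, 1, 1))
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seed < 2^31 from a master seed and integer indices.
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

# Read sequences into a plain named character vector. Accepts a named
# character vector (returned as-is), an XStringSet, or a FASTA file path.
as_seq_vector <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && !grepl("[\n>]", x) && file.exists(x)) {
    set <- if (type == "AA") Biostrings::readAAStringSet(x) else Biostrings::readDNAStringSet(x)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (!is.character(x)) {
    stop("sequences must be a named character vector, an XStringSet, or a FASTA path",
         call. = FALSE)
  }
  if (is.null(names(x)) && length(x) > 0L) {
    names(x) <- paste0("seq", seq_along(x))
  }
  toupper(x)
}

# Write a named character vector as FASTA.
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
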
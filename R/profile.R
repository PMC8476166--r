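# Position-specific profile construction and scoring. This engine stands in
# for the external profile-HMM search stage: it is fully self-contained, has
# exact small-case semantics (see enumerate_local_paths), and reports scores
# in bits.

# Fixed transition log-probabilities (natural log). Estimating transitions is
# out of scope; fixed values keep profile construction deterministic.
PROFILE_TRANS <- c(
  mm = log(0.9), mi = log(0.05), md = log(0.05),
  ii = log(0.4), im = log(0.6), dd = log(0.4), dm = log(0.6)
)

#' Build a position-specific profile from a marker family
#'
#' Alignment columns with a gap fraction of 0.5 or more are dropped; the rest
#' become match columns. Per-column emission probabilities come from residue
#' counts with add-one smoothing over the 20-letter alphabet and are stored as
#' natural-log odds against the background distribution. Non-standard residues
#' in the seeds are ignored for counting.
#'
#' @param family A [marker_family()].
#' @param background Amino-acid background frequencies (length 20, ordered as
#'   the alphabetical one-letter alphabet); defaults to uniform.
#' @return An object of class `protein_profile` with fields `marker_id`,
#'   `M` (number of match columns), `emissions` (M x 20 log-odds matrix),
#'   `background`, and `match_cols` (retained alignment column indices).
#' @export
build_profile <- function(family, background = NULL) {
  stopifnot(inherits(family, "marker_family"))
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-12)
  seqs <- family$seed_alignment
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0L) {
    stop("degenerate profile for marker '", family$marker_id,
         "': no alignment column has gap fraction < 0.5", call. = FALSE)
  }
  em <- matrix(0, nrow = length(keep), ncol = 20, dimnames = list(NULL, AA20))
  for (j in seq_along(keep)) {
    col <- mat[, keep[j]]
    col <- col[col %in% AA20]
    counts <- table(factor(col, levels = AA20))
    p <- (as.numeric(counts) + 1) / (length(col) + 20)
    em[j, ] <- log(p) - log(unname(background))
  }
  structure(
    list(marker_id = family$marker_id, M = length(keep), emissions = em,
         background = background, match_cols = keep),
    class = "protein_profile"
  )
}

#' @export
print.protein_profile <- function(x, ...) {
  cat("<protein_profile> marker", x$marker_id, "with", x$M, "match columns\n")
  invisible(x)
}

encode_protein <- function(protein) {
  r <- strsplit(toupper(protein), "")[[1]]
  m <- match(r, AA20)
  m[is.na(m)] <- 0L
  m - 1L  # 0-based; unknown becomes -1
}

#' Score a protein against a profile
#'
#' Local alignment with free entry into and exit from any match column.
#' The Viterbi score is the best single state path, the Forward score the
#' log-sum over all local paths; both are reported in bits. The alignment
#' envelope (and hence `aligned_length`) always comes from the Viterbi
#' traceback, whichever score is requested.
#'
#' @param profile A `protein_profile`.
#' @param protein A single amino-acid string. Residues outside the 20-letter
#'   alphabet score as background (log-odds 0).
#' @param mode `"viterbi"` (default) or `"forward"`.
#' @param sequence_id Identifier recorded in the hit.
#' @return A one-row tibble (`marker_id`, `sequence_id`, `bit_score`,
#'   `aligned_length`, `env_start`, `env_end`), or `NULL` for an empty
#'   protein (no-hit).
#' @export
score_sequence <- function(profile, protein, mode = c("viterbi", "forward"),
                           sequence_id = "query") {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "protein_profile"))
  if (is.null(protein) || nchar(protein) == 0L) return(NULL)
  res <- .dp_local_score(profile$emissions, encode_protein(protein), PROFILE_TRANS)
  bit <- if (mode == "viterbi") res$viterbi_bits else res$forward_bits
  tibble::tibble(
    marker_id = profile$marker_id,
    sequence_id = sequence_id,
    bit_score = bit,
    aligned_length = res$env_end - res$env_start + 1L,
    env_start = res$env_start,
    env_end = res$env_end
  )
}

#' Exhaustive enumeration oracle for local profile alignment
#'
#' Enumerates every legal local state path of the profile against a target
#' and returns the max-path (Viterbi) and log-sum (Forward) bit scores by
#' direct summation. Exponential in size - intended for profiles with up to
#' ~4 match columns and targets of up to ~5 residues, where it serves as an
#' independent reference for the dynamic-programming engine.
#'
#' @inheritParams score_sequence
#' @return A list with `viterbi_bits` and `forward_bits`.
#' @export
enumerate_local_paths <- function(profile, protein) {
  em <- profile$emissions
  M <- profile$M
  seq_int <- encode_protein(protein) + 1L  # 1-based, 0 = unknown
  L <- length(seq_int)
  tr <- PROFILE_TRANS
  emit <- function(c, i) {
    a <- seq_int[i]
    if (a == 0L) 0 else em[c, a]
  }
  scores <- numeric(0)
  # state: "M" at column c having consumed position i, or "I"/"D" likewise
  rec <- function(state, c, i, acc) {
    if (state == "M") {
      scores[[length(scores) + 1L]] <<- acc  # free exit
      if (c < M && i < L) rec("M", c + 1L, i + 1L, acc + tr[["mm"]] + emit(c + 1L, i + 1L))
      if (c < M && i < L) rec("I", c, i + 1L, acc + tr[["mi"]])
      if (c + 1L <= M - 1L) rec("D", c + 1L, i, acc + tr[["md"]])
    } else if (state == "I") {
      if (i < L) rec("I", c, i + 1L, acc + tr[["ii"]])
      if (c < M && i < L) rec("M", c + 1L, i + 1L, acc + tr[["im"]] + emit(c + 1L, i + 1L))
    } else { # D
      if (c + 1L <= M - 1L) rec("D", c + 1L, i, acc + tr[["dd"]])
      if (c < M && i < L) rec("M", c + 1L, i + 1L, acc + tr[["dm"]] + emit(c + 1L, i + 1L))
    }
  }
  for (i in seq_len(L)) {
    for (c in seq_len(M)) {
      rec("M", c, i, emit(c, i))
    }
  }
  list(
    viterbi_bits = max(scores) / log(2),
    forward_bits = logsumexp(scores) / log(2)
  )
}

#' Search configuration
#'
#' Holds the dials of the two-pass genome workflow: the sensitivity of each
#' search pass and the minimum ORF span. Defaults follow the standard
#' two-pass settings (first pass s = 4.5, rescue pass s = 6, 90 nt minimum
#' ORF halved in the rescue pass).
#'
#' @param sensitivity_pass1 Sensitivity of the first search pass, in \[1, 7\].
#' @param sensitivity_pass2 Sensitivity of the rescue pass; must be at least
#'   `sensitivity_pass1`. Sensitivities of 6 and above disable the k-mer
#'   prefilter entirely (exhaustive scoring).
#' @param min_orf_nt Minimum ORF span (nt) of the first pass; must be a
#'   positive multiple of 3. The rescue pass uses half this value (rounded to
#'   a codon multiple).
#' @return An object of class `search_config`.
#' @export
search_config <- function(sensitivity_pass1 = 4.5, sensitivity_pass2 = 6,
                          min_orf_nt = 90) {
  stopifnot(
    sensitivity_pass1 >= 1, sensitivity_pass1 <= 7,
    sensitivity_pass2 >= sensitivity_pass1, sensitivity_pass2 <= 7,
    min_orf_nt >= 3, min_orf_nt %% 3 == 0
  )
  structure(
    list(sensitivity_pass1 = sensitivity_pass1,
         sensitivity_pass2 = sensitivity_pass2,
         min_orf_nt = as.integer(min_orf_nt)),
    class = "search_config"
  )
}

# Distinct 4-mers of a set of (ungapped) sequences.
kmer_set <- function(seqs, k = 4L) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character())
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })))
}

# Prefilter: at sensitivity s a target is scored only if it shares at least
# ceiling(8 - s) distinct 4-mers with the marker's seed sequences; s >= 6
# disables the filter. Any such monotone dial preserves the subset property
# (raising s never loses hits).
prefilter_pass <- function(target_kmers, seed_kmers, sensitivity) {
  if (sensitivity >= 6) return(TRUE)
  need <- ceiling(8 - sensitivity)
  sum(target_kmers %in% seed_kmers) >= need
}

#' Search a protein collection against all markers of a dataset
#'
#' Scores every protein against every marker profile (subject to the
#' sensitivity prefilter) and reports hits whose Viterbi bit score reaches
#' the reporting floor of half the marker's classification cutoff. The full
#' cutoff is applied later, at classification time.
#'
#' @param dataset A [marker_dataset()].
#' @param proteins Named character vector of amino-acid sequences, an
#'   `AAStringSet`, or a FASTA path.
#' @param sensitivity Search sensitivity in \[1, 7\]; values below 6 engage a
#'   shared-4-mer prefilter, 6 and above score exhaustively.
#' @return A tibble of hits: `marker_id`, `sequence_id`, `bit_score`,
#'   `aligned_length`, `env_start`, `env_end`.
#' @export
search_markers <- function(dataset, proteins, sensitivity = 4.5) {
  stopifnot(inherits(dataset, "marker_dataset"))
  stopifnot(sensitivity >= 1, sensitivity <= 7)
  proteins <- as_seq_vector(proteins, "AA")
  proteins <- proteins[nchar(proteins) > 0L]
  if (length(proteins) == 0L) return(empty_hit_tibble())
  target_kmers <- lapply(proteins, kmer_set)
  hits <- purrr::map(dataset$markers, function(fam) {
    prof <- build_profile(fam)
    seed_kmers <- kmer_set(ungapped_seeds(fam))
    floor_bits <- 0.5 * fam$score_cutoff
    rows <- purrr::imap(proteins, function(p, pid) {
      if (!prefilter_pass(target_kmers[[pid]], seed_kmers, sensitivity)) return(NULL)
      h <- score_sequence(prof, p, mode = "viterbi", sequence_id = pid)
      if (!is.null(h) && h$bit_score >= floor_bits) h else NULL
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) empty_hit_tibble() else out
}

empty_hit_tibble <- function() {
  tibble::tibble(
    marker_id = character(), sequence_id = character(), bit_score = numeric(),
    aligned_length = integer(), env_start = integer(), env_end = integer()
  )
}

ungapped_seeds <- function(family) {
  gsub("-", "", family$seed_alignment, fixed = TRUE)
}
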
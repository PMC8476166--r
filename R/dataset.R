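# Marker families, lineage marker datasets, and the dataset hierarchy.

#' Create a marker family
#'
#' A marker family is one universal single-copy ortholog: a seed alignment of
#' representative members plus the per-marker classification cutoffs. The
#' score cutoff is in bits; the length statistics are over the ungapped seed
#' member lengths (amino acids).
#'
#' @param marker_id Unique label, no whitespace.
#' @param seed_alignment Named character vector of aligned amino-acid
#'   sequences (gap character `-`), all of equal aligned length.
#' @param score_cutoff Classification bit-score threshold (> 0).
#' @param length_mean Mean ungapped seed length (> 0).
#' @param length_sigma Population standard deviation of ungapped seed lengths.
#' @return An object of class `marker_family`.
#' @export
marker_family <- function(marker_id, seed_alignment, score_cutoff,
                          length_mean, length_sigma) {
  if (grepl("\\s", marker_id)) {
    stop("marker_id must not contain whitespace: '", marker_id, "'", call. = FALSE)
  }
  seed_alignment <- toupper(seed_alignment)
  if (is.null(names(seed_alignment))) {
    names(seed_alignment) <- paste0(marker_id, "_", seq_along(seed_alignment))
  }
  widths <- nchar(seed_alignment)
  if (length(seed_alignment) < 1L || widths[1] < 1L || length(unique(widths)) != 1L) {
    stop("seed alignment of '", marker_id,
         "' must contain sequences of equal aligned length >= 1", call. = FALSE)
  }
  stopifnot(score_cutoff > 0, length_mean > 0, length_sigma >= 0)
  structure(
    list(marker_id = marker_id, seed_alignment = seed_alignment,
         score_cutoff = as.numeric(score_cutoff),
         length_mean = as.numeric(length_mean),
         length_sigma = as.numeric(length_sigma)),
    class = "marker_family"
  )
}

DOMAINS <- c("bacteria", "archaea", "eukaryota", "viruses")
PROK_DOMAINS <- c("bacteria", "archaea", "viruses")

#' Create a lineage marker dataset
#'
#' A named set of marker families for one lineage, with the candidate genetic
#' codes used by the genome workflow and an optional pointer to the parent
#' (less specific) dataset in the hierarchy. Markers are stored sorted by
#' `marker_id`, so construction order does not affect equality or on-disk
#' output.
#'
#' @param name Dataset name (e.g. `"bacteria_x"`).
#' @param domain One of `"bacteria"`, `"archaea"`, `"eukaryota"`, `"viruses"`.
#' @param markers List of [marker_family()] objects with unique ids.
#' @param genetic_codes Ordered vector of NCBI translation-table numbers;
#'   required (non-empty) for bacterial, archaeal and viral datasets.
#' @param parent Name of the parent dataset, or `NA` for a root.
#' @param creation_meta Free-text provenance.
#' @return An object of class `marker_dataset` with `n_markers` filled in.
#' @export
marker_dataset <- function(name, domain, markers, genetic_codes = integer(),
                           parent = NA_character_, creation_meta = "") {
  domain <- match.arg(domain, DOMAINS)
  stopifnot(length(markers) >= 1)
  ids <- vapply(markers, function(m) m$marker_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate marker_ids in dataset '", name, "'", call. = FALSE)
  }
  if (domain %in% PROK_DOMAINS && length(genetic_codes) == 0L) {
    stop("dataset '", name, "' (", domain,
         ") requires at least one candidate genetic code", call. = FALSE)
  }
  ord <- order(ids)
  markers <- stats::setNames(markers[ord], ids[ord])
  structure(
    list(name = name, domain = domain, markers = markers,
         n_markers = length(markers),
         genetic_codes = as.integer(genetic_codes),
         parent = as.character(parent), creation_meta = creation_meta),
    class = "marker_dataset"
  )
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat("<marker_dataset>", x$name, sprintf("(%s), n = %d markers", x$domain, x$n_markers),
      if (length(x$genetic_codes)) paste0("codes [", paste(x$genetic_codes, collapse = ","), "]") else "",
      "\n")
  invisible(x)
}

#' Number of markers in a dataset
#' @param dataset A `marker_dataset`.
#' @return Integer marker count.
#' @export
n_markers <- function(dataset) dataset$n_markers

#' Write a marker dataset to a directory
#'
#' Emits the documented dataset layout: `dataset.cfg` (key=value), a
#' `scores_cutoff.tsv` (marker, bits), a `lengths_cutoff.tsv`
#' (marker, mean, sigma), and one aligned FASTA per marker under `seeds/`.
#' Output is byte-stable: markers are written in sorted order and all floats
#' use fixed two-decimal formatting (cutoffs are stored at that precision, so
#' writing then loading reproduces the dataset exactly).
#'
#' @param ds A [marker_dataset()].
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "marker_dataset"))
  if (ds$n_markers == 0L) stop("refusing to write an empty dataset", call. = FALSE)
  dir.create(file.path(path, "seeds"), recursive = TRUE, showWarnings = FALSE)
  cfg <- c(
    paste0("name=", ds$name),
    paste0("domain=", ds$domain),
    paste0("codes=", paste(ds$genetic_codes, collapse = ",")),
    if (!is.na(ds$parent)) paste0("parent=", ds$parent),
    paste0("n=", ds$n_markers)
  )
  writeLines(cfg, file.path(path, "dataset.cfg"))
  ids <- names(ds$markers)
  writeLines(
    vapply(ids, function(id) {
      sprintf("%s\t%.2f", id, ds$markers[[id]]$score_cutoff)
    }, character(1)),
    file.path(path, "scores_cutoff.tsv")
  )
  writeLines(
    vapply(ids, function(id) {
      m <- ds$markers[[id]]
      sprintf("%s\t%.2f\t%.2f", id, m$length_mean, m$length_sigma)
    }, character(1)),
    file.path(path, "lengths_cutoff.tsv")
  )
  for (id in ids) {
    write_fasta(ds$markers[[id]]$seed_alignment,
                file.path(path, "seeds", paste0(id, ".faa")), "AA")
  }
  invisible(path)
}

#' Load a marker dataset from a directory
#'
#' Reads the layout written by [write_dataset()]. A marker listed in the
#' score table must have a row in the length table and a seed FASTA; any
#' mismatch is a consistency error.
#'
#' @param path Dataset directory.
#' @return A [marker_dataset()].
#' @export
load_dataset <- function(path) {
  cfg_file <- file.path(path, "dataset.cfg")
  if (!file.exists(cfg_file)) {
    stop("not a dataset directory (no dataset.cfg): ", path, call. = FALSE)
  }
  lines <- readLines(cfg_file)
  kv <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    if (!grepl("^[a-z_]+=", lines[i])) {
      stop("malformed config in ", cfg_file, " at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    key <- sub("=.*$", "", lines[i])
    kv[[key]] <- sub("^[a-z_]+=", "", lines[i])
  }
  for (req in c("name", "domain", "codes", "n")) {
    if (is.null(kv[[req]])) {
      stop("malformed config in ", cfg_file, ": missing key '", req, "'", call. = FALSE)
    }
  }
  scores_file <- file.path(path, "scores_cutoff.tsv")
  lengths_file <- file.path(path, "lengths_cutoff.tsv")
  scores <- utils::read.table(scores_file, sep = "\t", header = FALSE,
                              col.names = c("marker_id", "cutoff"),
                              colClasses = c("character", "numeric"))
  lens <- utils::read.table(lengths_file, sep = "\t", header = FALSE,
                            col.names = c("marker_id", "mean", "sigma"),
                            colClasses = c("character", "numeric", "numeric"))
  missing_len <- setdiff(scores$marker_id, lens$marker_id)
  if (length(missing_len) > 0L) {
    stop("consistency error: markers without length cutoffs: ",
         paste(missing_len, collapse = ", "), call. = FALSE)
  }
  extra_len <- setdiff(lens$marker_id, scores$marker_id)
  if (length(extra_len) > 0L) {
    stop("consistency error: markers without score cutoffs: ",
         paste(extra_len, collapse = ", "), call. = FALSE)
  }
  markers <- lapply(seq_len(nrow(scores)), function(i) {
    id <- scores$marker_id[i]
    seed_file <- file.path(path, "seeds", paste0(id, ".faa"))
    if (!file.exists(seed_file)) {
      stop("consistency error: marker '", id, "' listed without seed file", call. = FALSE)
    }
    li <- lens[lens$marker_id == id, ]
    marker_family(id, as_seq_vector(seed_file, "AA"),
                  score_cutoff = scores$cutoff[i],
                  length_mean = li$mean, length_sigma = li$sigma)
  })
  codes <- if (nzchar(kv$codes)) as.integer(strsplit(kv$codes, ",")[[1]]) else integer()
  ds <- marker_dataset(
    name = kv$name, domain = kv$domain, markers = markers,
    genetic_codes = codes, parent = kv$parent %||% NA_character_,
    creation_meta = kv$creation_meta %||% ""
  )
  if (ds$n_markers != as.integer(kv$n)) {
    stop("consistency error: config declares n=", kv$n, " but found ",
         ds$n_markers, " markers", call. = FALSE)
  }
  ds
}

#' Build a marker dataset from an orthology table
#'
#' Implements the dataset construction strategy: orthogroups present in
#' exactly one copy in at least `single_copy_threshold` of the species are
#' retained as markers. Per-marker cutoffs are then calibrated from the seed
#' members themselves: the bit-score cutoff is 0.9 times the minimum Viterbi
#' self-score of the seed members against the family profile, and the length
#' statistics are the mean and population standard deviation of the ungapped
#' seed lengths. Cutoffs are stored at two-decimal precision (the on-disk
#' format's precision).
#'
#' @param orthology_table Data frame with columns `orthogroup`, `species`,
#'   `copies` (per-species copy number; species/orthogroup pairs absent from
#'   the table count as zero copies).
#' @param alignments Named list mapping each orthogroup to its seed alignment
#'   (named character vector of aligned amino-acid sequences).
#' @param single_copy_threshold Fraction of species required to carry exactly
#'   one copy, in (0, 1]; default 0.9 (the near-universality criterion).
#' @param name,domain,genetic_codes,parent,creation_meta Passed to
#'   [marker_dataset()].
#' @return A [marker_dataset()].
#' @export
build_dataset <- function(orthology_table, alignments,
                          single_copy_threshold = 0.9,
                          name, domain, genetic_codes = integer(),
                          parent = NA_character_, creation_meta = "") {
  stopifnot(single_copy_threshold > 0, single_copy_threshold <= 1)
  tab <- tibble::as_tibble(orthology_table)
  stopifnot(all(c("orthogroup", "species", "copies") %in% names(tab)))
  species <- unique(tab$species)
  if (length(species) < 2L) {
    stop("orthology table must cover at least 2 species", call. = FALSE)
  }
  frac <- tab |>
    dplyr::group_by(.data$orthogroup) |>
    dplyr::summarise(single = sum(.data$copies == 1L), .groups = "drop") |>
    dplyr::mutate(frac = .data$single / length(species))
  keep <- frac$orthogroup[frac$frac >= single_copy_threshold]
  if (length(keep) == 0L) {
    stop("no orthogroup passes the single-copy threshold of ",
         single_copy_threshold, "; refusing to build an empty dataset", call. = FALSE)
  }
  markers <- lapply(sort(keep), function(og) {
    aln <- alignments[[og]]
    if (is.null(aln)) {
      stop("no seed alignment supplied for retained orthogroup '", og, "'", call. = FALSE)
    }
    calibrate_family(og, aln)
  })
  marker_dataset(name = name, domain = domain, markers = markers,
                 genetic_codes = genetic_codes, parent = parent,
                 creation_meta = creation_meta)
}

# Calibrate cutoffs for one family from its own seed members.
calibrate_family <- function(marker_id, seed_alignment) {
  ungapped <- gsub("-", "", toupper(seed_alignment), fixed = TRUE)
  lens <- nchar(ungapped)
  fam0 <- marker_family(marker_id, seed_alignment, score_cutoff = 1,
                        length_mean = mean(lens),
                        length_sigma = sqrt(mean((lens - mean(lens))^2)))
  prof <- build_profile(fam0)
  self_scores <- vapply(ungapped, function(s) {
    score_sequence(prof, s)$bit_score
  }, numeric(1))
  cutoff <- round_half_up(0.9 * min(self_scores), 2)
  if (cutoff <= 0) cutoff <- 0.01  # degenerate seeds: keep the invariant cutoff > 0
  marker_family(marker_id, fam0$seed_alignment,
                score_cutoff = cutoff,
                length_mean = round_half_up(mean(lens), 2),
                length_sigma = round_half_up(fam0$length_sigma, 2))
}

#' Build a dataset hierarchy
#'
#' Links a collection of datasets into the tree used for automatic lineage
#' selection, via each dataset's `parent` field. Roots are datasets without a
#' parent. The tree must be acyclic and every named parent must be present.
#'
#' @param datasets List of [marker_dataset()] objects.
#' @param require_domain_roots If `TRUE`, insist that the roots are exactly
#'   one dataset per domain for bacteria, archaea and eukaryota (plus an
#'   optional virus root) - the configuration expected by the full
#'   auto-lineage workflow. Defaults to `FALSE` so that partial hierarchies
#'   (e.g. a single-domain subtree) can be represented.
#' @return An object of class `dataset_tree` with fields `datasets`,
#'   `parent`, `children`, `roots`.
#' @export
dataset_tree <- function(datasets, require_domain_roots = FALSE) {
  names(datasets) <- vapply(datasets, function(d) d$name, character(1))
  parent <- vapply(datasets, function(d) d$parent, character(1))
  known <- names(datasets)
  bad <- parent[!is.na(parent) & !(parent %in% known)]
  if (length(bad) > 0L) {
    stop("unknown parent dataset(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  # acyclicity: walk to root from every node
  for (nm in known) {
    seen <- character()
    cur <- nm
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("dataset hierarchy contains a cycle at '", nm, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  roots <- known[is.na(parent)]
  if (require_domain_roots) {
    root_domains <- sort(vapply(datasets[roots], function(d) d$domain, character(1)))
    want <- sort(c("bacteria", "archaea", "eukaryota"))
    if (!all(want %in% root_domains) ||
        !all(root_domains %in% c(want, "viruses"))) {
      stop("roots must be one dataset per domain (bacteria, archaea, eukaryota, ",
           "optionally viruses); found: ", paste(root_domains, collapse = ", "),
           call. = FALSE)
    }
  }
  children <- lapply(stats::setNames(known, known), function(nm) {
    known[!is.na(parent) & parent == nm]
  })
  structure(
    list(datasets = datasets, parent = parent, children = children, roots = roots),
    class = "dataset_tree"
  )
}

#' @export
print.dataset_tree <- function(x, ...) {
  cat("<dataset_tree>", length(x$datasets), "datasets,",
      length(x$roots), "root(s):", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

# Ancestors of a node (excluding itself), root last.
tree_ancestors <- function(tree, name) {
  out <- character()
  cur <- tree$parent[[name]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- tree$parent[[cur]]
  }
  out
}
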
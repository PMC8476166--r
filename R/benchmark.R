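# Gene-depletion benchmark: remove a known fraction of genes from a gene set
# (and mask their genomic spans), re-assess, and compare reported missingness
# with the truth. Protocol A ("full_gene_set") depletes any gene and measures
# score degradation only; protocol B ("marker_only") depletes genes mapped to
# markers and additionally counts FP/FN against the frozen mapping.

#' Define a depletion plan
#'
#' @param levels Depletion fractions. Defaults to 0/0.10/0.30/0.50; the
#'   marker-only protocol additionally includes 1.0 (exhaustive removal,
#'   which is deterministic and therefore run with a single replicate).
#' @param replicates Replicates per level (default 5).
#' @param protocol `"marker_only"` (protocol B: deplete only truth-mapped
#'   marker genes; FP/FN/precision computed) or `"full_gene_set"`
#'   (protocol A: deplete any gene; scores only).
#' @param seed Master seed; per-(level, replicate) child seeds are derived
#'   deterministically so replicates are independent yet reproducible.
#' @return An object of class `depletion_plan`.
#' @export
depletion_plan <- function(levels = c(0, 0.10, 0.30, 0.50), replicates = 5,
                           protocol = c("marker_only", "full_gene_set"),
                           seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(all(levels >= 0 & levels <= 1), replicates >= 1)
  if (protocol == "marker_only" && !any(levels == 1)) {
    levels <- c(levels, 1.0)
  }
  structure(
    list(levels = sort(unique(levels)), replicates = as.integer(replicates),
         protocol = protocol, seed = as.integer(seed)),
    class = "depletion_plan"
  )
}

#' Randomly remove a fraction of genes
#'
#' Removes `round(fraction * |eligible|)` genes (rounding half-up), sampled
#' without replacement with the given seed, from the collection.
#'
#' @param genes Named character vector of protein sequences.
#' @param fraction Fraction of the eligible set to remove, in \[0, 1\].
#' @param eligible Gene ids eligible for removal; defaults to every gene
#'   (protocol A). Protocol B passes the truth-mapped marker genes.
#' @param seed Integer seed; identical seeds give identical removals.
#' @return A list with `genes` (depleted collection) and `removed` (ids).
#' @export
deplete_gene_set <- function(genes, fraction, eligible = NULL, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  eligible <- eligible %||% names(genes)
  stopifnot(all(eligible %in% names(genes)))
  n_remove <- as.integer(round_half_up(fraction * length(eligible)))
  removed <- if (n_remove == 0L) character() else {
    with_seed(seed, sample(eligible, n_remove))
  }
  list(genes = genes[setdiff(names(genes), removed)], removed = sort(removed))
}

# Normalise a GFF3 annotation (path, GRanges, or tibble) to a gene table.
gene_table <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  if (methods::is(annotation, "GRanges")) {
    gr <- annotation[annotation$type == "gene"]
    ids <- gr$ID %||% gr$gene_id
    return(tibble::tibble(
      gene_id = as.character(ids),
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    ))
  }
  tab <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene_id", "seqid", "start", "end") %in% names(tab)))
  tab
}

#' Mask removed genes in a genome
#'
#' Replaces the genomic span of every removed gene (1-based inclusive
#' coordinates from the annotation, both strands alike) with `N`, leaving all
#' other positions and the sequence lengths untouched. Overlapping spans are
#' masked once.
#'
#' @param genome Named character vector of sequences (or `DNAStringSet`/path).
#' @param annotation GFF3 path, `GRanges`, or a tibble with columns
#'   `gene_id`, `seqid`, `start`, `end`.
#' @param removed_gene_ids Ids of the genes to mask; every id must have a
#'   gene feature in the annotation.
#' @return The masked genome as a named character vector.
#' @export
mask_genome <- function(genome, annotation, removed_gene_ids) {
  genome <- as_seq_vector(genome, "DNA")
  genes <- gene_table(annotation)
  absent <- setdiff(removed_gene_ids, genes$gene_id)
  if (length(absent) > 0L) {
    stop("removed gene(s) absent from annotation: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(removed_gene_ids) == 0L) return(genome)
  sel <- genes[genes$gene_id %in% removed_gene_ids, , drop = FALSE]
  for (sid in unique(sel$seqid)) {
    if (!sid %in% names(genome)) {
      stop("annotation sequence '", sid, "' not present in genome", call. = FALSE)
    }
    spans <- IRanges::reduce(IRanges::IRanges(
      sel$start[sel$seqid == sid], sel$end[sel$seqid == sid]))
    s <- genome[[sid]]
    for (k in seq_along(spans)) {
      a <- IRanges::start(spans)[k]
      b <- IRanges::end(spans)[k]
      substr(s, a, b) <- strrep("N", b - a + 1L)
    }
    genome[[sid]] <- s
  }
  genome
}

#' Freeze the marker-to-gene ground truth mapping
#'
#' Assesses the (undepleted) gene set in proteins mode at maximum sensitivity
#' and assigns to each marker its best-scoring complete-quality gene, if any.
#' This mapping is the frozen truth reference against which FP/FN are
#' counted; markers may remain unmapped.
#'
#' @param genes Named character vector of protein sequences.
#' @param dataset A [marker_dataset()].
#' @param config A [search_config()].
#' @return A tibble `marker_id`, `gene_id` (one row per mapped marker; each
#'   marker maps to at most one gene).
#' @export
map_ground_truth <- function(genes, dataset, config = search_config()) {
  hits <- search_markers(dataset, genes, sensitivity = 7)
  rows <- purrr::map(dataset$markers, function(fam) {
    st <- classify_marker(hits[hits$marker_id == fam$marker_id, , drop = FALSE], fam)
    loci <- st$loci[st$loci$quality == "complete", , drop = FALSE]
    if (nrow(loci) == 0L) return(NULL)
    # best score; ties resolved by gene order in the collection
    loci <- loci[order(-loci$bit_score, match(loci$sequence_id, names(genes))), ]
    tibble::tibble(marker_id = fam$marker_id, gene_id = loci$sequence_id[1])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(marker_id = character(), gene_id = character())
  else out
}

#' Count TP/FP/FN against the frozen truth
#'
#' For each truth-mapped marker: found (non-missing) while its gene remains
#' is a true positive; missed while its gene remains is a false negative;
#' found although its gene was removed is a false positive. Precision is
#' TP / (TP + FP), reported as `NA` when no positives exist.
#'
#' @param result A `marker_assessment` of the depleted input.
#' @param truth The mapping from [map_ground_truth()].
#' @param removed Character vector of removed gene ids.
#' @return A one-row tibble `tp`, `fp`, `fn`, `n_truth`, `n_removed_truth`,
#'   `precision`.
#' @export
evaluate_depletion <- function(result, truth, removed) {
  stopifnot(inherits(result, "marker_assessment"))
  status <- vapply(result$per_marker, function(s) s$status, character(1))
  found <- names(status)[status != "missing"]
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth))) {
    m <- truth$marker_id[i]
    gone <- truth$gene_id[i] %in% removed
    hit <- m %in% found
    if (gone && hit) fp <- fp + 1L
    if (!gone && hit) tp <- tp + 1L
    if (!gone && !hit) fn <- fn + 1L
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    n_truth = nrow(truth),
    n_removed_truth = sum(truth$gene_id %in% removed),
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  )
}

all_missing_assessment <- function(dataset, input_id, mode) {
  statuses <- lapply(dataset$markers, function(fam) {
    classify_marker(empty_hit_tibble(), fam)
  })
  new_assessment(input_id, dataset, mode, mode, statuses)
}

#' Run the depletion benchmark
#'
#' For every level and replicate of the plan: deplete the gene set (protocol
#' B restricts removal to truth-mapped marker genes), optionally mask the
#' genome at the removed genes' coordinates, assess in each requested mode,
#' and (protocol B) count FP/FN against the frozen truth mapping.
#'
#' @param genes Named character vector of protein sequences (the gene set).
#' @param dataset A [marker_dataset()].
#' @param plan A [depletion_plan()].
#' @param genome Named character vector of genome sequences; required for
#'   `"genome"` mode.
#' @param annotation Gene annotation (GFF3 path, `GRanges`, or tibble);
#'   required for `"genome"` mode.
#' @param modes Assessment modes to run, subset of
#'   `c("proteins", "genome")`.
#' @param config A [search_config()].
#' @return An object of class `depletion_report` with fields `table` (tidy
#'   tibble: level, replicate, mode, counts, scores, TP/FP/FN, precision),
#'   `truth`, and `plan`. `tidy()` returns the table.
#' @export
run_benchmark <- function(genes, dataset, plan = depletion_plan(),
                          genome = NULL, annotation = NULL,
                          modes = "proteins", config = search_config()) {
  stopifnot(inherits(plan, "depletion_plan"))
  modes <- match.arg(modes, c("proteins", "genome"), several.ok = TRUE)
  if ("genome" %in% modes && (is.null(genome) || is.null(annotation))) {
    stop("genome mode requires `genome` and `annotation`", call. = FALSE)
  }
  truth <- map_ground_truth(genes, dataset, config)
  eligible <- if (plan$protocol == "marker_only") truth$gene_id else names(genes)
  rows <- list()
  for (li in seq_along(plan$levels)) {
    level <- plan$levels[li]
    reps <- if (level == 1) 1L else plan$replicates
    for (r in seq_len(reps)) {
      seed_lr <- child_seed(plan$seed, li, r)
      dep <- deplete_gene_set(genes, level, eligible = eligible, seed = seed_lr)
      for (mode in modes) {
        res <- if (mode == "proteins") {
          if (length(dep$genes) == 0L) {
            # exhaustive depletion can empty the gene set; nothing can be
            # found, so every marker is missing by definition
            all_missing_assessment(dataset, sprintf("dep_%g_r%d", level, r),
                                   "proteins")
          } else {
            assess(dep$genes, dataset, mode = "proteins", config = config,
                   input_id = sprintf("dep_%g_r%d", level, r))
          }
        } else {
          masked <- mask_genome(genome, annotation, dep$removed)
          assess(masked, dataset, mode = "genome", config = config,
                 input_id = sprintf("dep_%g_r%d", level, r))
        }
        p <- completeness_pct(res)
        ev <- if (plan$protocol == "marker_only") {
          evaluate_depletion(res, truth, dep$removed)
        } else {
          tibble::tibble(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                         n_truth = nrow(truth),
                         n_removed_truth = sum(truth$gene_id %in% dep$removed),
                         precision = NA_real_)
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            level = level, replicate = r, mode = mode,
            n_removed = length(dep$removed),
            C = p[["C"]], S = unname(res$counts[["S"]]),
            D = unname(res$counts[["D"]]), F = unname(res$counts[["F"]]),
            M = unname(res$counts[["M"]]), n = res$n,
            summary = format_summary(res)
          ),
          ev
        )
      }
    }
  }
  structure(
    list(table = dplyr::bind_rows(rows), truth = truth, plan = plan,
         dataset_name = dataset$name),
    class = "depletion_report"
  )
}

#' @export
print.depletion_report <- function(x, ...) {
  cat("<depletion_report>", x$dataset_name, "protocol", x$plan$protocol,
      "-", nrow(x$table), "assessment rows,", nrow(x$truth), "truth-mapped markers\n")
  print(x$table, n = 10)
  invisible(x)
}
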
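# Synthetic lineage simulator: marker families evolved along a species tree,
# genomes with embedded single-exon genes and GFF3-style truth annotation.
# Every pipeline stage is testable against these bundles without downloads.
#
# The substitution model is deliberately minimal: i.i.d. per site, with
# probability 1 - exp(-branch length) of replacement by a residue drawn from
# the background excluding the current one. No rate heterogeneity, no indels
# (so seed alignments are trivial and family length sigma is 0). Gene starts
# are immutable methionines so every gene keeps a canonical ATG start.

# Palindromic guard placed around every gene: contains a stop codon in all
# three frames and equals its own reverse complement, so open reading frames
# can never extend across a gene boundary on either strand.
GENE_GUARD <- "TTAATTAATTAA"

#' Specify a synthetic lineage
#'
#' @param tree A Newick string or `ape::phylo` object with branch lengths in
#'   expected substitutions per site; tip labels name the species.
#' @param n_markers Number of marker genes.
#' @param marker_length_range Protein length range (amino acids), inclusive.
#' @param background Amino-acid background frequencies (length 20 over the
#'   alphabetical one-letter alphabet); defaults to uniform.
#' @param genetic_code NCBI translation table used to reverse-translate the
#'   proteins (codons drawn uniformly among synonyms; genes end with TAA).
#' @param intergenic_length_range Range of random intergenic spacer lengths
#'   (nucleotides) between genes.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the spec.
#' @return An object of class `lineage_spec`.
#' @export
lineage_spec <- function(tree, n_markers = 20,
                         marker_length_range = c(40, 80),
                         background = NULL, genetic_code = 11,
                         intergenic_length_range = c(30, 80), seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), n_markers >= 1,
            all(marker_length_range > 0), all(intergenic_length_range > 0))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("branch lengths must be >= 0", call. = FALSE)
  }
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9)
  structure(
    list(tree = tree, n_markers = as.integer(n_markers),
         marker_length_range = as.integer(marker_length_range),
         background = background, genetic_code = as.integer(genetic_code),
         intergenic_length_range = as.integer(intergenic_length_range),
         seed = as.integer(seed)),
    class = "lineage_spec"
  )
}

# Residues disallowed at a protein site of a TGA/TCA-free bundle (see
# reverse_translate): no interior methionine (its only codon ends in TG),
# and no K/N/I/T right after the start (their codons all begin with A, which
# would complete a TGA across the ATG junction).
excluded_residues <- function(pos, scrub) {
  if (!scrub) return(character())
  if (pos == 2L) c("M", "K", "N", "I", "T") else "M"
}

sample_residue <- function(background, exclude) {
  alt <- setdiff(AA20, exclude)
  w <- background[match(alt, AA20)]
  sample(alt, 1L, prob = w)
}

# Mutate a protein along a branch. Site 1 (the start methionine) is immune;
# scrubbed bundles keep the per-site residue exclusions.
mutate_protein <- function(protein, bl, background, scrub = FALSE) {
  if (bl <= 0) return(protein)
  r <- strsplit(protein, "")[[1]]
  p_sub <- 1 - exp(-bl)
  hit <- which(stats::runif(length(r)) < p_sub)
  hit <- hit[hit > 1L]
  for (i in hit) {
    r[i] <- sample_residue(background, c(r[i], excluded_residues(i, scrub)))
  }
  paste(r, collapse = "")
}

has_bad_motif <- function(w) grepl("TGA|TCA", w)

# Reverse-translate a protein, terminated by TAA (a stop in every supported
# table). Codons are drawn uniformly among synonyms; when `scrub` is set
# (codes in which TGA is a stop) the choice is junction-aware so that the
# finished gene contains no TGA on either strand (TGA or TCA on the forward
# strand), in any frame. Genomes built this way give byte-identical ORF sets
# under candidate codes that differ only in the TGA codon, so genetic-code
# selection falls through to the documented ordered tie-break.
reverse_translate <- function(protein, codon_choices, scrub = FALSE) {
  r <- strsplit(protein, "")[[1]]
  if (!scrub) {
    codons <- vapply(r, function(aa) {
      ch <- codon_choices[[aa]]
      if (is.null(ch)) stop("no codon for residue '", aa, "'", call. = FALSE)
      ch[sample.int(length(ch), 1L)]
    }, character(1))
    return(paste0(paste(codons, collapse = ""), "TAA"))
  }
  n <- length(r)
  out <- character(n)
  tail2 <- "AA"  # the guard ends ...TAA just before the gene start
  for (i in seq_len(n)) {
    cands <- codon_choices[[r[i]]]
    if (is.null(cands)) stop("no codon for residue '", r[i], "'", call. = FALSE)
    cands <- cands[!vapply(cands, function(cc) has_bad_motif(paste0(tail2, cc)),
                           logical(1))]
    if (i < n) {
      nxt <- codon_choices[[r[i + 1L]]]
      cands <- cands[vapply(cands, function(cc) {
        any(!vapply(nxt, function(c2) {
          has_bad_motif(paste0(substr(cc, 2, 3), c2))
        }, logical(1)))
      }, logical(1))]
    } else {
      cands <- cands[!vapply(cands, function(cc) {
        has_bad_motif(paste0(substr(cc, 2, 3), "TAA"))
      }, logical(1))]
    }
    if (length(cands) == 0L) {
      stop("no junction-safe codon for residue '", r[i], "' at position ", i,
           call. = FALSE)
    }
    out[i] <- cands[sample.int(length(cands), 1L)]
    tail2 <- substr(out[i], 2, 3)
  }
  paste0(paste(out, collapse = ""), "TAA")
}

codon_choices_for <- function(table) {
  map <- table$codon_map
  sense <- map[map != "*"]
  split(names(sense), unname(sense))
}

# Random intergenic spacer. When TGA is a stop under the bundle's code the
# spacer is scrubbed of TGA on both strands (TGA forward, TCA = reverse
# complement), so junk reading frames do not differ between candidate codes
# and genetic-code selection reflects genuine coding signal only.
random_intergenic <- function(n, scrub_tga) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (scrub_tga) {
    while (grepl("TGA|TCA", s)) {
      s <- gsub("TGA", "TTT", s, fixed = TRUE)
      s <- gsub("TCA", "TTT", s, fixed = TRUE)
    }
  }
  s
}

#' Simulate a lineage fixture bundle
#'
#' Draws ancestor marker proteins i.i.d. from the background (first residue
#' fixed to M), evolves them along the species tree, reverse-translates each
#' tip's proteins with uniformly chosen synonymous codons, and assembles one
#' genome contig per species with genes on random strands separated by random
#' intergenic spacers and stop-containing guards. The bundle carries, per
#' species, the genome, the protein gene set, and a gene table (GFF3-style
#' 1-based inclusive coordinates), plus the marker-to-gene truth mapping.
#'
#' @param spec A [lineage_spec()].
#' @return An object of class `fixture_bundle`: `species` (named list with
#'   `genome`, `proteins`, `genes`), `proteins` (per species per marker),
#'   `truth` (tibble `species`, `marker_id`, `gene_id`), and `spec`.
#' @export
simulate_lineage <- function(spec) {
  stopifnot(inherits(spec, "lineage_spec"))
  with_seed(spec$seed, simulate_lineage_impl(spec))
}

simulate_lineage_impl <- function(spec) {
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  table <- translation_table(spec$genetic_code)
  choices <- codon_choices_for(table)
  scrub <- "TGA" %in% table$stop_codons
  marker_ids <- sprintf("marker%03d", seq_len(spec$n_markers))
  lens <- sample(seq(spec$marker_length_range[1], spec$marker_length_range[2]),
                 spec$n_markers, replace = TRUE)
  ancestor <- lapply(seq_len(spec$n_markers), function(i) {
    paste(c("M", vapply(2:lens[i], function(pos) {
      sample_residue(spec$background, excluded_residues(pos, scrub))
    }, character(1))), collapse = "")
  })
  names(ancestor) <- marker_ids

  # evolve along the tree; cladewise edge order is a preorder, so every
  # edge's parent node is simulated before its children
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- ntip + 1L
  node_seqs <- list()
  node_seqs[[as.character(root)]] <- ancestor
  edge <- tree$edge
  elen <- tree$edge.length %||% rep(0, nrow(edge))
  for (k in seq_len(nrow(edge))) {
    par <- as.character(edge[k, 1]); chl <- as.character(edge[k, 2])
    parent_seqs <- node_seqs[[par]]
    node_seqs[[chl]] <- lapply(parent_seqs, mutate_protein,
                               bl = elen[k], background = spec$background,
                               scrub = scrub)
  }

  species <- stats::setNames(vector("list", ntip), tree$tip.label)
  truth_rows <- list()
  proteins_by_species <- list()
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    prots <- node_seqs[[as.character(t)]]
    proteins_by_species[[sp]] <- unlist(prots)
    contig_id <- paste0(sp, "_contig1")
    parts <- character()
    pos <- 0L
    gene_rows <- list()
    add <- function(piece) {
      parts[[length(parts) + 1L]] <<- piece
      pos <<- pos + nchar(piece)
    }
    add(random_intergenic(sample(
      seq(spec$intergenic_length_range[1], spec$intergenic_length_range[2]), 1L),
      scrub))
    add(GENE_GUARD)
    gene_set <- character()
    for (m in marker_ids) {
      nt <- reverse_translate(prots[[m]], choices, scrub)
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "+") nt else reverse_complement(nt)
      g_start <- pos + 1L
      add(placed)
      g_end <- pos
      gene_id <- paste0(sp, "_g_", m)
      gene_rows[[m]] <- tibble::tibble(
        gene_id = gene_id, marker_id = m, seqid = contig_id,
        start = g_start, end = g_end, strand = strand
      )
      gene_set[[gene_id]] <- prots[[m]]
      truth_rows[[paste(sp, m)]] <- tibble::tibble(
        species = sp, marker_id = m, gene_id = gene_id
      )
      add(GENE_GUARD)
      add(random_intergenic(sample(
        seq(spec$intergenic_length_range[1], spec$intergenic_length_range[2]), 1L),
        scrub))
      add(GENE_GUARD)
    }
    genome <- stats::setNames(paste(parts, collapse = ""), contig_id)
    species[[sp]] <- list(genome = genome, proteins = gene_set,
                          genes = dplyr::bind_rows(gene_rows))
  }
  structure(
    list(species = species, proteins = proteins_by_species,
         truth = dplyr::bind_rows(truth_rows), spec = spec),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>", length(x$species), "species x",
      x$spec$n_markers, "markers, code", x$spec$genetic_code, "\n")
  invisible(x)
}

#' Build a marker dataset from a fixture bundle
#'
#' Uses the proteins of the chosen species as seed members (the simulator
#' introduces no indels, so equal-length sequences are already aligned) and
#' delegates to [build_dataset()] for single-copy filtering and cutoff
#' calibration. Building from a subset of species and assessing a held-out
#' one avoids self-scoring bias in tests.
#'
#' @param bundle A `fixture_bundle`.
#' @param species Species names to use as seeds (default: all).
#' @param name,domain,genetic_codes,parent Dataset metadata; `genetic_codes`
#'   defaults to the bundle's simulation code.
#' @return A [marker_dataset()].
#' @export
dataset_from_bundle <- function(bundle, species = names(bundle$species),
                                name, domain = "bacteria",
                                genetic_codes = NULL, parent = NA_character_) {
  stopifnot(inherits(bundle, "fixture_bundle"), all(species %in% names(bundle$species)))
  genetic_codes <- genetic_codes %||% bundle$spec$genetic_code
  marker_ids <- sprintf("marker%03d", seq_len(bundle$spec$n_markers))
  orth <- tidyr::expand_grid(orthogroup = marker_ids, species = species) |>
    dplyr::mutate(copies = 1L)
  alignments <- lapply(stats::setNames(marker_ids, marker_ids), function(m) {
    vapply(stats::setNames(species, species),
           function(sp) bundle$proteins[[sp]][[m]], character(1))
  })
  build_dataset(orth, alignments, single_copy_threshold = 0.9,
                name = name, domain = domain, genetic_codes = genetic_codes,
                parent = parent,
                creation_meta = paste("simulated from", length(species), "species"))
}

#' Inject exact gene duplications into a species' genome
#'
#' Appends an exact copy of each listed marker's gene (flanked by guards) to
#' the end of the species' contig, adds the corresponding gene feature and a
#' duplicate protein entry. Assessing the modified genome reports those
#' markers as duplicated.
#'
#' @param bundle A `fixture_bundle`.
#' @param species Species name.
#' @param marker_ids Markers to duplicate; must exist in the species.
#' @return The modified bundle.
#' @export
inject_duplications <- function(bundle, species, marker_ids) {
  stopifnot(inherits(bundle, "fixture_bundle"), species %in% names(bundle$species))
  sp <- bundle$species[[species]]
  unknown <- setdiff(marker_ids, sp$genes$marker_id)
  if (length(unknown) > 0L) {
    stop("unknown marker(s) in species '", species, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  contig_id <- names(sp$genome)
  s <- sp$genome[[1]]
  for (m in marker_ids) {
    row <- sp$genes[sp$genes$marker_id == m, ][1, ]
    gene_nt <- substr(s, row$start, row$end)
    g_start <- nchar(s) + nchar(GENE_GUARD) + 1L
    s <- paste0(s, GENE_GUARD, gene_nt, GENE_GUARD)
    g_end <- g_start + nchar(gene_nt) - 1L
    dup_id <- paste0(row$gene_id, "_dup")
    sp$genes <- dplyr::bind_rows(sp$genes, tibble::tibble(
      gene_id = dup_id, marker_id = m, seqid = contig_id,
      start = g_start, end = g_end, strand = row$strand
    ))
    sp$proteins[[dup_id]] <- sp$proteins[[row$gene_id]]
  }
  sp$genome <- stats::setNames(s, contig_id)
  bundle$species[[species]] <- sp
  bundle
}

#' Mix two fixture genomes to emulate contamination
#'
#' Concatenates contigs from bundle `b` onto the assembly of a species from
#' bundle `a` until their total length reaches approximately `fraction` of
#' `a`'s genome length (or `b` is exhausted). `b`'s gene annotation is kept
#' (re-labelled to the mixed assembly) for truth tracking.
#'
#' @param bundle_a,bundle_b Fixture bundles (host and contaminant).
#' @param fraction Target contaminant fraction of `a`'s genome length,
#'   in (0, 1).
#' @param species_a,species_b Species to draw from each bundle (defaults:
#'   first of each).
#' @return A list with `genome` (named character vector: host contig plus
#'   contaminant contigs), `genes` (combined gene table with a `source`
#'   column), and `host`/`contaminant` species names.
#' @export
inject_contamination <- function(bundle_a, bundle_b, fraction,
                                 species_a = names(bundle_a$species)[1],
                                 species_b = names(bundle_b$species)[1]) {
  stopifnot(fraction > 0, fraction < 1)
  a <- bundle_a$species[[species_a]]
  b <- bundle_b$species[[species_b]]
  target <- fraction * sum(nchar(a$genome))
  added <- character()
  taken <- character()
  total <- 0
  for (cid in names(b$genome)) {
    if (total >= target) break
    # contaminant contigs get a distinct name so self-mixes stay well formed
    added[[paste0("mix_", species_b, "_", cid)]] <- b$genome[[cid]]
    taken <- c(taken, cid)
    total <- total + nchar(b$genome[[cid]])
  }
  genome <- c(a$genome, added)
  b_genes <- b$genes[b$genes$seqid %in% taken, ]
  b_genes$seqid <- paste0("mix_", species_b, "_", b_genes$seqid)
  genes <- dplyr::bind_rows(
    dplyr::mutate(a$genes, source = species_a),
    dplyr::mutate(b_genes, source = species_b)
  )
  list(genome = genome, genes = genes, host = species_a, contaminant = species_b)
}

#' Write a fixture species to FASTA/GFF3 files
#'
#' Materialises one species of a bundle as standard files: genome FASTA,
#' protein gene-set FASTA, and a GFF3 annotation with `gene` features.
#'
#' @param bundle A `fixture_bundle`.
#' @param species Species name.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture <- function(bundle, species, dir) {
  stopifnot(species %in% names(bundle$species))
  sp <- bundle$species[[species]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, paste0(species, ".fna")),
    proteins = file.path(dir, paste0(species, ".faa")),
    gff = file.path(dir, paste0(species, ".gff3"))
  )
  write_fasta(sp$genome, paths[["genome"]], "DNA")
  write_fasta(sp$proteins, paths[["proteins"]], "AA")
  gr <- GenomicRanges::GRanges(
    seqnames = sp$genes$seqid,
    ranges = IRanges::IRanges(sp$genes$start, sp$genes$end),
    strand = sp$genes$strand,
    type = "gene", ID = sp$genes$gene_id, marker = sp$genes$marker_id,
    source = "orthoscore_sim"
  )
  rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  paths
}

#' Balanced dataset-hierarchy fixture for lineage selection
#'
#' Builds a three-level hierarchy (one domain root, two intermediate clades,
#' four leaf datasets) from a single simulated lineage: 12 species in four
#' clades of three. Datasets at each node are built from the species below
#' it. Also returns a fresh query species evolved from inside a designated
#' leaf clade at a chosen divergence, with the name of its true
#' (most specific) dataset.
#'
#' @param n_markers Markers per dataset.
#' @param seed Integer seed.
#' @param query_divergence Branch length between the query species and its
#'   clade sibling (0 = exact clade member).
#' @param true_leaf Index 1-4 of the leaf clade the query belongs to.
#' @param domain,genetic_code Dataset metadata for all nodes.
#' @return A list with `tree` (a [dataset_tree()]), `query` (genome named
#'   character vector), `query_proteins`, `truth_dataset` (name), and
#'   `bundle`.
#' @export
lineage_tree_fixture <- function(n_markers = 20, seed = 1,
                                 query_divergence = 0, true_leaf = 1,
                                 domain = "bacteria", genetic_code = 11) {
  stopifnot(true_leaf %in% 1:4)
  clades <- paste0("clade", 1:4)
  # clade c species: c_s1..c_s3; query evolves from the target clade's stem.
  tip <- function(cl, i, bl) sprintf("%s_s%d:%.3f", cl, i, bl)
  clade_nwk <- function(cl) {
    sprintf("(%s,%s,%s):0.20", tip(cl, 1, 0.05), tip(cl, 2, 0.05), tip(cl, 3, 0.05))
  }
  nwk <- sprintf("((%s,%s):0.20,(%s,%s):0.20):0;",
                 clade_nwk(clades[1]), clade_nwk(clades[2]),
                 clade_nwk(clades[3]), clade_nwk(clades[4]))
  spec <- lineage_spec(nwk, n_markers = n_markers, genetic_code = genetic_code,
                       seed = seed)
  bundle <- simulate_lineage(spec)
  clade_species <- lapply(stats::setNames(clades, clades), function(cl) {
    paste0(cl, "_s", 1:3)
  })
  mk <- function(nm, sps, parent) {
    dataset_from_bundle(bundle, species = sps, name = nm, domain = domain,
                        parent = parent)
  }
  datasets <- list(
    mk("root", unlist(clade_species), NA_character_),
    mk("cladeAB", unlist(clade_species[1:2]), "root"),
    mk("cladeCD", unlist(clade_species[3:4]), "root"),
    mk("clade1", clade_species[[1]], "cladeAB"),
    mk("clade2", clade_species[[2]], "cladeAB"),
    mk("clade3", clade_species[[3]], "cladeCD"),
    mk("clade4", clade_species[[4]], "cladeCD")
  )
  tree <- dataset_tree(datasets)
  # query: a fresh species evolved from inside the target leaf clade
  query <- evolve_query(bundle, paste0(clades[true_leaf], "_s1"),
                        query_divergence, child_seed(seed, 11, true_leaf))
  list(tree = tree, query = query$genome, query_proteins = query$proteins,
       truth_dataset = paste0("clade", true_leaf), bundle = bundle)
}

# Evolve a fresh query species from an existing fixture species and assemble
# its genome the same way the simulator does.
evolve_query <- function(bundle, species, divergence, seed) {
  spec <- bundle$spec
  with_seed(seed, {
    table <- translation_table(spec$genetic_code)
    choices <- codon_choices_for(table)
    scrub <- "TGA" %in% table$stop_codons
    prots <- lapply(bundle$proteins[[species]], mutate_protein,
                    bl = divergence, background = spec$background,
                    scrub = scrub)
    parts <- list(random_intergenic(50L, scrub), GENE_GUARD)
    gene_set <- character()
    for (m in names(prots)) {
      nt <- reverse_translate(prots[[m]], choices, scrub)
      strand <- sample(c("+", "-"), 1L)
      parts <- c(parts, if (strand == "+") nt else reverse_complement(nt),
                 GENE_GUARD, random_intergenic(40L, scrub), GENE_GUARD)
      gene_set[[paste0("query_g_", m)]] <- prots[[m]]
    }
    list(genome = stats::setNames(paste(unlist(parts), collapse = ""), "query_contig1"),
         proteins = gene_set)
  })
}
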
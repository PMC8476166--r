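# The synthetic-lineage simulator itself.

test_that("zero branch lengths reproduce the ancestor in every species", {
  b <- simulate_lineage(lineage_spec("(a:0,b:0,c:0);", n_markers = 6, seed = 13))
  for (m in names(b$proteins$a)) {
    expect_identical(b$proteins$a[[m]], b$proteins$b[[m]])
    expect_identical(b$proteins$a[[m]], b$proteins$c[[m]])
  }
})

test_that("bundles are byte-identical for the same seed and differ across seeds", {
  s1 <- simulate_lineage(lineage_spec("(a:0.05,b:0.05);", n_markers = 5, seed = 8))
  s2 <- simulate_lineage(lineage_spec("(a:0.05,b:0.05);", n_markers = 5, seed = 8))
  expect_identical(s1$species$a$genome, s2$species$a$genome)
  expect_identical(s1$proteins, s2$proteins)
  s3 <- simulate_lineage(lineage_spec("(a:0.05,b:0.05);", n_markers = 5, seed = 9))
  expect_false(identical(s1$species$a$genome, s3$species$a$genome))
})

test_that("every annotated gene translates to its gene-set protein", {
  for (code in c(11, 4)) {
    b <- simulate_lineage(lineage_spec("(a:0.03,b:0.03);", n_markers = 8,
                                       seed = 15, genetic_code = code))
    sp <- b$species$a
    for (i in seq_len(nrow(sp$genes))) {
      g <- sp$genes[i, ]
      nt <- substr(sp$genome[[1]], g$start, g$end)
      if (g$strand == "-") nt <- orthoscore:::reverse_complement(nt)
      expect_identical(translate_nt(nt, code),
                       paste0(sp$proteins[[g$gene_id]], "*"))
    }
    # truth covers n_markers x n_species cells
    expect_identical(nrow(b$truth), 8L * 2L)
  }
})

test_that("lineage spec validates its inputs", {
  expect_error(lineage_spec("(a:-1,b:1);", n_markers = 2), "branch lengths")
  expect_error(lineage_spec("(a:0,b:0);", n_markers = 0))
  expect_error(lineage_spec("(a:0,b:0);", marker_length_range = c(-5, 10)))
})

test_that("duplication injection preserves genome bookkeeping and inverts", {
  fx <- fx_clean()
  b <- fx$bundle
  len0 <- nchar(b$species$s6$genome)
  marks <- c("marker001", "marker002")
  bd <- inject_duplications(b, "s6", marks)
  spans <- vapply(marks, function(m) {
    r <- b$species$s6$genes[b$species$s6$genes$marker_id == m, ]
    r$end - r$start + 1L
  }, integer(1))
  guard <- nchar(orthoscore:::GENE_GUARD)
  expect_identical(nchar(bd$species$s6$genome),
                   len0 + sum(spans) + 2L * guard * length(marks))
  expect_identical(nrow(bd$species$s6$genes),
                   nrow(b$species$s6$genes) + length(marks))
  expect_error(inject_duplications(b, "s6", "marker999"), "unknown marker")
  # removing the injected copies restores the original assessment
  res0 <- assess(b$species$s6$genome, fx$dataset, mode = "genome")
  resd <- assess(bd$species$s6$genome, fx$dataset, mode = "genome")
  expect_identical(unname(resd$counts[["D"]]), 2L)
  trimmed <- substr(bd$species$s6$genome, 1, len0)
  names(trimmed) <- names(b$species$s6$genome)
  res1 <- assess(trimmed, fx$dataset, mode = "genome")
  expect_identical(format_summary(res1), format_summary(res0))
})

test_that("contamination mixes stay within one contig of the target size", {
  roots <- fx_roots()
  mix <- inject_contamination(roots$bac, roots$euk, 0.4, "a3", "e3")
  len_a <- sum(nchar(roots$bac$species$a3$genome))
  len_mix <- sum(nchar(mix$genome))
  biggest_b <- max(nchar(roots$euk$species$e3$genome))
  expect_lte(len_mix, len_a * 1.4 + biggest_b)
  expect_gt(len_mix, len_a)
  # mixing a bundle with itself raises duplications, not domain flags
  selfmix <- inject_contamination(roots$bac, roots$bac, 0.99, "a3", "a3")
  scr <- cross_domain_screen(selfmix$genome, roots$datasets)
  expect_false(any(scr$flagged))
  res <- assess(selfmix$genome, roots$datasets[[1]], mode = "genome")
  expect_gt(unname(res$counts[["D"]]), 0)
})

test_that("self-consistency: a clade member scores complete on its own dataset", {
  fx <- fx_clean()
  res <- assess(fx$query, fx$dataset, mode = "genome")
  expect_identical(unname(res$counts[["S"]] + res$counts[["D"]]), res$n)
  expect_identical(unname(res$counts[["M"]]), 0L)
})

test_that("completeness degrades with divergence", {
  cs <- vapply(c(0, 0.08, 0.25), function(d) {
    fx <- if (d == 0) fx_clean() else fx_diverged(seed = 202 + round(d * 100),
                                                  tip = d)
    completeness_pct(assess(fx$query_proteins, fx$dataset,
                            mode = "proteins"))[["C"]]
  }, numeric(1))
  expect_true(all(diff(cs) <= 0))
  expect_lt(cs[3], cs[1])
})

test_that("written fixtures are valid FASTA/GFF3", {
  fx <- fx_clean()
  d <- withr::local_tempdir()
  paths <- write_fixture(fx$bundle, "s1", d)
  expect_true(all(file.exists(paths)))
  g <- Biostrings::readDNAStringSet(paths[["genome"]])
  expect_identical(length(g), 1L)
  gr <- rtracklayer::import(paths[["gff"]], format = "gff3")
  expect_identical(length(gr), nrow(fx$bundle$species$s1$genes))
})
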
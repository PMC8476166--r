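# Depletion benchmark: sampling, masking, truth mapping, FP/FN accounting.

bench_fx <- function() {
  fx_memo("bench", {
    b <- simulate_lineage(lineage_spec("(s1:0,s2:0,s3:0);", n_markers = 20,
                                       seed = 11))
    list(bundle = b,
         dataset = dataset_from_bundle(b, c("s1", "s2"), name = "bench_ds"),
         genes = b$species$s3$proteins,
         genome = b$species$s3$genome,
         genes_tab = b$species$s3$genes)
  })
}

test_that("deplete_gene_set removes the rounded fraction, deterministically", {
  fx <- bench_fx()
  d0 <- deplete_gene_set(fx$genes, 0, seed = 1)
  expect_length(d0$removed, 0)
  expect_identical(d0$genes, fx$genes)
  d1 <- deplete_gene_set(fx$genes, 1, seed = 1)
  expect_length(d1$removed, length(fx$genes))
  expect_length(d1$genes, 0)
  da <- deplete_gene_set(fx$genes, 0.3, seed = 42)
  db <- deplete_gene_set(fx$genes, 0.3, seed = 42)
  expect_identical(da$removed, db$removed)
  expect_length(da$removed, as.integer(round_half_up(0.3 * length(fx$genes))))
  dc <- deplete_gene_set(fx$genes, 0.3, seed = 43)
  expect_false(identical(da$removed, dc$removed))
  # eligible subset restricts removal
  elig <- names(fx$genes)[1:4]
  de <- deplete_gene_set(fx$genes, 0.5, eligible = elig, seed = 1)
  expect_length(de$removed, 2)
  expect_true(all(de$removed %in% elig))
})

test_that("mask_genome replaces exact spans with N and preserves length", {
  fx <- bench_fx()
  g <- fx$genome
  tab <- fx$genes_tab
  row <- tab[3, ]
  masked <- mask_genome(g, tab, row$gene_id)
  expect_identical(nchar(masked), nchar(g))
  span <- substr(masked[[row$seqid]], row$start, row$end)
  expect_identical(span, strrep("N", row$end - row$start + 1L))
  # positions outside the span untouched
  expect_identical(substr(masked[[row$seqid]], 1, row$start - 1L),
                   substr(g[[row$seqid]], 1, row$start - 1L))
  # empty removal set: byte-identical genome
  expect_identical(mask_genome(g, tab, character()), g)
  # overlapping spans are masked once, length preserved
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(tab[3, ], gene_id = "ov",
                                              start = start + 5L,
                                              end = end + 5L))
  masked2 <- mask_genome(g, tab2, c(row$gene_id, "ov"))
  expect_identical(nchar(masked2), nchar(g))
  expect_error(mask_genome(g, tab, "ghost_gene"), "ghost_gene")
})

test_that("masking accepts GFF3 files round-tripped through rtracklayer", {
  fx <- bench_fx()
  d <- withr::local_tempdir()
  paths <- write_fixture(fx$bundle, "s3", d)
  g <- as.character(Biostrings::readDNAStringSet(paths[["genome"]]))
  names(g) <- sub("\\s.*", "", names(g))
  row <- fx$genes_tab[1, ]
  masked <- mask_genome(g, paths[["gff"]], row$gene_id)
  expect_identical(substr(masked[[row$seqid]], row$start, row$end),
                   strrep("N", row$end - row$start + 1L))
})

test_that("ground-truth mapping is a function covering intact markers", {
  fx <- bench_fx()
  truth <- map_ground_truth(fx$genes, fx$dataset)
  expect_identical(nrow(truth), n_markers(fx$dataset))
  expect_false(anyDuplicated(truth$marker_id) > 0)
  # random proteins map to nothing
  withr::with_seed(9, {
    rnd <- stats::setNames(
      vapply(1:10, function(i) paste(sample(orthoscore:::AA20, 60, replace = TRUE),
                                     collapse = ""), character(1)),
      paste0("r", 1:10))
  })
  expect_identical(nrow(map_ground_truth(rnd, fx$dataset)), 0L)
})

test_that("evaluation counts TP/FP/FN against the frozen mapping", {
  fx <- bench_fx()
  truth <- map_ground_truth(fx$genes, fx$dataset)
  res <- assess(fx$genes, fx$dataset, mode = "proteins")
  ev <- evaluate_depletion(res, truth, character())
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(nrow(truth), 0L, 0L))
  expect_identical(ev$precision, 1)
  # remove 6 genes but assess the intact set: they are counted as FP
  removed <- truth$gene_id[1:6]
  ev2 <- evaluate_depletion(res, truth, removed)
  expect_identical(ev2$fp, 6L)
  expect_identical(ev2$tp + ev2$fn, nrow(truth) - 6L)
  expect_equal(ev2$precision, ev2$tp / (ev2$tp + ev2$fp))
})

test_that("the full benchmark tracks depletion exactly on a clean fixture", {
  fx <- bench_fx()
  plan <- depletion_plan(replicates = 2, seed = 7)
  expect_true(1 %in% plan$levels)   # marker-only protocol adds level 1.0
  rep <- run_benchmark(fx$genes, fx$dataset, plan, genome = fx$genome,
                       annotation = fx$genes_tab, modes = c("proteins", "genome"))
  tab <- tidy(rep)
  # 4 levels x 2 replicates x 2 modes + level 1.0 x 1 replicate x 2 modes
  expect_identical(nrow(tab), 18L)
  # missing exactly equals the number of removed truth genes, in both modes
  expect_identical(tab$M, tab$n_removed_truth)
  expect_true(all(tab$fn == 0L))
  expect_true(all(tab$fp == 0L))
  # level 0: perfect recovery and precision 1
  lvl0 <- tab[tab$level == 0, ]
  expect_true(all(lvl0$M == 0L))
  expect_true(all(lvl0$precision == 1))
  # 100% depletion: nothing found, nothing falsely found
  lvl1 <- tab[tab$level == 1, ]
  expect_true(all(lvl1$tp == 0L))
  expect_true(all(lvl1$fp == 0L))
  expect_true(all(is.na(lvl1$precision)))
  # genome and proteins modes agree exactly on single-exon fixtures
  wide <- tidyr::pivot_wider(tab[, c("level", "replicate", "mode", "M")],
                             names_from = "mode", values_from = "M")
  expect_identical(wide$proteins, wide$genome)
  # mean missing is non-decreasing in depletion level
  gl <- glance(rep)
  for (m in unique(gl$mode)) {
    mm <- gl$mean_missing[gl$mode == m][order(gl$level[gl$mode == m])]
    expect_true(all(diff(mm) >= 0))
  }
})

test_that("benchmark reports are reproducible at a fixed master seed", {
  fx <- bench_fx()
  plan <- depletion_plan(levels = c(0, 0.3), replicates = 2, seed = 31)
  r1 <- run_benchmark(fx$genes, fx$dataset, plan, modes = "proteins")
  r2 <- run_benchmark(fx$genes, fx$dataset, plan, modes = "proteins")
  expect_identical(tidy(r1), tidy(r2))
  # a different master seed removes a different gene subset (counts are
  # design-determined and stay equal; the sampled identities change)
  s1 <- deplete_gene_set(fx$genes, 0.3, seed = orthoscore:::child_seed(31, 2, 1))
  s2 <- deplete_gene_set(fx$genes, 0.3, seed = orthoscore:::child_seed(32, 2, 1))
  expect_false(identical(s1$removed, s2$removed))
})

test_that("a paralogous decoy above cutoff produces exactly one FP", {
  fx <- bench_fx()
  truth <- map_ground_truth(fx$genes, fx$dataset)
  decoy_src <- truth$gene_id[1]
  genes2 <- c(fx$genes, stats::setNames(fx$genes[decoy_src], "decoy1"))
  truth2 <- map_ground_truth(genes2, fx$dataset)
  # the mapping stays a function and keeps the original gene on ties
  expect_identical(truth2$gene_id[truth2$marker_id == truth$marker_id[1]],
                   decoy_src)
  dep <- deplete_gene_set(genes2, 1, eligible = truth2$gene_id, seed = 3)
  res <- assess(dep$genes, fx$dataset, mode = "proteins")
  ev <- evaluate_depletion(res, truth2, dep$removed)
  expect_identical(ev$fp, 1L)
  expect_identical(ev$tp, 0L)
  expect_equal(ev$precision, 0)
})
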
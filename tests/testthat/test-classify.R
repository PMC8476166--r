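# Status classification, aggregate results, the score string, the parasitic
# check, and the cross-domain screen.

hit_row <- function(marker = "m", seq = "s1", score = 10, alen = 10,
                    start = 1) {
  tibble::tibble(marker_id = marker, sequence_id = seq, bit_score = score,
                 aligned_length = as.integer(alen),
                 env_start = as.integer(start),
                 env_end = as.integer(start + alen - 1L))
}

test_that("classification boundaries are inclusive and sigma-aware", {
  fam <- marker_family("m", c(a = strrep("K", 10)), score_cutoff = 10,
                       length_mean = 10, length_sigma = 2)
  # boundary: score == cutoff, length == mean -> complete_single
  expect_identical(classify_marker(hit_row(score = 10, alen = 10), fam)$status,
                   "complete_single")
  # within 2 sigma still complete
  expect_identical(classify_marker(hit_row(score = 10, alen = 14), fam)$status,
                   "complete_single")
  # outside the band but above cutoff -> fragmented
  expect_identical(classify_marker(hit_row(score = 12, alen = 4), fam)$status,
                   "fragmented")
  # below cutoff -> missing
  expect_identical(classify_marker(hit_row(score = 9.99, alen = 10), fam)$status,
                   "missing")
  # sigma 0 requires exact length
  fam0 <- marker_family("m", c(a = strrep("K", 10)), 10, 10, 0)
  expect_identical(classify_marker(hit_row(score = 11, alen = 9), fam0)$status,
                   "fragmented")
  expect_identical(classify_marker(hit_row(score = 11, alen = 10), fam0)$status,
                   "complete_single")
})

test_that("distinct loci drive duplication; overlapping hits merge", {
  fam <- marker_family("m", c(a = strrep("K", 10)), 10, 10, 2)
  two_seq <- dplyr::bind_rows(hit_row(seq = "s1", score = 12),
                              hit_row(seq = "s2", score = 11))
  st <- classify_marker(two_seq, fam)
  expect_identical(st$status, "complete_duplicated")
  expect_gte(nrow(st$loci), 2)
  # same sequence, >= 50% overlap: merged, best kept -> single
  overlapping <- dplyr::bind_rows(hit_row(start = 1, alen = 10, score = 12),
                                  hit_row(start = 4, alen = 10, score = 11))
  expect_identical(classify_marker(overlapping, fam)$status, "complete_single")
  # same sequence, disjoint envelopes: genuinely distinct loci
  disjoint <- dplyr::bind_rows(hit_row(start = 1, alen = 10, score = 12),
                               hit_row(start = 40, alen = 10, score = 11))
  expect_identical(classify_marker(disjoint, fam)$status, "complete_duplicated")
  expect_error(classify_marker(hit_row(marker = "other"), fam), "belong")
})

test_that("assess yields full recovery on a clean fixture and is deterministic", {
  fx <- fx_clean()
  r1 <- assess(fx$query, fx$dataset, mode = "genome")
  expect_identical(unname(r1$counts[["M"]]), 0L)
  expect_identical(unname(r1$counts[["S"]] + r1$counts[["D"]]), r1$n)
  expect_conservation(r1)
  r2 <- assess(fx$query, fx$dataset, mode = "genome")
  expect_identical(format_summary(r1), format_summary(r2))
  expect_identical(tidy(r1), tidy(r2))
  expect_error(assess(character(), fx$dataset, mode = "proteins"), "no sequences")
})

test_that("conservation holds across modes and diverged inputs", {
  fx <- fx_diverged()
  for (res in list(
    assess(fx$query, fx$dataset, mode = "genome"),
    assess(fx$query_proteins, fx$dataset, mode = "proteins"),
    assess(fx$query, fx$dataset, mode = "transcriptome")
  )) {
    expect_conservation(res)
  }
})

test_that("format_summary reproduces the canonical score string", {
  mk_result <- function(S, D, F, M) {
    structure(list(input_id = "x", dataset_name = "d", domain = "bacteria",
                   mode = "proteins", workflow_label = "proteins",
                   counts = c(S = S, D = D, F = F, M = M), n = S + D + F + M,
                   per_marker = list(), genetic_code_used = NA_integer_),
              class = "marker_assessment")
  }
  expect_identical(format_summary(mk_result(470L, 4382L, 5L, 39L)),
                   "C:99.1%[S:9.6%,D:89.5%],F:0.1%,M:0.8%,n:4896")
  expect_identical(format_summary(mk_result(10L, 0L, 0L, 0L)),
                   "C:100.0%[S:100.0%,D:0.0%],F:0.0%,M:0.0%,n:10")
  expect_identical(format_summary(mk_result(0L, 0L, 0L, 8L)),
                   "C:0.0%[S:0.0%,D:0.0%],F:0.0%,M:100.0%,n:8")
})

test_that("percentage rounding is half-up at one decimal", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(99.0849, 1), 99.1)
  expect_equal(round_half_up(9.5996, 1), 9.6)
  expect_equal(round_half_up(2.25, 1), 2.3)  # base round() would give 2.2
})

test_that("parasitic recalculation removes markers and rescales", {
  fx <- fx_diverged(seed = 209, tip = 0.2)
  res <- assess(fx$query_proteins, fx$dataset, mode = "proteins")
  st <- vapply(res$per_marker, function(s) s$status, character(1))
  miss <- names(st)[st == "missing"]
  expect_gt(length(miss), 0)
  r2 <- parasitic_recalculate(res, miss)
  expect_identical(r2$n, res$n - length(miss))
  expect_identical(unname(r2$counts[["M"]]), 0L)
  expect_conservation(r2)
  # empty exclusion list is the identity on counts
  r3 <- parasitic_recalculate(res, character())
  expect_identical(r3$counts, res$counts)
  expect_identical(r3$n, res$n)
  # excluding one complete marker shifts S and n down by one
  comp <- names(st)[st == "complete_single"][1]
  r4 <- parasitic_recalculate(res, comp)
  expect_identical(unname(r4$counts[["S"]]), unname(res$counts[["S"]]) - 1L)
  expect_identical(r4$n, res$n - 1L)
  expect_error(parasitic_recalculate(res, "no_such_marker"), "not in the dataset")
  expect_error(parasitic_recalculate(res, names(st)), "every marker")
})

test_that("appending unrelated sequences never loses a complete marker", {
  fx <- fx_clean()
  base <- assess(fx$query_proteins, fx$dataset, mode = "proteins")
  st0 <- vapply(base$per_marker, function(s) s$status, character(1))
  withr::with_seed(23, {
    junk <- stats::setNames(
      vapply(1:5, function(i) paste(sample(orthoscore:::AA20, 80, replace = TRUE),
                                    collapse = ""), character(1)),
      paste0("junk", 1:5))
  })
  aug <- assess(c(fx$query_proteins, junk), fx$dataset, mode = "proteins")
  st1 <- vapply(aug$per_marker, function(s) s$status, character(1))
  was_complete <- names(st0)[st0 == "complete_single"]
  expect_true(all(st1[was_complete] != "missing"))
})

test_that("injected duplications are counted as duplicated, exactly", {
  fx <- fx_clean()
  for (k in c(1L, 3L)) {
    marks <- sprintf("marker%03d", seq_len(k))
    bd <- inject_duplications(fx$bundle, "s6", marks)
    res <- assess(bd$species$s6$genome, fx$dataset, mode = "genome")
    expect_identical(unname(res$counts[["D"]]), k)
    st <- vapply(res$per_marker, function(s) s$status, character(1))
    expect_true(all(st[marks] == "complete_duplicated"))
    expect_conservation(res)
  }
})

test_that("the cross-domain screen flags mixtures but not pure genomes", {
  roots <- fx_roots()
  pure <- cross_domain_screen(roots$bac$species$a3$genome, roots$datasets)
  expect_false(any(pure$flagged))
  expect_identical(pure$domain[pure$home], "bacteria")
  mix <- inject_contamination(roots$bac, roots$euk, 0.5, "a3", "e3")
  scr <- cross_domain_screen(mix$genome, roots$datasets)
  expect_true(scr$flagged[scr$domain == "eukaryota"])
  # determinism
  scr2 <- cross_domain_screen(mix$genome, roots$datasets)
  expect_identical(scr, scr2)
})

test_that("assessment files round-trip through the writers", {
  fx <- fx_clean()
  res <- assess(fx$query_proteins, fx$dataset, mode = "proteins")
  d <- withr::local_tempdir()
  paths <- write_assessment(res, d, config = search_config())
  expect_true(all(file.exists(paths)))
  tab <- utils::read.delim(paths[["full_table"]])
  expect_identical(sort(unique(tab$marker_id)), sort(names(fx$dataset$markers)))
  js <- jsonlite::read_json(paths[["summary_json"]])
  expect_identical(js$one_line, format_summary(res))
  expect_identical(js$counts$S + js$counts$D + js$counts$F + js$counts$M, js$n)
})
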
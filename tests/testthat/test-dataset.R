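# Dataset model: construction, on-disk round trip, and building from an
# orthology table.

make_ds <- function() {
  fams <- list(
    marker_family("mA", c(x = "MKLVAW", y = "MKLVAW"), 12.5, 6, 0),
    marker_family("mB", c(x = "MACD-F", y = "MACDEF"), 8.25, 5.5, 0.5),
    marker_family("mC", c(x = "MWYK"), 4.75, 4, 0)
  )
  marker_dataset("demo", "bacteria", fams, genetic_codes = c(11L, 4L))
}

test_that("marker_family enforces its invariants", {
  expect_error(marker_family("bad id", c("MK"), 1, 2, 0), "whitespace")
  expect_error(marker_family("m", c("MK", "MKL"), 1, 2, 0), "equal aligned length")
  expect_error(marker_family("m", c("MK"), -1, 2, 0))
  expect_error(marker_family("m", c("MK"), 1, 2, -0.1))
})

test_that("marker_dataset validates ids, codes and counts", {
  fam <- marker_family("m1", c("MKLV"), 1, 4, 0)
  expect_error(marker_dataset("d", "bacteria", list(fam, fam)), "duplicate")
  expect_error(marker_dataset("d", "archaea", list(fam)), "genetic code")
  ds <- marker_dataset("d", "eukaryota", list(fam))
  expect_identical(n_markers(ds), 1L)
  ds2 <- make_ds()
  expect_identical(ds2$n_markers, 3L)
  expect_identical(ds2$genetic_codes, c(11L, 4L))
})

test_that("write/load round-trips a dataset and is byte-stable", {
  ds <- make_ds()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(ds, d2)
  for (f in c("dataset.cfg", "scores_cutoff.tsv", "lengths_cutoff.tsv",
              "seeds/mA.faa", "seeds/mB.faa", "seeds/mC.faa")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- load_dataset(d1)
  expect_identical(back$name, ds$name)
  expect_identical(back$domain, ds$domain)
  expect_identical(back$genetic_codes, ds$genetic_codes)
  expect_identical(back$n_markers, ds$n_markers)
  expect_equal(back$markers, ds$markers)
})

test_that("loading rejects inconsistent or malformed directories", {
  ds <- make_ds()
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  # score table losing a marker row -> consistency error
  sc <- readLines(file.path(d, "scores_cutoff.tsv"))
  writeLines(sc[-1], file.path(d, "scores_cutoff.tsv"))
  expect_error(load_dataset(d), "consistency")
  writeLines(sc, file.path(d, "scores_cutoff.tsv"))
  # missing seed file
  unlink(file.path(d, "seeds", "mB.faa"))
  expect_error(load_dataset(d), "seed file")
  write_dataset(ds, d)
  # malformed config line, reported with file and line number
  cfg <- readLines(file.path(d, "dataset.cfg"))
  writeLines(c(cfg[1], "not a key value pair", cfg[-1]), file.path(d, "dataset.cfg"))
  expect_error(load_dataset(d), "line 2")
})

test_that("empty datasets cannot be written", {
  ds <- make_ds()
  ds$markers <- list()
  ds$n_markers <- 0L
  expect_error(write_dataset(ds, withr::local_tempdir()), "empty")
})

test_that("build_dataset retains single-copy orthogroups by threshold", {
  species <- paste0("sp", 1:5)
  orth <- dplyr::bind_rows(
    tibble::tibble(orthogroup = "og1", species = species, copies = 1L),
    tibble::tibble(orthogroup = "og2", species = species,
                   copies = c(1L, 1L, 1L, 1L, 2L)),
    tibble::tibble(orthogroup = "og3", species = species,
                   copies = c(1L, 1L, 0L, 2L, 2L))
  )
  aln <- list(og1 = c(a = "MKLVAWYC", b = "MKLVAWYC"),
              og2 = c(a = "MACDEFGH", b = "MACDEFGH"),
              og3 = c(a = "MWYKLRHN", b = "MWYKLRHN"))
  ds9 <- build_dataset(orth, aln, 0.9, name = "t", domain = "bacteria",
                       genetic_codes = 11)
  expect_identical(names(ds9$markers), "og1")     # og2 at 0.8 excluded
  ds7 <- build_dataset(orth, aln, 0.7, name = "t", domain = "bacteria",
                       genetic_codes = 11)
  expect_identical(names(ds7$markers), c("og1", "og2"))
  # monotone in threshold: raising it never adds markers
  for (thr in c(0.4, 0.6, 0.8, 1.0)) {
    lo <- build_dataset(orth, aln, thr - 0.2, name = "t", domain = "bacteria",
                        genetic_codes = 11)
    hi <- build_dataset(orth, aln, thr, name = "t", domain = "bacteria",
                        genetic_codes = 11)
    expect_true(all(names(hi$markers) %in% names(lo$markers)))
  }
  expect_error(
    build_dataset(orth[orth$orthogroup == "og3", ], aln, 0.9, name = "t",
                  domain = "bacteria", genetic_codes = 11),
    "no orthogroup"
  )
})

test_that("calibrated cutoffs follow the 0.9 x min self-score rule", {
  aln <- list(og1 = c(a = "MKLVAWYCDE", b = "MKLVAWYCDE", c = "MKLVAWYCDE"))
  orth <- tibble::tibble(orthogroup = "og1", species = c("a", "b", "c"),
                         copies = 1L)
  ds <- build_dataset(orth, aln, 0.9, name = "t", domain = "bacteria",
                      genetic_codes = 11)
  fam <- ds$markers$og1
  prof <- build_profile(fam)
  selfs <- vapply(gsub("-", "", fam$seed_alignment), function(s) {
    score_sequence(prof, s)$bit_score
  }, numeric(1))
  expect_equal(fam$score_cutoff, round_half_up(0.9 * min(selfs), 2))
})

test_that("length statistics equal direct recomputation over seed members", {
  fx <- fx_diverged()
  for (fam in fx$dataset$markers[1:5]) {
    lens <- nchar(gsub("-", "", fam$seed_alignment))
    expect_equal(fam$length_mean, round_half_up(mean(lens), 2))
    expect_equal(fam$length_sigma,
                 round_half_up(sqrt(mean((lens - mean(lens))^2)), 2))
  }
})

test_that("dataset_tree validates parents, cycles and domain roots", {
  fam <- function(id) marker_family(id, c("MKLV"), 1, 4, 0)
  mk <- function(name, parent = NA) {
    marker_dataset(name, "bacteria", list(fam("m")), genetic_codes = 11,
                   parent = parent)
  }
  tr <- dataset_tree(list(mk("root"), mk("kid", "root"), mk("leaf", "kid")))
  expect_identical(tr$roots, "root")
  expect_identical(orthoscore:::tree_ancestors(tr, "leaf"), c("kid", "root"))
  expect_error(dataset_tree(list(mk("a", "ghost"))), "unknown parent")
  a <- mk("a", "b"); b <- mk("b", "a")
  expect_error(dataset_tree(list(a, b)), "cycle")
  expect_error(dataset_tree(list(mk("solo")), require_domain_roots = TRUE),
               "one dataset per domain")
})
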
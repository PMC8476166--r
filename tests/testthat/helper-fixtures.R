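# Shared fixtures, built once per test run and memoised. All generation is
# seeded, so every helper is deterministic.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, force(expr), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# A clean rate-0 bundle: 6 identical species, dataset built from the first 5.
fx_clean <- function(n_markers = 20, seed = 101) {
  fx_memo(paste0("clean", n_markers, "_", seed), {
    b <- simulate_lineage(lineage_spec(
      "(s1:0,s2:0,s3:0,s4:0,s5:0,s6:0);",
      n_markers = n_markers, seed = seed))
    ds <- dataset_from_bundle(b, paste0("s", 1:5), name = "clean_ds")
    list(bundle = b, dataset = ds,
         query = b$species$s6$genome,
         query_proteins = b$species$s6$proteins)
  })
}

# A moderately diverged bundle: 5 close seed species plus a held-out tip.
fx_diverged <- function(n_markers = 20, seed = 202, tip = 0.05) {
  fx_memo(paste0("div", n_markers, "_", seed, "_", tip), {
    nwk <- sprintf("(s1:0.02,s2:0.02,s3:0.02,s4:0.02,s5:0.02,s6:%0.3f);", tip)
    b <- simulate_lineage(lineage_spec(nwk, n_markers = n_markers, seed = seed))
    ds <- dataset_from_bundle(b, paste0("s", 1:5), name = "div_ds")
    list(bundle = b, dataset = ds,
         query = b$species$s6$genome,
         query_proteins = b$species$s6$proteins)
  })
}

# Three small root datasets from unrelated lineages, one per domain.
fx_roots <- function() {
  fx_memo("roots", {
    bac <- simulate_lineage(lineage_spec("(a1:0.01,a2:0.01,a3:0.01);",
                                         n_markers = 15, seed = 301))
    arc <- simulate_lineage(lineage_spec("(r1:0.01,r2:0.01,r3:0.01);",
                                         n_markers = 12, seed = 302))
    euk <- simulate_lineage(lineage_spec("(e1:0.01,e2:0.01,e3:0.01);",
                                         n_markers = 12, seed = 303,
                                         genetic_code = 1,
                                         marker_length_range = c(40, 60)))
    list(
      bac = bac, arc = arc, euk = euk,
      datasets = list(
        dataset_from_bundle(bac, c("a1", "a2"), name = "bacteria_root",
                            domain = "bacteria"),
        dataset_from_bundle(arc, c("r1", "r2"), name = "archaea_root",
                            domain = "archaea"),
        dataset_from_bundle(euk, c("e1", "e2"), name = "eukaryota_root",
                            domain = "eukaryota", genetic_codes = 1)
      )
    )
  })
}

# A tiny hand-made family/profile for exact-value tests.
fx_tiny_family <- function(seqs = c(a = "MKLV"), cutoff = 1) {
  marker_family("tiny", seqs, score_cutoff = cutoff,
                length_mean = mean(nchar(gsub("-", "", seqs))),
                length_sigma = 0)
}

# Random profile + target pairs for the oracle sweep.
random_oracle_case <- function() {
  M <- sample(1:4, 1)
  k <- sample(1:3, 1)
  seqs <- vapply(seq_len(k), function(i) {
    paste(sample(orthoscore:::AA20, M, replace = TRUE), collapse = "")
  }, character(1))
  fam <- marker_family("case", stats::setNames(seqs, paste0("s", seq_len(k))),
                       score_cutoff = 1, length_mean = M, length_sigma = 0)
  L <- sample(1:5, 1)
  target <- paste(sample(orthoscore:::AA20, L, replace = TRUE), collapse = "")
  list(profile = build_profile(fam), target = target)
}

expect_conservation <- function(result) {
  expect_identical(sum(result$counts), as.integer(result$n))
}
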
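---
title: "orthoscore: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthoscore: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscore)
```

## The model

`orthoscore` estimates the completeness and redundancy of genomic data from
the recovery of *universal single-copy orthologs*: genes expected to occur
exactly once in nearly every genome of a lineage. A **marker dataset** is a
named collection of such gene families, each carrying a seed alignment, a
bit-score cutoff, and the mean and standard deviation of its members'
lengths. An input (genome assembly, annotated protein gene set, or
transcriptome) is searched for every marker; per-marker outcomes are
aggregated into the familiar categories

* **Complete, single-copy (S)** — exactly one locus reaches the marker's
  score cutoff with an alignment length inside the expected band,
* **Complete, duplicated (D)** — two or more such loci,
* **Fragmented (F)** — at least one locus reaches the score cutoff but none
  has an in-band length,
* **Missing (M)** — nothing reaches the cutoff,

and printed as the canonical one-line score string
`C:<c>%[S:<s>%,D:<d>%],F:<f>%,M:<m>%,n:<n>` with percentages rounded half-up
to one decimal. `S + D + F + M = n` holds for every result the package
produces, including after the parasitic recalculation and in batch mode.

## The search engine

The profile search is self-contained rather than delegated to an external
aligner, so that its semantics are exactly testable. Each family is compiled
into a position-specific profile: alignment columns with a gap fraction
below 0.5 become match columns; emissions are residue counts with add-one
smoothing over the 20-letter alphabet, stored as natural-log odds against a
uniform background. Scoring uses local alignment with free entry into and
exit from any match column, insert states emitting at background (log-odds
0), and silent delete states. Transition penalties are fixed rather than
estimated (match→insert = match→delete = ln 0.05, insert and delete
self-loops ln 0.4, with the complementary mass on the continuing moves):
estimating transitions from the small seed alignments would add variance
without changing what the scores are used for. Scores are reported in bits;
the Viterbi score is the best single path, the Forward score the log-sum
over all local paths, and the alignment envelope always comes from the
Viterbi traceback.

The dynamic-programming kernel is written in C++ for speed, and its
correctness is anchored by `enumerate_local_paths()`, a pure-R exhaustive
enumeration of every legal local state path. On profiles with up to four
match columns and targets of up to five residues the two routes agree to
machine precision; the test suite and the acceptance script sweep hundreds
of randomized cases.

**Sensitivity.** The search dial `s` in [1, 7] maps to a k-mer prefilter: a
target is scored against a marker only if it shares at least `ceiling(8 - s)`
distinct 4-mers with the marker's seed sequences, and `s >= 6` disables the
filter entirely (exhaustive scoring). Any monotone prefilter preserves the
property that matters: the recovered-marker set never shrinks as `s` grows.
Hits are reported down to half the marker's score cutoff; the full cutoff is
applied at classification time.

## Cutoff calibration

Marker datasets built with `build_dataset()` retain orthogroups present in
exactly one copy in at least a `single_copy_threshold` fraction of species
(default 0.9, the customary near-universality criterion). Per-marker cutoffs
are calibrated from the seeds themselves: the score cutoff is 0.9 times the
minimum Viterbi self-score of the seed members against the family profile,
and the length statistics are the mean and population standard deviation of
the ungapped seed lengths. These calibration rules are declared stand-ins:
they are deterministic, recomputable from the dataset alone, and stored at
the on-disk format's two-decimal precision so that writing and re-loading a
dataset is the identity.

A consequence worth knowing: when all seed members have equal length
(sigma = 0), the completeness band demands an exact length match, so even
mildly diverged orthologs are classified *fragmented* rather than complete
once local alignment trims a mismatched terminal residue. Completeness
percentages under divergence are therefore conservative; missingness — the
quantity the depletion benchmark tracks — is unaffected, because fragmented
markers still count as found.

## Gene extraction and genetic codes

Genome mode extracts candidate proteins by six-frame ORF calling: for each
stop codon, the ORF runs from the first start codon (ATG/GTG/TTG) after the
previous in-frame stop, and ORFs shorter than `min_orf_nt` (default 90 nt,
a conventional prokaryotic minimum) are discarded. This is deliberately the
simplest model that supports the workflow's own rule of genetic-code
auto-selection; intron-aware prediction is out of scope, and genome mode is
documented as valid for intron-poor inputs such as prokaryotes and the
package's fixtures.

For bacterial, archaeal and viral datasets the genetic code is chosen from
the dataset's candidate tables as the one maximising **coding density** —
the fraction of genome positions covered by the union of ORF spans on both
strands — with ties broken by the candidate order. ORF-based density has a
structural property one must reason about: a code whose stop set is a
subset of another's (table 4 drops the TGA stop of table 11) can only
lengthen ORFs, so its density is always at least as high. The decision
therefore rests on the tie-break for TGA-free genomes and on genuine
density differences otherwise. The simulator is built to respect exactly
this: genomes written under a TGA-stop code are generated TGA-free on both
strands (junction-aware codon choice, TAA-only gene stops, scrubbed
intergenic spacers, and no interior methionines whose single codon would
force a TGA across a junction), so candidate codes tie and the ordered
tie-break keeps the generating table; genomes written under table 4 carry
genuine internal TGA tryptophan codons, which truncate ORFs under table 11
and make table 4 strictly denser.

**Two-pass search.** Pass 1 runs at sensitivity 4.5 on ORFs of at least
90 nt. Markers with no hit reaching their full cutoff are re-searched in a
rescue pass at sensitivity 6 on ORFs of at least 45 nt; recovered markers
are never re-searched. The defaults realise the standard two-run tuning;
both dials and the minimum span are configurable via `search_config()`.

## Lineage selection

For inputs of unknown origin, `auto_lineage()` first assesses the input
against each domain-level root dataset and keeps the best (ties: fewer
missing markers, then the fixed order bacteria, archaea, eukaryota,
viruses). It then descends the dataset hierarchy greedily: at each node
every child dataset is assessed, and the walk moves to the best child as
long as its completeness is within 2 percentage points of the current
node's — more specific datasets carry more markers and slightly more
conservative scores, so a small tolerance prevents spurious early stops. A
child in which *every* marker is missing is never entered, whatever the
tie-break says: such a child carries no evidence, and descending on
zero-score ties would walk into arbitrary clades. The walk stops at a leaf
or when no child qualifies.

This score-driven descent is a deliberate functional stand-in for
phylogenetic placement: it honours the same contract (root scoring first,
then the most specific supportable dataset) with a different, fully
self-contained mechanism. On fixtures, an exact clade member reaches its
true leaf dataset in every seeded trial, and a diverged query stops on an
ancestor of the truth, never a sibling clade. The per-root scores double as
a **cross-domain contamination screen**: an off-domain root whose
completeness exceeds a configurable advisory threshold (default 40%) is
flagged. The threshold is heuristic; real data shows a nonzero background
of cross-domain matches, so the flag is advisory, and the package makes no
attempt to adjudicate duplication against contamination — it reports the
evidence.

## The depletion benchmark

`run_benchmark()` re-creates the classic gene-depletion experiment on a
fixture bundle. Protocol A removes a stated fraction of *any* genes and
records score degradation only. Protocol B removes only genes mapped to
markers: the mapping (`map_ground_truth()`, proteins mode at maximum
sensitivity, best complete-quality gene per marker) is frozen before
depletion and used afterwards to count true positives (marker found, gene
still present), false negatives (gene present, marker missed) and false
positives (gene removed, marker still reported), with precision
TP/(TP+FP). Genome-mode runs mask each removed gene's annotated span with
`N`, preserving sequence length. The number of genes removed is
`round(fraction x eligible)` with half-up rounding (the rounding rule is
unstated in the protocol's source and fixed here), sampled without
replacement; one master seed spawns per-(level, replicate) child seeds, so
replicates are independent but the whole report is reproducible.

On a clean rate-0 fixture the reported missing count equals the number of
removed truth genes exactly at every level, in both proteins and genome
mode; at moderate divergence the truth-restricted missing count stays
inside the exact 99% binomial interval around the depletion level. At 100%
depletion of a paralog-free fixture no false positives occur; a planted
exact decoy of a truth gene produces exactly one.

## The simulator

`simulate_lineage()` generates the study conditions end-to-end: ancestor
proteins drawn i.i.d. from a background distribution (start methionine
fixed), evolved along a species tree with per-site substitution probability
`1 - exp(-branch length)` and background-proportional replacement,
reverse-translated with uniformly chosen synonymous codons, and assembled
into one contig per species with genes on random strands between random
intergenic spacers. Every gene is flanked by the palindromic guard
`TTAATTAATTAA`, which contains a stop in all three frames, equals its own
reverse complement, and abuts the gene start so that the extracted ORF
coincides exactly with the annotated gene — a requirement of the
sigma = 0 exact-length classification rule.

The model has no rate heterogeneity, no indels (seed "alignments" are
trivially the equal-length tip proteins) and no codon-usage bias, so
passing tests demonstrate the engine's bookkeeping and decision rules, not
robustness to alignment-gapped, intron-containing or compositionally
skewed real data. Datasets built from fixtures use a held-out split (build
from k-1 species, assess the held-out one) to avoid self-scoring bias.

### Default problem sizes

The shipped tests and the acceptance script use 10–30 markers of 40–80
amino acids for most end-to-end checks, 100 markers for the depletion
benchmark, clade trees with 0.05 within-clade and 0.20 between-clade branch
lengths for lineage selection, and tip divergences of 0.05 ("moderate",
roughly 5% substitution) and 0.15–0.25 ("high"). These sizes exercise every
code path with comfortably non-degenerate statistics.

## Numerical choices and degenerate inputs

* Natural logarithms internally, bits at every interface; Forward uses
  numerically stable log-sum-exp.
* Percentages round half-up to one decimal (`round_half_up()`), matching
  the printed score strings; base `round()`'s half-to-even rule would
  mis-render some of them.
* Unknown residues (`X`, or N-containing codons) score as background
  (log-odds 0) everywhere.
* Empty proteins are a no-hit, not an error; an empty input *file* is an
  error; an empty depleted gene set in the benchmark is, by definition, an
  all-missing assessment.
* Ties: genetic-code selection keeps the earliest candidate; root selection
  uses fewer-missing then domain order; ground-truth mapping keeps the
  best-scoring gene, breaking exact ties by collection order.
* Overlapping hits on the same target merge into one locus when their
  envelopes overlap by at least half the shorter envelope (best score
  kept); distinct targets are always distinct loci. In genome mode, ORFs
  are distinct targets, so a hypothetical above-cutoff hit on the reverse
  frame of a real gene would count as a second locus — not observed on
  fixtures, but worth knowing on real data.

## Known limitations

* No intron-aware eukaryotic gene model; genome mode on spliced genomes
  will undercount.
* The sigma = 0 exact-length band makes completeness (though not
  missingness) conservative under divergence.
* The lineage descent is score-driven, not phylogenetic placement, and the
  40% contamination threshold is advisory.
* E-values, multi-hit alignment and DNA-space profile search are out of
  scope.
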
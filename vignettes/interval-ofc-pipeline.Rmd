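---
title: "Quantifying miRNA expression and calling differential expression with expression intervals and offset fold changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA expression and calling differential expression with expression intervals and offset fold changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Small RNA sequencing of multi-group, multi-replicate experiments — the
motivating case is bumblebee (*Bombus terrestris*) larvae sampled as four
phenotypes (early/late instar crossed with worker/queen developmental
pathway, EW/LW/EQ/LQ) in four biological replicates each — asks a simple
question of noisy data: which mature miRNAs differ in expression between
phenotype groups? `mircaste` implements the complete computational path from
raw FASTQ to that answer, together with a synthetic-data generator that
produces experiments with known truth so every stage is testable without
external downloads.

The libraries this pipeline is built for use *high-definition* (HD)
adapters: the 3' ligation adapter carries four degenerate (random) terminal
nucleotides that reduce ligation sequence bias. A read therefore has the
structure

```
5'  [insert (mature miRNA or other sRNA)] [4 HD bases] [3' adapter ...]  3'
```

truncated to the sequencer read length, and cleaning must remove both the
adapter and the HD signature.

## The pipeline, stage by stage

1. **Preprocess** (`preprocess_library()`): discard reads containing
   ambiguous bases (`N`); locate the leftmost exact occurrence of the first
   `min_overlap = 7` adapter bases that leaves at least `hd_length = 4`
   preceding bases, and cut read at the HD boundary; discard reads without
   an adapter match and inserts shorter than `l_min = 16` nt; collapse
   surviving inserts to unique tags with counts. Every read is accounted
   for: `input = ambiguous + no_adapter + short + accepted`.
2. **Map** (`map_to_genome()`): match each tag to the genome over its full
   length, ungapped, on both strands, with at most `k_genome = 1` mismatch.
   Mapping rates are reported redundantly (count-weighted over reads) and
   non-redundantly (over unique tags).
3. **Quantify** (`assign_to_mirbase()`, `build_matrix()`,
   `normalize_per_total()`): a tag is incident to a mature miRNA if it
   aligns sense-strand, full-length, ungapped *within* the mature sequence
   with at most `k_mirbase = 2` mismatches. Counts are normalized per
   library to a fixed total (`normalization_total = 4e6` by default, or the
   median accepted-read total rounded up to the nearest million with
   `"auto-median"`).
4. **Screen** (`screen_libraries()`): replicate libraries that disagree with
   their phenotype's median expression profile are flagged for exclusion
   (see below), or an explicit exclusion list can be supplied.
5. **Differential expression** (`call_de()`, `run_comparisons()`): the
   interval + OFC caller over a 2x2 comparison design — caste within instar
   (EW vs EQ, LW vs LQ) and instar within caste (EW vs LW, EQ vs LQ).

## The DE model

For one miRNA and one phenotype pair (A, B), let `x_1..x_m` and `y_1..y_n`
be the normalized counts across the included replicate libraries. The
*maximal expression interval* of each phenotype is simply
`[min(x), max(x)]`; replicate consistency is enforced by requiring the two
intervals to be **strictly disjoint** — a single overlapping replicate pair
vetoes the call. The magnitude of change is the **log2 offset fold change**

```
OFC(A, B) = log2( (mean(x) + c) / (mean(y) + c) ),   c = offset = 20
```

The additive offset stabilizes ratios at low counts: a change from 1 to 10
normalized reads is log2(30/21) = 0.5, not log2(10) = 3.3, so vanishingly
expressed miRNAs cannot produce extreme fold changes. A miRNA is called
differentially expressed when all three hold:

* the intervals are strictly disjoint;
* `|OFC| >= 1` (inclusive; a threshold of one OFC doubling);
* the larger phenotype mean reaches the abundance floor of 200 normalized
  reads (inclusive), i.e. 200 reads per 4 million.

No p-values or multiplicity corrections are involved; the method is
threshold-based by construction, and the interval criterion plays the role
of a nonparametric replicate-consistency test.

### Mean-based versus edge-based OFC

Computing OFC "across libraries" is ambiguous: it can be taken on the
phenotype means or, more conservatively, on the *nearest interval edges*
(the smallest ratio any replicate pair exhibits). Both are implemented
(`variant = "mean"` is the default; `"edge"` returns 0 when intervals
overlap). The two agree in direction and on clear calls; edge-based OFC is
systematically smaller. The default is mean-based because the interval
criterion already enforces replicate separation, so penalizing the
magnitude a second time double-counts the replicate spread.

### The library screen

The screen scores each library by the fraction of its phenotype's
floor-reaching miRNAs whose |log2 OFC| against the replicate-median profile
stays below 1; libraries scoring under `score_threshold = 0.8` are flagged.
This is a deliberately simple, testable criterion for "normalization
efficiency"; analyses that have an externally determined exclusion list
(e.g. from an independent QC) can supply it via `exclude`, which then
overrides the scores exactly.

## The matcher

Both mapping steps use one primitive: report *every* position at which a
tag aligns full-length, ungapped, within a Hamming-distance bound `k` of a
reference window. The implementation is seed-and-extend: the tag is split
into `k + 1` contiguous blocks, so any hit with at most `k` mismatches
contains a mismatch-free block whose leading q-gram occurs exactly in a
precomputed reference index; candidates are verified by a full mismatch
count. The contract — output identical to an exhaustive scan — is enforced
in the test suite against an independent brute-force oracle on randomized
instances, and tags too short for the block decomposition fall back to the
exhaustive scan itself. Coordinates are 0-based internally; minus-strand
hits are reported on forward reference coordinates.

Two assignment rules resolve multi-hits: only the minimal-mismatch stratum
per tag is kept (a perfect hit suppresses mismatched ones), and a tag
matching `m` distinct matures contributes `count/m` to each. Tag overhang
beyond the mature ends is disallowed — reads longer than the mature they
came from are not credited to it. The 5p and 3p arms of a duplex are
distinct sequences and are quantified separately by construction.

## The synthetic-data generator

`generate_reference()` builds a random genome (default 50 kb, one contig)
with 60 mature miRNAs of 20-24 nt embedded at recorded positions, one per
equal-width bin. Catalog candidates are resampled if they are within 2
mismatches of an accepted entry (so assignment is unambiguous at the
pipeline's bound) or if they contain an internal adapter-prefix occurrence
that trimming could mistake for the real junction and truncate the insert
below 16 nt — the check models the junction exactly, including completion
of a partial adapter prefix by the degenerate HD bases.

`sim_design()` fixes the experimental conditions. Defaults describe the
motivating study's shape and realistic sequencing behaviour:

| parameter | default | meaning |
|---|---|---|
| `phenotypes`, `replicates_per_phenotype` | EW/LW/EQ/LQ, 4 | 16 libraries |
| `depth` | 500,000 | reads per library (a desk-scale stand-in for multi-million-read libraries) |
| `base_abundance` | `rank^-1.5` | skewed abundance profile; a few miRNAs dominate, as in real libraries |
| `junk_fraction` | 0.25 | random non-genomic 16-30 nt inserts, so mapping rates land near the ~70% seen in practice |
| `error_rate` | 0.005 | per-base substitution probability |
| `dispersion` | 0.2 | sd of the per-replicate natural-log abundance factor (log-normal biological noise) |
| `hd_length`, `read_length` | 4, 50 nt | HD signature and a typical HiSeq sRNA read length |
| `adapter` | 33 nt TruSeq sRNA adapter + downstream primer context | long enough to fill a 50 nt read behind a 16 nt insert |

Spikes (`default_spikes()`) multiply chosen miRNAs' abundance by a linear
fold (default 16) in one phenotype. Spiked miRNAs are drawn from the
lower-abundance stratum of the catalog so the added mass stays a small
fraction of the library: because libraries are compositional (proportions
must sum to one), spiking abundant species would depress every other miRNA
in the spiked phenotype and manufacture spurious apparent changes. The
truth table records the expected fold change after this renormalization,
which is therefore slightly below the nominal spike.

Quality strings are constant: no stage of the pipeline reads quality
values, and no quality-based error profile is simulated. Indels,
ligation-bias mechanisms (the phenomenon HD adapters exist to reduce) and
non-miRNA structured sRNAs (tRFs, rRNA fragments, degradation products with
genomic origin) are deliberately not modeled. Consequences worth keeping in
mind: simulated non-redundant mapping rates are much lower than real ones
(junk reads are unique, miRNA reads collapse onto few tags, while real
libraries contain a broad spectrum of genome-matching non-miRNA tags), and
the miRNA incidence among mapped reads is near 100% instead of the ~25%
typical of real data. Passing tests on synthetic data therefore validate
the *computational contract* of each stage, not the biological composition
of real libraries.

## Numerical and degenerate-input choices

* Adapter matching is exact over the first `min_overlap = 7` adapter bases;
  the leftmost eligible occurrence wins. Reads whose adapter is found but
  whose insert is empty or shorter than 16 nt count as `discarded_short`;
  reads with no eligible occurrence (including occurrences without room for
  the HD signature) are `discarded_no_adapter` and are dropped rather than
  kept untrimmed.
* Normalized counts are never rounded; the abundance floor applies to
  real-valued counts (199.99 fails, 200 passes).
* Interval disjointness is strict (touching intervals overlap); OFC and
  abundance thresholds are inclusive.
* Empty inputs degrade explicitly: mapping statistics on an empty tag set
  are `NA`, an empty expression interval is an error, phenotypes with one
  replicate get `NA` screen scores and a warning, and comparisons with
  fewer than two included libraries per side are skipped with a warning.
* All simulation randomness derives from a single integer seed;
  per-library seeds are deterministic functions of it, and identical
  designs produce byte-identical FASTQ files.

## Problem sizes used by the test suite

The packaged tests exercise the matcher on ~50 randomized instances against
a brute-force oracle (references up to a few kb, tags of 16-28 nt, k in
0..2), a noiseless 16-library experiment at 100,000 reads per library
(raw-count recovery must be exact and mapping 100%), and the default spiked
experiment at 500,000 reads per library (all six 16-fold spikes must be
called DE with at most one false call). These sizes were chosen as the
smallest at which each property is meaningfully stressed — multinomial
sampling error at the spiked depth is far below the spike magnitude, so
recovery failures would indicate logic errors, not noise.

## Known limitations

* The interval criterion's stringency grows with replicate number; it is
  calibrated for the 3-4 replicates per group it was designed around and
  will become very conservative for many replicates.
* Mean-based OFC on two phenotypes does not model within-group variance
  beyond the interval veto; borderline calls near `|OFC| = 1` are sensitive
  to the offset.
* The matcher is exhaustive within its bound and intended for small
  references (genomes of tens of kilobases in the synthetic setting,
  mature-miRNA catalogs generally); mapping full insect genomes is better
  served by dedicated aligners, after which the quantification and DE
  stages apply unchanged.
* The screen is a replicate-consistency heuristic, not a reimplementation
  of any particular published QC; the `exclude` override exists precisely
  so an external QC decision can be reproduced exactly.
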
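---
title: "Discovering NAT pairs and phased nat-siRNAs from de novo transcriptomes"
author: "natphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering NAT pairs and phased nat-siRNAs from de novo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Natural antisense transcripts (NATs) are pairs of endogenous transcripts with
long complementary regions that can anneal in vivo. In organisms with an
annotated genome, a NAT pair can be classified as *cis* (two overlapping loci
on opposite strands, perfectly annealed) or *trans* (distant loci, annealing
with mismatches). Many species of interest have no usable reference genome,
so `natphase` works directly on de novo assembled transcripts: complementarity
is detected by sequence alignment, annealing is confirmed at the
duplex-structure level, and — because the annealed double-stranded regions are
substrates of Dicer-like (DCL) processing — the perfectly annealed stretches
are searched for phase-distributed nat-siRNAs whose duplexes carry the
characteristic 2-nt 3′ overhangs. Degradome (PARE) 5′-end tags, which capture
uncapped processing intermediates, can then corroborate individual phased
siRNAs.

```{r, eval = FALSE}
library(natphase)
fx <- make_fixture(fixture_spec(seed = 1))        # synthetic demo inputs
run <- run_pipeline(run_config(
  transcripts = fx$transcripts,
  srna = fx$srna, degradome = fx$degradome))
run$summary
```

## Stage 1: antisense search

Every unordered transcript pair (A, B) is searched for local alignments of A
against the reverse complement of B, by seed-and-extend: exact `seed_len`-mer
matches (default 12 nt) are grouped by diagonal (within `band = 20`) and each
group is extended by a Smith–Waterman alignment with affine gaps restricted to
a window (`window_pad = 50` nt) around the group. Scoring defaults
(+1 match, −2 mismatch, −5 gap open, −2 gap extend, `min_score = 60`)
approximate blastn-like behaviour; all are exposed in `aligner_params()`. The
suite verifies on planted pairs that the windowed search equals a full
unseeded Smith–Waterman whenever a seed exists inside the optimum, which is
the regime the seed length is chosen for.

Each reported region is classified (`classify_params()`):

* **HC** (high coverage) — the complementary span is *strictly longer than
  50%* of at least one transcript of the pair (`hc_fraction = 0.5`,
  `hc_mode = "any_transcript"`). The coverage sentence is ambiguous between
  "either" and "both" transcripts; we read it as at-least-one and provide
  `both_transcripts` as an option.
* **100-nt** — the *consecutive* complementary region is 100 nt or longer
  (inclusive boundary). "Consecutive" is interpreted as the longest gap-free
  aligned block, mismatches allowed, because trans-NAT annealed regions
  usually contain mismatches; `nt100_perfect = TRUE` switches to the longest
  mismatch-free block.

Pairs in neither class are dropped.

## Stage 2: duplex-structure validation

Each surviving region (padded by `pad = 10` nt) is re-examined with an
inter-molecular duplex alignment that maximizes
`pairs − λ · unpaired_columns` (`λ = 1`), where a column is either a
Watson–Crick or G·U pair (G·U on by default; `gu = FALSE` disables wobble) or
part of a *bubble*; there is no mismatch column, so a mismatched opposition
costs a 1+1 bubble. This base-pair-maximization objective is a deliberate
design choice: the structure stage is used to confirm annealing and locate
bubbles and perfectly annealed segments, not to estimate folding free
energies, and a combinatorial objective is exactly testable against
exhaustive enumeration (which the test suite does on toy duplexes). Users
with external thermodynamic predictions can import them through
`parse_rnaplex_line()`.

Two retention criteria follow (`duplex_params()`):

1. the structure-predicted annealed region must overlap the
   alignment-predicted complementary region at **80% or more** on both
   transcripts (`overlap_min`, denominator = structure-predicted region);
2. every bubble must be **no larger than 10%** of the annealed region
   (`bubble_max_frac`); bubble size is the larger of the two strand gaps, and
   the denominator is the region length on strand A (the strands differ only
   by bubble asymmetry; `bubble_denominator = "max_strand"` is available).

A retained pair whose duplex is a *single perfectly annealed region* (one
maximal segment, no bubbles, and only one validated region between the two
transcripts) is flagged as a **cis-NAT candidate** — the best available proxy
without genomic coordinates.

## Stage 3: phased nat-siRNA detection

Perfectly annealed segments **longer than 80 bp** (`min_region_len = 81`; the
boundary is strict, an 80-bp segment is skipped) are searched. Collapsed sRNA
reads are mapped strand-specifically and only perfect full-length matches are
kept; multi-mapped reads count at every locus. A read matching a transcript's
reverse complement is not a hit there — in a NAT pair it is a sense-strand
substring of the partner transcript, where the mapper finds it.

DCL processing of a double-stranded region releases consecutive sRNA duplexes
with 2-nt 3′ overhangs, so for a fixed sRNA length *n* (each length in
`srna_len_set = {21, 24}` is searched independently — mixed-length clusters
are not merged) the sense-strand 5′ ends of successive duplexes differ by
exactly *n*, and the antisense partner of the sense slot `[i, i + n − 1]`
occupies sense-coordinates `[i − 2, i + n − 3]`. For each phase register
`r ∈ [0, n)` the segment is tiled into slots; a slot is *evidenced* when a
mapped read's 5′ end coincides with the slot 5′ end on **either** strand
(sequencing depth rarely covers both strands of every duplex; an
`evidence_mode = "both"` flag provides the stricter rule). Evidence is the
union over the selected libraries, with per-library presence retained for
reporting. Every maximal run of at least `min_duplexes = 4` consecutive
evidenced slots is reported as a phased cluster.

Edge handling: the sense footprint must lie fully inside the perfect segment;
the antisense partner's 2-nt overhang must also stay inside it by default
(`allow_edge_overhang = TRUE` lets it protrude up to 2 nt). Slots whose
partner interval exits the segment can still be evidenced on the sense
strand.

## Stage 4: degradome evidence

Degradome tags are mapped perfectly and strand-specifically onto the
transcripts that carry clusters. A tag supports a phased siRNA when its
5′ end equals the siRNA's 5′ end on that strand, and supports a cluster
terminus when it sits on the nucleotide immediately 3′ of the last phased
siRNA of a strand (3′ end + 1; both strands are searched). Matching is exact
by default; `degradome_window` admits a ±1 tolerance. Because most degradome
libraries are built from poly(A)-tailed RNA, absence of evidence on
non-Pol II transcripts is not informative; the report carries this caveat as
a footnote rather than a computation.

## The synthetic-data generator

`make_fixture()` builds deterministic inputs with exact ground truth: one
planted NAT pair whose complementary core can carry mismatches and a
one-sided bubble, seed-free decoy transcripts, phased reads cut from the two
strands with exact 2-nt 3′ overhang geometry, and degradome tags at chosen
slot 5′ ends and at terminus + 1. Construction choices that make truth exact:

* defect bases are chosen so they cannot pair (including G·U) with any
  neighbouring column, and four non-pairing guard columns flank the planted
  region, so the optimal alignment and structure are unique;
* flanks and decoys are rejection-sampled until they share no 12-mer with the
  reverse complement of any other sequence, so expected hit counts are exact
  (zero off-target matches);
* a single integer seed drives all randomness, and generation never perturbs
  the caller's RNG state.

Default fixture conditions mirror the illustrative four-duplex layout: a
120-bp perfect region, four 21-nt duplexes at register 2 with both strands
evidenced (8 sRNAs), one sRNA library at 10 counts per read, one degradome
library tagging slot 1 and the terminus. What the generator deliberately does
*not* emulate: realistic expression dispersion, sequencing errors, partial
adapter artefacts, repeat-induced multi-mapping, or transcriptome-scale pair
counts — passing tests demonstrate correctness of the detection geometry and
thresholds, not performance on noisy full-scale data.

## Numerical and procedural choices

* All external coordinates are 1-based inclusive on the forward strand of
  each transcript; collapsed-read headers use the `>{id}_x{count}`
  convention; U is folded to T on input, and N never matches or pairs.
* Alignment tie-breaking is deterministic (first optimum in scan order,
  diagonal preferred in traceback), and all outputs are canonically ordered,
  so identical inputs yield byte-identical reports.
* Overlapping, near-duplicate alignment regions between the same pair are
  collapsed to the highest-scoring one; distinct regions are kept separately.
* Degenerate inputs (no seeds, empty windows, segments shorter than `n + 2`,
  missing libraries) return empty results rather than errors; configuration
  errors are aggregated and raised before any stage runs.
* Test problem sizes — oracle comparisons on pairs ≤ 500 nt, duplex toys
  ≤ 40 nt, 50-fixture closure — were chosen so the full suite completes in
  well under a minute while still covering every boundary.

## Known limitations

* No thermodynamic scoring: a structurally plausible duplex with very low
  pairing energy is treated the same as a stable one; RNAplex output can be
  imported when energies matter.
* Without a genome, cis/trans assignment is heuristic; a "cis-NAT candidate"
  is a hypothesis, not a classification.
* No phasing significance statistic is computed (the detection criterion is
  combinatorial); miRNA loci are not excluded and may appear among mapped
  sRNAs.
* The pairwise antisense search is quadratic in the number of transcripts;
  transcriptome-scale runs should pre-filter or shard the input.
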
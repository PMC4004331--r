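---
title: "Methods: CRISPR cassettes and spacer-protospacer statistics in gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR cassettes and spacer-protospacer statistics in gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

CRISPR cassettes are arrays of short conserved direct repeats (roughly 24-48
nt) alternating with unique spacers (25-70 nt) acquired from phages and
plasmids. New spacers are added at the leader end of a cassette, so spacer
order within an array is a chronological record: spacers still matching a
replicon present in the same community ("targeting" spacers) should sit near
the leader, while spacers shared between individuals (hence older) should
drift toward the trailer. `gutcrispr` implements the full contig-level
workflow that turns assembled metagenomic contigs plus external CRISPR array
predictions into those statements, with permutation inference at every step:

1. **Candidate construction and consensus filtering.** Per-program array
   predictions on a contig are merged when their spans reciprocally overlap
   by at least 50% (single linkage). Candidates are accepted by three rules
   applied in priority order: (1) predicted by all three detector programs;
   (2) predicted by one or two programs but lying within the cas-gene
   adjacency window; (3) carrying a repeat consensus that clusters with the
   repeat of an already-accepted cassette, iterated to a fixed point. Every
   accepted cassette records exactly one rule.
2. **Repeat analysis.** Repeat consensi are majority votes over the
   modal-length copies (ties broken alphabetically). Clustering emulates the
   classic BLASTCLUST setting for nucleotide mode: an exact shared 15-mer on
   either strand seeds an ungapped extension under +1/-2 scoring, and two
   repeats are linked when the maximal-scoring segment reaches 50% identity
   while covering 50% of the longer sequence; clusters are connected
   components. Cassettes are oriented by adjacent cas genes (leader = the
   end nearer the cas locus) and orientation propagates through repeat
   clusters by strand, leaving conflicts unresolved rather than guessing.
3. **Protospacer discovery.** The default matcher is an exhaustive
   both-strand sliding-window Hamming comparison at full spacer length with
   a 4-mismatch reliability threshold. Word-based aligners truncate
   alignments whose mismatches fall within one word of an end, so externally
   produced BLAST hits are ingested and extended to full spacer length with
   the mismatch count recomputed; gapped hits are rejected because the
   threshold is an ungapped notion. A hit is discarded when the repeat of
   the spacer's own cassette also matches the target contig (an undetected
   array, not a protospacer). `N` never counts as a match on either side.
4. **Randomized control.** Each spacer is replaced by a same-length fragment
   drawn uniformly from the cassette-free part of its own contig; when both
   non-cassette flanks are shorter than 100 nt the fragment comes from a
   cassette-free contig of the same individual. Pseudospacer hits whose
   repeat-length flanks also match the target are discarded, removing
   gene-homology artifacts.
5. **Statistics.** Three permutation analyses: the leader-position test
   (sums of flagged-spacer serials, within-cassette shuffles), the
   cassette-shuffle sharing test (distinct canonical spacer sequences seen
   in two or more individuals, cassettes relabeled across individuals with
   per-individual counts preserved), and the Cochran-Mantel-Haenszel
   statistic over per-individual 2x2 tables of spacer-protospacer pairs with
   a protospacer-shuffle null.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_mismatches` | 4 | full-length Hamming threshold defining a reliable protospacer |
| `adjacency_window` | 2,000 nt | cas gene to cassette distance for rules 2 and orientation |
| `min_flank` | 100 nt | non-cassette flank required on both sides for a "complete" cassette |
| `min_reciprocal` | 0.5 | reciprocal span overlap for cross-program merging |
| `min_identity`, `min_coverage`, `word_size` | 0.5, 0.5, 15 | repeat-cluster link test |
| flank width | 10 nt | PAM search windows on both protospacer sides |
| contamination budget | `ceiling(0.15 * query length)` | mismatch allowance for repeat/flank contamination scans |
| `n_perm` | 100,000 / 10,000 | position & sharing tests / CMH shuffle |

Values with a published basis keep it: the 4-mismatch threshold, spacer
lengths 25-70 nt, the 100-nt flank rule, the 10-nt PAM windows, the
BLASTCLUST-style `-L 0.5 -S 50 -W 15` semantics and the permutation counts
are all stated study conditions. Where the source procedure names no number
the package picks one and exposes it: the 2,000-nt cas adjacency window
(typical cas loci sit directly beside their arrays; "adjacent" is otherwise
undefined), the 50% reciprocal-overlap merge rule (the conservative standard
for calling two interval predictions the same object), and the 15%
contamination budget (mirroring the 4-of-27 ratio of the spacer threshold).

# Design choices in genuinely open spots

* **Leader-side evidence.** "Proper orientation" of a cas gene is read
  weakly: the leader is the cassette end nearer the cas locus, regardless of
  cas strand. `strict = TRUE` additionally requires transcription toward the
  cassette. The weak reading orients more cassettes and never contradicts
  the strict one on the synthetic data.
* **Strand-insensitive spacer identity.** Uniqueness, sharing and the
  sharing-test statistic use the canonical sequence
  (`min(seq, revcomp(seq))`), because cassette strand is often unknown.
  A strand-sensitive count would treat a cassette and its reverse-complement
  twin as disjoint.
* **p-value convention.** Permutation p-values are plain fractions `k/n`,
  which is what makes `p < 1e-5` reportable at 100,000 permutations; the
  `(k+1)/(n+1)` value is carried alongside (`p_value_add1`) for users who
  prefer the add-one estimator.
* **CMH continuity correction.** Both modes are implemented
  (`correct = FALSE` default); the closed form is cross-checked against
  `stats::mantelhaen.test` in the tests rather than delegated to it, since
  the permutation null re-evaluates the statistic thousands of times via a
  reduced form (only the within-individual pair count varies under the
  protospacer shuffle; all stratum margins are invariant).
* **Word-size gate.** The repeat-link matcher requires an exact shared
  15-mer before extending, as the emulated clustering tool does. A mutated
  repeat pair whose mismatches break every 15-mer run can therefore stay
  unlinked although an unseeded aligner would link it. The test suite
  stratifies its oracle comparison accordingly: full equality where a seed
  word exists, soundness (every seeded link confirmed by the unseeded
  oracle) where none does.
* **Rejected BLAST rows.** Gapped raw hits and hits whose full-length
  extension would cross a contig end are rejected outright; a full-length
  ungapped mismatch count is not defined for either.

# The synthetic community generator

`generate_community()` emulates the data assumptions of the analysis:
multi-individual contig sets with embedded repeat-spacer arrays (exact
repeat copies by default), cas genes planted within 500 nt of the leader end
for a configurable fraction of cassettes, phage contigs (never carrying
cassettes) holding planted protospacers at controlled Hamming distance 0-6,
cross-individual spacer sharing at a configurable rate, and leader-proximal
placement of targeting spacers with probability proportional to
`exp(-leader_bias * serial)`. Background sequence is i.i.d. uniform ACGT, so
chance full-length matches at spacer length >= 25 nt are vanishingly rare
and every reliable hit on synthetic data is attributable to the manifest.
`emit_detector_predictions()` simulates per-program detection with
false-negative rates and boundary jitter, plus decoy reports for planted
tandem-repeat and low-complexity regions (the classic false positives of
k-mer detectors, reported preferentially by the CRT- and PILER-like
simulated programs).

What the generator does **not** emulate: real phage genome architecture, GC
content and compositional bias, within-array repeat divergence (available as
an option but off by default), assembly fragmentation and chimerism, and
read-level errors. Passing tests therefore demonstrate correctness of the
pipeline's logic under clean conditions, not robustness to the full noise
spectrum of real assemblies.

# Numerical and degenerate-input conventions

All interval arithmetic is 0-based half-open internally; GFF3, BLAST
tabular and the prediction/cas TSVs convert at the I/O boundary. Repeat
consensus ties break alphabetically; candidate merging breaks ties by most
repeat copies, then span length, then leftmost start. Zero-spacer
(repeat-only) arrays are excluded with a warning. A pseudospacer flank
truncated by a contig end is used when at least half the repeat length
remains and treated as non-matching otherwise. Matches hanging over a
target end are never counted: a protospacer must fit the full spacer
length. Degenerate CMH strata contribute nothing to either sum, and a test
with no eligible cassette fails loudly naming the filter responsible.

# Problem sizes used by the checks

The bundled verification (tests and `scripts/acceptance.R`) exercises the
pipeline at sizes a laptop handles in minutes, chosen as the smallest
configurations at which the statistical properties are identifiable:
recovery and filter-semantics runs use 5 individuals x 4 contigs (4-8 kb)
with 10 cassettes, 5 phage contigs and 30 planted protospacers; the
position-test power check uses 100 replicate communities with 60 planted
events at `leader_bias = 0.5`; the size (type-I) check uses 1,000 unbiased
replicates with 1,000-permutation tests; oracle-equivalence checks run 500
randomized instances per matcher. Every reported quantity is recomputed at
run time from these simulations.

# Known limitations

* The three external detectors are ingested, not run; the built-in k-mer
  chain detector exists so synthetic end-to-end runs need no external tools
  and is deliberately simple (exact seeds, unanimous extension). On highly
  diverged repeats it under-calls; use real detector output there.
* Repeat-cluster links require an exact 15-mer; highly diverged repeat
  families fragment into several clusters, which weakens rule 3 and cluster
  orientation propagation (both degrade safely: fewer acceptances, more
  `unknown` orientations).
* Taxonomy labeling formalizes stated criteria that were originally applied
  with manual judgment; edge cases near the majority boundary may differ
  from a curator's call.
* The pair-matrix analyses (CMH, majority-foreign counts) need the
  published per-individual pair matrix to reproduce the published values;
  the package ships the readers and the statistics but not that
  supplementary table.
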
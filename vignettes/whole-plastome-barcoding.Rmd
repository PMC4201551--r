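---
title: "Whole-plastome barcoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plastome barcoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Shotgun sequencing of total plant DNA yields enough chloroplast-derived
reads to reconstruct the whole plastome, which can then serve as a
species/genotype barcode. Two practical routes exist: **reference mapping**
(map reads to a close reference, extract a majority-vote consensus) and
**de novo assembly** (assemble contigs, scaffold them against the
reference, join them). Different sequencing platforms err differently —
short paired reads err mostly by substitutions at a low rate, while
semiconductor single reads err at roughly an order of magnitude higher
rate, dominated by insertions/deletions in homopolymer runs — so the two
routes and two platforms disagree at a handful of sites, almost all of
them homopolymer indels. `cpbarcode` implements the whole analysis:
simulation of both platforms' reads over a plastome-like truth genome,
trimming, mapping-consensus, de novo consensus, variant classification,
homopolymer-bias profiling, and an explicit evidence-based reconciliation
of cross-platform discrepancies into an amended barcode validated by
remapping.

Everything below documents the models, the defaults and why they were
chosen, and what the synthetic data does and does not emulate.

# The synthetic plastome and truth variants

`generate_plastome()` draws bases i.i.d. at a target GC of 0.39 (the
AT-rich plastome regime), implants a homopolymer spectrum admitting runs
up to 17 bases (longer runs mostly A/T, as in real plastomes), and lays
the genome out as `LSC | IR | SSC | revcomp(IR)` — the quadripartite
structure whose two identical inverted repeats (IRs) cause multi-mapping
and assembly branching. Defaults are 130 kb with 20 kb IRs; tests and the
acceptance script use 10–40 kb genomes with proportionally smaller IRs so
each run finishes in seconds to a couple of minutes on one CPU — the
algorithms are the same at full scale.

`implant_variants()` defaults to a 128-variant load shaped like a
wild-vs-cultivated rice chloroplast comparison: 92 SNPs, 5 MNVs, 13
insertions, 18 deletions, with 80% of indels placed inside homopolymer
runs of length 2–9. Events are kept ≥ 12 bp apart so that extraction
never merges two truth events, and are left-normalized so the truth table
is directly comparable with extracted variants. By default variants avoid
the annotated IRs: real plastomes homogenize their IR copies, so a variant
confined to one copy would be atypical — and it would also be ambiguous
under any assembler, since repeat copies collapse in the assembly graph.

# Platform error models

`simulate_reads()` separates three error processes:

* **substitutions** — per-base Bernoulli (`0.001` for the short-read
  preset, `0.002` for the semiconductor preset);
* **baseline homopolymer indels** — per-read, per-run Bernoulli with a
  rate depending on base class (A/T vs G/C) and run length, one event max
  per run per read. The semiconductor deletion rates peak at 3-bp G/C runs
  (0.06 per read per run) and fall off outside 2–5 bp; insertion rates
  ramp up with A/T run length from 5 bp (0.02) to 17 bp (0.09);
* **systematic runs** — a small fraction of genome runs (0.5% of 2–5 bp
  G/C runs for deletions, 0.8% of ≥5 bp A/T runs for insertions) are
  drawn once per simulation as *systematically* miscalled, with a per-read
  error rate of 0.85. This is the component that produces consensus-level
  indel errors: a run miscalled in most reads defeats majority voting, in
  the same way the real platform's homopolymer signal saturation does. A
  run miscalled in only a few percent of reads never does.

The split matters: published error *rates* are averages, but the
consensus-level error counts reported for whole-plastome studies (tens of
indel positions per ~134 kb) can only arise from site-specific systematic
error, so the simulator models both components explicitly. Rates were
calibrated once so that the semiconductor preset lands near 1% total error
with indels dominating substitutions, deletions concentrated in short G/C
runs and insertions in long A/T runs, and a realistic handful of
systematic sites per 30 kb; they are fixed defaults, not fitted
quantities. Claimed base qualities are drawn independently of the error
truth (mean PHRED 30.5/25.5 for the two presets) because quality trimming
operates on claimed, not actual, reliability.

Not emulated: flowgram/signal-level effects, PCR duplicates, GC-coverage
bias, chimeric reads, adapter read-through, and organelle/nuclear mixture
(reads of nuclear-plastid paralogs). Consequently a passing test suite
shows the *pipeline logic* is correct under realistic error structure; it
does not certify performance on real libraries, where mapping ambiguity
from nuclear paralogs (emulated here only via the mapping-ambiguity
statistic) is an additional error source.

# Trimming

`trim_params()` implements two modes. The default is Mott-style trimming
on claimed error probabilities: keep the contiguous interval maximizing
`sum(limit - p_i)`. The operative parameter is the probability `limit`
itself — 0.05 for the semiconductor preset, 0.01 for short reads — with a
30 bp minimum length; ties in the maximization break leftmost, then
longest, fixed so results are reproducible. `N` bases are assigned
`p = 1`, which naturally trims terminal `N` runs; reads still containing
`N` afterwards are dropped. The alternative sliding-window mode truncates
at the first 20 bp window whose mean claimed PHRED falls below 17, with a
20 bp minimum length. When one mate of a pair is dropped the survivor is
retained as a single read.

# Mapping and the majority-vote consensus

`map_reads()` is a seed-and-extend mapper with an explicit cost model:
mismatch 2, insertion 3, deletion 3 per base, global on the read (no soft
clipping), local on the reference. Seeds are exact 15-mers at stride 7;
candidate diagonals are clustered with a ±16 band and each candidate
window is solved exactly by dynamic programming, so within its window the
placement cost is optimal (tests compare against an independent
full-matrix oracle). Acceptance applies *after* optimization: ≥ 0.9 of
the read aligned (always true under global-on-read) and ≥ 0.9 identity
over aligned columns. Equal-best placements — the IR situation — are
reported as multimapped and placed uniformly at random under a seed (or
discarded). Pairing does not constrain placement; insert statistics are
observational.

`call_consensus()` votes by read count, not quality: at each reference
position the plurality of {A, C, G, T, deletion} wins, a majority deletion
removes the position, and an insertion is emitted when more
junction-spanning reads support one identical inserted string than support
no insertion or any other string (reads only partially overlapping the
anchor do not vote). Voting ties go to the reference allele — a
conservative, logged choice. Zero-coverage positions emit the reference
base with a flag rather than `N`, so consensus length obeys
`L - majority_deletions + inserted_bases` exactly; this identity is
asserted on every run in the test suite.

# Assembly, scaffolding and joining

`assemble()` is a de Bruijn unitig assembler over both strands: k-mers
below a multiplicity floor of 2 are dropped (singleton error k-mers),
branch alternatives dominated 4:1 in coverage are pruned (recurring-error
branches; a *systematic* error branch dominates and survives, which the
reconciliation stage relies on), short dead-end tips (< 2k bases) are
clipped, simple bubbles up to 50 bp are popped by coverage (toward the
reference allele in reference-guided mode), and maximal unbranched paths
become contigs, filtered at 200 bp. The automatic word size is
`round(log4(total input bases))` clipped to [15, 31] and forced odd; the
pipeline default pins `k = 21` for plastome-scale inputs because random
15-mer collisions in 100+ kb genomes needlessly fragment the graph, and
because adjacent unitigs then share k−1 = 20 bases, exactly the minimum
overlap the joiner requires.

`polish_contigs()` maps reads back to the contigs with the same cost model
and replaces each contig by its majority consensus (≤ 3 rounds or
convergence). `align_contigs()` places contigs on the reference by unique
20-mer anchors (up to 4 reference occurrences, so both IR copies are
found), refines each diagonal cluster with an anchored global alignment,
and clips each placement to its well-matching core — an IR-spanning
contig carries flanking sequence foreign to the other copy, which must not
be tiled there. Placements under 80% identity are discarded as spurious.

`join_contigs()` automates the manual step of scaffold joining with the
explicit rule: rank placements by (aligned length, identity, query
coverage) descending, greedily tile the reference, merge adjacent tiles
overlapping ≥ 20 bp at ≥ 95% agreement, and fail with a conflict error
naming the interval otherwise. Any uncovered internal interval aborts
joining with a gap report — short low-depth reads reproduce exactly this
outcome — while uncovered stretches of ≤ 150 bp at the genome ends are
treated as coverage erosion (the de novo consensus simply starts late or
ends early), not as gaps.

# Variants

`align_consensus()` aligns consensus to reference globally with unit
mismatch and affine gaps (open 2, extend 1), via unique-20-mer anchor
decomposition with exact dynamic programming between anchors (equal to a
full affine DP oracle in tests). `extract_variants()` merges only directly
adjacent substituted columns into MNVs (a single matching base keeps two
SNPs separate — the minimal, testable grouping rule), turns maximal gap
runs into single indels, and left-normalizes indels so both platforms
report a repeat indel at the same coordinate. Transitions are exactly
A↔G and C↔T. Homopolymer context is the maximal run containing a
deleted base, the maximal run of the inserted base touching the anchor, or
the run containing a substituted position; `summarize_bias()` deduplicates
indels by (position, type, alleles) before tallying by indel type, run
length and base class.

# Reconciliation

`diff_variant_sets()` matches variants by left-normalized *site* (point
position or insertion anchor) rather than by (site, type): a SNP in one
platform against a deletion in the other at the same position is one
conflicting record, which is how such sites are reported in practice.
`gather_evidence()` collects, per discrepancy: the allele implied by each
de novo contig source at the site (reference allele when covered but
variant-free, absent when uncovered), the homopolymer context, and a
mapping-ambiguity flag codifying what would otherwise be visual inspection
— a site is ambiguous when, within ±25 bp, more than 20% of covering
reads carry ≥ 3 mismatches or were randomly placed multimappers. This
statistic also stands in for a BLAST-based nuclear-paralog check: both
detect reads that align but do not belong.

`resolve_discrepancies()` applies five rules in a fixed order (the order
is a design choice; the underlying logic is applied narratively in
practice): R1 mapping artifact (contigs all reference + ambiguity →
reference), R2 contig-supported variant (all sources agree on one
non-reference allele → adopt it; this is what rescues long insertions
that read mapping mis-places), R3 homopolymer read error (single-platform
indel in a ≥ 2 bp run with reference-agreeing contigs → reference), R4
long-homopolymer ambiguity (≥ 8 bp run, contigs disagreeing →
unresolved), R5 default (contigs agree with exactly one platform → adopt
it; otherwise unresolved). Unresolved sites conservatively keep the
reference allele and are flagged `uncertain`. Any resolution other than
unresolved requires at least one covering contig source.

`amend_consensus()` applies the shared variants plus resolved
non-reference alleles right-to-left, and `validate_by_remap()` maps reads
back to the amended sequence and reports any site where a fresh
majority-vote consensus still disagrees — on clean synthetic data the
residual list is empty or confined to unresolved long-homopolymer sites.

# Numerical and degenerate-input choices

* Alignment tie-breaks: the mapper prefers match over insertion over
  deletion during traceback and the smallest reference end among equal
  costs; Mott ties are leftmost-then-longest; consensus voting ties go to
  the reference allele. All fixed so reruns are bit-identical.
* Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from one global seed and the stage
  name. Two runs with the same configuration produce identical files
  (hash-compared in the tests).
* Empty inputs (no reads, empty variant tables, empty FASTQ) are legal
  and produce empty, typed results; dropping a read in trimming is a
  counted outcome, not an error.
* `map_read` refuses reads shorter than the seed k (15) with a
  `too_short` status rather than guessing.
* The consensus-to-reference aligner refuses inputs whose lengths differ
  by more than 20% — a cheap guard against passing the wrong sequence.

# Known limitations

* The assembler resolves *systematic*-error branches toward the error
  (they dominate coverage), so a platform's own contigs corroborate its
  systematic errors; reconciliation then relies on the other platform's
  contigs, and such sites resolve as unresolved-reference rather than by
  positive evidence. With more than ~50% of reads wrong at a site, no
  read-count-based method can do better without cross-platform evidence.
* Reads are sampled from a linear genome; the circularity flag is
  reserved but unused, so junction-spanning reads of a circular plastome
  are not simulated and terminal coverage erodes (visible as the
  end-tolerance rule in joining).
* Quality strings are independent of the error truth, so quality-aware
  consensus weighting would show no benefit on these simulations; the
  consensus deliberately votes by read count only.
* The homopolymer census and GC checks against the real rice chloroplast
  reference require that sequence to be supplied locally (it is too large
  to bundle); all other tests are download-free.
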
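---
title: "Haplotype-resolved STR pileups: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved STR pileups: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpileup)
```

## The problem

Short tandem repeats are genotyped from short-read data by specialised
callers that realign reads to a sequence-graph model of the locus and
report per-STR allele sizes. Those calls are fallible in characteristic
ways — an allele supported by a single spanning read, an expansion
supported only by poorly aligning reads, a locus whose two alleles cannot
be distinguished — and the natural diagnostic is a *haplotype-resolved*
pileup: reconstruct the two locus haplotypes implied by the genotype,
assign each read pair to one haplotype and one position, and draw the
result. `strpileup` implements that reconstruction, the assignment, the
drawing, quality metrics, and a consensus caller for repeat interruptions,
plus a paired-end simulator so the whole pipeline is testable
self-contained.

## Model and procedure

A locus is an ordered alternation of constant segments and STR segments,
beginning and ending with constant flanks. Given one allele size per STR
per chromosome, a haplotype is realised by concatenating flanks, spacers
and `unit^count` expansions; its `segment_map` records where each segment
landed. All coordinates are 0-based half-open (the BAM-native convention;
VCF positions are converted on ingest).

**Pair enumeration.** With $k$ heterozygous STRs there are $2^{k-1}$
distinct unordered pairings for $k \ge 1$, one otherwise. Homozygous STRs
contribute a single allele (no phantom pairings), pairs are canonicalised
with the lexicographically smaller sequence first, and enumeration operates
on sizes only — interruption structures are applied when building simulation
truth or annotating, never during enumeration, because upstream genotypes
are sizes. A cap (default 64 pairings) guards pathological catalogs; real
loci carry at most a few STRs.

**Alignment.** Reads are aligned to candidate haplotypes either by
projecting their graph-alignment tag onto the haplotype's segment map
(when tags are present) or de novo with an affine-gap aligner
(Gotoh local alignment with free read-end soft clips; C++ via Rcpp). The
aligner returns *every* placement tied at the maximum score. This is the
load-bearing primitive: a read wholly inside a pure repeat of $U$ units has
$U-u+1$ equivalent placements, and downstream stages need the whole set.
The default scoring scheme is match $+5$, mismatch $-4$, gap open $-8$,
gap extend $-2$ — a conventional bwa-like parameterisation, exposed in
`scoring_scheme()` so tests can pin it; `N` scores as a universal mismatch.
Soft clips score zero so reads running off a haplotype remain comparable.

**Pair selection.** Each candidate pair is scored
$\sum_r \max(S(r,H_1), S(r,H_2))$ and the argmax selected; single-candidate
loci skip scoring entirely. We use the per-read maximum rather than a
per-fragment joint score: it matches the plain reading of a "cumulative
read alignment score", and fragment-level information re-enters at the
next stage anyway. Ties are broken canonically and reported.

**Fragment assignment.** The fragment-length distribution is estimated
from read pairs whose mates both have a unique placement lying wholly in
constant segments — uniqueness is judged *per haplotype*, since a flank
read legitimately places once on each haplotype of a diploid pair. Below
`min_flank_pairs` (10) qualifying pairs the estimator falls back, loudly,
to a configured default (450 ± 100 bp). Joint placements are the per-
haplotype Cartesian product of the mates' placements, restricted to proper
forward–reverse orientation and to fragment lengths at most 4 standard
deviations above the mean; the distance metric is the absolute deviation
from the mean (the literal "closest to the mean" rule, not a z-score).
Minimal-distance candidates are pooled **across** both haplotypes before
the random draw — this realises the ambiguity class of reads that fit both
haplotypes equally well, which are flagged and rendered faint. Each placed
read also records how its haplotype was decided (`score`, `fragment` or
`random`) and how many tied placements it had on that haplotype; the
consensus caller uses both.

**Randomness.** One RNG stream per locus, seeded from the `seed` argument
(CLI `--seed`, default 42), consumed in sorted-fragment-id order, so a
fixed input and seed give byte-identical SVGs and metrics.

## Pileup metrics and flags

Per allele and STR: spanning / flanking / in-repeat read counts
(classification needs `min_anchor` = 5 bp aligned in each flank for a
spanning call, so 1 bp overlaps don't count as spanning); repeat-region
and flank mean depth; a depth-evenness score (coefficient of variation
over the haplotype interior, trimming one read length at each end where
coverage ramps are geometry, not signal); and an in-repeat indel rate
(insertion+deletion events per aligned kb inside repeats). Three flags
mirror the visual low-confidence heuristics, with explicitly qualitative
thresholds exposed as arguments: `short_allele_weak` (shorter allele has
≤ 1 spanning read), `expansion_weak` (repeat depth < 0.3 × flank depth),
`noisy_repeat` (indel rate > 20/kb). The flank/spanning read ratio is
exported raw, without a flag, because no principled cutoff exists. No
normal/premutation/full-mutation verdicts are attempted — thresholds are
gene-specific and belong to the analyst.

## Consensus interruption calling

For each repeat-unit column, covering reads vote with the unit-length word
they carry; a non-canonical motif (e.g. AGG inside a CGG tract) is called
when at least `min_frac` = 0.8 of at least `min_depth` = 5 votes agree,
and columns below `min_depth` are unresolved. Only *anchored* reads vote:
the read's haplotype must be decided by alignment score (not fragment
length or the random tie-break) and the read must have a single placement
on that haplotype. Both restrictions matter. Reads assigned by fragment
length alone belong to either allele with non-trivial probability and
would blend the two alleles' sequences; reads with many tied placements
(in-repeat reads against a pure candidate haplotype) carry no reliable
column position and would smear real interruptions into neighbouring
columns. With the restrictions, a 30-unit allele's columns are covered by
its spanning reads and a 60-unit allele's columns by boundary-anchored
flanking reads, at depth comfortably above `min_depth` at 30×. Interruption
detection is at unit granularity (whole-word votes); sub-unit variants
appear as mismatch glyphs but never as structure runs. 5′ and 3′ ends are
treated symmetrically. When assignment ambiguity leaves columns unresolved
the structure is reported incomplete rather than guessed — phasing
interruptions through ambiguous reads is explicitly out of scope.

## Rendering

SVG 1.1, built as text for determinism. Two tracks (one per haplotype)
show flank segments in grey and each STR interval in a per-STR colour with
an allele label ("30 × CGG"); reads are rectangles in lanes (greedy
interval packing, mates sharing a lane; first-fit on sorted intervals is
optimal for interval graphs); mismatches are unit rectangles in the base's
colour, deletions a connector line, insertions a caret; ambiguous reads
get `faint_opacity` = 0.4. Repeats whose width would exceed
`max_width_px` are compressed with a piecewise-linear x-map and annotated
— full-width rendering of multi-kb expansions is a print-shop luxury the
format cannot afford. Mate connector lines are off by default (an option),
as their value is unclear for dense pileups.

## The simulator, and what passing tests do not show

`simulate_read_pairs()` draws fragments uniformly along each haplotype
with lengths Normal(`frag_mean`, `frag_sd`) truncated below at the read
length, emits the two fragment ends as mates (forward/reverse roles
randomised per fragment), applies uniform per-base substitution errors,
and writes fixtures (indexed BAM with graph tags, VCF, catalog JSON,
wrapper TSV, truth table) so both the graph-projection path and the
linear-BAM wrapper path can be exercised. `coverage` is per-haplotype fold
coverage. Defaults emulate a PCR-free short-read library: 150 bp reads,
450 ± 100 bp fragments, 0.2% base error, 30×.

The validation suites use these study conditions, with sizes chosen to
keep each suite to a few minutes on one CPU: phase recovery on 200
simulated two-STR loci (400 bp flanks, 20 bp spacer, CAG/CCG units,
heterozygous allele sizes in the 3–14 unit range, 100 bp reads, 300 ± 40
bp fragments) at 30× and 0.2% error; structure recovery on FMR1-like
single-STR loci with up to three AGG interruptions and alleles of 20–60
units (500 bp flanks, 150 bp reads, 450 ± 70 bp fragments); and
uniquely-assignable fragment accuracy at zero error.

The simulator deliberately omits PCR artefacts, GC-dependent coverage
dips, chimeric fragments and non-uniform error profiles. Passing recovery
bars on simulated data therefore demonstrates the correctness of the
reconstruction/assignment machinery, not that real full-mutation FMR1
samples will always yield readable structures — in real data, coverage
dips over long GC-rich expansions and assignment ambiguity between
near-equal long alleles remain genuine failure modes, and the metrics
flags rather than the consensus caller are the tool for spotting them.

## Numerical and degenerate-input choices

* Alignment ties (mismatch vs indel tracebacks at equal score) resolve
  diagonal > deletion > insertion; placements are deduplicated by
  (start, CIGAR) and ordered by start — all downstream behaviour is
  deterministic given the seed.
* An STR with allele size 0 contributes an empty interval; classification
  treats a zero-length repeat as spannable but never `in_repeat`.
* Empty pileups render tracks, labels and a banner instead of erroring.
* Graph-alignment tags use a simple documented dialect
  (`seg:off:len;seg:len;…`); the decoder is pluggable since upstream tag
  layouts vary, and the wrapper path (de novo realignment) never needs
  tags.
* Orphan mates are loaded and counted but excluded from fragment-length
  estimation, pairing and the pileup; discordant orientations and
  no-shared-haplotype fragments are dropped with counters that the CLI
  logs.
* The consensus structure for a tract whose every column is below depth is
  reported as unresolved with zero confident runs, not as a pure repeat.

## Known limitations

* Phase comes only from read alignment scores; population-based phasing is
  out of scope, so two long near-identical alleles may select an arbitrary
  (tied, logged) pairing.
* The cumulative pair score uses the per-read maximum; a per-fragment
  joint score could in principle phase a handful of additional loci and is
  noted as a sensitivity question rather than implemented.
* Genotypes are inputs, never inferred or corrected: when no candidate
  pair fits the reads well the pileup is still produced and the metrics
  flag the misfit.
* Confidence intervals on allele sizes are parsed and stored but pairs are
  enumerated over point estimates only.
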
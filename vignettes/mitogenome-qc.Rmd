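---
title: "Quality control of circular mitogenome assemblies"
author: "mitoqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of circular mitogenome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoqc)
```

## The problem

Nanopore (ONT) sequencing makes it cheap to assemble the ~14–18 kb
circular mitochondrial genomes of animals directly in the field, but the
consensus carries a characteristic error load: mostly single-base
insertions and deletions, concentrated in homopolymer runs, at a rate
that grows with run length. Short-read (Illumina) data can polish those
errors away, but collapses over highly AT-biased sequence — in
gastropods the control region between tRNA-Phe and *cox3* can approach
99% AT — so each technology misses something the other sees.

`mitoqc` packages the comparative QC a careful analyst performs on such
assemblies:

* **Normalization.** Circular assemblies start at arbitrary rotations
  and strands. `canonical_rotation()` anchors them to a shared origin
  (an anchor sequence such as the *cox1* start, or the lexicographically
  minimal rotation when no anchor is available) and records the applied
  rotation/flip so it can be inverted exactly.
* **Difference calling.** `align_assemblies()` computes a base-level
  difference stream between two assemblies; `differences_from_paf()`
  derives the identical stream from an external minimap2 alignment with
  `cs` difference strings. Both left-normalize indels so counts are
  aligner-independent.
* **Error profiling.** `attribute_homopolymer()` and
  `summarize_profile()` classify differences (`+A`, `-T`, `*CT` labels),
  attribute them to homopolymer context, and convert counts to a
  consensus quality `QV = -10·log10(errors / length)` with its
  equivalent error spacing `10^(QV/10)` bases per error.
* **Structure.** `window_stats()` (AT and coverage in 50 bp windows),
  `detect_unique_segments()` (sequence present in only one assembly),
  `completeness_check()` / `count_premature_stops()` (annotation QC),
  and `gene_order_breakpoints()` (circular synteny).
* **Simulation.** A seeded generator produces mitogenome-like sequences,
  annotations, ONT-style corrupted copies with exact truth, and
  technology-specific coverage tracks, so every stage is testable
  against known ground truth.

## The error model

Corruption is a per-position Bernoulli process. At a position inside a
homopolymer run of length $r$, the indel probability is

$$p_{\mathrm{indel}}(r) = p_1 \cdot m^{\,r-1},$$

with base rate $p_1$ (`base_indel_rate`) and multiplier $m \ge 1$
(`runlength_multiplier`); substitutions occur at a flat per-base rate.
Models whose scaled rate exceeds 1 for an observed run length are
rejected with the offending run length named. Inserted bases duplicate
the run base, which is what basecaller run-length miscalls look like.
Indels are single-base by default (`max_indel_size = 1`) because
single-base events dominate the emulated spectrum; larger sizes are
configurable.

A second injector, `inject_error_mixture()`, bypasses rates entirely
and draws a fixed number of events with stated composition — the share
of single-base indels, of T/A indels, and of events in homopolymer runs
— by sampling loci from the corresponding position strata. This is the
natural tool for emulating an empirically reported error spectrum
(roughly 3/4 single-base indels, about half of all errors being single
T/A indels, about 71% in homopolymers) without reverse-engineering rate
parameters, and it supports a minimum spacing between events for tests
that require isolated errors.

Default study conditions for the generator: a 16 kb circular genome at
66% background AT (the emulated assemblies run 61.8–69.5%), a 1 kb
control region at 98.7% AT between tRNA-Phe and *cox3*, homopolymer
enrichment 0.15 (each base extends the previous run with that
probability), and a 37-gene template with typical, slightly compact
gene lengths so the complement plus a 2 kb control region still fits.
Protein-coding genes are written codon-wise, in frame and stop-free
under the invertebrate mitochondrial code (NCBI table 5), so a clean
assembly translates cleanly and any premature stop is attributable to
injected corruption. Coverage is negative-binomial around `mean_depth`
(ONT default 30×, Illumina 300×, inside the emulated 11–47× and
52.8–973× ranges); Illumina windows above 85% AT have their expectation
multiplied by `at_suppression = 0.05`, reproducing short-read dropout
over the control region.

## Difference calling

The native aligner chains k-mers (default $k = 15$) that are unique in
both sequences, takes the longest increasing subsequence (ties broken
leftmost for determinism), merges same-diagonal anchors into exact
segments, and closes the gaps between segments by global alignment
(Biostrings' Needleman–Wunsch) banded to the gap-length difference plus
a 50 bp margin. Two guards keep the output honest:

* gaps needing a band wider than 2,500 bp are not forced into an
  alignment — both sides surface as *unaligned segments*;
* a one-sided surplus of 200 bp or more (`segment_threshold`) is
  likewise reported as an unaligned segment rather than a giant indel
  record, so multi-kilobase assembly-specific sequence (the AT-rich
  control-region insertions that motivate this package) appears as a
  segment with exact anchor-derived boundaries.

All indels are left-normalized — shifted to the lowest reference
coordinate that describes the same edit — which makes the native
records directly comparable with records parsed from minimap2's `cs`
strings. The test suite verifies exact agreement of the two routes, and
of both against the simulator truth, on random 5 kb pairs with events
at least 10 bp apart. Closer event pairs can legitimately diverge:
aligners may represent an insertion plus a nearby deletion as a run of
substitutions, an equivalent edit script that no per-record
normalization can reconcile.

## Numerical and definitional choices

* **Homopolymer = run of ≥ 3.** Runs of 2 cover roughly a third of
  random sequence, which would make "fraction of errors in
  homopolymers" uninformative. The threshold is exposed (`min_run`)
  rather than hard-coded.
* **Zero-error QV** is capped at `-10·log10(1/L)` and flagged as a
  lower bound (`qv_is_lower_bound`), mirroring consensus-QV practice
  and avoiding infinities.
* **Single-base indel fraction** counts `size == 1` records only;
  multi-base indels are one record with `size > 1`. The T/A indel
  fraction uses all errors as denominator.
* **Rare-label filtering** (`min_count_filter`, default 3) affects only
  the plotting view of the label table, never the fractions or the QV.
* **AT fractions** exclude ambiguity codes from numerator and
  denominator, so Ns cannot bias the control-region statistic.
* **Gene order.** Adjacencies are unordered, orientation-aware pairs in
  canonical encoding, so the breakpoint count is invariant to rotation
  and full reflection of either circular order and symmetric in its
  arguments. Inverted blocks are reported relative to the orientations
  as given: reflecting one input wholesale exchanges which genes count
  as inverted, and the package deliberately does not second-guess the
  submitted orientation.
* **Genetic code** defaults to NCBI table 5 (invertebrate
  mitochondrial; TGA = Trp) and is configurable, since the relevant
  taxa span heterobranchs and caenogastropods.
* **Coordinates** are uniformly 0-based half-open internally; files
  keep their native conventions (PAF and BED 0-based half-open, the
  package's own annotation TSV 1-based inclusive), with the convention
  declared at the reader.

## What the simulator does and does not show

The generator reproduces the features the QC stages key on: length and
composition of the molecule, an AT-rich control region in its canonical
position, run-length-dependent indel errors, and technology-specific
coverage. It does not model read-level artifacts (chimeras, adapter
remnants, strand bias), basecaller-specific error motifs beyond run
length, heteroplasmy, or true repeat structure beyond what AT-biased
i.i.d. sequence with run enrichment produces. Passing tests therefore
demonstrate that the *analysis* is correct and well-calibrated on data
with known truth — not that any particular real assembly is accurate.

Problem sizes in the shipped tests were chosen to exercise the
asymptotics the methods rely on while keeping the suite quick: 16 kb
genomes for profile recovery (20 replicates of 500 events), 5 kb pairs
for the alignment oracles, and 100-case randomized sweeps for each
brute-force oracle (N50, window AT, run attribution, adjacency
breakpoints, minimal rotation).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
sim <- simulate_mitogenome(cfg)
inj <- inject_errors(sim$sequence, error_model(seed = 2))

rec <- attribute_homopolymer(sim$sequence, inj$truth)
summarize_profile(rec, seq_length(sim$sequence))
```

The printed profile reports the error count, the Phred-scaled consensus
QV with its bases-per-error equivalent, and the headline composition
fractions. The same numbers, computed end to end through alignment
rather than from truth records, come out of `cmd_compare()`; the two
routes agreeing is itself one of the package's tests.

## Known limitations

* The native aligner assumes both assemblies are normalized to a shared
  rotation and strand; it does not search rotations itself.
* Minus-strand PAF records are rejected rather than re-oriented; callers
  normalize strands first.
* Gap closure is exact but quadratic in the gap size; pathological
  inputs (thousands of differences in one gap) would be slow, though the
  band and segment guards bound the damage.
* The breakpoint statistic counts adjacencies only; it is not a
  rearrangement *distance* (no DCJ/HP model).
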
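---
title: "Spike-in benchmarking of low-frequency ctDNA variant calls: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in benchmarking of low-frequency ctDNA variant calls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(umispike)
```

This vignette documents the models behind umispike: what is simulated and
under which assumptions, which parameters matter and why their defaults
are what they are, the statistical form of the checks the test suite runs,
and the design decisions that were genuinely open.

## The spike-in model

### Template library

`make_template()` simulates a targeted cfDNA sequencing library as a set
of *duplicate groups*. A group is a fragment coordinate
(contig, start, end) plus one or more read-pair copies of it — the
in-silico analogue of PCR duplicates of one template molecule. The model:

* **Duplicate-set sizes** are `1 + Poisson(m − 1)` for a requested mean
  `m` (default 3). This is the simplest distribution that is
  zero-truncated by construction and has a tunable mean of at least 1;
  `m = 1` degenerates to a deduplicated library.
* **Fragment lengths** are normal with mean 166 bp and sd 40 bp — the
  cfDNA mononucleosome peak — clamped between the read length and the
  target length.
* **Sequencing error** is an independent per-base substitution at rate
  0.001 (Q30 scale), drawn independently for every read copy, with base
  qualities reported as constant Q30. Without this, "putative false
  positive" evaluation would be degenerate: no caller could ever make a
  wrong call on simulated data.
* **Placement** is uniform within a target, fully contained, so the mean
  on-target depth is `n_pairs × 2 × read_length / target_bases` by
  construction, accurate to duplicate-set-size sampling noise. The test
  suite asserts a ±15% band.

Read 1 reports the fragment 5' end and read 2 the reverse complement of
the 3' end (sequencer orientation); with 100 bp reads and 166 bp
fragments, mates typically overlap in the middle, as real cfDNA read
pairs do.

### Allele painting and group-atomic mixing

`paint_alleles()` produces the two extreme copies of the template: every
read base overlapping a panel locus is overwritten with the alternate
(or reference) allele on both mates; nothing else changes. Painting
overrides any simulated sequencing error at the locus, which is exactly
what "100% allele frequency" means.

`mix_to_vaf()` then composes a dataset at VAF `p`: for each duplicate
group key, the alternate-painted copy is selected with probability `p`,
the reference-painted copy otherwise. Two properties follow:

* the expected alternate fraction at every covered locus is `p`, and
* no group is ever split between origins, so when UMI families are
  assigned afterwards, a spiked variant is carried by *every* read of its
  families — the property a UMI-aware caller relies on.

Because selection is per whole group, the independent unit of the mixing
law is the **group**, not the read. All statistical checks in the test
suite therefore use binomial concentration at the group level: the
fraction of alternate groups is Binomial(`n_groups`, `p`) exactly, and
the read-weighted VAF has standard error
`sqrt(p(1-p) * sum(w_i^2)) / sum(w_i)` where `w_i` is the number of read
bases group `i` contributes over panel loci. Asserting the naive
read-level binomial error would be wrong (anticonservative) because reads
within a group are perfectly correlated. A small additive allowance
(5×10⁻⁴) covers alternate bases created by sequencing error on
reference-origin reads (rate/3 per base toward a specific alternate).

An `exact` mode (select exactly `round(p × n_groups)` alternate groups,
sampled proportional to group size) is available where a fixed count is
preferred over a fixed expectation.

Depth is controlled by uniform subsampling of whole groups before
mixing. Requests above the available template depth are capped with a
warning rather than failing: the template is the supply.

### The dataset grid

`spike_plan()` defaults encode the standard design of this benchmark:
VAF levels 0.005, 0.01, 0.02, 0.04, 0.05, 0.075; depth targets 200x,
450x and 850x; 5 replicates per cell; and exclusion of the two lowest
levels at 200x, where a 0.5–1% variant is frequently supported by no
read at all. That yields 5 × (6 + 6 + 4) = 80 datasets. Panel loci that
happen to be covered by no template read are *kept* in the truth VCF:
sensitivity loss at low depth is the phenomenon being measured, not an
input error. Each dataset derives its own seed from the master seed via
a stable string hash (`derive_seed()`), recorded in the manifest, so any
single dataset can be regenerated in isolation.

## Synthetic UMI families

`assign_umis()` partitions each duplicate set into UMI families with
Poisson(λ = 1/2) sampling, attaches a random 9-mer over {A, T, C, G} to
each family, and reports all UMI base qualities as Q37. Both mates of a
pair share the UMI.

"Assigning reads to families by Poisson sampling" admits two readings,
and the distinction is not recoverable from the description alone:

* **label** (default): each read independently draws an integer from
  Poisson(λ); reads of a set sharing a value form a family. This is the
  most literal per-read reading.
* **carve**: family sizes `max(1, Poisson(λ))` are cut sequentially off
  the set until it is exhausted.

Both honour λ = 1/2; the choice is a flag, and the raw Poisson draws are
exposed for statistical testing. Under the label model the probability
that a set of size *n* remains a single family is `Σ_k P(X = k)^n`, which
the suite verifies against simulated family counts for set sizes up to 6.

Two scoping decisions: family identity keys on (coordinates, origin
group), not coordinates alone — otherwise the reference and alternate
copies of one locus, which share coordinates by construction, could be
fused into one family across the origin boundary, defeating the
preservation property that `family_preservation_check()` enforces. And
UMI uniqueness is guaranteed only *within* a duplicate set (by rejection
resampling); collisions across sets are allowed, as they are in real
libraries, where the 4⁹ UMI space makes them rare but meaningful.

The three encoding dialects (`encode_umi()`) — R1/UMI/R2 FASTQ triple,
UMI prepended 5' of R1 with its Q37 qualities, and `RX:Z:`-tagged SAM —
are decodable back to the identical (read → UMI) map, which the suite
asserts. Plain SAM (not BAM) is the canonical artifact so that every
file in a run is inspectable text; the writer's output is additionally
validated against htslib via Rsamtools in the tests.

## Filtering and evaluation

The filtering pipeline applies, in order: depth/quality thresholds
(DP ≥ 50, QUAL ≥ 50), dbSNP-style exclusion (discard on exact key match
when the entry's allele frequency is ≥ 5% *in all populations recorded
for it* — a conjunction, so an entry at {4%, 6%} is retained), and
COSMIC-style annotation (database pre-filtered to sample count ≥ 3;
never drops records). QUAL 50 is the PHRED value at which
`qual_to_probability()` returns 0.99999 — the "99.999% correct" reading
of the quality threshold. Numerical conventions:

* A uniformly missing QUAL column auto-disables quality filtering with a
  notice (callers that do not report QUAL are filtered on depth alone).
* A record with unparseable DP fails the depth filter (conservative),
  but a call set whose DP is unparseable on *every* record bypasses the
  depth/quality stage entirely with a logged, machine-readable note in
  the stage log — the situation of UMI-aware caller VCFs whose
  non-standard fields defeat standard filtering tools.
* Multiallelic records are split to biallelic rows at parse time, so
  matching is always on exact (contig, pos, ref, alt) keys; no
  left-alignment or normalisation is attempted since only SNVs are in
  scope.
* The first two stages commute (both are per-record predicates), which
  the suite asserts; so does monotonicity — raising any threshold never
  enlarges the retained set.

Scoring: a call is a true positive on exact key match against the truth
(each truth record matched at most once); everything else is a putative
false positive, because on a real cfDNA background true negatives are
unknowable. `intersections()` computes, for every non-empty caller
subset, the number of variants called by exactly that subset — the
quantities an UpSet plot draws — plus each caller's private fraction of
the union. Percentages are reported to one decimal place.

### The built-in naive caller

External variant callers are deliberately out of scope. To exercise the
downstream machinery end-to-end without them, `call_pileup()` implements
the simplest defensible caller: call the best-supported non-reference
base wherever it has ≥ 3 supporting reads and ≥ 0.4% of the pileup, with
QUAL the PHRED-scaled binomial tail probability of that much support
arising from sequencing error alone. It exists for tests and
demonstrations; nothing about the package's evaluation semantics depends
on it. Ties between alternate bases at a position are broken
alphabetically after support, making output deterministic.

## What the generator does and does not emulate

The synthetic data reproduce the *structural* features the machinery
depends on: targeted coverage with PCR-duplicate groups, cfDNA-scale
fragment lengths, overlapping mates, uniform sequencing error, and truth
known by construction. They deliberately omit GC bias, fragmentomics
size signal, strand bias, PCR jackpotting and early-cycle errors,
context-dependent error spectra, germline variation, and real genome
sequence content. Passing tests therefore demonstrate that the
simulator, encoder, filters and scorers implement their contracts — not
that any particular caller would achieve the same sensitivity on real
ctDNA libraries.

## Problem sizes and reproducibility

The test suite runs on desk-scale configurations chosen to keep the
whole suite under a minute while leaving every statistical check well
powered: references of 1–8 kb of target, templates of 40–450x,
panels of 10–303 SNVs, 10⁵ Poisson draws for distributional checks, and
a 16-dataset grid (depths 200x/500x, four VAF levels, two replicates,
150-variant panel) for the sensitivity-trend checks. The acceptance
script uses a ~100 kb, 4-target footprint — the scale of a multi-gene
ctDNA panel — at 450x with the full 303-variant panel, which spaces loci
~330 bp apart so that a 166 bp fragment essentially never spans two of
them and the 303 per-locus VAF measurements are effectively independent.

Every stochastic stage takes an explicit seed; `run_all()` fans a single
master seed out via `derive_seed()`, and reruns are byte-identical, which
the suite asserts on the written report files.

## Known limitations

* Fragments are always fully contained in a target; off-target reads and
  edge-overlapping fragments are not modelled, so near-target BED
  bookkeeping is untested territory.
* The error model is substitution-only; no indels anywhere (panel,
  painting, calling, filtering) — indel semantics (normalisation,
  left-alignment) are a different problem.
* One UMI per fragment; duplex/dual UMI schemes are not represented.
* UMI consensus collapsing (the job of downstream consensus tools) is
  intentionally absent: this package produces the encoded inputs such
  tools consume and evaluates the calls they emit, nothing in between.
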
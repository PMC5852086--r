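---
title: "Detecting extrachromosomal circular DNA from circle-enriched sequencing: methods and design"
author: "circlescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circlescan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlescan)
```

## The detection problem

Extrachromosomal circular DNA (eccDNA) arises when a chromosomal segment
is excised and rejoined into a circle. After circle enrichment
(column purification, exonuclease digestion of linear DNA and
rolling-circle amplification), sequencing reads derived from a circle
`[s, e)` betray the junction in three ways when aligned back to the
linear reference:

* **Discordant pairs.** A fragment straddling the junction maps its two
  mates in reverse–forward (RF) orientation instead of the concordant
  forward–reverse (FR): the leftmost mate sits reverse-stranded near
  `s`, the rightmost forward-stranded near `e`. Coordinates are
  approximate, bounded by the insert size.
* **Soft-clipped reads.** A read crossing the junction aligns partially;
  the clip boundary marks one circle coordinate at base-pair
  resolution (a left clip marks a circle start, a right clip a circle
  end). Only clips of at least 50 bases count as evidence.
* **Split reads.** When the clipped fragment realigns on the same
  chromosome and strand, both junction coordinates are fixed exactly.

`circlescan` extracts these three evidence classes from coordinate-sorted
SAM/BAM alignments, clusters mutually compatible evidence into candidate
circles, and ranks candidates by read coverage. Internally all
coordinates are 0-based half-open; SAM input is converted on read and
BED output needs no conversion, which eliminates off-by-one drift.

## Confidence model

A candidate needs at least **two independent structural-read variants**
(distinct read names) and a span of at most **1 Mb**. Each call is then
compared against its sequence neighbourhood:

* mean coverage and covered fraction over `[s, e)`;
* mean coverage of the upstream flank `[s - L, s)` and downstream flank
  `[e, e + L)`, where `L = e - s`.

Tiers:

| tier | rule |
|------|------|
| `hconf` | covered fraction > 0.95 **and** mean coverage > 2 × (sum of the two flank means) |
| `conf`  | covered fraction > 0.95 only |
| `lowq`  | covered fraction ≤ 0.95; the call rests on its structural reads |

The phrase "sum of coverage of adjacent regions" admits two readings; the
default comparator is the literal **sum of the two flank means**
(`flank_mode = "sum"`). The alternative, the mean depth over the union of
the flanks, is effectively a 4-fold test against local background and is
available as `flank_mode = "mean"`. Flanks truncated by a chromosome end
use only their available bases; a fully unavailable flank contributes the
other flank's mean (doubling it), so a circle at a contig edge is not
spuriously promoted.

A consequence worth knowing: when linear background coverage equals the
circle's internal coverage, the interior reaches ~2× the local depth
while the flank sum is also ~2×, so the fold test (>2× the *sum*) can
never pass — matched background demotes every call to `conf` by
construction.

## Evidence clustering

The grouping of "overlapping structural-read variants" is
operationalized as interval-compatibility clustering with transitive
closure. Two evidence items are directly compatible when they share at
least one boundary on which both carry a coordinate, every shared
boundary agrees within tolerance, and the combined interval is a valid
circle (≤ 1 Mb). Tolerances: **5 bp** when both coordinates are exact
(clip/split resolution), otherwise **500 bp** — about one insert size
(430 ± 30 nt libraries). A START-only and an END-only soft clip share no
boundary and therefore never link directly; they join one cluster only
through a bridging split read or discordant pair. This prevents chaining
two unrelated clipped loci up to 1 Mb apart into a phantom candidate.
Consensus coordinates come from the modal exact coordinate when one
exists, otherwise from the extremal hints. Clustering is invariant to
input order, which the test suite checks against an adjacency-matrix
closure oracle.

Two soft-clip evidences on the same side from different reads do count
as two variants; per-kind counts (`n_split`, `n_softclip`,
`n_discordant`) are retained in every call so users can re-filter.

## Clipped-fragment realignment

When a soft-clipped read lacks a supplementary-locus (`SA`) annotation
and a reference is supplied, the clipped sequence is realigned by exact
k-mer seeding (k = 15, seeds at the fragment's start, middle and end)
followed by ungapped identity scoring, searching the anchor chromosome
within ±1 Mb of the clip — genome-wide search is equivalent for accepted
calls, since only ≤1 Mb same-chromosome junctions are annotated, but
wasteful. The best locus is accepted at ≥95% identity; a tie between
distinct best loci is rejected as ambiguous (conservatism over recall).
Only same-strand matches are accepted, matching the circularization
geometry. Hard clips contribute to clip length but carry no sequence, so
they can seed soft-clip evidence but never realignment.

## Merging, recurrence, and external intervals

Calls whose reciprocal overlap — `min(ov/|a|, ov/|b|)` — is at least
**0.50** are collapsed by transitive closure; below that both are kept,
because circles can derive repeatedly from the same locus in close
proximity. The merged representative is the member with the most
distinct evidence reads (ties: larger covered fraction, then leftmost),
preserving exact junction coordinates rather than blurring them into a
union interval; constituents stay available in `merged_members`, and
`n_merged` accumulates so that merging is idempotent.

Cross-sample recurrence uses reciprocal overlap ≥ **0.90** with
single-linkage grouping followed by a pairwise verification (pure single
linkage can chain intervals below threshold; groups that fail are split
greedily). Calls larger than 25 kb can be intersected with external
variant databases at reciprocal overlap ≥ **0.99**; the full intervals
are compared, matching the semantics of standard BED intersection tools.

## Junction transcripts

An RNA split read in back-splice orientation — left part of the read
aligned downstream (3′) of the right part — evidences transcription
across a circle junction. A read supports a circle when its implied
interval (right-part start to left-part end) lies entirely within the
circle and its start deviates by at most **20 nt** from the circle
start; larger deviations are discarded as likely trans-splicing.
"Overlapped 100%" is read as containment, with both-end agreement
required only for ranking — otherwise the 20-nt rule would be redundant.
Only circles with at least one soft-clip or split evidence (exact
junction coordinates) are eligible, and mitochondrial reads are excluded.
Ranks: `hconf` for a perfect both-end match with a genome-unique junction
sequence; `conf` for a perfect match that multi-maps; `lowq` when only
one coordinate matches and the read multi-maps. Junction-sequence
uniqueness is counted with the same seeding-and-identity rule as the
realigner, a desk-scale substitute for an aligner's mapping-quality flag.

## Randomization nulls

Both the circle/transcript overlap test and the recurrence null place
length-preserving intervals uniformly on the genome (chromosome drawn
proportional to length, intervals wholly within chromosomes) and use the
add-one estimator `p = (hits + 1) / (n + 1)` over `n = 1000`
randomizations by default, guaranteeing `p ∈ [1/(n+1), 1]` and a nonzero
floor. The same seed always reproduces the same p.

## Quantification and saturation

Spike-in anchoring converts read fractions to copies per nucleus:

    copies = (f_target / f_spike) · (copies_added / nuclei) · (L_spike / L_target)

The length correction reflects that read counts scale with template mass
rather than copy number; `length_correction = FALSE` recovers the
equal-length reading. These are rough estimates — rolling-circle
amplification biases read counts toward abundant, small templates — so
the package fixes one documented formula rather than tuning toward any
particular published range. The shipped spike inventory is the five
control plasmids (100 pSH63, 100 pUC19_yEGFP3, 10,000 YGPM3k20, 20,000
pBR322, 50,000 pUG72). The per-diploid-cell DNA mass constant defaults
to the working value 6.77×10⁻³ ng; deriving it from first principles
(2 × 3.14×10⁹ bp × 650 g/mol / Nₐ) gives 6.78×10⁻³ ng, and
`derive_ng_per_diploid_cell()` exposes that derivation.

Saturation curves decimate reads in 10% steps. Subsampling assigns each
read pair a seeded permutation rank over the sorted name set and keeps
the top `round(f · n)` pairs: fractions are exact, mates stay together,
and the 10% set is contained in the 20% set, so curves are smooth and
reproducible. The fraction-1 point reproduces the full run identically.

## The simulator

The generator emits post-alignment records directly — what an ideal
aligner would report — because the package's scope begins at aligned
reads; sequences are genuine substrings of the simulated genome, so the
realignment path can be exercised against them. It emulates:

* circle sizes from a two-component log-normal mixture with modes at
  **0.1 kb and 5 kb** (equal weights, σ = 0.25/0.30, floor 60 bp), the
  characteristic bimodal size profile of circle-enriched somatic
  libraries;
* copy numbers from a log-normal scaled by `(size/1 kb)^-α` (α = 1), a
  phenomenological stand-in for the small-template amplification bias;
* 2 × 100 nt pairs at 430 ± 30 nt inserts; junction-crossing reads with
  soft clips, clipped sequence, and supplementary-locus annotations;
  RF pairs for fragments straddling the junction; concordant FR pairs
  inside arms; optional uniform linear background and chimeric
  (random-ligation) artifact pairs;
* at least `junction_read_min` evidence-grade junction reads per circle.
  For circles shorter than one read, a size-clamped read cannot carry a
  50-base clip, so the simulator emits a merged-pair singleton contig
  covering the circle plus 50 wrapped bases — mirroring how read-pair
  merging rescues small circles in real pipelines;
* back-splice RNA split reads for a chosen circle subset, with a jitter
  knob (0 by default, up to >20 nt to exercise the deviation filter);
* spike-in/repeat class reads as multinomial draws over labelled
  contigs.

Circles are placed non-overlapping with a flank-sized margin so the
confidence flanks of one circle are not confounded by a neighbour. What
the simulator does **not** model: sequencing-error realism beyond a
uniform substitution rate, quality scores, repeat-driven mappability
structure, multi-fragment circles, and inter-chromosomal junctions.
Passing recovery tests therefore demonstrates the pipeline inverts its
declared read geometry exactly; it does not certify performance on
repeat-rich real genomes.

## Numerical and degenerate-input choices

* Coordinates are integers throughout; read depth is held as run-length
  encodings per chromosome.
* `mapq ≥ 1` is the default evidence floor (excludes ambiguous
  placements); duplicates and secondary records never contribute to
  evidence or coverage; supplementary alignments act only through the
  `SA` annotation of their primary record.
* Empty inputs yield empty, well-formed outputs (header-only tables,
  p = 1 with a warning for empty Monte Carlo sets).
* Ties: modal-coordinate ties resolve to the smallest coordinate; merge
  representative ties resolve by covered fraction then leftmost;
  realignment identity ties are rejected.
* Output tables report coverage to two decimals and covered fraction to
  four (the 0.95 boundary needs them); ordering is deterministic by
  (chrom, start, end).

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run on simulated genomes of
0.3–1.2 Mb with 4–50 planted circles at 20–30× internal depth — sizes
chosen so every property (exact recovery, tier demotion under matched
background, decimation monotonicity, Monte Carlo floors) is exercised at
full fidelity while a complete run stays in the minutes range on a
single core. All randomized steps funnel through explicit seeds; two
runs with identical inputs, configuration and seed produce byte-identical
primary outputs.

## Known limitations

* Single-fragment circles only: a circle assembled from several distant
  fragments is reported as its separate junctions.
* No inter-chromosomal or inversion-type (same-strand) junction classes.
* The ≤1 Mb cap is structural: larger circles are counted as dropped,
  never called.
* Per-circle copy number is not inferred; spike-in anchoring estimates
  class-level abundances only.
* Paired and single-end (merged-contig) records are treated uniformly
  downstream of evidence extraction.
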
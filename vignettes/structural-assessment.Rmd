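---
title: "Validating organelle genome structure from paired-end reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating organelle genome structure from paired-end reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A linear scaffold or a circular map is a *representation* of an organelle
genome, not a statement about the molecules in the cell. Plant mitogenomes
in particular maintain multipartite and interconverting structures, and an
assembler will happily emit a single linear sequence for a genome that is
really two circles exchanging a low-copy linker. Two read-level signals
expose such situations without any new sequencing: the positional
consistency of read pairs against the library insert model, and the
per-base depth of coverage. `mitostructr` turns those two signals into an
explicit, testable topology model, and packages the surrounding standard
steps (homology scanning for repeats, plastid-derived segments and genes;
conserved-block alignment trimming for downstream phylogenetics) behind the
same tabular interfaces.

## The insert-consistency model

A sequencing fragment of length $F$ yields two inward-facing mates of
length $r$ from its ends. If the scaffold faithfully represents the
molecule the fragment came from, the mates map head-to-head (leftmost mate
on "+", rightmost on "−") with outer distance
$d = \text{right end} - \text{left start} + 1 = F$. A pair is therefore
classified **consistent** when both mates map uniquely, head-to-head, and

$$\mu (1 - \tau) \le d \le \mu (1 + \tau),$$

with insert mean $\mu = 800$ bp and tolerance $\tau = 0.5$ by default
(bounds inclusive: 400–1200 bp for the default library). Pairs violating
orientation or distance are **inconsistent**; pairs with an unmapped or
multi-mapping mate are **unresolved** and carry no localizable junction
signal, so they are excluded from clustering. Multi-mapping placements
*are* counted in coverage — that is precisely what makes plastid-derived
segments visible as spikes — but a repeat-induced ambiguous pair must not
vote for a junction, or every dispersed repeat would fabricate one.

Inconsistent pairs are binned by mate start into unordered pairs of
$w = 1$ kb windows ($\lceil \text{pos}/w \rceil$). Window-pair cells whose
indices are each within ±1 merge into one candidate junction, support is
summed after merging, and a junction needs at least `min_support = 5`
supporting pairs. Merging before thresholding means a junction straddling a
window boundary is neither split below threshold nor reported twice; the
sharp 5-vs-4 boundary is preserved for isolated cells, which the tests pin.
Junction reads that cross a circular origin by up to
$\lfloor r(1-0.9)\rfloor = 12$ bases still map (identity just above the
floor) with starts slightly left of the true flank; adjacency merging
absorbs this one-window blur.

## Mapping and its thresholds

The built-in mapper anchors exact $k = 31$ seeds (probed every 10 bp along
the read plus the final offset) against a reference k-mer table, places the
read gaplessly on the seed diagonal on both strands, clips at reference
ends, and filters placements to aligned span ≥ 90% of the read length and
identity ≥ 90% over the aligned span — "90% length, 90% identity"
interpreted as two independent floors, so a 125 bp read tolerates at most
12 substitutions. The mapper is substitution-only by design: the simulator
emits no indels, and real data should come in as SAM/BAM from a gapped
mapper through `ingest_alignments()`, which applies the same floors using
CIGAR spans and `NM`-derived substitution counts and uses primary
alignments only. N never matches anything, on either side.

With seeds every 10 bp, any placement with three or fewer scattered
substitutions is guaranteed an intact seed; recovery of error-free
simulated reads is a tested invariant (≥ 99.9%). Heavily mutated reads near
the 12-substitution boundary may lack an intact probed seed — a deliberate
trade of exhaustiveness for speed, shared with every seeded mapper.

## Coverage, anomalies and stoichiometry

Depth at base $i$ counts mate alignments covering $i$, so
$\sum_i d(i)$ equals the total aligned bases (a conservation identity the
tests assert). Anomaly detection scans non-overlapping 1 kb windows and
flags window medians above `spike_factor = 2` or below `dip_factor = 0.6`
times the genome-wide median; medians, not means, so a handful of
multi-mapped reads cannot drag a window over threshold. Same-kind runs of
flagged windows merge; a run is reported if its window-level extent reaches
`min_len = 2000` bp, and its exact boundaries are then refined to the
first/last base at which a running-median-smoothed depth (width 51) crosses
the threshold. Three numerical choices deserve a note:

* `min_len` applies to the window-run extent *before* refinement: a
  ~1.7 kb multi-mapping feature that dominates two windows is still
  reported, with its refined (shorter) boundaries.
* The running-median smoothing is exact on step-like profiles (the smoothed
  value flips exactly at a step for an odd window) but immune to the
  single-base Poisson excursions that otherwise make "first base crossing
  the threshold" jump hundreds of bases early at 30× depth.
* The stoichiometry ratio, genome median over region median, is computed on
  medians of 125 bp *window means*. Raw per-base medians are integers: a
  6× region simply cannot express a 5-fold ratio against a 30× genome to
  within ±15%. Window means restore fractional resolution; the outer median
  keeps robustness. The profile's own `mean`/`median` summaries remain
  plain position-wise statistics.

Parameter recovery is tested end to end: planted copy ratios of 2, 3 and 5
at 30× are each recovered within 15% (five seeded replicates per ratio,
10 kb bridge — a 3 kb bridge at 6× holds only ~70 inserts, whose counting
noise alone is ~12%, so identifiability dictates the longer bridge for the
tight property; the 3 kb condition is still exercised for classification
and for the mean ratio across ten replicates).

## Topology rules

Coverage segments (split at anomaly boundaries, each carrying its median
depth) and junction clusters form a graph whose cluster edges get *roles*:
scaffold left/right end, or left/right flank of a dip segment, assigned to
the nearest qualifying boundary within a 2-window tolerance. Nearest, not
first-matching: for a dip only three or four windows wide, both flanks fall
inside one tolerance radius and a first-match rule misassigns the right
flank. The classification rules are applied in order:

1. one cluster edge joining the two scaffold ends, no dip → **single
   circle** of full scaffold length;
2. exactly one dip $D$ with cluster edges (left end ↔ left flank of $D$)
   and (right end ↔ right flank of $D$) → **two circles with a bridge**:
   circle A $= [1, D_\text{start}-1]$, circle B $= [D_\text{end}+1, L]$,
   bridge $= D$ as a linear molecule at relative copy equal to the dip
   ratio;
3. no cluster edges → **linear**;
4. anything else → **unresolved**, with the raw edge list as evidence.
   Contradictory evidence is never resolved by guessing.

Only these patterns are implemented. General breakpoint-graph traversal is
out of scope on purpose: with no large repeats there is no combinatorial
isoform space to enumerate, and each added pattern is another way to be
confidently wrong. Molecule lengths are exact integer functions of segment
boundaries; kb values are rounded only in printed reports. Copy numbers are
medians over each molecule's own (exclusive) interval, normalized so the
maximum is 1.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the study
conditions the analysis assumes: 2 × 125 bp mates from an 800 bp library at
tens-fold depth over sequences of tens to hundreds of kb, with planted
dispersed repeats (up to ~500 bp), plastid-derived segments (1–2 kb,
~80–85% identity) and multi-isoform stoichiometries. Specific choices:

* Coordinates are 1-based fully closed everywhere.
* Insert lengths are Normal(μ = 800, σ = 80) truncated to
  [2r, molecule length]; the σ default is a 10% spread, chosen because a
  ±50% acceptance window implies a broad but unimodal library and the true
  spread of such libraries is rarely published. It is configurable.
* Errors are substitutions only, at a configurable per-base rate (< 0.1);
  quality strings are constant placeholders. This suffices to exercise the
  90%/90% floors; it does not emulate machine-specific error profiles,
  PCR duplicates or adapters, so passing tests say nothing about those
  artifacts in real data.
* Planted features are written by replacement (the scaffold length never
  changes) and mutated to an exact identity: `round((1 − identity) · len)`
  distinct positions substituted.
* Molecule choice weights are `copy_number × effective length`, where
  effective length is the number of positions an insert can occupy
  (`length − μ + 1` for linear molecules, full length for circles).
  Weighting by raw length over-covers the interior of short linear
  molecules — their inserts are squeezed away from the ends — which biases
  recovered stoichiometry by 10–20% for a 3–5 kb bridge. With effective
  lengths, interior depth is `depth × copy` for every molecule. Copy
  numbers are normalized so the highest-copy molecule attains the target
  depth.
* `two_circle_bridge_spec()` realizes the bridged condition as circle A,
  circle B (both excluding the bridge) and the bridge as a linear molecule
  padded by ±1.1 kb of flanking scaffold. The padding makes the low-copy
  molecule a fragment of the linearized full-genome form — which is also
  the structure the junction evidence implies — and keeps paired-sampling
  edge ramps out of the dip interval. The naive alternative (both circles
  containing the bridge) cannot produce a coverage dip at all: the bridge
  would then carry the *sum* of both circles' depth.

Determinism is a contract: identical specs and seeds give byte-identical
sequences, reads and truth tables, which the suite asserts.

## Homology scanning

One engine serves repeats (self-comparison, strict > 90% identity,
following the convention that a repeat inventory uses an open bound),
MIPTs (cross-comparison, inclusive ≥ 80%) and gene location (best hit at
≥ 70% identity and ≥ 70% reference coverage). It anchors exact k-mers
(k = 16 for repeats, 12 for the looser floors), extends gaplessly along the
diagonal with score-based X-drop, polishes boundaries, and filters each hit
by length and identity. Two scoring decisions matter:

* The extension penalty is **permissive** (mismatch −1.5 against match +1,
  neutral near 60% identity, the reward:penalty regime of standard
  nucleotide local search). A diverged region is thereby delineated as
  *one* alignment and accepted or rejected whole by the identity floor. The
  tempting alternative — hunting for the longest sub-segment that clears
  the floor — quietly reports the short lucky islands that any long 75%
  region contains above an 80% floor, which is not what a similarity
  inventory means.
* Boundary polish re-extends the score-maximal core at +1/−2 with a short
  X-drop and trims ends to matches. This walks through the mutation
  clusters that sit at a feature's edge (local identity above 2/3) but
  halts within a base or two of random flanking sequence (~25% identity);
  without it, an edge cluster pulls the score maximum up to ~20 bp inside
  the planted feature. Planted-feature boundaries are recovered to ≤ 5 bp,
  a tested invariant.

Hits are deduplicated (trivial self-hit removed, symmetric pairs
canonicalized so the first interval starts no later than the second,
redundant overlaps merged keeping the higher-scoring hit). The tests
cross-check the engine against two independent oracles: a brute-force
all-diagonals window scan (for absence claims) and the standard external
nucleotide search tool's tabular output (for presence and boundaries, at
≥ 95% reciprocal overlap on 20 kb instances). Gapped sensitivity is out of
scope; externally computed tabular hits can be imported into the same
contract (`read_hits_tsv()`).

## Conserved-block trimming

The trimmer transcribes the published five-step block-selection procedure:
classify each column (gap rule first, then modal-residue counts against
b1/b2); reject runs of more than b3 contiguous nonconserved columns; trim
candidate blocks back to highly conserved terminal columns; remove gap
columns inside blocks together with adjacent nonconserved runs (which may
split a block); drop blocks shorter than b4. The relaxed default family is
b1 = b2 = "half", b3 = 8, b4 = 5, gaps tolerated in up to half the rows.
Interpretation notes, each of which changes outputs if gotten wrong:

* "half" is ⌊n/2⌋ + 1 sequences — minimum majority, *not* n/2;
* with b1 = b2 the conserved/highly-conserved distinction collapses, but
  both thresholds are implemented separately so other settings work;
* `-` and `.` both count as gaps; ambiguity codes are non-gap residues that
  never contribute to the modal count;
* under the "half" gap rule a column is gap-disqualified when gaps occur in
  *more than* half the rows (6 of 10 disqualifies, 5 of 10 does not);
* ties for the modal residue are harmless: only the count matters.

Columns are only ever dropped, never reordered or edited — `kept_columns`
is strictly increasing in original coordinates, and relaxing b4 can only
add columns (both property-tested). Batch mode trims each gene
independently, pads missing taxa with all-gap rows, concatenates in input
order and emits a partition table. The reference oracle is an independent,
deliberately loop-by-loop transcription of the same published procedure
kept in the test helpers; its outputs on twelve seeded toy alignments are
frozen as text fixtures, and the suite checks the vectorized implementation
against both the frozen files and a fresh oracle run. Where the published
description of gap-adjacent handling is ambiguous, the reference
transcription is the ground truth.

## Problem sizes and test design

The suite runs entirely on synthetic data built in code at test time:
module fixtures use 20–60 kb genomes at 25–30×, the end-to-end recovery
condition uses ten seeded 100 kb two-circle genomes with a 3 kb bridge at
30× and copy ratio 3:1, homology oracle comparisons use ≤ 20 kb instances,
and trimming fixtures are ≤ 12 taxa × 200 columns. These sizes keep the
full suite under a couple of minutes while leaving every estimator's
sampling noise well inside its tested tolerance; the pipeline itself is
linear-time in reads and scaffold length and runs comfortably at real
365 kb / 30× scale.

## Limitations

* Inference is deliberately limited to the single-circle, bridged
  two-circle, linear and unresolved patterns; repeat-mediated isoform
  enumeration is out of scope.
* An inferred circular or bridged map is a statement about read support for
  junctions in the assembly representation, not about in vivo molecule
  conformations.
* The built-in mapper and similarity engine are gapless; indel-rich data
  belongs to external gapped tools whose output both modules ingest.
* Depth-based stoichiometry assumes no GC bias correction and no
  mappability model; ratios over regions near the mapper's ambiguity
  boundary inherit multi-mapping artifacts by design.
* The synthetic library emulates insert geometry and substitution error
  only; conclusions about adapter, duplicate or quality artifacts in real
  libraries are outside what a passing suite demonstrates.
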
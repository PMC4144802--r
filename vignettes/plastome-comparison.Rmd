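---
title: "Comparing conspecific plastomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing conspecific plastomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastdiff)
```

## The problem

Chloroplast genomes of closely related individuals — here, two conspecific
plants from disjunct continental populations — differ by a modest number of
small mutations: single-nucleotide substitutions, slippage indels in
homopolymer runs, and copy-number changes in tandem repeat arrays. A careful
pairwise comparison of two complete plastomes quantifies this divergence,
localizes it across the quadripartite architecture (large single-copy
region, small single-copy region, and the two inverted repeats), and can be
turned into a rough divergence date by scaling a calibrated node age with
the ratio of observed divergences. `plastdiff` implements that workflow end
to end, together with a dedicated analysis of the kind of hypervariable
intergenic spacer (IGS) that dominates length variation in some lineages:
a tandem array of short palindromic units that fold into DNA hairpins.

Because the interesting statistics are counts of individually rare events,
the package ships a synthetic plastome-pair generator with a full truth
catalog: every planted mutation is recorded with its lineage, position and
mechanism, so the entire call chain (alignment, event calling,
classification) can be validated against known answers at desk scale.

## Data model and conventions

A genome is an `AnnotatedPlastome`: one linearized circular sequence over
`{A,C,G,T,N}`, four segments (`LSC`, `SSC`, `IRa`, `IRb`) that tile it
exactly, and a feature table (`CDS`, `tRNA`, `rRNA`, `intron`, `IGS`).
Coordinates are 0-based half-open everywhere inside the package; the 1-based
conventions of GenBank and VCF apply only at those file boundaries. The
genome is assumed linearized at the conventional origin — the start of a
single-copy region — and the IGS across the origin is included when deriving
spacers on a circular genome.

Two structural invariants are enforced at construction: segments tile
`[0, length)` disjointly, and IRa equals the reverse complement of IRb
within a configurable mismatch tolerance. `detect_segments()` recovers the
quadripartite partition de novo by seeding exact k-mers (k = 21) between
the sequence and its reverse complement, chaining seeds on anti-diagonals,
and extending the best candidate under the mismatch tolerance.

Variants inside the inverted repeat are counted **once** (calls on IRb are
dropped as mirror images of IRa calls) while per-region densities divide by
**twice** the IR length, since both copies contribute sites. This is the
"IR(x2)" accounting used in comparative plastome tables.

## Alignment

Homologous genomes are aligned globally with affine gap penalties
(defaults: match +1, mismatch −2, gap open −5, gap extend −1 per base).
The open/extend asymmetry deliberately favors one long gap over several
short ones, so a multi-unit tandem indel surfaces as a single event — the
unit the downstream tables count.

* `align_global()` is exact dynamic programming (delegated to
  `Biostrings::pairwiseAlignment`), for regions up to a configurable limit
  (default 50 kb).
* `align_anchored()` scales to whole plastomes: k-mers that occur exactly
  once in each sequence (k = 21) are collapsed into maximal exact blocks,
  the heaviest collinear block chain is selected, and inter-anchor gaps are
  closed with exact DP. Tandem arrays carry no unique k-mers and are closed
  by DP between their flanking anchors, which is where the gap-scoring
  asymmetry matters most.
* After any alignment, every gap run is **left-normalized**: it slides
  leftward as long as the slide preserves both sequences and the score
  (i.e. through repeated context). This is the pairwise analogue of VCF
  indel normalization and makes event coordinates deterministic and stable
  for context classification. We chose left-normalization (rather than
  3′-shifting) as the single convention because it matches the VCF export
  the package writes.

For outgroup polarization, `align_triplet()` threads an outgroup onto the
A–B alignment by aligning it independently against each genome and reading
its base over every A–B column. A column's outgroup state is `A-like`,
`B-like`, `both` (uninformative), `other`, or `gap`. An indel is polarized
only when the flanking columns show real homology with the outgroup —
at least half of them must *agree* with one of the two genomes, not merely
be covered by outgroup bases, since a non-homologous region aligns
base-to-base without being evidence of anything.

## Variant catalog

Each maximal single-row gap run becomes one indel event; the **carrier** is
the genome holding the extra bases. With an outgroup: if the outgroup lacks
the segment, the event is an insertion in the carrier lineage; if it has
it, a deletion in the non-carrier lineage; otherwise polarity stays
unknown. Carrier assignment never changes during polarization.

Context classification is content-based, on the carrier genome:

* `homopolymer` — the event is a run of one base and the carrier's run
  covering the site is at least 4 bp (the event bases count toward the
  run). The 4 bp floor separates slippage-prone runs from chance; shorter
  runs are not credible slippage templates.
* `tandem` — the event sequence (2 bp or longer) exactly duplicates an
  immediately adjacent window of the same length in the carrier.
* `other` — everything else, including dispersed-repeat context, which the
  reporting tables do not separate.

Mismatch columns with both bases in `{A,C,G,T}` become SNPs (columns with
N are excluded, and no MNP merging is performed — adjacent mismatches stay
separate events, matching count-based tables). Compartment comes from the
genome A annotation with precedence CDS > intron > tRNA > rRNA > IGS.
A coding SNP is classified synonymous or nonsynonymous by rebuilding the
codon around the site on the coding strand from each genome (companion
positions taken from the same genome via the alignment) and translating
with the bacterial/plastid genetic code (NCBI table 11); codons interrupted
by alignment gaps, and CDS features whose length is not a codon multiple
(flagged degenerate at load), are excluded.

Summaries cross-tabulate indels by segment × context × carrier and SNPs by
segment × compartment × mutation class; transition/transversion ratios are
reported per compartment, per-gene tables add synonymous/nonsynonymous
counts and a Kimura two-parameter distance
(K = −½·ln[(1−2P−Q)·√(1−2Q)], with P and Q the transition and transversion
proportions; inputs with 2P+Q ≥ 1 or Q ≥ ½ are rejected as saturated).
Density ratios normalize per-region event densities to the IR density
(or, when the IR count is zero, to the smallest nonzero density). Printed
statistics round half-away-from-zero at the reported precision — `round()`
in R rounds half-to-even, which would misreproduce published values.

## Hypervariable spacer analysis

`find_tandem_arrays()` detects tandem arrays by lagged self-comparison:
for each candidate unit length the sequence is compared with itself shifted
by that period, and regions whose rolling per-period identity stays at or
above `min_identity` (default 0.8) seed candidate arrays. Copies are then
chopped in phase and the array is extended copy-by-copy outward while each
new copy stays within `min_identity` of the *running consensus*. The
consensus criterion matters: real arrays mix unit variants (the A/B loop
forms below), and two adjacent copies of different variants can fall below
the threshold even though both sit close to the consensus. Arrays of 19 bp
units are re-phased against the canonical unit `TATGGATTTCTTGTCCATA` when
that improves the consensus match, so position numbering is comparable
across genomes.

`fold_hairpin()` folds a unit by pairing terminal positions inward
(position i with position L+1−i), accepting A:T, G:C and the G:T wobble,
and stopping at the first disallowed pair or when the unpaired middle would
drop below `min_loop` (default 3 nt). This is a complementarity scan, not a
thermodynamic fold — minimum-free-energy structure prediction is explicitly
out of scope. The canonical 19-mer folds to a 7 bp stem (`TATGGAT`, with
one G:T wobble) closing the 5 nt loop `TTCTT`.

`classify_form()` labels the two predominant loop variants: A (`TTCTT`)
and B (`TTTAA`). One subtlety: under maximal pairing with a 3 nt loop
floor, the B form's terminal T:A contact at positions 8/12 would extend
the stem to 8 and leave a 3 nt loop, hiding the published 5 nt loop. The
A/B forms are defined on the consensus structure — a 7 bp stem closing a
5 nt loop — so classification folds with `min_loop = 5`, which caps a
19-mer's stem at 7. `fold_hairpin()` itself keeps the generic rule.

Consensus profiles report per-position base frequencies, the majority
consensus (ties broken alphabetically), and invariable positions; copies
bearing internal indels must be excluded or phase-aligned upstream, and the
function refuses mixed-length input rather than guessing an alignment.
`dotplot()` provides the windowed self- and cross-comparison matrices
(default window 19 with 15 required matches, ~80%, the repeat-unit scale),
and `dispersed_repeats()` is a thin window scan for forward and palindromic
repeat pairs (10 bp minimum, Hamming distance up to 3).

## Distances and dating

p-distances use **pairwise deletion**: comparable sites are columns with
both bases in `{A,C,G,T}`; gap and N columns leave the denominator. This
convention reproduces published difference-count arithmetic of the form
2/4,534 → 0.0004. Multi-sequence matrices are built from independent
pairwise alignments, not a joint multiple alignment — a deliberate
simplification that can shift individual cells slightly on real data.

`scale_divergence()` implements calibration-ratio dating: if a calibrated
split is `fold` times more diverged than the focal split, the focal age is
the calibration age divided by `fold`, with the half-width scaled
identically. Error propagation is strictly proportional; no resampling
interval is attempted, because the calibration itself is a point ± half
width, not a distribution.

## The synthetic generator

`generate_ancestor()` builds a desk-scale quadripartite genome — defaults
20 kb LSC + 2 kb IR + 4 kb SSC + 2 kb IR (~28 kb), GC fraction 0.33 —
with plastid-style CDS genes (one intron-split), a tRNA pair flanking the
hotspot spacer, an rRNA in the IR, homopolymer-enriched spacers (mean run
length 3× the iid baseline by default; factor 1 reproduces the iid process
exactly), and a planted tandem array: 30 copies of the canonical 19-mer
with 3% per-copy substitution heterogeneity and 40% of copies carrying the
B-form loop. The desk scale keeps a full simulate-analyze round trip to a
few seconds per seed; the structure, not the absolute size, is what the
analysis consumes.

`evolve_pair()` evolves two lineages and an outgroup (12× the per-lineage
rates) independently from the ancestor on a star tree. Defaults:
substitutions at 6×10⁻⁴ per site per lineage (pairwise expectation ~0.12%,
a realistic conspecific plastome divergence), transition/transversion rate
ratio κ = 1.1 (expected Ts/Tv count ratio κ/2 ≈ 0.55, the weak genome-wide
bias typical of noncoding-dominated plastome comparisons), slippage indels
at 4×10⁻⁴ per site targeted at runs ≥ 4 bp, tandem duplications at 9×10⁻⁵,
other indels at 9×10⁻⁵, and 0.5 expected copy-number steps of the planted
array per lineage (steps of 1–3 units at true unit boundaries). Mutations
are planted on `[0, IRb)` only and IRb is re-mirrored from the mutated IRa,
emulating plastome copy correction: IR events exist once, and the IR
invariant stays exact.

Design choices worth knowing:

* **No planted event overlaps another** — a footprint registry shared
  across all three lineages redraws colliding events (substitutions
  included). This is what makes per-event recovery well-defined; it also
  means the generator slightly underdisperses event spacing relative to a
  pure Poisson process.
* **Truth context labels are content-based.** Each planted indel records
  both its generating `mechanism` (slippage, array step, duplication,
  other) and a `context` label computed from the carrier genome's content
  at planting time with the same rule the caller uses. The two can differ
  legitimately — an array step lands next to a diverged copy, say — and
  recovery is scored against content, which is the only thing an aligner
  can see. "Other" candidates whose random content would read as slippage
  or duplication are redrawn, and tandem events outside the array are
  duplications only (the ancestor carries no other repeat to contract).
* **What the generator does not emulate:** sequencing error (including
  pyrosequencing homopolymer artifacts), heteroplasmy, rearrangements,
  gene conversion between single-copy regions, coalescent sampling, and
  rate heterogeneity along the genome beyond the homopolymer/array
  targeting. Passing recovery tests therefore demonstrates correctness of
  the call chain under the stated mutation model, not robustness to
  assembly artifacts in real accessions.

`recovery_stats()` matches called events to the truth: SNPs at their lifted
genome A coordinate (±2 bp), indels by exact length within ±60 bp — the
generous indel window exists because left-normalization can slide a gap
through repeated sequence (inside a tandem array, typically by a unit or
two before per-copy heterogeneity stops it).

## Numerical and degenerate-input policy

* Ties in DP alignment resolve to Biostrings' fixed internal preference,
  then gap runs are left-normalized; results are deterministic for fixed
  inputs.
* Consensus ties break alphabetically; array candidates are accepted
  greedily by copy count, then unit length, then position.
* Zero comparable sites, zero-length regions, a zero focal divergence, a
  non-positive fold, overlapping groups, and saturated K2P inputs all
  raise errors rather than returning sentinel values.
* Empty event lists summarize to all-zero tables with Ts/Tv marked `NA`.
* All user-facing randomness flows through a single integer seed;
  identical seeds give byte-identical genomes, truth catalogs and reports.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
~28 kb simulated genomes (20 recovery seeds), alignment oracle instances
up to 5 kb, 100 synonymy oracle cases, 200-copy profiles, and the
published summary tables as direct inputs. A full simulate-and-analyze
round trip with outgroup takes on the order of ten seconds; the whole
suite runs in minutes on one core.

## Limitations

* The aligner is pairwise-plus-threading; no true multiple alignment is
  built, so three-way columns near ambiguous indels can differ from an
  MSA-based analysis.
* Copy counts in real, highly diverged arrays depend on the identity
  cutoff; published copy counts for real accessions are reproducible only
  up to that parameter, which their sources do not state.
* Dotplots are coordinate tables; plotting is left to the caller.
* GenBank parsing covers the location forms used by organelle records
  (`a..b`, `complement`, `join`); esoteric operators are not supported.
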
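---
title: "Mining, classifying and genotyping Stowaway-like MITEs"
author: "stowawaykit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, classifying and genotyping Stowaway-like MITEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stowawaykit)
```

## The biological problem

Miniature inverted-repeat transposable elements (MITEs) of the *Stowaway*
superfamily are short (< 500 bp), AT-rich, non-autonomous class II
transposons. Each element is bounded by terminal inverted repeats (TIRs)
and, having inserted into a TA dinucleotide, is flanked by a duplicated
`TA` target site (TSD). In carrot, *DcSto* elements additionally share a
highly conserved 6 bp terminal motif, `CTCCCT`, at the 5' end of the left
TIR (and therefore `AGGGAG` at the element's 3' terminus). These three
structural signatures — TSD, TIR, terminal motif — make the elements
minable directly from sequence, and their presence/absence at a locus
makes them usable as codominant genetic markers.

`stowawaykit` implements that entire computational workflow:

1. **simulation** of host sequence with planted elements and exhaustive
   ground truth, so every downstream stage can be benchmarked;
2. **structural mining** (TSD + TIR + motif scan) and **homology search**
   with BAC-end-style validation filters;
3. **family classification** under the 80-80-80 rule, with star-alignment
   consensi, Kimura two-parameter (K2P) distances and Neighbor-Joining
   (NJ) trees;
4. **copy-number estimation** from a BAC-library PCR screen;
5. **local structure analysis**: nested insertions, pre-insertion
   reconstruction, locus-variant genotyping and in-silico PCR.

## The synthetic-data model

The generator is first-class, tested code, not a fixture. It emulates the
features of real MITE-bearing plant genomic sequence that the analysis
stages key on, and nothing more:

* **Background**: i.i.d. bases with `P(A) = P(T) = at/2`, default
  `at = 0.65` — the midpoint of the 0.60–0.72 AT range typical of these
  elements' hosts and of the elements themselves.
* **Family consensus** (`family_spec()`): length 274 bp (the canonical
  first-discovered element), 16 bp TIRs whose left copy opens with
  `CTCCCT`, exact AT composition control (the consensus AT fraction is
  constructed to within rounding of the request; when unspecified it is
  drawn uniformly from [0.60, 0.72]).
* **Copies**: the consensus mutated per site at rate `divergence`
  (uniform over the three alternative bases) plus single-base indels at
  `indel_rate` (default 0.002 — a deliberately light but non-zero indel
  load; real element copies are not indel-free). The terminal motif
  positions are immutable, matching the empirical observation that the
  termini are the most conserved part of the element.
* **Insertion**: every planting replaces one `TA` occurrence with
  `TA + element + TA`. Truth records store the element span only
  (0-based, half-open, TIRs included); the flanking TAs are implied,
  which avoids double-counting the duplicated dinucleotide.
* **Locus variants**: occupied, empty, excision footprint (1–10 bp
  junction residual, inserted or deleted with equal probability — the
  literature records footprints of "variable length" without a
  distribution), internal deletion (20–80% of the element removed,
  possibly including a terminus), and clustered (a second element 20–100
  bp upstream, covering the empirically observed 20 bp and 48 bp cases
  with margin).

What the generator does **not** emulate: real chromosome-scale
heterogeneity (centromeric exclusion, gene-proximal insertion bias),
recombination, methylation, retrotransposons, or sequencing error.
Passing round-trip tests therefore demonstrates correctness of the
algorithms under the structural model above, not performance on raw
sequencing data.

Elements are planted without overlap, so planted positions are slightly
more evenly spaced than a Poisson process; at realistic densities (one
element per ~200 kb) this is negligible, but it is visible at the high
densities used in stress tests (see the copy-number notes below).

## Structural mining

`find_tir_candidates()` pairs occurrences of the terminal motif with
downstream occurrences of its reverse complement within `max_len`
(default 600 bp, the accepted MITE size bound) and extends the inverted
repeat inward from both termini. The extension is a banded edit-distance
walk: substitutions *and* single-base bulges each consume one unit of
`max_mismatch_per_tir` (default 2). Bulge tolerance matters: a single
indel inside a TIR otherwise destroys the positional register and costs
several percent recall at realistic indel loads. Pairs whose TIR reaches
`min_tir` (13 bp, the shortest TIR reported for this element group) are
kept, and with `require_tsd = TRUE` the literal `TA` must sit immediately
outside both termini.

Overlapping candidates are resolved deterministically: longer TIR, then
fewer TIR edits, then longer element, then leftmost. Candidates strictly
nested one inside another are *both* kept, because genuine nested
insertions exist and are the subject of `detect_nested()`.

Because a Stowaway element's right terminus is the reverse complement of
its left one, the motif-pair pattern is identical on both strands; a
plus-strand scan therefore finds elements in either orientation, and all
candidates are reported on the plus strand.

The **hairpin score** replaces a thermodynamic fold with a
dependency-free, monotone proxy: the maximum number of nested
Watson–Crick pairs (Nussinov dynamic programming, minimum loop 3 nt,
optional G·T wobble off by default) divided by `floor(length/2)`. It
ranks fold-back potential; it is not a free energy.

`homology_search()` is a k-mer-seeded (word size 11) local-alignment
search; seed clusters are aligned with full affine-gap Smith–Waterman
restricted to the cluster's window (a window of ± one query length
around the seeds — equivalent to a banded search but simpler). Identity
plus query-coverage thresholds (0.6 / 0.5) replace a database-size
dependent e-value, which would not be reproducible without a specific
statistics implementation; fixed thresholds are. `validate_hit()` applies
the screening filters used for BAC-end survey sequences: characteristic
TSD, detectable TIR pair at the hit boundary (± 5 bp slack), and at
least `min_flank` (100 bp) of flanking sequence on both sides. The search
scans the plus strand; a hit to the element's reverse complement would
require searching the reverse-complemented query as a second pass, which
callers can do explicitly.

## Family classification

Two elements belong to one family when a global affine-gap alignment
(match +1, mismatch −1, gap open −4, gap extend −1, end gaps penalized)
shows **identity ≥ 0.80 over coverage ≥ 0.80**, considering only
elements **≥ 80 bp** — the 80-80-80 rule. Design choices where the rule
is ambiguous:

* identity is computed over columns where both rows are non-gap
  (pairwise deletion, the dnadist default);
* the coverage denominator is the *shorter* raw sequence — the stricter,
  symmetric reading of "80% of their length";
* families are the *connected components* (single linkage) of the
  relation; no linkage rule is standard here, and single linkage is the
  most permissive deterministic choice;
* family numbering is by decreasing size, ties by smallest member id, so
  output is invariant under input permutation.

Consensi are built by **star alignment** to the longest member: members
are projected onto the reference columns (insertions relative to the
reference are discarded), each column takes the majority base,
majority-gap columns are dropped, and ties become IUPAC degenerate codes
(T/C → `Y`, A/G → `R`, …). A full progressive MSA would be more accurate
above ~20% intra-family divergence, but families are defined to be ≥ 80%
identical, where star projection reconstructs the generating consensus to
≥ 99% in the round-trip tests.

K2P distance is the closed form `d = −½ ln((1 − 2P − Q)·√(1 − 2Q))` with
transition proportion `P` and transversion proportion `Q`; outside the
model's domain a typed saturation error is raised, never `NaN`. The NJ
implementation is the canonical Saitou–Nei agglomeration with two fixed
conventions so trees are bit-reproducible: Q-matrix ties are broken by
the lexicographically smallest label pair, and negative branch lengths
are clamped to zero with the deficit moved to the sibling (path lengths
preserved, so additive matrices are still reproduced exactly — the test
suite checks to 1e-9 against path distances of random trees, and checks
topology against an independent NJ implementation). A 2-taxon matrix is
returned as two branches of `d/2` joined at one node, since an `ape`
tree object cannot represent a single rootless edge; the tip-to-tip path
length is exactly `d`.

`tir_consensus()` aligns left TIRs flush at the terminus (no internal
gaps — TIR homology is anchored at the element end), pads short TIRs on
the right, writes the per-column IUPAC consensus and reports the longest
terminal run of non-degenerate columns; on synthetic families sharing
the planted motif this run is at least 6.

## Copy number from a BAC screen

With `n` clones screened, `k` positive, mean clone size `c` Mbp and
genome size `G` Mbp:

* `estimate_naive()` assumes one element per positive clone:
  density `= k/(n·c)`, spacing `= 1000/density` kb, copies
  `= G·density`. This is the published estimator; with the published
  screen (141 clones, 87 positive, 0.121 Mbp, 980 Mbp) it yields one
  element per 196 kb and ≈ 5,000 copies.
* `estimate_poisson()` corrects for multi-hit clones: under random
  insertion the per-clone count is Poisson, so
  `λ = −ln(1 − k/n)` and copies `= G·λ/c`. It is always ≥ the naive
  estimate for `0 < k < n` (since `−ln(1−p) ≥ p`) and saturates (typed
  error) when every clone is positive. Whether any real screened clone
  contained several elements is unknown; the naive/Poisson gap brackets
  the answer rather than resolving it.
* `copies_confidence_interval()` propagates a Clopper–Pearson exact
  interval on `k/n` through the chosen estimator; both estimators are
  monotone in the proportion, so endpoint propagation is exact.

Two caveats surfaced by the end-to-end tests: a clone is scored positive
only when it *fully contains* an element, so the effective clone size is
smaller than nominal by about one element length (a −3% bias at 10 kb
clones); and because a single simulated genome's planted positions carry
a few percent of coverage noise that `−ln(1−p)` amplifies at high
occupancy, the recovery test averages three replicate genomes at
moderate occupancy (λ ≈ 0.5) rather than relying on one realization.

## Local structure and genotyping

`reconstruct_preinsertion()` excises `[start − 2, end)` — the element
plus one TSD copy — after verifying both TAs; by construction it exactly
inverts `plant_insertions()`. Which TA copy was ancestral after excision
is unknowable, and for a TA duplication the resulting string is identical
either way.

`detect_nested()` re-runs the structural scanner inside a mined element,
once per candidate TSD (`TA`, plus `TTA` for Tourist-like elements), and
rejects inner spans that touch the outer TIRs. Each inner hit is
reported with the outer sequence reconstructed to its pre-nesting state.

`classify_locus_variant()` anchors the observed haplotype with 30 bp
anchors taken at the *outer ends* of the reference flanks (≥ 90%
identity required; junction-adjacent anchors would be destroyed by the
very footprints and clustered insertions being classified), then decides
from the structural scan plus the length offset `d` relative to the
reconstructed empty site:

| observation | class |
|---|---|
| ≥ 2 structural candidates | `clustered` |
| one candidate ≥ 90% of element length and `d ≈ L + 2` | `occupied` |
| one candidate ≥ 20 bp short of the element | `internal_deletion` |
| no candidate, `d = 0` | `empty` |
| no candidate, `1 ≤ |d| ≤ 10` | `footprint` |
| no candidate, `d ≥ 20` | `internal_deletion` |
| anything else | `complex` |

The footprint bound (10 bp) and the internal-deletion threshold (20 bp)
are the package's fixed conventions; the literature gives qualitative
descriptions, not distributions. Alternative occupied alleles carrying
*different* element families at the same position are reported as
`occupied`; family attribution is a downstream classification step, not
a genotype class.

`insilico_pcr()` finds primer binding sites on both strands (mismatch
budget 2, 3'-terminal 3 bases exact — a standard primer-fidelity proxy;
no mismatch tolerance is published for the original assays) and reports
all convergent pairs within `max_product` (5 kb). Single-primer mode
uses the same primer on both strands, reproducing TIR-anchored
amplification of entire elements. Output is strand-symmetric by
construction.

## Numerical and scale choices

* Coordinates are 0-based half-open everywhere internally; GFF3 export
  is the only 1-based surface.
* All randomness flows through per-operation seeds derived from one
  top-level seed; identical configurations give byte-identical
  artifacts (checked by checksum in the pipeline test).
* Alignment kernels (affine NW, local SW, Nussinov) are compiled; an
  alignment problem above 3×10^7 cells raises an error rather than
  exhausting memory.
* Test problem sizes: mining recall/precision uses ten 500 kb genomes
  with 200 planted copies in total at 5% divergence; classification
  uses 3 families × 8 copies; genotyping uses 5 loci × 40 accessions;
  the alignment oracle comparison uses 50 random pairs ≤ 200 bp. These
  sizes give stable statistics while keeping the default test run fast.

## Known limitations

* The star consensus discards insertions relative to the longest member;
  consensi can be locally short where most members share an insertion.
* `homology_search()` does not model alignment statistics (no e-values)
  and scans one strand.
* The miner requires the terminal motif; a family whose motif has
  diverged beyond the IUPAC pattern supplied is invisible to structural
  mining (homology search remains available).
* The Poisson copy-number model assumes independent random insertion;
  clustered real distributions violate it in the direction of
  undercounting.
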
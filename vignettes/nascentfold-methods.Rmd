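---
title: "Methods: structural analysis of folding pathway intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of folding pathway intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentfold)
```

`nascentfold` analyzes 3D structures of protein folding pathway
intermediates: the time-ordered conformations a chain passes through before
reaching its native structure. This vignette is the package's account of
the models it implements, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## Conformations, pathways, and the catalogue manifest

A *conformation* is one structural state of a (possibly partial) chain:
a tibble of residues (author residue number, one-letter code, Cα
coordinates in Å) carrying the chain metadata — protein id, time index,
conformation label, deposited vs modeled sequence range, native flag — as
attributes. Residue identity is always the author residue number with
inclusive ranges, matching how depositions report ranges such as 1–27;
insertion codes are rejected rather than silently misread. A *pathway* is a
nested tibble of conformations ordered by time index; an intermediate may
hold several conformations (NMR-style ensembles deposit up to three per
nascent-chain state).

Multi-model PDB input goes through `bio3d`; only one chain is read (first
chain by default) because the deposited entries embed the nascent chain in
a ribosome or fusion-partner complex, and chain selection is how those
entities are excluded. Alternate locations resolve to the highest
occupancy, ties broken by altloc letter. The writer emits Cα-trace
ATOM records, with MODEL/ENDMDL blocks for ensembles, at the format's
3-decimal precision — hence the 1e-3 Å round-trip tolerance used in tests.

The packaged manifest (`cotranslational_catalogue()`) is the
machine-readable catalogue of the experimentally determined co-translational
intermediates reported across four studies: 17 conformations over 11
intermediates, six conformations with modeled ranges shorter than deposited
ranges, two of which (PDB ids 70II, 5B3Y) are excluded for major
discrepancies, leaving 15 conformations over 10 intermediates. Per-conformation
ids that are not public in the main record are synthetic placeholders
(9AX1…), and the file is named accordingly. One catalogued pathway has its
native structure at the *first* time index (a folded domain deposited
before a longer ribosome-bound construct), so pathway validation treats
"native not last" as a warning with a recorded flag, not an error.

## TM-score superposition

Similarity between conformations is the Template Modeling score over their
shared residues, mapped by author residue number (never positionally):

$$\mathrm{TM} = \max \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0(L) = \max\{0.5,\ 1.24 (L-15)^{1/3} - 1.8\}\ \text{Å}.$$

The maximum is over rigid superpositions. The search runs a Kabsch fit on
the full mapped set and on contiguous fragments of lengths n, n/2, n/4 at
every offset; each fit is refined by re-superposing on residues within an
inclusion cutoff until the included set is stable (at most 20 iterations).
Numerical choices:

* **Inclusion cutoffs.** Refinement runs at `max(d0, 4.5)` Å and, in
  addition, at tighter d0-scale cutoffs (`max(d0, 2)` and `d0`). The
  conventional 4.5 Å floor alone is too coarse when `d0` sits at its 0.5 Å
  floor (short fragments): the score is then dominated by a few
  sub-Ångström pairs that a 4.5 Å-refined superposition never tightens.
  A final "closest-m" sweep re-superposes on the m best-fitting residues
  for every m ≥ 3. With these additions the reported score dominates both
  the plain global Kabsch fit and a 10,000-placement Monte-Carlo oracle on
  small structures (an acceptance property of the engine).
* **Reflections** are always excluded (determinant forced to +1) —
  chirality is physical.
* **d0 floor** at 0.5 Å keeps fragments of L ≤ 21 scorable.
* **Normalization.** Default `common` (number of mapped residues), because
  partial-vs-full nascent-chain comparisons have no conventional target
  length; `target` and `shorter` are provided. For a model covering a
  subset of the target with small distances, target-normalized ≤
  common-normalized; the inequality can invert for large distances when
  the two normalization lengths straddle the d0 floor region (L just above
  21), where $L/d_0(L)^2$ is non-monotone — the package makes no claim
  there.
* **Bands.** < 0.17 random-like, (0.17, 0.3] intermediate zone, (0.3, 0.5]
  significant, > 0.5 same fold; 0.5 itself belongs to the lower band since
  only scores *above* 0.5 indicate the same fold.

Sequence-order-independent alignment (unknown correspondences) is out of
scope; mapping is always by residue number.

## Proxy co-translational intermediates

A protein's proxy intermediates are the prefix substructures of its native
structure at lengths k, 2k, …, ending exactly at the full length. k = 5
residues by default, mimicking the addition of individual secondary
structure elements during translation. Coordinates are copied unchanged —
proxies deliberately capture no conformational dynamics, which is what
makes them a useful *baseline*: any pathway whose across-time TM-scores are
all exactly 1 is proxy-like rather than genuinely dynamic, a differential
the test suite exploits. Prefixes run over modeled residues in order, so a
native with unmodeled gaps still yields well-formed proxies. Experimental
conformations match to the proxy of closest length (ties to the longer
proxy), since experimental modeled ranges rarely align to multiples of k.

## Protein structure networks and graphlet features

A PSN has amino-acid nodes and edges between residues "close enough" in
3D. The default contact rule is Cα–Cα ≤ 6.0 Å with all non-self pairs
eligible — a common PSN convention, configurable (`psn_params()`), with an
any-atom rule (≤ 4.0 Å) for full-atom records. A dynamic PSN is the ordered
sequence of snapshots along a pathway; snapshots of proxy-derived pathways
are provably nested (node and edge sets grow monotonically), which is
validated and recorded rather than assumed.

Features are counts of the 9 connected induced graphlets on 2–4 nodes
(edge, 2-path, triangle, 3-path, 3-star, 4-cycle, tailed triangle, diamond,
4-clique). Counting is exact, via adjacency-matrix combinatorics:
non-induced pattern counts from degree, triangle and common-neighbour sums
plus trace(A⁴), converted to induced counts by inclusion–exclusion over the
4-node superpattern lattice. Tests verify the implementation against
exhaustive subset enumeration (all C(n,2)+C(n,3)+C(n,4) subsets, n ≤ 12),
against closed forms on complete graphs, stars and paths, and against an
independent igraph motif census. Limiting graphlets to 2–4 nodes keeps the
exhaustive oracle tractable; 5-node graphlets and orbit (graphlet-degree)
decompositions are out of scope, and the dynamic feature defined here is
this package's own per-snapshot scheme, documented as such:

* per-bin graphlet frequencies: snapshots are resampled to `n_bins`
  (default 10) time bins by nearest position — graphs are selected, never
  interpolated — normalizing pathway length;
* a 9-entry arrival histogram: the normalized snapshot t/n at which each
  graphlet class first appears (1.0 if never).

Total length 9·n_bins + 9. A snapshot with no graphlets contributes an
all-zero frequency vector rather than NaNs.

## Static-vs-dynamic classification

The comparison experiment assigns each pathway two feature vectors — static
graphlet frequencies of its final (native) snapshot, and dynamic features
of the whole pathway — and classifies both with an L2-regularized logistic
regression (ridge, one-vs-rest beyond two classes; `glmnet` with
λ = 1/n_train, the λ that matches a unit-strength L2 penalty). Stratified
5-fold cross-validation uses *identical* fold splits and seed for both
modes, so accuracy differences are attributable to the dynamic information
alone; a paired sign test across folds accompanies the reports. Features
are standardized to zero mean and unit variance using training-fold
statistics only; all-constant feature sets fall back to majority-class
prediction (an empty design is unfittable, and majority vote is the
correct degenerate behaviour). Everything is deterministic given the seed.

## Folding-kinetics statistics

**Contact order** is the mean |i − j| over contacting residue pairs
(default Cα ≤ 6.0 Å, |i − j| ≥ 2 to exclude backbone neighbours), with the
relative form divided by chain length. Zero contacts yield NA markers, not
numbers.

**Two-state fraction.** Given pathways, a native structure and labelled
secondary-structure-element (SSE) ranges (annotations are inputs; no
assignment algorithm is bundled), the package records for every SSE pair
with at least one native inter-SSE contact the first snapshot at which at
least half (`formation_fraction = 0.5`) of its native contacts are present.
A pathway is two-state when the spread of formation times is at most
`window = 1` snapshot — "around the same time" made operational; both
values are explicit parameters because the qualitative criterion they
implement has no canonical quantitative form. A pair that never forms is
assigned time n+1 (past the end), making never-forming pairs count against
two-state behaviour. Pairs without native contacts are excluded and logged;
with fewer than two informative pairs the criterion is degenerate and a
warning says so. The two-state fraction is the share of two-state pathways
and is invariant to pathway order and duplication.

## The synthetic generators

The generators stand in for deposited structures in all tests, so their
defaults are fixed study conditions, not tuning knobs:

* `make_helix()`: ideal α-helical spiral — radius 2.30 Å, rise 1.50
  Å/residue, 100°/residue (consecutive Cα distance 3.83 Å). Helices give
  contact-dense, triangle-rich PSNs.
* `make_strand()`: extended zigzag, rise 3.50 Å/residue, with the zigzag
  half-amplitude (0.7395 Å) chosen so consecutive Cα distances are exactly
  3.80 Å — local chain geometry is the constraint that matters, and a
  1.0 Å offset would break the 3.8 ± 0.1 Å virtual-bond length that all
  generators guarantee. Strands give sparse, path-like PSNs.
* `make_coil(seed)`: self-avoiding random walk, 3.8 Å steps, bend angles
  20–100°, non-consecutive pairs kept ≥ 3.4 Å apart (with backtracking).
* `make_hinged()`: rotates the chain tail about the local chain axis
  through a hinge residue. Hinges model fold-level conformational change
  between time points while preserving local geometry exactly — matching
  the observation that a nascent subsequence can change its fold (TM < 0.5)
  between consecutive intermediates, which isotropic noise cannot emulate
  without destroying local structure.
* `simulate_cotranslational_pathway()`: prefixes at the proxy schedule with
  a persistent hinge inside the first translated segment whose angle,
  `per_step × (n − t)`, decays to zero — the earlier subsequence relaxes
  toward its native conformation as translation proceeds, divergence
  between two snapshots grows with their time distance, the final
  intermediate is exactly the native, and a zero magnitude reduces
  bit-identically to the proxy pathway (the reduction is itself a test).
* `make_classification_dataset()`: `order_only` classes share one final
  structure — an asymmetric native, helix-dense N-half and strand-sparse
  C-half — and differ only in which half folds first (the unfolded half is
  held extended); `topology` classes differ in final contact topology
  (helix vs antiparallel hairpin ladder). Per-item jitter is σ = 0.3 Å.
  Balanced labels; 50 pathways per class by default, chain length 40,
  8 snapshots.

All generators are pure functions of parameters and seed (no global RNG
state is touched). What they deliberately do **not** emulate: side chains,
real amino-acid sequences, ribosome/tunnel geometry, chaperones, energetics
or any physically realistic folding simulation. Passing tests therefore
demonstrate the correctness of the *measures and pipelines* on structures
with realistic local geometry and controllable global change — not that
any biological claim about real intermediates is reproduced from real data.

## Problem sizes and determinism

The shipped tests and the acceptance script use chain lengths 12–120,
classification datasets of 15 pathways per class over 10 seeds, 100 random
motions / 100 random graphs for invariance and oracle checks, and a
10,000-placement Monte-Carlo oracle on 12-residue structures — sizes chosen
so the full suite completes in roughly two minutes on one CPU while every
oracle remains exhaustive or statistically stable. Every stochastic step
takes an explicit integer seed; reported quantities are reproducible
bit-for-bit for a given seed.

## Known limitations

* TM-scores are computed over residue-number correspondences; structures
  renumbered inconsistently across depositions must be harmonized upstream.
* The dynamic-graphlet feature scheme is a package-specific stand-in for
  richer temporal graphlet formalisms (orbit-resolved, 5-node); it is
  sufficient for the order-vs-topology differential but not a
  reimplementation of those formalisms.
* The two post-translational studies' accession ids are not part of the
  packaged catalogue (they are not public in the main record); the manifest
  schema accepts them as user-supplied rows.
* Proxy intermediates inherit every limitation discussed above by design:
  they contain no dynamics, and results based on them measure what static
  native structure plus growth ordering can explain — nothing more.
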
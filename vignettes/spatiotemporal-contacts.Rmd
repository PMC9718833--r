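---
title: "Spatiotemporal analysis of GPCR-G protein interface contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal analysis of GPCR-G protein interface contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcontacts)
```

## The problem

G protein-coupled receptors (GPCRs) transduce signals by coupling to
heterotrimeric G proteins, whose Galpha subunit (Gs, Gi, Gq, G12/13)
determines the downstream pathway. Receptors range from strictly selective
to broadly promiscuous in which Galpha subfamilies they activate. Static
co-complex structures have not yielded a receptor-side sequence code for
this selectivity: the receptor surface is too divergent. The premise of
this package is that selectivity is *spatiotemporal* — it lives not only in
*which* receptor-Galpha residue contacts form, but in *how persistently*
each contact is sampled over a dynamical ensemble.

`stcontacts` implements that analysis as a reusable pipeline:

1. **Contact detection** — per-frame sidechain-sidechain contacts between
   the receptor and Galpha selections of a trajectory, by five geometric
   criteria.
2. **Fingerprints** — one-hot encoding of contacts per frame, keyed by
   generic residue numbers so different receptors share a feature space.
3. **Persistence taxonomy** — per-system contact frequencies, and the
   partition into subfamily-specific and common contacts.
4. **Selectivity code** — a linear discriminant model over fingerprints,
   a composite weight-frequency score per contact, and the top-k
   "spatiotemporal code" per Galpha class.
5. **Promiscuity index** — a weighted multi-dataset summary of coupling
   tables, independent of the structural pipeline.

A synthetic-data module generates toy 3-D complexes and class-structured
fingerprints so every stage is testable without external downloads.

## Contact detection

Contacts are evaluated between the sidechain atoms of two disjoint residue
selections ("gpcr", "galpha"), assigned by chain. Backbone atoms
(N, CA, C, O, OXT and backbone hydrogens) are excluded so that contacts
reflect sequence-specific chemistry. Five criteria are applied per frame,
all with *strict* inequalities:

| type | criterion | default |
|------|-----------|---------|
| SB   | anion-cation distance | < 4.0 Å |
| HB   | donor-acceptor distance, and D→H / D→A angle when hydrogens exist | < 3.5 Å, < 70° |
| VDW  | distance < r_i + r_j + slack | slack 0.5 Å |
| PS   | ring-centroid distance and ring-normal angle (folded to [0°, 90°]) | < 7.0 Å, < 30° |
| PC   | cation-centroid distance and normal-to-cation angle (folded) | < 6.0 Å, < 60° |

Notes on the open choices:

* **Van der Waals rule.** The criterion is the widely used
  radius-sum-plus-slack convention with an element radius table
  (C 1.70, N 1.55, O 1.52, S 1.80 Å, ...) and a configurable 0.5 Å slack.
* **Hydrogen bonds.** Analysis frames may or may not carry hydrogens.
  When any hydrogen is present in the topology the angular criterion is
  applied using hydrogens found within 1.25 Å of the donor heavy atom;
  otherwise the distance criterion alone applies. The mode used is recorded
  in the timeline metadata (`hbond_mode`).
* **Histidine.** His ND1/NE2 are excluded from the cation set by default
  (protonation is ambiguous); `contact_criteria(his_cation = TRUE)`
  restores them. His participates in the aromatic ring set regardless.
* **Ring normals** are defined as the least-squares plane normal of the
  ring atoms and treated as unsigned axes, so a flipped ring stacks
  identically.
* **Prefilter.** Residue pairs whose sidechain centroids are ≥ 12 Å apart
  are skipped. With all distance cutoffs ≤ 7 Å and sidechain extents of a
  few Å this is lossless; it is also verified against an all-pairs
  evaluation in the test suite, and can be disabled (`prefilter = Inf`).
* Multiple criteria satisfied by one residue pair in one frame are all
  recorded in the timeline but collapse to a single binary event at the
  fingerprint level — the downstream code is pair-level, not type-level.

Generic numbering (GPCRdb `3x53`-style for receptors, CGN `G.H5.16`-style
for Galpha) is consumed from user-supplied TSV maps, never computed from
structure; residues absent from the map are excluded from fingerprinting
and tallied. Residue identity is `(chain, resnum)`; insertion codes are
rejected. Frames are 0-indexed and windows are half-open `[start, end)`,
applied per replicate file before concatenation — the convention for
keeping the terminal window of each replicate.

## Fingerprints and the persistence taxonomy

The pair universe is the lexicographically ordered union of observed
contact pairs across systems, optionally filtered to receptor positions
resolved in *every* system (so no class is credited with a contact another
class's structure could not form). Encoding sets entry (frame, pair) to 1
iff any contact type links the pair in that frame. Per-system frequencies
are exact column means.

A pair is *persistent in a class* when its frequency exceeds 0.20
(strictly) in at least one system of that class. Pairs persistent in
exactly one class are subfamily-specific; pairs persistent in all three
simulated classes (Gs, Gi, Gq) are common; everything else is "other",
sub-labelled `two-family` or `never-persistent` — the two-family pairs
matter because several code contacts are of this kind. The 20% threshold
corresponds to tens to hundreds of nanoseconds of a microsecond-scale
ensemble, long enough to exclude transient encounters.

## The discriminant model and the spatiotemporal code

Frames are labelled by the Galpha class of their system and a 3-class
linear discriminant model is fitted on the binary matrix (SVD route,
`MASS::lda` underneath). Columns constant within every class carry no
discriminant information and are excluded from the fit (their weights
report as 0). The two discriminant components carry explained-variance
ratios summing to 1, and scalings are deterministically signed (first
nonzero loading positive) so projections are reproducible run to run.

Per-class weight vectors use the centered class-mean convention

  w_X = S Sᵀ (μ_X − x̄),  b_X = −½‖Sᵀ(μ_X − x̄)‖² + log π_X,

with S the whitening scaling matrix, μ_X the class mean, x̄ the
prior-weighted grand mean and π_X the class prior (empirical by default).
`argmax_X wᵀ_X (x − x̄) + b_X` reproduces the Gaussian equal-covariance
decision rule, which is verified against the reference implementation in
the tests. These w_X are the feature-ranking weights.

The composite score combines spatial importance and temporal persistence:
for class X and pair p,

  cGx(p) = mean frequency of p over X's systems,
  wGx(p) = w_X(p) · cGx(p).

The plain product is the minimal reading of "composite weight"; ranks are
assigned per class by descending wGx with ties broken by larger |w_X| then
pair key. The *spatiotemporal code* is the top-10 pairs per class,
annotated with persistence labels and (optionally) presence in the
starting structures. Projection of external fingerprints aligns the
universe first — missing pairs imputed 0, novel pairs dropped, both
tallied — because a new system carries no weight for contacts the model
never saw.

The 80:20 holdout is seeded and stratified by system. A generic
position-subset mean comparison (`compare_position_subsets`) supports
downstream analyses of the code positions, e.g. population-variant
frequencies at code positions versus the rest of the receptor.

## Promiscuity index

Coupling categories map to numeric scores (primary 1, secondary 0.5,
none 0). Emax-style tables are categorized with primary > 0.8 and
secondary in (0.2, 0.8]; boundary values fall to the lower category, per
the strict printed inequalities. The per-dataset index is the mean score
over the four Galpha subfamilies — a subfamily a dataset never measured
counts as 0, keeping the four-subfamily denominator. Dataset weights
reflect how directly coupling was measured: direct BRET activation 4,
curated literature 2, chimeric-Gq assay 1. The composite is the mean of
the weighted indices over the datasets covering the receptor (0 ≤
composite ≤ 4); including absent datasets as zeros is available behind
`missing_as_zero = TRUE` for sensitivity analyses.

## The synthetic generators, and what passing tests show

`generate_fingerprints()` draws every entry independently Bernoulli with
class-dependent occupancies. The defaults are the study conditions used
throughout the tests and the acceptance script: 3 classes × 2 systems ×
500 frames; 6 common pairs at 0.6 everywhere; 3 specific pairs per class
at 0.6 in their own class and 0.02 elsewhere; 40 background pairs at 0.05.
These occupancies sit where the persistence threshold is unambiguous
(0.6 ≫ 0.2 ≫ 0.05 in expectation at n = 500) while leaving genuine
sampling noise.

Frames are temporally i.i.d. — a deliberate simplification of MD frames,
which are autocorrelated. Persistence classification and the discriminant
statistics depend only on marginal occupancies, so the simplification does
not weaken those checks; what passing tests do *not* show is behaviour
under correlated frames, force-field realism, or contact cooperativity.

Two LDA checks need different conditions and use a documented variant:

* At the default occupancies a frame of class X shows *no* X-specific
  contact with probability 0.4³ = 6.4%, and such frames are genuinely
  ambiguous — frame-level accuracy saturates near 95%, for the
  nearest-class-mean rule as well. The "separable data classifies
  perfectly" check therefore uses `p_specific_own = 1.0` (class-specific
  contacts deterministically present in their own class), which makes
  class membership decidable per frame.
* The chance-level check permutes labels at the default occupancies
  (n = 3000 frames) and expects holdout accuracy within 0.05 of 1/3.

`generate_toy_complex()` builds two-chain structures from idealized
residue templates (literature-ish bond lengths, planar rings; no rotamer
library), with the functional atom — charged atom, hydroxyl oxygen, or
ring centroid — as the placement anchor, optional rotation, per-frame
Gaussian jitter, and an overlap guard (< 1 Å rejects). Writing the frames
as a multi-model PDB and re-reading them reproduces detection results to
coordinate precision.

## Numerical choices and degenerate inputs

* All cutoffs strict; plane/axis angles folded into [0°, 90°].
* Percentage reporting rounds half-up to one decimal (so SSE compositions
  sum to 100 ± 0.1 after rounding).
* Empty frame windows, empty selections, duplicate residue keys, unknown
  subfamily labels, single-class fits and all-constant feature matrices
  raise immediate, stage-tagged errors rather than propagating NA.
* Every stochastic step (generators, splits, jitter) is driven by an
  explicit seed; identical inputs and seeds give byte-identical outputs,
  which the pipeline test verifies on its model JSON.

## Problem sizes

The bundled analyses and tests run on desk-scale inputs chosen to exercise
every code path: toy complexes of 2-10 residues over 3-200 frames,
synthetic fingerprint sets of 3000 frames × 55 pairs, and 20 replicate
generations for the code-recovery property. The same functions operate
unchanged on real topologies (multi-model PDB or DCD frames against a PDB
topology) and deposited fingerprint/frequency tables.

## Known limitations

* XTC trajectories are not read directly; convert to DCD or multi-model
  PDB first.
* Water-mediated, backbone and intra-chain contacts, and Gbetagamma
  contacts, are out of scope by design.
* The donor/acceptor/cation atom tables cover the 20 standard amino
  acids' sidechains; modified residues are treated as VDW-only bodies.
* Generic-number assignment is consumed, never computed: a numbering map
  is required for cross-receptor feature spaces.
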
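# stcontacts

Spatiotemporal analysis of GPCR–G protein interface contacts in R.

G protein-coupled receptors (GPCRs) select among Gα subfamilies (Gs, Gi,
Gq, G12/13) with anything from strict selectivity to broad promiscuity,
and static co-complex structures have not produced a receptor-side
sequence code for that choice. `stcontacts` implements the
dynamics-based alternative: score every receptor–Gα residue contact by
*where* it sits (spatial, via generic residue numbers) and *how
persistently* it is sampled across trajectory frames (temporal), then let
a discriminant model rank contacts by how well they separate Gα classes.

It is aimed at structural bioinformaticians working with MD ensembles of
receptor–Gα complexes (or with deposited per-frame fingerprint /
contact-frequency tables) who want a tested, scriptable version of this
analysis.

## What it computes

- **Per-frame contacts** between the receptor and Gα sidechains, by five
  geometric criteria with strict cutoffs: salt bridge (< 4.0 Å),
  hydrogen bond (< 3.5 Å and < 70° when hydrogens are present), van der
  Waals (< r_i + r_j + 0.5 Å), π-stacking (< 7.0 Å, normals < 30°),
  cation-π (< 6.0 Å, < 60°).
- **Binary fingerprints**: frames × contact-pairs matrices keyed
  `"3x53:G.H5.19"` (GPCRdb : common-G-protein-numbering), so different
  receptors share one feature space.
- **Persistence taxonomy**: a contact is *persistent* in a class when its
  frequency exceeds 20% in at least one of that class's systems;
  persistent in exactly one class ⇒ *subfamily-specific*, in all three ⇒
  *common*.
- **Spatiotemporal code**: a 3-class linear discriminant fit on the
  fingerprints gives per-class weight vectors w_X; the composite score
  wGx(p) = w_X(p) · cGx(p), with cGx the mean class frequency, ranks
  contacts; the top-10 per class is the code. New systems can be
  projected into the discriminant plane and classified.
- **Promiscuity index**: coupling categories (primary/secondary/none →
  1/0.5/0) from up to three dataset dialects are averaged over the four
  Gα subfamilies, weighted by assay directness (4/2/1), and combined into
  a composite in [0, 4].

A synthetic-data module generates toy 3-D complexes (idealized residue
templates, seeded jitter) and class-structured Bernoulli fingerprints
with planted common/specific contacts, so the full pipeline runs and is
tested without any downloads.

## Worked example

The numbered scripts under `analysis/` run the pipeline on generated
data. Stage 2 + 3 on the planted synthetic fingerprints
(`Rscript analysis/02_fingerprints_persistence.R`,
`Rscript analysis/03_selectivity_code.R`) print:

```
Persistence taxonomy (>20% frequency in >=1 system of a class):
     common       other specific-Gi specific-Gq specific-Gs
          6          40           3           3           3
Planted labels recovered: 100.0%

Holdout accuracy (80:20 split): 92.00%
Explained variance: component 1 51.35%, component 2 48.65%
 class rank         pair      wGx   cGx persistence_label
    Gs    1 1x41:G.H5.08 2.681949 0.600       specific-Gs
    Gi    1 5x41:G.H5.12 2.595607 0.597       specific-Gi
    Gq    1 7x41:G.H5.14 2.692584 0.627       specific-Gq
Gs: 3/3 planted specific pairs in the top-10 code
```

The taxonomy recovers exactly the planted 6 common and 3-per-class
specific pairs; the code ranks every planted specific pair at the top of
its own class (wGx is the discriminant weight times the 0.6 planted
occupancy); holdout accuracy sits near the ceiling set by frames that
happen to show no class-specific contact. Stage 4 scores the bundled
*synthetic* coupling tables:

```
 receptor idx_avet idx_gtp idx_inoue composite n_datasets
   BDKRB2    1.000   0.750     1.000     2.167          3
   P2RY12    0.250   0.250     0.375     0.625          3
```

— the pan-subfamily coupler scores high, the Gi-selective receptor low.

Or run the whole thing from one config with
`run_pipeline("run.yaml")`, which writes timelines, fingerprints,
frequencies, persistence labels, the model JSON, scores, the code table
and a manifest.

## Layout

- `R/` — the implementation (I/O, detection, fingerprints, discriminant
  code, promiscuity, generators, pipeline)
- `analysis/` — numbered narrative drivers writing under `results/`
- `tests/testthat/` — unit, property and end-to-end suites, including an
  independent brute-force contact oracle
- `vignettes/spatiotemporal-contacts.Rmd` — the methods vignette
- `inst/extdata/` — small synthetic coupling tables (see
  `README_extdata.txt`)
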
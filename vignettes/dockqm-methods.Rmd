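---
title: "Docking-based quantitative matrices for HLA-DQ peptide binding: methods and design"
author: "dockQM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-based quantitative matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockQM)
```

## The problem

HLA-DQ2.5 and HLA-DQ8.1 are the MHC class II molecules that confer genetic
risk of celiac disease: they present gluten-derived peptides to CD4+ T cells.
The class II groove is open at both ends; a nine-residue binding core
(`p1..p9`) sits in the groove, with flanking residues (`p0`, `p10`, and for
longer peptides `p-1`, `p11`) extending beyond it. Anchor positions p1, p4,
p6, p7 and p9 contact polymorphic pockets whose chemistry determines which
residues are tolerated.

dockQM implements a docking-based route to a position-specific scoring model
for these molecules. A combinatorial peptide library is built from a
structurally characterized parent peptide by single amino acid substitution
(SAAS, "one peptide – one substitution"); every library member is assigned a
best docking affinity (kcal/mol, more negative = stronger); and the
affinities are normalized into a **quantitative matrix** (QM) of per-position,
per-residue contribution coefficients. A peptide's predicted binding score is
then the *sum* of its core residues' coefficients, which makes screening
whole proteomes a table-lookup exercise.

## The SAAS library

For a parent of length 11 with all eleven positions (`p0..p10`) open to
substitution, each position is replaced in turn by the 19 alternative amino
acids, giving `19 × 11 + 1 = 210` peptides including the parent. A 13-mer
parent whose terminal `p-1`/`p11` residues are held fixed yields the same 210.
All 20 residues, including cysteine, participate in substitutions. Variant
order (position, then alphabetical residue) and ids
(`<parent>_<position><aa>`, parent `<parent>_wt`) are deterministic so that
score tables are stable across runs.

## From affinities to a matrix

Let `N` be the *normalization set*: the parent plus all variants substituted
within the matrix's coverage — `p1..p9` (parent + 171) for the core-normalized
nonamer matrix, `p0..p10` (parent + 209) for the whole-peptide endecamer
matrix. With `μ` the mean best affinity over `N`, the coefficient of residue
`a` at position `L` is

$$c(L,a) \;=\; \frac{s(L,a)}{\mu} \;-\; 1,$$

where `s(L,a)` is the best affinity of the variant carrying `a` at `L`, and
the parent's affinity for the parent residue at each position. The exact form
of "mean-normalization" is a design choice of this package; this form was
chosen because, with negative affinities, it maps stronger-than-average
binders to *positive* coefficients (matching the field's sign convention for
QM coefficients) and produces magnitudes on the familiar ±0.1…±0.7 scale.
Two properties follow algebraically and are enforced by tests:

* the coefficients over `N` average exactly zero (to ~1e-16);
* the matrix is invariant under rescaling all affinities by a positive
  constant, and within a position coefficients are a strictly decreasing
  affine function of affinity (slope `1/μ < 0`).

Two caveats are documented rather than hidden. First, the parent residue's
coefficient reuses the single parent affinity and is therefore numerically
identical at every position — an artefact of all SAAS designs. Second, an
additive shift of all affinities changes coefficients by the factor
`μ/(μ+c)`; the matrix is scale-free but not offset-free, which is why `μ` is
stored in the QM metadata. Whether the core-mode `μ` should include
flank-substituted variants is genuinely open; this package excludes them,
pairing each normalization span with its own matrix coverage, and records
`μ` so users can remap scores.

Alternative normalizations (`μ − s`, z-scoring) were considered and rejected
as defaults: the first changes units with library depth, the second distorts
relative magnitudes between positions; both break the "sum of dimensionless
contributions" reading of peptide scores.

## Scoring peptides and proteomes

A peptide of length `L ≥ 9` admits `L − 8` placements of the binding core;
each register is scored additively (`p0`/`p10` terms included when the matrix
covers them and the peptide provides them; a flank missing at a terminus
contributes 0) and the **maximum** over registers is reported, ties going to
the smallest offset. Max-over-registers is the natural test-time rule for a
model trained on a fixed register, and is what the validation and screening
code use throughout. The binder call is inclusive, `score ≥ cutoff`, fixed
once and used everywhere. Windows containing non-standard residues (X, B, Z,
U) are skipped and counted, never imputed.

## Validation: decoys and the cutoff scan

Non-binder decoys are random combinations of *non-preferred* residues
(coefficient < 0) at all nine core positions; flank residues, where a longer
decoy is requested, are uniform over the full alphabet. Because every core
term is strictly negative, a threshold-0 decoy scores below 0 by
construction, which guarantees binder/decoy separation for noise-free
synthetic constructions and makes the end-to-end 100%-accuracy property a
sharp test of the whole pipeline rather than a statistical accident.

Sensitivity (% binders called), specificity (% non-binders called) and
accuracy (% all called) are evaluated on a cutoff grid from −0.5 to +0.5 in
steps of 0.1 — grid values are built from integer multiples of the step, so
the printed cutoffs are exact decimals, not accumulated floats. The selected
cutoff maximizes accuracy; ties break to the lowest cutoff, then to the
highest sensitivity (the tie-break is a package convention). Percentages are
stored at full precision and conventionally printed as whole percent;
rounding is half-up via R's `round()`. A single-class set yields `NA` for the
undefined metric, never a silent 0.

## The synthetic docking simulator

Real docking engines are deliberately out of scope: the package parses their
output but never invokes them. In their place, a planted additive energy
model generates affinities: `affinity = base + Σ delta(L, residue) + ε`, with
per-position increments `delta` drawn i.i.d. uniform on ±`delta_spread_kcal`
and `ε ~ N(0, noise_sd_kcal²)` from a seeded stream. Defaults — base −7.0
kcal/mol, spread 1.0 kcal/mol — echo typical peptide–MHC docking magnitudes;
uniform (not Gaussian) increments keep preferred and non-preferred residues
bounded away from each other, which the decoy construction relies on. One
seeded stream per simulation run, with peptides in library order, makes score
tables byte-identical across platforms, and all simulator entry points
restore the caller's RNG state.

When a `reference` peptide is supplied to `sample_ground_truth()`, the
increment of the reference residue at each position is pinned to 0, i.e. the
deltas are substitution energies relative to the parent composition — the
standard reference-state convention of mutational scans. The demonstration
pipeline uses this convention because it keeps the parent away from the
per-position extremes, so every core position retains both preferred and
non-preferred residues for any seed; with fully i.i.d. increments the parent
residue is the per-position optimum with probability 1/20 per position,
which can empty a position's preferred set and is a legitimate (if
inconvenient) draw users of the i.i.d. default should anticipate.

What the simulator does *not* emulate: pose geometry, backbone-conformation
coupling between positions (the mechanism by which rigid poly-proline
gliadin backbones and flexible non-gliadin backbones produce different
residue preferences), epistasis between substitutions, and deamidation.
Passing the synthetic suite therefore demonstrates that the estimator
recovers an additive signal from docking-shaped data — it does not
demonstrate that real docking scores *are* additive, which is an assumption
inherited from the SAAS design itself.

## Parameter recovery and what the tests show

With zero noise the fitted coefficients are affine in the planted increments,
so Spearman rank correlation between them is exactly −1 at every position
(negative because lower energy = stronger binding = higher coefficient). With
noise sd 0.1 kcal/mol against spread 1.0 the worst-position |rank
correlation| stays ≥ 0.9 in the seed-fixed test runs. The end-to-end check
plants a model, rebuilds the QM, draws binders from positive-coefficient
residues and decoys from negative ones, and requires a grid point with 100%
sensitivity, specificity and accuracy.

Problem sizes used by the test suite and the acceptance script — 210-member
libraries, 100 random 9–25-mers for the scoring oracle, 50 random score sets
for metric monotonicity, 4249 binders and 4249 decoys for the end-to-end
scan — were chosen to mirror the workflow's natural scales while keeping a
full run in seconds.

## Known limitations

* Accuracy figures from synthetic data say nothing about accuracy on
  experimentally eluted peptide sets; validating against such sets requires
  the external data and docking runs this package does not ship.
* The additive model ignores inter-position coupling; peptides whose binding
  mode depends on backbone strain are exactly the cases where a single-parent
  QM is least transferable.
* Deamidation (Q→E editing by transglutaminase 2), digestion and peptide
  length preferences are not modelled; screening operates on the literal
  input sequence.
* A QM inherits its parent's backbone: matrices from a rigid gliadin parent
  and a flexible non-gliadin parent can disagree strongly at some positions
  (`compare_qms()` exists precisely to quantify this), so screening novel
  proteins is best done with matrices from more than one parent.
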
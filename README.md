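# dockQM

Position-specific **quantitative matrices (QMs)** for predicting peptide
binding to the celiac-disease risk molecules **HLA-DQ2.5** and **HLA-DQ8.1**,
derived from molecular-docking affinities of combinatorial peptide libraries.

Gluten-derived peptides presented by HLA-DQ2.5/DQ8.1 drive the CD4+ T-cell
response of celiac disease, and regulatory assessment of novel food proteins
asks whether they could yield such binders. Experimental binding assays do
not scale to whole proteomes; a docking-derived scoring matrix does. dockQM
is aimed at computational immunologists and protein risk assessors who want
to go from a structurally characterized peptide–HLA-DQ complex to a
proteome-screenable binding model, with every step scripted and reproducible.

## Method

1. **SAAS library.** From a parent peptide bound in a known structure (e.g.
   the α-gliadin 11-mer `QPFPQPELPYP` in HLA-DQ2.5), every open position is
   substituted in turn by the 19 alternative amino acids — "one peptide, one
   substitution" — giving 19 × 11 + 1 = **210** peptides for an 11-mer.
   Positions follow the class II register notation: binding core `p1..p9`,
   flanks `p0`/`p10` (and `p-1`/`p11`, held fixed for the 13-mer HLA-DQ8.1
   parent `SGEGSFQPSQENP`).
2. **Affinities.** Each library member gets one best docking affinity *s* in
   kcal/mol — parsed from docking logs (with energy-range pose filtering), read
   from a CSV score table, or produced by the built-in seeded simulator, which
   plants an additive per-position energy model plus Gaussian noise.
3. **Quantitative matrix.** With μ the mean affinity over the normalization
   set (parent + all variants within the matrix's coverage), the contribution
   coefficient of residue *a* at position *L* is

   *c(L, a) = s(L, a) / μ − 1*

   Positive coefficients mark preferred residues (stronger than average),
   negative non-preferred; coefficients average exactly 0 over the
   normalization set. Core mode covers `p1..p9` (nonamer QM), whole-peptide
   mode `p0..p10` (endecamer QM).
4. **Screening & validation.** A peptide's score is the sum of its core
   residues' coefficients, maximized over all L − 8 core registers; proteins
   are screened window-by-window from FASTA. Non-binder decoys are random
   combinations of non-preferred residues at all nine core positions, and a
   cutoff scan over −0.5…+0.5 (step 0.1) reports sensitivity, specificity and
   accuracy, selecting the most accurate cutoff.

## Worked example

```r
library(dockQM)

parent <- parent_peptide("QPFPQPELPYP", core_start = 1, id = "aglia")
lib <- build_saas_library(parent)
lib
#> SAAS combinatorial library from parent 'aglia'
#>   210 peptides (11 mutable positions x 19 + parent)

# affinities from the synthetic simulator (planted additive model, 0.1
# kcal/mol score noise); swap in read_score_table() for real docking output
gt <- sample_ground_truth(paste0("p", 0:10), seed = 42, noise_sd_kcal = 0.1,
                          reference = parent)
scores <- simulate_library_scores(gt, lib)

qm <- build_qm(lib, scores, mode = "core", allele = "HLA-DQ2.5")
summary(qm)
#> QM HLA-DQ2.5 (core): coefficients in [-0.159, 0.172]
#> Anchor-position preferences (top residues):
#>    preferred non_preferred
#> p1 E V K     F C A
#> p4 H Y I     C F T
#> p6 M C V     L R G
#> p7 V A N     D G P
#> p9 P E R     N C F

round(coef(qm)["p4", c("F", "W", "E", "P", "K")], 3)
#>      F      W      E      P      K
#> -0.117 -0.084  0.094 -0.074  0.077
```

The summary lists, per anchor position, the residues the fitted matrix most
prefers (highest coefficients) and most disfavours — here reflecting the
planted synthetic energies, not gluten biology. `coef()` exposes the full
9 × 20 matrix; each number is that residue's additive contribution to a
peptide's score when it occupies the position.

Screen a protein FASTA and validate against synthetic binders/decoys:

```r
fa <- system.file("extdata", "synthetic_proteins.fasta", package = "dockQM")
screen_fasta(qm, fa, cutoff = 0.1)$proteins
#>            protein_id length n_windows n_skipped n_binders best_score best_register
#> 1 synthA_gliadin_like     34        26         0        10  0.4555740            25
#> 2       synthB_random     34        26         0         8  0.4667184             1
#> 3        synthC_withX     28        13         7         4  0.3970490            16

decoys  <- generate_decoys(nonpreferred_from_qm(qm), 300, seed = 7)
binders <- generate_decoys(preferred_from_qm(qm), 300, seed = 8)
cutoff_scan(qm, labelled_set(binders, decoys))
#> Cutoff scan (percentages rounded to whole percent):
#>  cutoff  TP FN  TN FP sensitivity specificity accuracy
#>    -0.5 300  0 253 47         100          84       92
#>    -0.4 300  0 293  7         100          98       99
#>    -0.3 300  0 299  1         100         100      100
#>    -0.2 300  0 300  0         100         100      100
#>    ...
#>     0.5 216 84 300  0          72         100       86
#> Selected cutoff (highest accuracy): -0.2
```

Each scan row is a confusion matrix at one cutoff: at the selected cutoff
every synthetic binder and decoy is classified correctly (windows overlapping
the ambiguous `X` in `synthC` are skipped, not scored). `run_demo(out_dir,
seed)` chains all of the above — library → simulated docking → QM → decoys →
cutoff scan — and writes every artifact with a run summary.

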
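# plddg

Persistent-Laplacian evaluation of predicted protein–protein complexes for
mutation-induced binding free energy (ddG) prediction.

## The problem

Structure predictors (AlphaFold 3 and kin) now produce protein–protein
complexes good enough to feed downstream biophysics, but two questions have
to be answered before trusting them for mutation effects: *how faithful is
the predicted complex to the experimental one*, and *do features computed
from it support quantitative ddG prediction*? `plddg` is a toolkit for both,
aimed at structural bioinformaticians benchmarking predicted complexes
against SKEMPI-style mutation data.

Its layers:

- **Element/site-specific topological features.** Atoms of the mutation
  site, its neighborhood (radius *r*, default 10 Å) and the two
  binding-site subsets are paired with element groups ({C}, {N}, {O} and
  pairs such as C–C, N–O). Cross-set contacts use the modified distance
  `D_mod` (Euclidean across subsets, excluded within a subset). Filtered
  simplicial complexes — Vietoris–Rips for dimension 0, Alpha (Delaunay)
  for dimensions 1–2 — yield combinatorial Laplacians
  `L_k = B_{k+1} B_{k+1}ᵀ + B_kᵀ B_k` (with `L_0 = B_1 B_1ᵀ`), whose
  zero-eigenvalue multiplicity is the Betti number β_k (harmonic spectrum)
  and whose positive eigenvalues (nonharmonic spectrum) add shape
  information. Statistics of both over a filtration grid form the feature
  vector.
- **Structure comparison.** Kabsch superposition RMSD, per-residue backbone
  RMSD under a single global transform, B-factor concordance, ipTM/pTM
  confidence bands (> 0.8 high confidence, < 0.6 likely incorrect), and
  the five-region residue classification (interior / surface / support /
  rim / core) from monomer-vs-complex relative accessible surface area at
  the 25% cutoff (Shrake–Rupley, Tien-2013 normalization).
- **Regression.** Gradient-boosted trees (xgboost) with 10-fold
  cross-validation reporting Pearson R_p and RMSE (kcal/mol), with
  direct/reverse mutation augmentation and optional complex-grouped folds.
- **Synthetic data.** Deterministic generators for toy two-chain
  complexes, flexibility-controlled "predictions", point clouds with known
  Betti signatures, and ddG tables with planted linear signal — the whole
  pipeline runs and is tested without any downloads.

## Worked example

```r
library(plddg)

# a reference complex and a flexibility-perturbed "prediction"
cfg  <- synth_config(n_residues = 30, seed = 42)
ref  <- make_toy_complex(cfg, id = "DEMO")
pred <- perturb_structure(ref, "flexible", amplitude = 0.5, seed = 43)
pred$confidence <- new_confidence_scores(iptm = 0.84, ptm = 0.9)

# compare prediction against reference
report <- per_residue_rmsd(ref, pred)
report
#> alignment_report 'DEMO': global backbone RMSD 1.052 A over 60 residues (0/0 unmapped ref/pred)
classify_confidence(pred$confidence)
#> [1] "high_confidence"
cor(report$per_residue$bfactor, report$per_residue$rmsd, method = "spearman")
#> [1] 0.779

# topological features of a mutation (compact configuration)
fv <- spectral_features(ref, parse_mutation("AA10G"), pl_feature_config_compact())
length(fv)
#> [1] 182
head(attr(fv, "layout")[, c("block", "dim", "n_atoms", "empty")], 3)
#>                          block dim n_atoms empty
#> 1     vr0_site.neighborhood_cc   0      23 FALSE
#> 2     vr0_site.neighborhood_no   0       7 FALSE
#> 3 vr0_p1_binding.p2_binding_cc   0     177 FALSE
```

The global RMSD of ~1 Å comes from the injected per-residue displacements
(sd proportional to B-factor); the Spearman correlation of 0.78 between
B-factor and per-residue RMSD recovers exactly that mechanism — the
analysis used to show that flexible regions are where predicted complexes
go wrong. The 182-entry feature vector concatenates Betti numbers and
nonharmonic eigenvalue statistics per subset pair, element pair, dimension
and grid scale; the layout table documents every block.

For a ddG model: `make_ddg_table()` (or your SKEMPI-style CSV via
`read_mutation_table()`) → `build_feature_table()` →
`crossvalidate(table, folds = 10)`, which prints pooled and per-fold R_p
and RMSE.

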
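---
title: "Persistent Laplacian features and structure evaluation for ddG prediction"
author: "plddg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent Laplacian features and structure evaluation for ddG prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plddg)
```

## What the package does

`plddg` evaluates predicted protein–protein complex structures for the task
of predicting mutation-induced binding free energy changes (ddG, kcal/mol).
It has three scientific layers:

1. **Topological featurization.** Atoms around a mutation site and across
   the binding interface are organized into element- and site-specific
   subsets; filtered simplicial complexes are built over them; and the
   harmonic and nonharmonic spectra of combinatorial Laplacians along the
   filtration become the feature vector of the mutation.
2. **Structure comparison.** A predicted complex is superposed on its
   reference (Kabsch), scored globally and per residue (backbone RMSD),
   related to crystallographic B-factors, binned by ipTM/pTM confidence,
   and its residues are classified into five structural regions by
   relative accessible surface area (rASA).
3. **Regression.** A gradient-boosted tree model is cross-validated on the
   feature table, reporting the Pearson correlation $R_p$ and RMSE.

A deterministic synthetic-data generator supplies toy complexes, perturbed
"predictions", point clouds of known topology and ddG tables with planted
signal, so all three layers are testable offline.

## The model

### Subsets and the modified distance

Four atom subsets are drawn from a complex with partner proteins $P_1$ and
$P_2$: the mutation-site residue's atoms; atoms within radius $r$ of the
site (the neighborhood); and the atoms of each partner within $r$ of the
other (the two binding-site subsets). Each subset is additionally filtered
to an element group; pairs such as C–C capture hydrophobic and N–O
hydrophilic contacts. The radius $r$ is nowhere canonical; the package
default is 10 Å (a config key, not a constant), consistent with the
contact-distance scale of protein interfaces.

Cross-set interactions use the modified distance
$D_{\mathrm{mod}}(A_i, A_j)$: the Euclidean distance when $A_i$ and $A_j$
belong to different subsets, and an excluded value beyond every filtration
scale when they share a subset. Exclusion ensures that only *inter*-set
contacts generate topology. Internally exclusions are `Inf` entries that
the Vietoris–Rips builder never turns into edges, which realizes
"beyond any scale" without feeding infinities into numeric kernels.

### Filtrations

- **Vietoris–Rips** (dimension-0 features, on $D_{\mathrm{mod}}$): vertices
  at scale 0, an edge at the pair distance, higher simplices at the
  maximum of their edge values. The VR scale is an *edge length* (diameter
  convention).
- **Alpha** (dimension-1/2 features, on raw coordinates): the Delaunay
  triangulation restricted by circumscribing-sphere radius, with the
  standard Gabriel/coface assignment of filtration values. Alpha values
  are reported on the *radius* scale in Å. The two conventions are stated
  here precisely because mixing them silently produces factor-of-two
  errors; the package keeps both grids in Å under their own declared
  convention.

Because $D_{\mathrm{mod}}$ has no geometric embedding, element-pair
$D_{\mathrm{mod}}$ features are dimension-0 only (VR); Alpha complexes are
built per site/binding subset on actual coordinates. The 3-D Delaunay
triangulation is computed by an incremental Bowyer–Watson algorithm
(compiled code). Degenerate clouds — collinear, coplanar, cospherical —
receive a deterministic jitter of $10^{-6}$ Å from a fixed-seed generator
before triangulation; synthetic lattices would otherwise break the
triangulation. Filtration values are unaffected beyond that perturbation
scale.

### Laplacian spectra

For a face-closed complex $K_t$ at scale $t$, with signed boundary
matrices $B_k$ (sorted-vertex orientation, real coefficients), the
combinatorial Laplacian is

$$ L_k = B_{k+1} B_{k+1}^{\mathsf T} + B_k^{\mathsf T} B_k, \qquad
   L_0 = B_1 B_1^{\mathsf T}. $$

$L_k$ is symmetric positive semidefinite; its zero-eigenvalue multiplicity
equals the Betti number $\beta_k$ (combinatorial Hodge theorem), and the
positive eigenvalues — the nonharmonic spectrum — add geometric shape
information that Betti numbers lack. Eigenvalues are independent of
simplex orientation choices, which the test suite asserts under random
sign flips. Real coefficients are required for a meaningful eigenspectrum,
which is why the chain coefficients are real throughout.

Per grid scale and dimension the feature block is: $\beta_k$ plus the
minimum, maximum, mean, standard deviation, sum and count of the
nonharmonic eigenvalues (a config list; an empty spectrum contributes
zeros with count 0, and the block layout flags empty subsets).

Numerical choices:

- **Zero tolerance.** $\lambda < 10^{-8}\max(1, \lambda_{\max})$ counts as
  harmonic — scale-aware, so unit changes do not reclassify eigenvalues.
- **Dense eigensolvers** are used up to order 2,000 (config `max_order`);
  a larger Laplacian contributes a zero block recorded in the layout
  rather than an hours-long diagonalization. With the default radius and
  element groups, protein-sized binding subsets stay well under the cap.
- **Snapshot (non-persistent) Laplacians** $L_k(K_t)$ on the grid are the
  feature source. The $p$-persistent extension (up-Laplacian restricted
  across $K_t \hookrightarrow K_{t+p}$) is deliberately not implemented:
  its definition is not pinned down in the source material for this
  design, and guessing an operator would silently change the features.

Default grids: dimension 0 (VR on $D_{\mathrm{mod}}$) 0–12 Å in 0.25 Å
steps; dimensions 1–2 (Alpha) 0–10 Å in 0.25 Å steps. Both bracket
typical interaction distances and the default $r$, and both are
config-overridable. A compact configuration
(`pl_feature_config_compact()`: $r = 8$ Å, two element pairs, coarse
grids, Alpha dimension 1 on the site and neighborhood subsets) is used by
the synthetic generator and the recovery experiments, where a fast
low-dimensional featurization is preferable to the full menu.

## Structure evaluation

- **Superposition** is least-squares rigid (Kabsch; proper rotation via
  the SVD determinant correction). Collinear point sets are rejected by a
  singular-value check rather than returning an arbitrary rotation.
- **Residue correspondence** between reference and prediction is computed
  per chain pair by global sequence alignment (BLOSUM62,
  Needleman–Wunsch), with greedy chain assignment by percent identity;
  a best pairing under 30% identity errors out as a probable file mixup.
- **Per-residue backbone RMSD** uses *one* global superposition on all
  mapped backbone atoms (N, CA, C, O present in both), then reports each
  residue's RMS deviation under that single transform. No per-residue
  refitting: the point is exactly that flexible regions deviate from the
  rigid global frame. The global RMSD over backbone atoms of mapped
  residues is the reported superposition RMSD (the atom set is a
  recorded choice; Cα-only and all-atom variants differ by small amounts
  but the backbone set matches the per-residue statistic). Missing
  residues are excluded and counted, never imputed.
- **ipTM/pTM** come from an AF3-style JSON summary; both a flat summary
  and a per-chain-pair matrix (reduced to the cross-partner mean) are
  accepted, since server output varies. Interface confidence bands:
  ipTM > 0.8 high-confidence, < 0.6 likely incorrect, otherwise
  ambiguous.
- **rASA** is computed by Shrake–Rupley (probe 1.4 Å, 960 sphere points,
  standard van der Waals radii) and normalized by per-residue theoretical
  maxima (Tien 2013). The five-region classification compares monomer and
  complex rASA at the 25% exposure cutoff: non-interface residues are
  *interior* (< 25% in the complex) or *surface*; interface residues
  (any monomer-to-complex burial ≥ δ) are *support* (buried already as a
  monomer), *core* (exposed as monomer, buried in complex) or *rim*
  (still exposed). δ defaults to 0.001 as a fraction — any measurable
  burial marks interface, with a small guard against sphere-point noise;
  the 25% cutoff is the only threshold with literature standing.

## Regression stage

Feature rows concatenate the spectral blocks, one-hot wild-type and
mutant amino acids, a one-hot of the mutated residue's region, and an
optional external embedding block (the interface point for sequence
embeddings, which this package does not compute). Records whose structure
cannot be resolved go to an exclusion report rather than being silently
dropped — the same bookkeeping by which benchmark records whose complexes
are unavailable (e.g. sequence-restricted on prediction servers) are
excluded with an audit trail. Direct and
reverse mutations (negated ddG, mirrored one-hots, identical geometry
block) are generated when `reverse = TRUE`, and fold assignment keeps a
pair in one fold.

The learner is gradient-boosted trees. Package defaults follow the
production configuration (depth 7, 10,000-round ceiling with early
stopping on a 5% validation slice, learning rate 0.01). Folds are drawn
at the mutation-pair level by default; `group_by_complex = TRUE` assigns
whole complexes to folds. The two modes answer different questions —
interpolation within known complexes versus generalization to unseen
complexes — and the anti-leakage regression test shows a pure per-complex
offset signal collapsing to $R_p \approx 0$ under grouped folds while
record-level folds inflate it.

For the synthetic recovery experiments the tests use shallower trees
(depth 3, learning rate 0.05): the planted signal is additive in a few
features, where shallow ensembles are the appropriate learner; deep trees
waste capacity on interactions that do not exist in that generator. This
is an experiment-level configuration, not a package default.

## What the generator emulates — and what it does not

`make_toy_complex()` builds two poly-alanine chains on idealized backbone
geometry (3.8 Å Cα spacing, heavy atoms N/CA/C/O/CB), facing each other
across a configurable interface gap (default 5 Å, within contact range of
the default selection radius). B-factors are flat at a baseline (20 Ų)
except over a flexible segment (default: the central 30% of each chain)
multiplied by 5. `perturb_structure()` makes the "prediction": a random
rigid transform, plus — in flexible mode — a per-residue Gaussian
displacement with sd proportional to the residue's B-factor. That linear
B-to-displacement link is the simplest mechanism producing the monotone
flexibility/misalignment trend seen in real predicted complexes.
`make_ddg_table()` plants a sparse linear signal on computed spectral
feature columns with Gaussian noise scaled to a target explained variance
$R^2$; marginal ddG sd is 1.5 kcal/mol, a typical single-mutation spread.

Deliberate non-realism: no side-chain rotamers, no sequence diversity, no
Ramachandran sampling, no energy minimization. Flexibility tests need
controlled geometry, not realism. Consequently, passing recovery tests
shows the *machinery* is correct — selection, featurization, alignment,
statistics, CV plumbing — not that the features predict real SKEMPI ddG
values; a full-scale benchmark requires the real SKEMPI 2.0 mutation set
with its PDB structures and predicted complexes, which the pipeline
accepts as inputs but does not download.

## Problem sizes used in tests and the acceptance script

The shipped experiments use: 100 random complexes (5–10 vertices) for the
Hodge consistency sweep; Alpha filtrations on random clouds up to 30
points cross-checked against an independent boundary-reduction
persistent-homology oracle; a 30-complex cohort (40 residues per chain)
for the evaluation statistics; five 100-residue complexes for the
flexibility recovery; and 500-mutation tables over 20 complexes for the
cross-validation recovery (planted $R^2$ of 0.99 and 0.8, plus pure-noise
nulls). These sizes were chosen so the complete suite runs comfortably on
a laptop-class single core while keeping every statistical assertion well
powered.

## Known limitations

- Alpha filtration values rely on double-precision predicates with
  deterministic jitter, not exact arithmetic; pathological inputs could
  in principle misclassify a near-degenerate tetrahedron. All shipped
  uses are far from that regime, and the test suite cross-checks against
  brute-force empty-circumsphere enumeration.
- Dimension > 3 simplices are never built; features stop at $\beta_2$.
- No TM-score/lDDT/DockQ; the comparison statistic is superposition RMSD.
- Nucleic-acid chains, ligands and covalent modifications are out of
  scope, as is any network access (RCSB, AF3 server).
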
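---
title: "Automated pharmacophore-aligned 3D-QSAR: models and methods"
author: "autogpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pharmacophore-aligned 3D-QSAR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classical CoMFA-style 3D-QSAR needs every training molecule in its
bioactive conformation, mutually aligned — information that normally comes
from crystal structures or expert superposition. `autogpa` automates that
step: given nothing but 2D structures (SMILES/SDF) and activities (pIC50),
it searches for common pharmacophore arrangements across low-strain
conformers, aligns each candidate arrangement, builds steric/electrostatic
grid fields over every aligned ensemble, fits PLS regressions, and ranks
the pharmacophore + field model pairs by leave-one-out q².  The top-ranked
pair is the working hypothesis for both the bioactive conformation and the
structure-activity relationship.

## Pipeline and models

### Conformers

Each molecule is embedded deterministically (fused-polygon layout for ring
systems, ideal bond lengths/angles for acyclic atoms, a small seeded
Gaussian jitter of 0.02 Å to break symmetric saddle points), then MMFF94-
minimized.  Rotamers are enumerated by systematic torsion driving and
re-minimized; strain energies are MMFF94 energies relative to the ensemble
minimum.  Conformers above the `energy_window` (default 7 kcal/mol) are
discarded and near-duplicates (heavy-atom best-fit RMSD < `rmsd_prune`,
default 0.5 Å) pruned keeping the lower-energy member, capped at
`max_confs` (default 250).  Every step is bit-deterministic given
(structure, parameters, seed): the stochastic 3D builders in common
toolkits take no seed, which is why the embedding is our own.  The MMFF94
variant used here has no implicit-solvent term; strain windows are
therefore gas-phase quantities.  Unspecified stereocenters are built in
one deterministic configuration rather than enumerated — a known
limitation for chiral series.

Partial charges (default `mmff-like`, alternatively Gasteiger) are
topological bond-charge-increment charges: identical across conformers and
summing exactly to the formal charge.

### Pharmacophore features

Features are perceived from the typed molecular graph (SYBYL atom types)
plus the conformer geometry:

| kind | letter | rule |
|------|--------|------|
| aromatic ring | R | centroid of each aromatic cycle |
| hydrophobe | H | centroid of each maximal group of ≥3 connected aliphatic carbons with no heteroatom neighbour (halogens excluded) |
| donor | D | N/O bearing ≥1 H |
| acceptor | A | O (formal charge ≤ 0); N that is not amide, not aromatic N–H, < 4 connections |
| projected donor | d | 3.0 Å from the donor along each D–H axis |
| projected acceptor | a | 3.0 Å along each idealized lone-pair axis (sp² and sp³ O emit two, nitrile/pyridine N one) |
| cation | C | formally positive N |
| anion | N | carboxylate/sulfonate/phosphate O-centroid, or any formally negative heavy atom |

The 3.0 Å projection distance is the canonical hydrogen-bond heavy-atom
separation: projected points approximate where the complementary receptor
atom would sit, which makes arrangements of them far more transferable
across a congeneric series than the raw donor/acceptor positions.

### Elucidation and alignment

Candidate queries are all k-point subsets (default k = 4) of the feature
sets of the most active reference molecules (default top 3), minus subsets
with points closer than 1.5 Å, deduplicated by kind multiset and distance
matrix (0.5 Å).  A candidate matches a conformer when an injective,
kind-preserving assignment exists whose inter-feature distances agree with
the query's entrywise within `dist_tol` (default 1.0 Å); the matched
features are rigidly superposed onto the query (Kabsch, proper rotations
only) and the minimum-RMSD assignment wins, ties broken by lowest feature
indices.  Per molecule the lowest-RMSD conformer is placed.  Candidates
covering fewer than `min_coverage` (default 0.9) of the active training
molecules are discarded; when explicit inactive flags exist, candidates
matching more than half of the inactives are demoted to the bottom.
Survivors are ranked by the mean pairwise Gaussian atomic volume overlap

$$V_{AB} = \sum_{i \in A}\sum_{j \in B} 2.7\,
  \exp\!\left(-\,2\ln 2\; d_{ij}^2 / (r_i^2 + r_j^2)\right),$$

with element van der Waals radii — a ranking score only; its absolute
scale is not comparable to other programs' overlap scores.  At most
`max_queries` (default 10) alignments survive.

On the matching tolerance under noise: if feature positions carry
independent jitter of sd σ per coordinate, the distance between two
jittered copies of the same pair deviates with sd ≈ σ√2 on each side, i.e.
≈ 2σ between two copies.  Recovery tests with σ = 0.3 Å therefore use
`dist_tol = 1.5` (≈2.5 sigma); the default 1.0 Å is calibrated for
minimized conformer geometry, not artificially jittered points.

### Grid fields

A regular axis-aligned grid with 2.0 Å spacing and 4.0 Å padding encloses
the aligned ensemble (origin floored to the spacing so that jointly
translating molecules and grid reproduces identical fields).  An sp³
carbon probe of charge +1.0 e visits every point:

* steric: Lennard-Jones 6–12, $\varepsilon^*[(R^*/r)^{12} - 2(R^*/r)^6]$
  with $R^* = r_i + r_\text{probe}$, $\varepsilon^* =
  \sqrt{\varepsilon_i\,\varepsilon_\text{probe}}$, Tripos-style per-element
  parameters bundled in the package;
* electrostatic: Coulomb with distance-dependent dielectric ε(r) = r,
  $332.0637\, q_i q_\text{probe} / r^2$ kcal/mol, distance floor 0.05 Å.

Any grid point where **any** molecule's steric energy exceeds +30 kcal/mol
is discarded globally (point removal, not value truncation — the
interpretation that matches the method's description; classic CoMFA-style
truncation is available behind the cutoff parameter by passing a larger
cutoff and filtering downstream).  Electrostatics at buried points receive
no extra masking beyond this discard.

### PLS and ranking

Columns are variance-filtered per block (`min_sd`, default 0.1 kcal/mol),
centered, and block-scaled so the steric and electrostatic blocks carry
equal total variance (the CoMFA convention; per-column autoscaling would
amplify noise columns and destroy spatial contrast).  Components are
extracted by NIPALS with deflation; the number of components (up to
`noc_max` = 10, capped at n − 2) maximizes leave-one-out q², where every
fold re-centers and re-scales on its n − 1 rows (no leakage) and

$$q^2 = 1 - \mathrm{PRESS} / \sum_i (y_i - \bar y)^2$$

uses the full-sample mean, the convention of the original CoMFA
literature.  Ties prefer fewer components, then fewer grid columns.  The
reported MSE is the training MSE at the selected dimensionality.  Models
are ranked by q²; the head of the list is the saved best model.

### Prediction

A new molecule is predicted by generating its conformers, keeping those
that (i) match the model's pharmacophore query and (ii) satisfy the grid
potential model — after alignment, the probe steric energy at every grid
column the model uses must stay below the model's steric cutoff.  Each
surviving conformer is scored by the PLS regression and the **maximum**
over conformers is adopted.  The steric gate matters: without it, a
rotamer protruding into space never sampled by the training set is scored
by unbounded linear extrapolation, and the max rule then guarantees the
worst possible answer.  Molecules with no surviving conformer are
reported `no_match` and excluded (never imputed) from external
validation, which uses
$r^2_\text{pred} = 1 - \sum(y-\hat y)^2 / \sum(y - \bar y_\text{train})^2$
with the training mean — the standard external-validation convention.

## The synthetic fixtures and what they do (and do not) show

Two generators make every stage testable without external data:

* `make_planted_feature_sets()` plants one k-point typed arrangement
  (points ≥ 2 Å apart), re-expressed in each synthetic molecule under a
  random rigid motion plus optional jitter and decoy features (uniform in
  a 12 Å box, ≥ 1.5 Å from planted points).  It validates elucidation and
  alignment against known ground truth.
* `make_congeneric_series()` emits a 20-molecule series of naphthols
  substituted at three spatially separated ring positions under a balanced
  Latin-square-style design, with activities
  $y = 7.0 + z_1 - 0.8 z_2 + 0.6 z_3 + \varepsilon$,
  $\varepsilon \sim N(0, 0.1^2)$, where $z_j$ are standardized values of
  three designated field columns computed from the series' own alignment.
  Roles are a seeded 16/4 train/test split.  The manifest records
  everything needed to verify recovery.

Designated truth columns are chosen as a **self-identifying triple**: a
fixed point of a noiseless probe — fitting the response planted on exactly
those columns ranks exactly those columns as the three largest
standardized coefficients (|β|·SD), stable across 3, 6 and 10 components.
This construction is necessary because CoMFA field matrices are strongly
collinear (neighbouring grid points see the same substituents; in this
series only ~1% of columns lack a ≥0.95-correlated neighbour), so a
coefficient planted on an arbitrary column provably re-appears partly on
its neighbours and cannot be attributed back.  Identifiability is a
property of the planted truth, not of the estimator.

One subtlety in verifying recovery: a grid column's linear index is
relative to its alignment's overlay frame.  Two alignments of the same
molecules that differ by a rigid motion produce the same physical columns
under different indices (and slightly re-sampled values, since the grid
is axis-aligned in each frame).  `designated_recovery()` therefore checks
recovery by value pattern: the best model's three largest standardized
effects (|β|·SD, see `coefficient_effects()`) must match the three
designated columns one-to-one with |correlation| ≥ 0.995 across the
training molecules — in this series, re-sampled copies of the same column
correlate above 0.998 while the closest distinct columns stay below
0.99.

What passing these fixtures shows: the search recovers planted geometric
arrangements; the regression machinery recovers planted, recoverable
linear signals; the plumbing is deterministic.  What it does not show:
performance on real assay data, where activity is not a linear function
of a handful of field columns, conformational penalties matter, binding
modes can differ within one series, and the true pharmacophore need not
be shared by all actives.

## Numerical choices

* Matching search is depth-first over the correspondence graph with
  entrywise distance pruning; exhaustive at k ≤ 7.
* Superposition: Kabsch via SVD with determinant correction; collinear
  point sets are refused.
* Degenerate PLS inputs: zero-variance response is an error; requesting
  more components than extractable warns and caps.
* Model files store doubles as 17-significant-digit strings inside
  versioned, checksummed JSON, so save/load round-trips reproduce
  predictions bit-identically and tampering is detected.
* Problem sizes in the test-suite and acceptance runs: the 20-molecule
  series (16 train / 4 test), ~25 atoms per molecule, grids of ~10³
  points, and 20-seed repetitions for the statistical checks — sizes at
  which every stage's behaviour is still exactly auditable against
  brute-force oracles.  Conformer ensembles are reused across noise seeds
  where the molecules are identical (conformer generation does not depend
  on the response).

## Known limitations

* The overlap score ranks alignments but is not normalized to any
  published overlap scale.
* Variance filtering (`min_sd`) controls the column count only coarsely;
  no claim is made that it reproduces any particular published grid
  count.
* No solvation term in the conformer energies; no tautomer or protonation
  enumeration; unspecified stereocenters are not enumerated.
* Prediction quality degrades to `no_match` for molecules whose every
  conformer protrudes past the training envelope — by design, rather than
  extrapolating.
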
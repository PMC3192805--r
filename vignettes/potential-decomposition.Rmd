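---
title: "Decomposing contact potentials into hydrophobic and hydrogen-bonding terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing contact potentials into hydrophobic and hydrogen-bonding terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potdecomp)
```

## The model

Knowledge-based contact potentials summarise how often residue types are
found in contact in solved structures, converted to free energies by
Boltzmann inversion against a reference state. A 20×20 symmetric matrix
$e_{ij}$ of this kind has 210 unique elements and mixes several physical
effects. potdecomp separates two of them explicitly — side-chain
hydrophobic clustering and backbone hydrogen bonding — plus a
residue-specific remainder.

The two-body model is

$$e_{ij} \;=\; \eta_0 \;-\; \big(\eta_{HH}\,HH_{ij} + \eta_{HP}\,HP_{ij}
  + \eta_{HB}\,HB_{ij}\big),$$

where $HH$, $HP$ and $HB$ are binary indicator matrices: $HH_{ij}=1$
when both residues are hydrophobic, $HP_{ij}=1$ when exactly one is, and
$HB_{ij}=1$ when both residues can donate a backbone amide hydrogen bond
— every residue except proline. Under the default hydropathy
classification (`"dill"`: hydrophobic C,F,L,W,V,I,M,Y,A,P) the unique
pair counts are 55 (HH), 100 (HP), 55 (PP) and 190 (HB).

The $\eta$ coefficients are positive stabilization magnitudes entering
with a minus sign. This convention makes $\eta_0$ the free energy of the
reference polar–polar, non-hydrogen-bonded contact; $\eta_{HH}$ and
$\eta_{HP}$ the extra stabilization of hydrophobic contacts; and
$\eta_{HB}$ the gain from forming a backbone hydrogen bond. The quantity
of interest is the ratio $\eta_{HB}/\eta_{HH}$: below 1 the potential is
hydrophobic-dominated (native-fold-like), above 1 hydrogen-bond-dominated
(amyloid-like). Adding a constant to every matrix element moves only
$\eta_0$, so the ratio is invariant to the choice of reference.

The full model adds residue-specific one-body terms,

$$e_{ij} \;=\; \eta_0 \;-\; \big(\eta_{HH}\,HH_{ij} + \eta_{HP}\,HP_{ij}
  + \eta_{HB}\,HB_{ij}\big) \;+\; q_i + q_j,$$

interpreted as the free energy of forming hydrogen-bonded secondary
structure plus a class-level solvation free energy.

## Gauge fixing

The one-body terms are degenerate with the two-body ones: adding a
constant $c$ to every hydrophobic $q_i$ changes $e_{ij}$ by
$c\,(2HH_{ij}+HP_{ij})$, which is exactly absorbed by
$\eta_{HH}\mapsto\eta_{HH}-2c$, $\eta_{HP}\mapsto\eta_{HP}-c$; the
hydrophilic class has the analogous degeneracy through $\eta_0$. The fit
therefore imposes the class-wise zero-sum gauge

$$\sum_{i\in H} q_i = 0, \qquad \sum_{i\in P} q_i = 0,$$

which removes both degeneracies and leaves the reconstruction
$\hat e_{ij}$ unchanged. The bundled reference table of fitted one-body
terms satisfies this gauge to ≤ 2·10⁻⁴, which is how the convention was
identified. `fit_full()` solves the constrained problem in closed form on
a reduced parameterization (one free parameter per residue except the
last of each class); since the model is linear in all 24 parameters,
ordinary least squares over the 210 unique elements — each counted once,
unweighted — is exact.

## Parameters that matter

* **Hydropathy classification.** `"dill"` is the default;
  `"pro_polar"` (proline hydrophilic) and `"pro_ala_polar"` (proline and
  alanine hydrophilic) are provided because the headline ratio must
  survive reclassification to be meaningful. Custom partitions are a
  constructor call away.
* **Proline policy** in `solvation_correct()`. The published analyses
  this package reproduces use different effective groupings: the
  1.45 RT hydrophobic penalty of the q-value scale is the plain
  10-residue class mean (proline included); the strongest correlation of
  the centred q-values with the fitted native-fold one-body terms is
  obtained with proline grouped hydrophilic; and the β-sheet scales are
  centred with proline excluded, since proline's value there reflects
  hydrogen-bond incapacity rather than solvation. Each analysis pins its
  policy explicitly rather than hard-coding one.
* **Sign of the solvation shifts.** `solvation_correct()` reports the
  class means it removes. Published "cost/gain of solvation" values are
  the *negative* of the class mean of a free-energy scale; the β-sheet
  shifts computed here (−0.320/+0.514 parallel, −0.344/+0.255
  antiparallel, proline excluded) match the published +0.32 (−0.51) and
  +0.34 (−0.25) in magnitude under that convention.
* **Annealing schedule.** `anneal_refine()` is an independent stochastic
  route to the `fit_full()` optimum, used for cross-validation of the
  solver, with geometric cooling (t0 = 1, factor 0.995, 2·10⁵ steps).
  The Gaussian proposal width decays geometrically from 0.05 to 10⁻⁴
  across the run. This adaptive step is a deliberate design choice: a
  fixed width stalls at its own resolution limit (about 0.3 above the
  optimum residual sum of squares), and tying the width to the
  temperature freezes the walk before it reaches the basin; the
  decoupled decay reaches within ~5·10⁻⁴ of the closed-form optimum
  from a zero start. Runs are deterministic under a seed, and the best
  visited state is retained, so the result is never worse than the
  initialization.
* **Pro-X scaling.** "Reducing the Pro-X free energies k-fold" is
  interpreted multiplicatively — the proline row and column are divided
  by k — which moves the strongly destabilising (positive) Pro-X
  elements of strand-pairing potentials toward neutrality.
  `find_pro_factor()` bisects on k (ratio tolerance 10⁻³) after checking
  numerically that the ratio is monotone over the bracket.
* **Disulfide handling.** The Cys-Cys element can carry a covalent
  contribution; `refit_with_disulfide()` either drops it
  (`exclude_cys_cys`, the default) or gives it a dedicated indicator
  regressor (`ss_regressor`).

## Distribution summaries

`class_gaussians()` describes the 210 unique elements as three
per-class Gaussians using sample moments (the maximum-likelihood fit) —
deterministic and bin-free, rather than a histogram least-squares fit.
Standard deviations are population values (divide by N) throughout, so
summaries are reproducible to the last digit. Mixture weights are class
element-count fractions (55/210, 100/210, 55/210 under `"dill"`);
published native-fold analyses quote contact fractions of 37/39/24%,
which cannot arise from element counts and presumably reflect
structure-derived contact frequencies not contained in the matrices
themselves — those fractions are therefore not a quantity this package
computes, while the per-class means and standard deviations are.

## What the synthetic generator emulates — and what it does not

`generate_matrix()` draws matrices from the model itself:
$e_{ij} = \eta_0 - (\eta_{HH}HH + \eta_{HP}HP + \eta_{HB}HB) + q_i + q_j
+ \varepsilon_{ij}$, with $\varepsilon$ iid Gaussian per unique element,
mirrored across the diagonal. The default preset uses the native-fold
coefficients (3.64, 1.48, 1.76, 0.07) with noise 0.23 RT — the residual
scale of the full fit to the native-fold potential — and a `"parallel"`
preset (1.40, 0.21, 2.23, 2.97; noise 0.42) mimics a strand-pairing
potential. With the bundled fitted one-body terms as ground truth, the
synthetic native-fold pipeline reproduces the published fit quality
(two-body r ≈ 0.87, full-model r ≈ 0.99) without any real matrix.

The generator's residuals are iid and Gaussian by construction. Real
potentials have structured residuals — correlated across pairs sharing a
residue, heavier-tailed (the Cys-Cys disulfide element being the obvious
example) — so passing recovery tests on synthetic data demonstrates the
estimator's correctness and calibration under the model, not that the
model is adequate for any particular published matrix. Adequacy for real
matrices is what the correlation metrics measure when such a matrix is
supplied.

## Numerical choices and degenerate inputs

* Fits go through a QR decomposition; a rank-deficient design (possible
  under degenerate classifications, e.g. an empty class) is an explicit
  error, as are zero-variance inputs to any Pearson correlation.
* Symmetry is enforced on construction: square input asymmetric beyond
  10⁻⁹ is a parse error naming the offending cell; values are exactly
  symmetrized afterwards.
* Matrices serialize with 15 significant digits, so write/read round
  trips are faithful to well below 10⁻¹².
* The lower-triangle file dialect carries the diagonal (210 values,
  row-major); the AAindex-style dialect is read-only.
* Ties in bisection cannot occur (the ratio is checked to be strictly
  monotone over the bracket before the search starts).

## Problem sizes used in the tests

The bundled analyses are desk-scale: every fit involves 210
observations and at most 24 parameters. The calibration check runs 500
seeded replicates of the noisy two-body fit (a few seconds); the
noise-ladder property test uses 50 replicates per noise level; the
annealer's cross-check runs its full 2·10⁵-step schedule (about one
second). These sizes give Monte-Carlo standard errors comfortably below
the tolerances asserted (e.g. ±0.9 percentage points on a 95% coverage
estimate from 500 replicates).

## Known limitations

* The package consumes contact matrices; it does not derive them from
  structures, and the published MJ / strand-pairing / SJKG matrices are
  not bundled (they are other publications' data). Loaders with optional
  checksum pinning accept user transcriptions under
  `inst/extdata/external/`.
* Standard errors are plain OLS values from the residual variance. For
  published coefficient ±values whose method is unstated, agreement
  should not be over-interpreted.
* The β-sheet propensity-to-free-energy conversion behind the bundled
  reference scales is upstream of this package and is not reimplemented;
  the converted values are shipped as data.
* Energies are treated as a consistent dimensionless RT-like scale; no
  unit conversion is attempted.
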
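---
title: "Methods: multimodal connectome prediction of cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal connectome prediction of cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`cogniconn`: the model and its assumptions, the parameters that matter,
what the synthetic cohort does and does not emulate, and where the
design was genuinely open. It states no empirical result beyond what the
test suite itself computes.

## The scientific problem

In healthy older adults (here: ages 55–85), cognitive performance varies
widely between individuals, and a long-standing question is whether that
variation can be predicted from brain imaging — the organisation of
functional connectivity (FC; correlated spontaneous fMRI signal between
cortical regions), structural connectivity (SC; white-matter streamline
weights), and regional grey-matter volume (GMV) — and whether combining
modalities beats any single one. A second, equally important question is
methodological: age, sex and education are themselves strongly related
to cognition, so any pipeline that does not control them *inside* the
cross-validation can mistake demographic signal for brain signal. The
package implements both the prediction machinery and the controls needed
to ask that question honestly.

## Connectome features

Each subject has one symmetric weighted adjacency matrix per modality
over a parcellation of `n_nodes` cortical nodes (default 400) assigned
to 7 canonical resting-state networks. Matrices are symmetrized by
averaging and their diagonal is excluded everywhere.

**FC preprocessing order** is: Pearson correlation of node time series →
surrogate-based edge significance filter → Fisher r-to-z → restriction
to the positive branch. The order matters and follows the pipeline as
printed: thresholding happens on r, the z-transform afterwards (zeros
are a fixed point of atanh, so the two commute for zeroed edges, but
clipping and the positive-part step do not).

The **edge filter** tests each observed |r| against a null distribution
of correlations among phase-randomized surrogates: the FFT amplitude
spectrum of every node's series is kept exactly, phases of the free
frequencies are drawn uniformly with conjugate symmetry (DC and Nyquist
retained, so mean and variance are preserved). With `n_perm` surrogate
panels (default 1000) the p-value uses the add-one rule
`p = (k+1)/(n_perm+1)` — the standard conservative convention for
surrogate tests; the source text does not specify the rule, and the
add-one form guarantees p > 0 and near-exact type-I control, which the
acceptance suite verifies against a 99% binomial interval around
alpha = 0.05. The test is two-sided on |r| (the source is silent;
two-sided is the safer default given the later negative-FC analysis).

**Nodal metrics.** For node *i* in network *g*:
`W_i = (sum of i's weights to g) / E_g`,
`B_i = (sum of i's weights outside g) / E_g`, and the ratio `W_i / B_i`.
Two genuinely open readings of "the number of edges in the network" are
implemented:

- `denominator = "subject_edges"` (default): E_g counts the *nonzero*
  within-network unordered pairs of the subject's own thresholded
  matrix. Rationale: the metrics are computed on subject-specific,
  thresholded graphs, and this matches the normalized-strength
  convention of the graph-metric library the field uses.
- `denominator = "all_pairs"`: all possible pairs, and `double_count =
  TRUE` counts edges as summed degrees (a factor 2). These only rescale
  features within network blocks, which standardization inside the CV
  later removes — the choice is therefore consequential mostly for
  interpretability, not prediction.

Networks with E_g = 0 yield metric 0 (not NaN), and ratio nodes with
B_i = 0 yield 0 (not infinity), keeping feature matrices finite; the
affected indices are flagged on the returned vector. The SC log
transform defaults to `log10(1 + w)` because plain `log10` is undefined
at absent edges; `zero_safe = FALSE` gives `log10(w)` on the nonzero
support for users whose weights are bounded away from 0.

**Feature sets** reproduce the printed arithmetic exactly on 400 nodes:
A = 2000 (FC/SC within + inter + GMV), B = 1200 (ratios + GMV), C = 2800
(A plus negative-FC within + inter), full vector = 2800; appending
demographics adds 3 columns. FC metrics are computed on the thresholded,
z-transformed, positive-part weights (the printed pipeline order); the
negative branch uses absolute values of the negative z entries.

## Cognitive targets

The 14-test battery is imputed by the median of the subject's sex ×
age-band cell (55–64, 65–74, 75–85; whole-sample fallback for empty
cells); subjects with more than three missing tests are excluded.
Z-scores use the population (n) denominator — the convention of the
commercial statistics package the source pipeline used; a sample-sd
switch exists. Tests where higher raw values mean worse performance are
multiplied by −1 after z-scoring.

PCA operates on the test correlation matrix. The global composite is the
first component; profiles retain components with eigenvalue > 1 and are
Varimax-rotated (Kaiser-normalized, the default of `stats::varimax`).
Component scores use the regression method, `Z R^{-1} Λ`, standardized
to unit population variance, with signs fixed so each component's
largest-magnitude loading is positive. The exact score-extraction
convention of the original software is not documented; the regression
method is its default and is stated here so results are reproducible.
KMO is computed from the anti-image partial correlations,
`Σr² / (Σr² + Σp²)`.

## The cross-validation engine

The outer scheme is repeated k-fold (default 10 folds × 10 repeats);
within each repeat the folds partition subjects exactly once, and the
*same plan object* is reused across modalities and stacking layers, so
train/test identities can never drift apart. Hyperparameters are tuned
on inner 5-fold CV minimizing MAE (accuracy for classifiers); ties take
the first grid entry in enumeration order. Feature scaling (mean 0,
population sd 1) is fitted on the outer-training subjects and applied to
the test fold; for compute reasons it is not re-fitted inside the inner
folds — a deliberate, documented simplification whose leakage risk is
nil (scaling uses no target information) and which the permuted-target
sentinel confirms empirically.

**Confound regression** removes nuisance variables from the *target*,
never the features: OLS of the target on [1, confounds] fitted on the
outer-training subjects only, residuals carried to the test fold with
the training coefficients. eTIV is always included; the deconf.
condition adds age, sex (0/1) and education. Whether the eTIV-only
condition used whole-sample or train-only fitting was not stated beyond
"within the ML pipeline"; train-only fitting is used for both modes, the
strictly more conservative reading.

**Algorithms.** Ridge is solved exactly (eigendecomposition shared
across the lambda path; primal or dual form depending on n vs p). Lasso
and elastic net use `glmnet`, whose objective `1/(2n)·RSS + λ·penalty`
matches the parameterisation of the grids as printed (λ overall, α the
L1 ratio). Linear SVR/SVC have no pre-installed implementation in this
stack, so they are fitted as primal optimizations (smoothed
ε-insensitive loss with ε = 0, resp. squared hinge, L-BFGS); the random
forest is implemented in C++ (CART, bootstrap, per-node feature
subsampling, impurity importances, seed-pinned RNG per tree). Defaults
mirror the reference ML library of the source era: regression forests
consider all features per split, classification forests √p. Grids are
the printed ones: linSVR C ∈ 10^[−4,1], lasso λ ∈ 10^[−1,2], ridge λ ∈
10^[−3,5] (10 log steps each), EN λ × α (10 × 10), RF {100, 1000} trees ×
depth {4, 6, 8, 10, 20, 40, ∞}. Classifier grids are not printed in the
source; they mirror the regression grids (C as linSVR, λ as ridge, RF
unchanged) — a package choice, documented here.

**Stacking** trains per-modality models in layer 1; their out-of-fold
predictions over the outer-training subjects (produced with the tuned
configuration via the inner splits) form the layer-2 training matrix,
and the tuned models refitted on the full outer-train produce the
layer-2 test matrix. The layer-2 RF meta-estimator is tuned by a *fresh*
inner 5-fold on the stacked training rows (the source does not specify
the meta-estimator's inner structure; a fresh split avoids reusing folds
that generated the predictions). Demographic extra features enter
stacking as their own modality block. `check_stacking_exclusivity()`
audits that no test subject appears in any training structure of its
fold.

**Reporting.** R² uses `1 − SS_res/SS_tot` with the *test-set* mean in
SS_tot and may be negative. "Better than the dummy" is the strict
per-fold comparison `R² > R²_dummy` (the dummy predicts the training
mean); the MAE comparison is stored alongside. Multimodal bonuses
default to the R² basis — the source reports them in R² units — with an
MAE basis available (signs flipped so positive always means a
multimodal benefit). Feature importance ranks |fold-averaged
coefficients| (impurity importances for forests); "highest coefficients"
is read as magnitude, with signs reported alongside.

## The synthetic cohort: what it emulates, and what not

The generator's defaults state the world the pipeline assumes: n = 594
subjects aged 55–85, a 400-node/7-network parcellation, 296 timepoints
(300 volumes minus 4 discarded), 14 tests with a few percent
missingness, education on an 8-level ordinal scale with a mild
male-higher and age-lower dependence (so deconfounding tests are not
degenerate), eTIV larger for males, and a DemTect-like screening score.
Cognition is a linear combination of standardized age (negative
coefficient), sex, education, a latent brain factor and Gaussian noise;
the achieved true R² of the generating predictor is recorded in the
cohort object. The brain factor is planted sparsely — 20 signal nodes,
loading on their GMV (40 mm³ per sd against 50 mm³ node noise) and,
secondarily, on their SC edge weights — so feature-importance tests have
a known answer and ridge regression on GMV can recover the planted
variance share.

FC panels share one latent signal per network (within-network
correlation = strength², default 0.4² = 0.16); SC edges are Bernoulli
(density 0.25) with log-normal weights (median 20 streamline units).
These choices produce matrices with the right symmetry, sparsity and
positivity structure, but the generator deliberately does *not* emulate:
spatial autocorrelation and distance-dependent connectivity, hub/rich-
club topology, the empirical distribution of the 14 test scores (raw
scores are standard-normal based; the source does not report per-test
distributions), scanner or motion artefacts, or any nonlinear
brain-cognition coupling. A green test therefore establishes the
*pipeline's correctness and calibration* — fold bookkeeping, absence of
leakage, recovery of linear planted signal, type-I control — not that
real cohorts carry comparable signal. The quality-control rule for GMV
outliers (mean GMV beyond 1.5 IQR) is implemented (`gmv_outliers`) but
not applied during synthesis, since the generator does not produce such
outliers.

## Numerical conventions and degenerate inputs

- Symmetry tolerance 1e-10 on construction (relative guard for large
  entries); readers reject asymmetric files by name.
- |r| ≥ 1 off-diagonal is clipped to ±(1 − 1e-7) with a warning before
  atanh; zero-variance nodes get zeroed correlations with a warning.
- Constant series pass through the surrogate generator unchanged (with a
  warning); surrogate spectra match to 1e-8 by construction.
- Zero-variance features are left centred (scale divisor 1); a
  zero-variance test score is an error at z-scoring.
- Singular correlation matrices in KMO are ridge-regularized (1e-8) with
  a warning; collinear confound or control columns are dropped with a
  warning.
- All randomness derives from named substreams of a single master seed
  (`substream_seed`), so cohorts, CV plans, surrogates and forests are
  bit-reproducible; RF trees are seeded individually, making forests
  independent of evaluation order.
- Propensity matching is greedy 1:1 nearest-neighbour on the logit scale,
  processed in decreasing propensity order, without replacement, caliper
  0.2 sd of the logit — the common convention; the source names only
  "propensity score matching".

## Known limitations

- The linear SVR/SVC primal optimizers approximate the reference
  implementations to optimization tolerance, not bit-exactly; grids and
  losses match, solvers differ.
- The random forest is a faithful but compact CART implementation; it
  does not reproduce any specific library's tree-by-tree randomness,
  only the algorithmic contract (and is itself seed-stable).
- Inner-fold re-scaling is omitted (see above); with standardized
  synthetic features the effect is nil, with strongly heavy-tailed real
  features it could slightly bias inner model selection.
- At desk scale the acceptance suite runs cohorts far smaller than
  n = 594 × 400 nodes; the full-size configuration is supported but
  compute-heavy (the FC edge filter at 1000 permutations × 594 subjects
  dominates).
- No anatomical atlas lookup is included: feature reports stop at
  node/network identity plus optional centroid coordinates.
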
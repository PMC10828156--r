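# cogniconn

Multimodal connectome-based prediction of cognitive performance in older
adults: graph-theoretic features from functional (FC) and structural (SC)
brain connectomes plus region-wise grey-matter volume (GMV), PCA-derived
cognitive composite targets, and a repeated nested cross-validation
engine with explicit confound handling, in both feature-concatenation and
stacked-generalization form.

The package is aimed at researchers who want to study *how much* of
individual cognitive variation in aging cohorts is predictable from brain
network organisation — and how much of that apparent signal is carried by
demographics (age, sex, education) instead. Because the kind of cohort
data this targets is typically request-only, the package ships a
synthetic-cohort generator with planted, known ground truth, so every
stage of the pipeline is verifiable end to end without any download.

## The model in brief

**Connectome features.** Each subject contributes a weighted 400-node
adjacency matrix per modality (7 resting-state networks). FC entries are
Pearson correlations of node time series, screened by a surrogate test:
each observed |r| is compared against correlations of phase-randomized
(Fourier) surrogates, p = (k+1)/(B+1) with B = 1000 repeats, and edges
with p ≥ 0.05 are zeroed; the matrix is then Fisher z-transformed
(z = atanh r) and restricted to positive weights. SC weights
(streamline-count-like) are log10-transformed. For node *i* in network
*g* with edge weights *w_ij*:

- within-network connectivity  `W_i = sum_{j in g} w_ij / E_g`
- inter-network connectivity  `B_i = sum_{j not in g} w_ij / E_g`
- ratio score  `R_i = W_i / B_i`  (0 when `B_i = 0`)

where E_g is the number of (nonzero) within-network edges of *g*.
Feature sets follow the printed arithmetic: **A** = FC/SC within+inter +
GMV = 2000 columns; **B** = FC/SC ratio + GMV = 1200; **C** adds
negative-FC within+inter = 2800.

**Targets.** The 14-test battery is imputed by sex × age-band medians
(55–64, 65–74, 75–85), z-scored, sign-aligned (timed tests inverted) and
reduced by PCA: a one-component global composite, and Varimax-rotated
profile components retained by the eigenvalue > 1 rule. A theoretically
defined composite (the row mean of the 14 z-scores) is available as a
validation target, as are KMO sampling-adequacy checks.

**Prediction.** Repeated nested CV (10 × 10-fold outer, 5-fold inner;
MAE-minimizing grid search) over ridge, lasso, elastic net, linear SVR
and random forest, each with its printed hyperparameter grid. Confounds
are regressed *from the target* with train-only coefficients inside
every fold (eTIV always; age/sex/education in the deconf. condition).
Multimodal input is either concatenated, or stacked: per-modality
out-of-fold predictions feed a random-forest meta-estimator while outer
train/test identities are preserved across both layers. Every fold also
scores a train-mean dummy regressor; summaries report mean MAE, R²
(test-set-mean convention, can be negative), Pearson r, and the
percentage of folds beating the dummy. Multimodal bonuses
B_all = R²(multi) − mean R²(uni) and B_best = R²(multi) − max R²(uni)
quantify the gain from fusion.

## Worked example

```r
library(cogniconn)

cfg <- cohort_config(n_subjects = 120, n_nodes = 40, n_timepoints = 80,
                     brain_r2 = 0.25, seed = 7)
cohort <- generate_cohort(cfg)
#> synthetic cohort: 120 subjects, 40 nodes / 7 networks, 14 tests
#>   true R2 (linear predictor): 0.529; brain share: 0.141

parc <- cohort$parcellation
fc <- connectome_metric_matrices(
  lapply(cohort$connectomes, function(x) positive_part(fisher_z(x$fc))), parc)
sc <- connectome_metric_matrices(
  lapply(cohort$connectomes, function(x) log10_sc(x$sc)), parc)
features <- assemble_feature_set("A", fc, sc, cohort$gmv, parc)
#> feature matrix: 120 subjects x 200 features (FC, SC, GMV)

battery <- impute_group_median(cohort$battery, cohort$subjects)
targets <- pca_targets(zscore_invert(battery), mode = "global")
#> composite solution: 1 component(s), rotation none, KMO 0.902

plan <- make_cv_plan(cohort$subjects$subject_id, outer_k = 5, repeats = 2,
                     inner_k = 5, seed = 11)
res <- fit_predict_concat(features, targets$scores[, 1],
                          model_config("ridge"), plan,
                          deconf = deconfound_spec("no_deconf", cohort$subjects))
summarize_performance(res)
#>   algorithm n_folds mean_mae  mean_r2  mean_r mean_dummy_r2 pct_beats_dummy
#> 1     ridge      10    0.750    0.077   0.523        -0.106              90
```

At this deliberately small scale the multimodal ridge model explains ~8%
of variance in the global composite and beats the dummy regressor in 90%
of folds. Comparing with unimodal runs:

```r
uni <- c(fc = -0.110, sc = -0.140, gmv = 0.231)   # mean outer R² per modality
multimodal_bonus(mean(res$folds$r2), uni)
#> multimodal bonus (r2 basis): B_all = 0.0835, B_best = -0.1541
```

a positive B_all but negative B_best: fusing helps relative to the
*average* modality, but here GMV alone (where the generator plants most
of the brain signal) beats the fused model — exactly the kind of
comparison the bonus scores are designed to expose. At this n the
connectome modalities contribute mostly noise, hence their negative
unimodal R².

The same analysis runs from the command line:

```sh
Rscript inst/cli/cogniconn run --seed 7 --out run1 --fset A \
    --approach concat --algorithms ridge --outer-k 5 --repeats 2
```

which writes `subjects.csv`, `features.csv` (+ metadata sidecar),
`targets.csv`, per-fold `folds.csv`, `summary.csv` and a `manifest.json`
tying outputs to the seed and configuration.

## Package layout

- `R/synthetic-cohort.R`, `R/parcellation.R` — cohort generator and
  parcellation schemes
- `R/connectome.R`, `R/fc-filter.R`, `R/transforms.R`,
  `R/nodal-metrics.R`, `R/feature-sets.R` — connectome processing and
  feature assembly
- `R/cognition.R` — battery imputation, PCA composites, KMO
- `R/cv-plan.R`, `R/models.R`, `R/deconfound.R`, `R/ml-pipeline.R`,
  `src/rf.cpp` — the nested-CV engine
- `R/evaluation.R` — bonus scores, importances, extreme groups,
  propensity matching, partial correlations
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — formats, orchestration, CLI
- `vignettes/methods.Rmd` — the methods vignette (modelling choices,
  synthetic-data assumptions, numerical conventions, limitations)
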
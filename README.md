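# rmfm — relaxed mean-field modelling of brain connectomes

`rmfm` is an R package for connectome-informed biophysical modelling of
resting-state fMRI, aimed at researchers who want to ask *mechanistic*
questions of structural and functional connectivity data: how much of a
cohort's functional connectome is explained by its anatomical wiring, and
which regional microcircuit parameters — recurrent excitation–inhibition
and excitatory subcortical drive — differ between clinical groups.

## The model

Each cortical region carries one average synaptic gating variable
`S_i ∈ [0,1]`:

    dS_i = [ -S_i/τ_s + r (1 − S_i) H(x_i) ] dt + σ dW_i
    H(x)  = (a x − b) / (1 − exp(−d (a x − b)))
    x_i   = w_i J S_i + G J Σ_{j≠i} C_ij S_j + I_i

with `C` the structural connectome (normalised to unit maximum weight),
`J = 0.2609` nA, `a = 270` Hz/nA, `b = 108` Hz, `d = 0.154` s,
`τ_s = 0.1` s, `r = 0.641`. The *relaxed* variant lets the recurrent
strength `w_i` and subcortical input `I_i` vary per region. Neural
activity drives a Balloon–Windkessel hemodynamic model whose BOLD output,
sampled at TR = 2 s, yields simulated functional connectivity (FC).

`fit_rmfm()` inverts the model against an empirical FC matrix: a coarse
scan over the global coupling `G` and noise `σ` picks the dynamical
regime, then a damped Gauss–Newton scheme with common random numbers and a
finite-difference Jacobian refines all `2N + 2` parameters by maximising
the Pearson similarity between simulated and empirical FC. The
accepted-objective trace is non-decreasing by construction, and every fit
reports the raw SC–FC correlation as the baseline it must beat.

The statistical battery (`flip_to_ipsilateral`, `zscore_vs_controls`,
`glm_contrast`, `permutation_fwe`, `mahalanobis_d`, `hotelling_t2`,
`parameter_contrast`) covers the accompanying group-level analyses:
hemisphere pooling, control-referenced z-scoring, covariate-adjusted
contrasts with max-statistic permutation FWE control, multivariate
distances and tests, and network-SD-normalised parameter contrasts.

Because the MRI data behind such studies cannot be redistributed, the
package ships a synthetic-study generator (`make_synthetic_sc`,
`make_ground_truth`, `generate_cohort_fc`, `generate_feature_tables`,
bundled as `standard_study()`): a 40-region modular connectome with
mirrored hemispheres and four intrinsic networks, and three cohorts — HC,
GE (genetic generalized epilepsy: raised subcortical input, unchanged
recurrent excitation–inhibition) and TLE (temporal lobe epilepsy: reduced
subcortical input, raised recurrent excitation–inhibition in limbic and
somatomotor networks) — with known ground truth.

## Worked example

```r
library(rmfm)

study <- standard_study(seed = 1, n_subjects = 20)   # ~1 min
fit <- fit_rmfm(study$sc, study$group_fc$HC, standard_fit_config())
print(fit)
#> rmfm fit: similarity 0.619 (SC-FC baseline 0.566), G = 0.234,
#> sigma = 0.0020, 8 iterations, converged
```

The fitted similarity (0.619) is the Pearson correlation between the
model's simulated FC and the cohort's group-average FC over all region
pairs; it exceeds the raw SC–FC baseline (0.566), i.e. the dynamics
explain functional structure beyond the anatomical weights themselves.
`fit$params$w` and `fit$params$I` hold the regional estimates;
`contrast_ready_params()` + `parameter_contrast()` turn two cohort fits
into network-normalised regional differences.

A word of caution that the package documents prominently (see the methods
vignette): with an FC-correlation objective, the two regional parameters
are close to collinear — FC constrains mainly one effective-drive
combination per region — so regional `w`/`I` estimates are far better
interpreted at network level and in contrasts between cohorts fitted with
common random numbers than as region-wise point estimates.

The numbered scripts under `analysis/` run the full study
(`01_synthesize_study.R` → `04_feature_statistics.R`), writing tables
under `results/`; `run_full_pipeline()` does the same in one call with a
reproducibility manifest.

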
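---
title: "Relaxed mean-field modelling of brain connectomes: models, inversion, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxed mean-field modelling of brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`rmfm` implements a complete, self-contained pipeline for connectome-informed
biophysical modelling of resting-state fMRI:

1. simulate whole-brain neural dynamics on a structural connectome with a
   relaxed mean-field neural-mass model;
2. turn neural activity into BOLD with a Balloon-Windkessel hemodynamic
   model and compute functional connectivity (FC);
3. invert the model against an empirical FC matrix to estimate, per cortical
   region, the recurrent excitation-inhibition `w_i` and the excitatory
   subcortical input `I_i`, together with the global coupling `G` and noise
   amplitude `sigma`;
4. contrast fitted parameters between cohorts (healthy controls, genetic
   generalized epilepsy, temporal lobe epilepsy) and run the accompanying
   parcel-level statistical battery.

Because the imaging data behind such studies cannot be redistributed, the
package ships a synthetic-study generator with known ground truth; every
stage of the pipeline is exercised and tested against it.

# The neural-mass model

Each of N cortical regions carries one average synaptic gating variable
$S_i \in [0, 1]$ obeying

$$\dot S_i = -\frac{S_i}{\tau_s} + r\,(1 - S_i)\,H(x_i) + \sigma\,\nu_i(t),$$

with the sigmoidal population transfer function

$$H(x) = \frac{a x - b}{1 - \exp(-d\,(a x - b))}$$

and total input current

$$x_i = w_i J S_i + G J \sum_{j \neq i} C_{ij} S_j + I_i.$$

$C$ is the structural connectome (symmetric, non-negative, zero diagonal),
normalised to unit maximum weight so that `G` is comparable across
connectomes. The synaptic constants are the standard reduced Wong-Wang
values: $J = 0.2609$ nA, $a = 270$ Hz/nA, $b = 108$ Hz, $d = 0.154$ s. The
printed unit of $a$ in the source literature is ambiguous; the package
treats it as Hz/nA, the only dimensionally consistent reading with $x$ in nA
and $H$ in Hz. $\tau_s = 0.1$ s and $r = 0.641$ are not always printed with
the model; the package adopts the standard values of the mean-field lineage
and exposes them in `mfm_global_params()`.

Two conventions deserve emphasis:

* **The inter-regional sum runs over $S_j$, not $S_i$.** Typeset versions
  of the current equation sometimes show $\sum_j C_{ij} S_i$; the package
  implements $\sum_j C_{ij} S_j$, the form used throughout the mean-field
  literature, and does not support the other reading. Recurrent self-input
  is carried exclusively by the $w_i$ term (the diagonal of $C$ is zero by
  contract).
* **$H$ has a removable singularity at $a x = b$** with limit $1/d$. The
  implementation switches to the series
  $1/d + y/2 + d\,y^2/12$ for $|y| = |a x - b| < 10^{-4}$, which keeps the
  function smooth and monotone through the switch point to well below any
  tolerance used in the tests.

Integration is Euler-Maruyama with one standard normal increment per region
per step, drawn from R's RNG so that `set.seed()` fixes entire
trajectories. $S$ is clamped to $[0, 1]$ after every step: the drift keeps
the noise-free system inside the unit interval, but the noise does not, and
$S$ is a gating *fraction*. The default step is `dt = 0.001` s
($\tau_s/100$); constructors reject any `dt` above $\tau_s/10$. The
fitting and generation pipelines use `dt = 0.002` s, which halves runtime
and changes noise-free terminal states by well under the integrator-
consistency tolerance of the tests.

# Hemodynamics

Neural gating drives the four-state Balloon-Windkessel system per region
(vasodilatory signal, inflow, venous volume, deoxyhemoglobin) with the
canonical constants $\kappa = 0.65$/s, $\gamma_f = 0.41$/s,
$\tau_v = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$,
$k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$. BOLD is sampled every
TR = 2 s, the repetition time of the scans the synthetic study emulates.

Two numerical choices matter and were made once, on numerical grounds:

* **Burn-in is 50 s**, not a nominal few seconds. The hemodynamic states
  start at the resting point $(0, 1, 1, 1)$ while the neural input jumps to
  its operating level, and the slowest hemodynamic mode decays at
  $\approx 0.33$/s. A 10 s burn-in leaves a few-percent transient that is
  *shared across all regions* and therefore inflates every pairwise
  correlation; empirically it can dominate the FC of weakly coupled
  networks. At 50 s the residual transient is order $10^{-7}$.
* **Hemodynamic states update every 5th neural step** (`stride = 5`, i.e.
  a 10 ms hemodynamic step at the fitting `dt`). The fastest hemodynamic
  rate is 0.65/s, so this is still a ~300-fold stability margin; it saves
  most of the transcendental-function cost of the fused simulation kernel.
  The fused scan-resolution kernel and the chained module path
  (`simulate_neural()` then `simulate_bold()` then `downsample_to_tr()`)
  produce bit-identical output for the same seed and stride, and a test
  pins that equivalence.

Pearson FC is computed on the TR-sampled BOLD. No band-pass filter is
applied to simulated BOLD by default: the simulation has no scanner drift
or aliased physiological noise to remove, and Pearson correlation is
scale-invariant.

# The synthetic study

`standard_study()` builds the reference fixture: 40 regions in two mirrored
hemispheres (homologue pairing `i <-> i + 20`), four intrinsic networks
(`limbic`, `somatomotor`, `default`, `control`) assigned contiguously and
mirrored, log-normal edge weights denser and stronger within networks, and
guaranteed homotopic edges. Connectivity is redrawn (up to 10 times) until
the graph is connected.

Cohort ground truth starts from the canonical operating point
$w_i = 0.9$, $I_i = 0.3$ nA with region-level Gaussian heterogeneity
(SD 0.10 on $w$, 0.02 on $I$) and adds the per-network shifts that encode
the study's qualitative findings:

* **TLE**: $I$ reduced by 0.06 nA and $w$ increased by 0.15 in the limbic
  and somatomotor networks;
* **GE**: $I$ increased by 0.04 nA everywhere, $w$ unchanged;
* **HC**: no shifts.

The shift magnitudes are package choices (the study this emulates reports
maps and directions, not parcel-level effect sizes) and are recorded as
such. Subject-level jitter (SD 0.02 on $w$, 0.3 of that on $I$) individualises
each of the 20 subjects per cohort; each subject contributes 500 s of
simulated signal (250 volumes at TR = 2 s, matching a typical acquisition),
and subject FCs are averaged in Fisher-z space into the cohort FC.

The generating global parameters are $G^\ast = 0.115$, $\sigma^\ast = 0.05$.
They were calibrated once to place the network just below its saturation
bifurcation, in the noise-driven multistable regime where regions make
occasional excursions between a low and a high gating state: this is the
regime in which FC carries the most information about the regional
parameters, and it yields group FC with realistic magnitudes and raw SC-FC
correlations of roughly 0.4-0.6 across the three cohorts (the control
cohort sits near 0.56, the TLE cohort near 0.41). Past
$G \approx 0.15$-$0.2$ the network locks into a saturated high-gating
state with degenerate, near-uniform FC; well below $G \approx 0.1$ FC
becomes a faint linear echo of the connectome. A caveat documented here
deliberately: the cohort contrasts themselves move the operating point, and
the GE cohort's globally raised subcortical input carries it across the
regime boundary where the switching fluctuations quench, so the synthetic
GE group FC is markedly weaker than the control cohort's. The effect
magnitudes are the generator's fixed choices; the consequences for what
the inversion can and cannot recover are laid out below.

What the generator does *not* emulate: spatially correlated measurement
noise, head-motion artefacts, vascular heterogeneity across regions,
indirect (polysynaptic) structural routes absent from the drawn connectome,
and subject-level structural variability. Passing recovery tests on this
fixture therefore demonstrates the correctness of the estimation machinery
under the model's own assumptions, not robustness to empirical confounds.

# Model inversion

`fit_rmfm()` maximises the Pearson similarity between simulated and
empirical upper-triangle FC over $(G, \sigma, w_1..w_N, I_1..I_N)$,
honouring an expectation-maximisation-flavoured alternation:

* **Common random numbers.** Every objective evaluation reuses the same
  noise seeds (derived from `base_seed`), which turns the stochastic
  objective into a deterministic function of the parameters. Gauss-Newton
  steps and a monotone acceptance rule are then meaningful; the accepted
  objective trace is non-decreasing by construction.
* **Global-parameter scan.** The objective surface over $(G, \sigma)$ at
  baseline regional parameters is multimodal (distinct dynamical regimes
  can mimic each other's FC), so the fit first scans a geometric
  $(G, \sigma)$ grid with short simulations and starts the refinement from
  the best cell. Supplying explicit `init$G`/`init$sigma` skips the scan.
* **E-like step.** Simulate FC at the current parameters: once at the
  official setting (550 s, 8 noise realizations averaged in z-space) for
  the recorded objective and the residual, and once per Jacobian column at
  the short setting (150 s, 1 realization) for the finite-difference
  linearisation. Short columns share seeds with their base, so the
  differences are nearly noise-free even though each FC alone is noisy.
* **M-like step.** Damped Gauss-Newton:
  $(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = J^\top r$ with
  the residual $r$ taken against the official simulated FC. The candidate
  is clipped to bounds and accepted only if the official objective
  improves; otherwise $\lambda$ grows (up to `max_tries` times) and the
  solve is repeated with the same Jacobian. Finite-difference steps are
  absolute (0.01 on $G$, 0.004 on $\sigma$, 0.05 on $w$, 0.015 on $I$):
  small relative to each parameter's physiological scale, because a step
  sized by the *bound range* would carry $G$ across the bifurcation and
  destroy the linearisation.
* **Stopping.** The fit stops at the iteration cap, after two consecutive
  iterations without an acceptable step, or when the accepted improvement
  falls below `tol`.

Parameter bounds ($w \in [0, 2]$, $I \in [0, 0.5]$ nA, $G \in [0, 5]$,
$\sigma \in [0.001, 0.1]$) bracket the scale set by $J = 0.2609$ nA.
Cohort-level fitting follows the study design: one fit per group-average
(SC, FC) pair, no subject-level fits. `sigma` is fitted as a single global
value. The scan covers $G$, $\sigma$, and the baseline input level, and
restarts are taken from the best cells of *distinct* regions of the scan
(distinct $G$ or baseline input), stopping once a fit clearly exceeds the
SC-FC baseline. The number of outer iterations, simulation lengths, and
realization counts in `standard_fit_config()` are desk-scale choices
recorded in the configuration and in each `fit_result`.

## What an FC-correlation objective can identify

A structural fact shapes every regional estimate this package produces:
in any stationary dynamical regime, the sensitivities of the simulated FC
matrix to $w_i$ and to $I_i$ are almost perfectly collinear (empirically
their finite-difference columns correlate at $|r| \approx 0.998$). Both
parameters act on FC only through the region's scalar operating point and
linearised gain, so the correlation structure of BOLD constrains a single
effective-drive combination $e_i \approx I_i + J S^\ast_i w_i$ per
region. Two consequences follow. First, any optimizer's fitted $(w, I)$
deviations are essentially proportional to the estimate of $e$, so the
correlations of $\hat w$ and $\hat I$ with independent ground-truth
patterns cannot *both* exceed $1/\sqrt{2} \approx 0.707$ — joint
region-wise recovery of both parameters from FC correlation alone is
mathematically capped, not merely hard. Second, only the multistable
switching regime, where $w$'s state-dependent contribution and $I$'s
constant drive leave different signatures across excursions, breaks the
collinearity at all — at the price of violent anisotropy (FC sensitivity
to $I$ near a switching threshold can exceed that to $w$ a thousandfold).
The generating conditions put the study in that regime, the fits exceed
the anatomical baseline there, and the global parameters $(G, \sigma)$
are recovered well; but region-wise $w$/$I$ recovery correlations remain
far below what a time-series (state-space) inversion could achieve, and
the package reports them honestly rather than presenting FC-only regional
estimates as well-identified. This is also why the vignette recommends
interpreting fitted regional parameters at network level, in paired
contrasts between cohorts fitted with common random numbers.

# Group statistics

The statistical battery mirrors the study's analyses at parcel level:

* `flip_to_ipsilateral()` swaps each right-sided patient's regional values
  with their contralateral homologues so lesions align on the left; the
  operation is an involution and never touches controls or GE subjects
  (side label `none`).
* `zscore_vs_controls()` z-scores every subject against the control mean
  and SD per region (sample SD, divisor $n-1$ -- one convention used
  everywhere in the package and pinned by tests).
* `glm_contrast()` fits per-region OLS with an intercept, the named
  covariates, and a two-level group indicator; with no covariates it
  reduces exactly to the pooled two-sample t test. Rank-deficient designs
  are rejected with the offending terms listed.
* `permutation_fwe()` controls family-wise error with max-statistic
  permutations in the Freedman-Lane style: data and group indicator are
  residualised on the nuisance covariates, the residualised indicator is
  permuted, and the maximum |t| across regions forms the null.
  $p_{FWE} = (1 + \#\{\max_t \ge |t_i|\}) / (n_{perm} + 1)$, floored at
  the parametric uncorrected p so corrected never undercuts uncorrected.
  This replaces the vertex-wise random-field-theory correction of
  surface-based pipelines, which needs surface geometry that is out of
  scope here; permutation is exact under exchangeability and directly
  testable (the test suite verifies the empirical FWER on a global null).
* `mahalanobis_d()` and `hotelling_t2()` provide the multivariate
  patient-vs-control dissimilarity and the two-sample T-squared test
  (`T2` at one feature equals the squared pooled t; the F conversion uses
  $F = T^2 (n_a + n_b - M - 1) / (M (n_a + n_b - 2))$).
* `parameter_contrast()` normalises regional between-group parameter
  differences by the SD of the differences *within the region's intrinsic
  network*. Cohort-level fits provide no subject-level spread, so the SD
  across the network's regions is the only computable reading of
  network-SD normalisation; this is the convention implemented and
  documented. Networks with zero spread are flagged rather than silently
  divided.

The thalamic-style univariate analyses can be run either as plain
t tests or with age/sex adjustment through the same `glm_contrast()`
interface; both paths are exposed because published descriptions of such
analyses are often ambiguous about covariate adjustment.

# Degenerate inputs and tie-breaks

* All-zero structural connectomes pass through `normalize_sc()` unchanged
  with a `degenerate` flag and a warning.
* Perfect correlations are clipped to $\pm(1 - 10^{-7})$ before the Fisher
  transform, so degenerate seeds yield large finite z rather than
  infinities.
* A failed or exploding simulation inside the inversion yields objective
  $-1$ with a `failed` flag and is treated as a rejected step; it never
  aborts a fit.
* `find_fixed_point()` flags non-convergence instead of throwing, since
  multistable configurations legitimately fail the damped iteration from
  some starting points.

# Known limitations

* The synthetic SC-FC baseline (~0.6-0.7) exceeds the empirical ~0.4, as
  discussed above; the package documents rather than disguises this.
* FC-only inversion is a hard, multimodal problem: distinct $(G, \sigma)$
  regimes can produce similar FC patterns, and the grid-scan plus
  common-random-number Gauss-Newton finds good optima but carries no
  global guarantee. Recovered global parameters should be read as
  regime-level, not point, estimates.
* No edge delays, no conductance-based dynamics, no regional hemodynamic
  variability, no subject-level hierarchical fitting -- all outside the
  model family this package implements.
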
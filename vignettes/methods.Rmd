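---
title: "Methods: posture tuning, population structure, and the network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture tuning, population structure, and the network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturenet)
```

This vignette documents the statistical methods implemented by
**posturenet**. Throughout, a *recording* is a long-format trial table
(neuron, target, forearm angle, trial, firing rate) over the task's 54
static posture conditions: 27 hand targets on a 3 x 3 x 3 lattice whose
main diagonal is 12.1 cm, each held in pronation and in supination.

```{r grid}
grid <- make_target_grid()
grid
```

`condition_index(target, angle)` maps a (target, angle) pair to a column in
the 1 x 54 response layout used everywhere below; `angle_columns()` returns
the 27 columns of one angle.

# 1. Tuning-curve models

Let $x_i \in \mathbb{R}^3$ be the target positions and $m_\theta(x_i)$ a
neuron's trial-averaged rate at angle $\theta$.

* **Spatial-linear model** (per angle, 4 parameters):
  $m(x) = a_0 + a^\top x$, fitted by ordinary least squares
  (`fit_linear_tuning()`). The fitted gradient direction
  $a / \lVert a \rVert$ is the *preferred position* (PP) vector; goodness of
  fit is the ordinary $R^2$.
* **Extended model** (`fit_extended_tuning()`, 8 parameters): both angles
  jointly, with a shared spatial gradient, an angle-specific gain and an
  angle-specific offset.
* **Multiplicative model** (`fit_multiplicative_tuning()`): a rank-one
  position-by-angle interaction fitted by alternating least squares.

Under the null of an unstructured 27-point response with i.i.d. Gaussian
entries, the linear-model $R^2$ follows a Beta distribution with shape
parameters $k/2$ and $(n - k - 1)/2 = (27 - 3 - 1)/2$, i.e.
$\mathrm{Beta}(3/2,\, 23/2)$, with mean $3/26 \approx 0.115$. The package's
tests verify this analytically known null by Kolmogorov–Smirnov test and
use it as the "chance" reference for tuning strength.

```{r beta-null}
curve(dbeta(x, 3/2, 23/2), 0, 1, xlab = expression(R^2),
      ylab = "null density")
```

## Response complexity

`complexity_measure()` quantifies spatial roughness on the lattice. The
27-point response is range-normalized (centred, divided by its range), the
absolute difference is taken across each of the 54 axis-aligned
nearest-neighbour target pairs, divided by the nearest-neighbour distance
$D_{\min}$, and the **standard deviation** of those 54 normalized
derivatives is reported. A constant response and any response that is
affine in position have low complexity; a parity checkerboard on the
lattice has complexity exactly 0 (all neighbour differences are equal in
magnitude); unstructured responses score high. Positions are in cm by
default; a `distance_unit` argument ("cm", "step", "diag") rescales
$D_{\min}$.

## Screening and confound checks

`screen_tuned()` applies a per-neuron one-way ANOVA over the 54 conditions.
`detect_jitter_segments()` flags within-hold movement periods from a speed
trace; `fit_velocity_tuning()` fits lagged linear kinematic models to
binned rates so that postural tuning can be checked against movement
confounds.

# 2. Synthetic surrogate populations

`generate_recording(synthetic_config())` draws, per neuron and angle,

$$ m_\theta(x) = \Big[\, b + A\big(\sqrt{f}\,L(x) +
   \sqrt{1-f}\,N_\theta(x)\big)\, g_\theta + \delta_\theta \Big]_+ , $$

where $L$ is a unit-norm linear map of position (the planted PP),
$N_\theta$ is a smooth Gaussian-process nonlinearity on the lattice with a
controllable smoothness length-scale and between-angle correlation, $f$ is
the neuron's planted *linear fraction* (Beta-distributed across the
population), $g_\theta$ and $\delta_\theta$ are per-angle gain and offset
perturbations, and the baseline $b$ is chosen by quantile so that the
population hits a target *coding level* (fraction of active
neuron-conditions) after rectification. Responses are affinely rescaled
into the configured rate range (never clipped), and trials add
gamma-distributed noise whose SD scales with the response range. All
planted quantities are returned as ground truth, which the test-suite
oracles rely on. `generate_emg_set()` produces smooth muscle tuning over
the 9-target EMG subset with a configurable nonlinear fraction per muscle.

Matched controls reproduce first-order statistics without the quantity
under test: `generate_linear_control()` (fitted linear predictions plus
resampled noise), `generate_random_control()` (range-matched unstructured
responses) and `generate_regular_nonlinear_control()` (smooth monotone
warps of linear responses).

# 3. Population dimensionality

`pca_signal_noise()` performs PCA on the neurons-by-54 mean-response matrix
and compares each eigenvalue with a noise floor obtained by bootstrapping
PCA spectra of *noise traces* — per-trial deviations from the condition
mean scaled by $1/\sqrt{K}$ for $K$ trials (`extract_noise_traces()`), so
the noise matrix has the variance of a trial-averaged mean. Two estimates
are reported: **strict** dimensionality (components whose eigenvalue
exceeds the bootstrap *maximum* noise eigenvalue at that rank) and **mean**
dimensionality (exceeding the bootstrap mean), with strict <= mean by
construction. `pc_linear_fit()` fits the spatial-linear model to individual
PC projections per angle; `explainable_variance_curve()` and
`pc_reconstruction_r2()` summarize how much trial-averaged signal the
leading components capture.

# 4. Pronation/supination interaction

For each neuron, the two 27-point tuning curves are compared:

* `pronation_supination_correlations()` — the per-neuron Pearson
  correlation between the pronation and the supination curve (flat curves
  excluded). A population whose angle effect is **purely additive**
  ($m_s = m_p + \delta$) or **purely multiplicative** ($m_s = g\, m_p$) has
  correlation exactly 1 for every neuron; sub-unity correlations indicate a
  non-separable position-by-angle interaction.
* `baseline_shift_test()` / `gain_change_test()` — per-neuron tests of
  additive offset and multiplicative gain between angles, each using
  trial-based split-half F statistics so that measurement noise enters the
  null and the alternative symmetrically.
* `correlation_controls()` — noise-matched reference distributions:
  `"bootstrap"` (observed mean vs observed mean plus one resampled noise
  trace: the correlation attainable given trial noise), `"splithalf"`
  (independent trial halves) and `"shuffle"` (condition-permuted, the
  chance level). `median_difference_test()` compares observed and control
  medians.

# 5. EMG decoding

`build_pseudo_population()` assembles pseudo-simultaneous trials by
randomly pairing trials across independently recorded neurons within each
condition. Decoders (`fit_linear_decoder()`):

* `"pinv"` — minimum-norm least squares via the Moore–Penrose
  pseudoinverse;
* `"lasso"` — L1-penalized regression (**glmnet**), penalty chosen by
  internal cross-validation; the package's tests verify the solution
  against the LASSO Karush–Kuhn–Tucker conditions.

`evaluate_decoding()` cross-validates over held-out conditions
(`make_cv_splits()`), reporting per-muscle correlation and normalized
error. `decompose_components()` splits each pseudo-trial response into its
spatial-linear component and the nonlinear residual (their sum plus the
condition mean reconstructs the trial exactly), so decoding can be
attributed to linear versus nonlinear response structure.
`pc_projection_decoding()` decodes from leading-PC projections to test how
many population dimensions the readout needs;
`subset_selection_summary()` summarizes LASSO support stability across
splits.

# 6. Random-connectivity network model

`posture_network()` composes two input layers:

* a **visual array** (`build_visual_array()`): Gaussian radial-basis units
  with tuning width $\sigma$ on a 3D lattice extending well beyond the
  target cube, whose population output is normalized to sum to one at every
  target (so width changes response *shape*, not overall drive);
* **forearm units** (`build_forearm_units()`): each visual input carries an
  angle gain, drawn uniform on $[1, 2]$ for its preferred angle and on
  $[0, 1]$ for the other, with half the inputs preferring each angle.

Each model neuron draws 10,000 random inputs with i.i.d. uniform weights
and responds through a threshold-linear nonlinearity
$r = [\,h - \varphi\,]_+$ (`simulate_m1()`, `apply_threshold()`).

Two scalar parameters are **calibrated, not fitted**:

* `calibrate_width()` — bisection on $\sigma$ so that the model's mean
  response complexity matches a reference value (e.g. the mean complexity
  of a recording), with deterministic per-width seeding so the objective is
  monotone and the bracket valid;
* `calibrate_threshold()` — bisection on $\varphi$ to a target coding
  level, either a single population threshold or per-neuron thresholds
  matched to a reference coding-level distribution.

Everything else about the model population — its linear-fit $R^2$
distribution and its pronation/supination correlation distribution — is
emergent. `fit_enhanced_widths()` additionally fits per-neuron width and
threshold on a grid; `generate_model_trials()` adds trial noise matched to
a reference recording's noise statistics;
`scale_to_reference_ranges()` maps model rates affinely onto reference
response ranges for side-by-side comparison.

```{r model, eval = FALSE}
syn <- generate_recording(synthetic_config(seed = 1), grid)
rs  <- response_from_trials(syn$recording)
cx  <- complexity_distribution(rs$mean, grid)

cal <- calibrate_width(mean(cx), grid, n_neurons = 150, seed = 2)
sim <- simulate_m1(cal$network, 400, seed = 3)
thr <- calibrate_threshold(sim, 0.85)
sim <- apply_threshold(sim, thr$threshold)

mean(pronation_supination_correlations(sim$rates)$r)
```

# 7. Pipeline

`run_posture_pipeline(pipeline_config(), out, seed)` chains the stages
(generate, tuning, pca, interaction, decoding, model) with seeds derived
deterministically from the master seed, writing one CSV per stage plus a
JSON manifest; reruns are byte-identical. `export_report(out)` renders PDF
summary panels for whichever tables are present.
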
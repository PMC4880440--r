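# posturenet

Analysis suite for single-neuron tuning to static 3D arm posture and a
random-connectivity feedforward network model of primary motor cortex.

The experimental design the package targets is a hold-at-target task: the
hand is held at one of 27 targets arranged on a 3 x 3 x 3 lattice (12.1 cm
main diagonal), at each of two forearm rotation angles (pronation /
supination), giving 54 static posture conditions with repeated trials per
condition. Muscle activity (EMG) is recorded at a 9-target subset (the 8
lattice corners plus the centre) at both angles.

## What the package provides

- **Task geometry** (`make_target_grid()`, `condition_table()`): the target
  lattice, the 54-condition layout, and the 54 axis-aligned nearest-neighbour
  target pairs used by the complexity measure.
- **Recordings** (`as_recording()`, `read_recording()`/`write_recording()`,
  `response_from_trials()`): a validated long-format trial table, CSV
  round-tripping, and trial-averaged condition responses with SEMs.
- **Synthetic surrogate data** (`synthetic_config()`,
  `generate_recording()`, `generate_emg_set()`): a generator with stored
  ground truth (planted preferred-position vectors, linear fractions, coding
  levels, trial noise) plus matched control populations
  (`generate_linear_control()`, `generate_random_control()`,
  `generate_regular_nonlinear_control()`).
- **Tuning curves** (`fit_linear_tuning()`, `fit_extended_tuning()`,
  `fit_multiplicative_tuning()`): classed S3 fits with
  `print`/`summary`/`coef`/`predict`/`residuals`, per-angle spatial-linear
  R-squared, preferred-position vectors, and the Beta(3/2, 23/2) null for
  unstructured 27-point responses. `complexity_measure()` implements the
  nearest-neighbour response-roughness statistic; `screen_tuned()` the
  ANOVA tuning screen; `detect_jitter_segments()` and
  `fit_velocity_tuning()` the movement-confound checks.
- **Dimensionality** (`pca_signal_noise()`, `pc_linear_fit()`,
  `explainable_variance_curve()`): population PCA against a
  trial-resampled noise floor, strict/mean dimensionality estimates, and
  linear fits of individual principal components.
- **Posture interaction** (`baseline_shift_test()`, `gain_change_test()`,
  `pronation_supination_correlations()`, `correlation_controls()`): additive
  versus multiplicative forearm-angle effects and per-neuron
  pronation/supination tuning-curve correlations with bootstrap, split-half
  and shuffle controls.
- **EMG decoding** (`build_pseudo_population()`, `fit_linear_decoder()`,
  `evaluate_decoding()`, `decompose_components()`,
  `pc_projection_decoding()`): pseudo-simultaneous population assembly,
  pseudoinverse and LASSO readouts with cross-validated correlation and
  error metrics, linear/nonlinear response decomposition, and decoding from
  leading-PC projections.
- **Network model** (`build_visual_array()`, `build_forearm_units()`,
  `posture_network()`, `simulate_m1()`, `calibrate_width()`,
  `calibrate_threshold()`): a Gaussian visual-input lattice combined with
  forearm-angle gain units through random uniform weights and a
  threshold-linear output nonlinearity; bisection calibration of the visual
  tuning width (to a reference complexity) and of the activation threshold
  (to a coding level), plus the enhanced per-neuron width/threshold fit
  (`fit_enhanced_widths()`) and trial generation
  (`generate_model_trials()`).
- **Pipeline and reporting** (`pipeline_config()`,
  `run_posture_pipeline()`, `export_report()`): a seeded end-to-end run that
  writes per-stage CSV tables and a JSON manifest, and renders summary PDF
  panels from whatever tables are present.

## Quick start

```r
library(posturenet)

grid <- make_target_grid()

# synthetic surrogate recording with stored ground truth
syn <- generate_recording(synthetic_config(seed = 1), grid)
rs  <- response_from_trials(syn$recording)

# single-neuron tuning
fit <- fit_linear_tuning(rs$mean[1, angle_columns("pronation")],
                         grid, "pronation")
summary(fit)
cx <- complexity_distribution(rs$mean, grid)

# population dimensionality
nt  <- extract_noise_traces(syn$recording)
dec <- pca_signal_noise(rs$mean, nt, n_boot = 100, seed = 2)
print(dec)

# pronation/supination interaction
cc <- pronation_supination_correlations(rs$mean)
print(cc)

# network model calibrated to the recording's complexity
cal <- calibrate_width(mean(cx), grid, n_neurons = 150, seed = 3)
sim <- simulate_m1(cal$network, 400, seed = 4)
thr <- calibrate_threshold(sim, 0.85)
sim <- apply_threshold(sim, thr$threshold)
```

Or run everything at once:

```r
run_posture_pipeline(pipeline_config(), "out/", seed = 1)
export_report("out/")
```

## Acceptance script

`scripts/acceptance.R` builds the calibrated network model end-to-end and
writes its four emergent population statistics (mean/SD of the per-angle
linear-fit R-squared distribution; mean/SD of the per-neuron
pronation/supination correlation distribution) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

It runs against the installed package and takes well under a minute.

## Tests

```r
testthat::test_dir("tests/testthat")   # or devtools::test()
```

The suite includes per-module unit tests, property/oracle tests
(brute-force complexity enumeration, analytic nulls, RNG-replication of the
simulator) and an end-to-end acceptance file.

See `vignette("methods", package = "posturenet")` for the statistical
methods in detail.
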
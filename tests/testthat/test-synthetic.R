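test_that("synthetic_config validates parameters", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_neurons = 0))
  expect_error(synthetic_config(linear_fraction = 1.2))
  expect_error(synthetic_config(noise_scale = -1))
  expect_error(synthetic_config(rate_range = c(10, 5)))
  expect_error(synthetic_config(noise_model = "cauchy"))
})

test_that("generation is deterministic in the seed", {
  g <- test_grid()
  cfg <- synthetic_config(n_neurons = 5L, seed = 77L)
  a <- generate_recording(cfg, g)
  b <- generate_recording(cfg, g)
  expect_identical(a$recording$rate_hz, b$recording$rate_hz)
  expect_identical(a$ground_truth$mean, b$ground_truth$mean)
  c_ <- generate_recording(synthetic_config(n_neurons = 5L, seed = 78L), g)
  expect_false(identical(a$recording$rate_hz, c_$recording$rate_hz))
})

test_that("zero noise reproduces the ground-truth means exactly", {
  g <- test_grid()
  syn <- generate_recording(
    synthetic_config(n_neurons = 6L, noise_scale = 0, seed = 2L), g)
  rs <- response_from_trials(syn$recording)
  expect_equal(unname(rs$mean), unname(syn$ground_truth$mean),
               tolerance = 1e-10)
})

test_that("a fully linear noise-free population fits with R^2 = 1", {
  g <- test_grid()
  syn <- generate_recording(
    synthetic_config(n_neurons = 8L, linear_fraction = 1,
                     linear_fraction_conc = 1e6, noise_scale = 0,
                     coding_level_target = 1, gain_sd = 0, shift_sd = 0,
                     seed = 3L), g)
  rs <- response_from_trials(syn$recording)
  for (i in 1:8) {
    f <- fit_linear_tuning(rs$mean[i, ], g, "pronation")
    expect_equal(f$r_squared, 1, tolerance = 1e-8)
    # fitted PP equals the stored ground-truth PP vector
    expect_equal(f$pp_vector, syn$ground_truth$pp[i, ], tolerance = 1e-6)
    expect_equal(fit_extended_tuning(rs$mean[i, ], g)$r_squared, 1,
                 tolerance = 1e-8)
  }
})

test_that("planted PP direction is recovered for strongly linear neurons", {
  g <- test_grid()
  # coding level 1 keeps the planted mean un-rectified, so the stored PP
  # is the true gradient of the response
  syn <- generate_recording(
    synthetic_config(n_neurons = 30L, linear_fraction = 0.95,
                     linear_fraction_conc = 200, noise_scale = 0.02,
                     coding_level_target = 1, seed = 4L), g)
  rs <- response_from_trials(syn$recording)
  for (i in seq_len(30L)) {
    f <- fit_linear_tuning(rs$mean[i, ], g, "pronation")
    if (f$r_squared < 0.9 || f$pp_norm == 0) next
    tp <- syn$ground_truth$pp[i, ]
    cosang <- sum(f$pp_vector * tp) /
      (f$pp_norm * sqrt(sum(tp^2)))
    expect_gt(cosang, cos(12 * pi / 180))
  }
})

test_that("realized coding level tracks the target", {
  syn <- small_synth()
  cl <- coding_level(syn$recording)
  expect_equal(mean(cl), syn$config$coding_level_target, tolerance = 0.04)
})

test_that("planted linear fraction correlates with fitted R^2", {
  syn <- small_synth()
  rs <- small_responses()
  g <- test_grid()
  r2 <- vapply(seq_len(nrow(rs$mean)), function(i)
    fit_extended_tuning(rs$mean[i, ], g)$r_squared, numeric(1))
  expect_gt(cor(syn$ground_truth$linear_fraction, r2), 0.5)
})

test_that("rougher nonlinear fields raise population complexity", {
  g <- test_grid()
  cx_of <- function(sm) {
    syn <- generate_recording(
      synthetic_config(n_neurons = 40L, linear_fraction = 0.2,
                       noise_scale = 0, nonlinear_smoothness = sm,
                       seed = 6L), g)
    mean(complexity_distribution(syn$ground_truth$mean, g))
  }
  expect_gt(cx_of(0.4), cx_of(2))
})

test_that("linear control equals predictions when noise pool is zero", {
  g <- test_grid()
  lin <- linear_recording(n = 6L, k = 1L, seed = 21L)
  fits <- lapply(seq_len(6L), function(i)
    fit_linear_tuning(lin$mean[i, angle_columns("pronation")], g))
  zero_pool <- matrix(0, 4L, 27L)
  ctrl <- generate_linear_control(fits, zero_pool, n_resamples = 2L,
                                  grid = g, seed = 1L)
  expect_equal(dim(ctrl), c(12L, 27L))
  expect_equal(attr(ctrl, "fit_index"), rep(1:6, times = 2L))
  preds <- t(vapply(fits, predict, numeric(27L), grid = g))
  expect_equal(unname(ctrl[1:6, ]), unname(preds), tolerance = 1e-10)
  # refit of noise-free linear controls is perfect
  expect_equal(fit_linear_tuning(ctrl[1, ], g)$r_squared, 1,
               tolerance = 1e-10)
})

test_that("random control stays in range and refits near zero", {
  set.seed(30)
  rr <- cbind(rep(0, 10), runif(10, 30, 60))
  ctrl <- generate_random_control(rr, matrix(0, 2L, 27L), seed = 2L)
  expect_true(all(ctrl >= 0 & ctrl <= rr[, 2]))
  g <- test_grid()
  r2 <- vapply(seq_len(10L), function(i)
    fit_linear_tuning(ctrl[i, ], g)$r_squared, numeric(1))
  expect_lt(median(r2), 0.4)
})

test_that("regular nonlinear controls are range-matched warps", {
  g <- test_grid()
  lin <- linear_recording(n = 5L, k = 1L, seed = 22L)
  fits <- lapply(seq_len(5L), function(i)
    fit_linear_tuning(lin$mean[i, angle_columns("pronation")], g))
  zero_pool <- matrix(0, 2L, 27L)
  preds <- t(vapply(fits, predict, numeric(27L), grid = g))
  # zero-curvature exponential is the identity warp
  ctrl0 <- generate_regular_nonlinear_control(
    fits, "exponential", zero_pool, shape_param = 0, grid = g, seed = 1L)
  expect_equal(as.vector(ctrl0), as.vector(preds), tolerance = 1e-10)
  for (kind in c("threshold-linear", "exponential", "sigmoid")) {
    ctrl <- generate_regular_nonlinear_control(
      fits, kind, zero_pool, grid = g, seed = 1L)
    expect_equal(unname(t(apply(ctrl, 1, range))),
                 unname(t(apply(preds, 1, range))), tolerance = 1e-8)
  }
})

test_that("complexity orders linear < regular nonlinear < random controls", {
  g <- test_grid()
  syn <- small_synth()
  rs <- small_responses()
  fits <- lapply(seq_len(nrow(rs$mean)), function(i)
    fit_linear_tuning(rs$mean[i, ], g, "pronation"))
  zero_pool <- matrix(0, 2L, 27L)
  cx <- function(M) {
    v <- apply(M, 1L, function(y)
      if (diff(range(y)) > 0) complexity_measure(y, g)$value else NA)
    mean(v, na.rm = TRUE)
  }
  lin <- generate_linear_control(fits, zero_pool, grid = g, seed = 3L)
  thr <- generate_regular_nonlinear_control(fits, "threshold-linear",
                                            zero_pool, grid = g, seed = 3L)
  rr <- t(apply(rs$mean, 1L, range))
  rnd <- generate_random_control(rr, zero_pool, seed = 3L)
  expect_lt(cx(lin), cx(thr))
  expect_lt(cx(thr), cx(rnd))
})

test_that("EMG set with zero nonlinearity is exactly linear in posture", {
  g <- test_grid()
  e <- generate_emg_set(g, seed = 5L, nonlinear_fraction = 0)
  cond <- e$emg$conditions
  pos <- g$positions[cond$target_index + 1L, ]
  sup <- as.numeric(cond$forearm_angle == "supination")
  for (m in 1:5) {
    y <- e$emg$mean_emg[m, ]
    fit <- lm.fit(cbind(1, pos, sup), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    expect_equal(r2, 1, tolerance = 1e-8)
  }
})

test_that("EMG set has the documented shape and ground truth", {
  e <- generate_emg_set(test_grid(), seed = 6L)
  expect_s3_class(e$emg, "emg_set")
  expect_equal(dim(e$emg$mean_emg), c(5L, 18L))
  expect_true(all(e$emg$mean_emg >= 0 & e$emg$mean_emg <= 1))
  expect_equal(e$ground_truth$nonlinear_fraction,
               c(0.2, 0.2, 0.2, 0.6, 0.6))
  expect_equal(dim(e$ground_truth$linear_coef), c(5L, 5L))
  tt <- emg_trial_targets(e$emg, 3L)
  expect_equal(dim(tt), c(5L, 54L))
  expect_equal(unname(tt[, 1:3]),
               unname(e$emg$mean_emg[, c(1, 1, 1)]))
})

test_that("gamma trial noise has the planted mean and SD", {
  g <- test_grid()
  cfg <- synthetic_config(n_neurons = 2L, trials_per_condition = 500L,
                          seed = 9L)
  syn <- generate_recording(cfg, g)
  rs <- response_from_trials(syn$recording)
  M <- syn$ground_truth$mean
  SD <- syn$ground_truth$noise_sd
  ok <- M > 10 & SD > 1         # away from the taper region
  z <- (rs$mean[ok] - M[ok]) / (SD[ok] / sqrt(500))
  expect_lt(max(abs(z)), 5)
  expect_lt(mean(abs(z)), 1.2)
  emp_sd <- rs$sem * sqrt(500)
  expect_equal(median(emp_sd[ok] / SD[ok]), 1, tolerance = 0.1)
  expect_true(all(syn$recording$rate_hz >= 0))
})
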
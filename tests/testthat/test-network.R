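# small network sizes keep these tests fast; the acceptance suite
# exercises the full-resolution model
small_va <- function(width = 2.5, n_per_axis = 12L, ...)
  build_visual_array(test_grid(), width, n_per_axis = n_per_axis, ...)

test_that("visual array geometry and normalization", {
  g <- test_grid()
  va <- small_va()
  expect_s3_class(va, "visual_array")
  expect_equal(nrow(va$tuning), 12L^3)
  expect_equal(nrow(va$centers), 12L^3)
  # per-target normalization: summed array activity is 1 at every target
  expect_equal(unname(colSums(va$tuning)), rep(1, 27), tolerance = 1e-12)
  # extent: outermost target plus extent_factor cube widths
  expect_equal(va$extent, g$spacing + 3 * 2 * g$spacing)
  expect_equal(max(va$centers), va$extent)
  expect_equal(min(va$centers), -va$extent)
  # brute-force oracle on a tiny array
  va3 <- build_visual_array(g, 3, n_per_axis = 3L)
  ax <- seq(-va3$extent, va3$extent, length.out = 3L)
  ctr <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  raw <- sapply(1:27, function(t)
    exp(-rowSums(sweep(ctr, 2L, g$positions[t, ])^2) / (2 * 9)))
  expect_equal(unname(va3$tuning),
               unname(sweep(raw, 2L, colSums(raw), "/")),
               tolerance = 1e-12)
})

test_that("visual array validates width and supports distributions", {
  expect_error(build_visual_array(test_grid(), -1, n_per_axis = 3L))
  expect_error(build_visual_array(test_grid(), c(1, 3), n_per_axis = 3L))
  va <- small_va(width = c(2.5, 1), n_per_axis = 8L, seed = 4L)
  expect_true(all(va$widths >= 2 & va$widths <= 3))
  expect_gt(sd(va$widths), 0)
  # a scalar width gives identical widths
  expect_equal(sd(small_va(n_per_axis = 8L)$widths), 0)
})

test_that("forearm units have the documented gain structure", {
  fu <- build_forearm_units(n = 4000L, seed = 5L)
  expect_equal(dim(fu$gain), c(4000L, 2L))
  expect_true(all(fu$gain >= 0 & fu$gain <= 2))
  pref_sup <- fu$gain[, 2L] > fu$gain[, 1L]
  expect_equal(mean(pref_sup), 0.5, tolerance = 0.05)
  # preferred-angle gains live on [1,2], other on [0,1]
  hi <- pmax(fu$gain[, 1L], fu$gain[, 2L])
  lo <- pmin(fu$gain[, 1L], fu$gain[, 2L])
  expect_true(all(hi >= 1))
  expect_true(all(lo <= 1))
  expect_equal(mean(hi), 1.5, tolerance = 0.05)
  expect_equal(mean(lo), 0.5, tolerance = 0.05)
})

test_that("simulate_m1 matches a brute-force double loop", {
  va <- small_va(n_per_axis = 6L)
  fu <- build_forearm_units(n = 300L, seed = 6L)
  net <- posture_network(va, fu, n_inputs = 500L)
  sim <- simulate_m1(net, 2L, seed = 7L)
  expect_equal(dim(sim$h), c(2L, 54L))
  # replicate the RNG stream and accumulate inputs one by one
  set.seed(7L)
  H <- matrix(0, 2L, 54L)
  for (j in 1:2) {
    iv <- sample.int(nrow(va$tuning), 500L, replace = TRUE)
    ig <- sample.int(300L, 500L, replace = TRUE)
    J <- runif(500L)
    for (i in 1:500) {
      for (t in 1:27) {
        H[j, 2 * t - 1] <- H[j, 2 * t - 1] +
          J[i] * va$tuning[iv[i], t] * fu$gain[ig[i], 1L]
        H[j, 2 * t] <- H[j, 2 * t] +
          J[i] * va$tuning[iv[i], t] * fu$gain[ig[i], 2L]
      }
    }
  }
  expect_equal(sim$h, H, tolerance = 1e-10)
  # zero threshold: all inputs are nonnegative products, so coding is 1
  expect_true(all(sim$rates > 0))
  expect_equal(sim$rates, sim$h)
})

test_that("threshold calibration hits its target and is monotone", {
  va <- small_va(n_per_axis = 8L)
  fu <- build_forearm_units(n = 2000L, seed = 8L)
  net <- posture_network(va, fu, n_inputs = 2000L)
  sim <- simulate_m1(net, 60L, seed = 9L)
  cal85 <- calibrate_threshold(sim, 0.85)
  expect_equal(cal85$achieved, 0.85, tolerance = 1e-3)
  expect_true(cal85$converged)
  cal50 <- calibrate_threshold(sim, 0.50)
  expect_gt(cal50$threshold, cal85$threshold)
  # coding_target = 1 keeps every condition active
  cal1 <- calibrate_threshold(sim, 1)
  expect_equal(mean(apply_threshold(sim, cal1$threshold)$rates > 0), 1)
  # per-neuron mode matches each neuron's drawn reference level
  ref <- runif(200, 0.5, 1)
  calp <- calibrate_threshold(sim, reference_coding = ref, seed = 10L)
  expect_length(calp$threshold, 60L)
  simp <- apply_threshold(sim, calp$threshold)
  per_neuron <- rowMeans(simp$rates > 0)
  expect_true(all(per_neuron >= min(ref) - 1 / 54))
  expect_equal(mean(per_neuron), mean(ref), tolerance = 0.05)
  # a target between the attainable 1/54 steps errors out
  sim1 <- simulate_m1(net, 1L, seed = 11L)
  expect_error(calibrate_threshold(sim1, 0.013, tol = 1e-6),
               "unattainable")
})

test_that("complexity decreases with visual width and calibrates back", {
  g <- test_grid()
  # the array must resolve the tuning width; 16 units/axis puts the
  # centre spacing near 3 cm, below the widths probed here
  cx_at <- function(w) {
    sim <- simulate_m1(
      posture_network(small_va(width = w, n_per_axis = 16L),
                      build_forearm_units(1000L, seed = 12L),
                      n_inputs = 1000L), 25L, seed = 13L)
    cal <- calibrate_threshold(sim, 0.85)
    mean(complexity_distribution(apply_threshold(sim, cal$threshold)$rates,
                                 g))
  }
  widths <- c(1.8, 2.8, 4.2)
  cx <- vapply(widths, cx_at, numeric(1L))
  expect_true(all(diff(cx) < 0))
  # calibrating to the middle complexity recovers a width near 2.8
  # (the calibration draws its own networks, so only approximately)
  cal <- calibrate_width(cx[2], g, bracket = c(1.8, 4.2),
                         coding_target = 0.85, n_neurons = 25L,
                         n_per_axis = 16L, n_inputs = 1000L,
                         tol = 0.05, seed = 12L)
  expect_true(cal$converged)
  expect_lt(abs(cal$width - 2.8), 0.8)
  expect_lt(abs(cal$achieved - cx[2]), 0.05 * cx[2])
  # an unbracketable target errors before iterating
  expect_error(
    calibrate_width(cx[1] * 10, g, bracket = c(1.8, 4.2),
                    n_neurons = 25L, n_per_axis = 16L,
                    n_inputs = 1000L, seed = 12L),
    "not bracketed")
})

test_that("enhanced width fit returns the best grid point", {
  g <- test_grid()
  ref_coding <- runif(100, 0.6, 1)
  ef <- fit_enhanced_widths(
    target_complexity = 0.05, target_r2_mean = 0.4, target_r2_sd = 0.19,
    reference_coding = ref_coding, grid = g,
    width_means = c(1.8, 2.6), width_ranges = c(0, 1.2),
    refine = FALSE, n_neurons = 25L, n_per_axis = 10L,
    n_inputs = 1000L, seed = 14L)
  expect_s3_class(ef, "enhanced_fit")
  expect_equal(dim(ef$grid_loss), c(2L, 2L))
  expect_equal(ef$loss, min(ef$grid_loss, na.rm = TRUE))
  expect_true(ef$width_mean %in% c(1.8, 2.6))
  expect_true(ef$width_range %in% c(0, 1.2))
  expect_true(is.finite(ef$model_r2_sd))
  expect_s3_class(ef$simulation, "m1_simulation")
})

test_that("scaling to reference ranges is an exact affine match", {
  va <- small_va(n_per_axis = 8L)
  fu <- build_forearm_units(1000L, seed = 15L)
  sim <- simulate_m1(posture_network(va, fu, n_inputs = 1000L), 20L,
                     seed = 16L)
  cal <- calibrate_threshold(sim, 0.85)
  sim <- apply_threshold(sim, cal$threshold)
  # plant one flat neuron
  sim$rates[3, ] <- 0
  R <- small_responses()$mean
  sc <- scale_to_reference_ranges(sim, R, seed = 17L)
  expect_false(3 %in% sc$kept)
  expect_equal(nrow(sc$rates), 19L)
  # each scaled neuron's range equals some reference neuron's range
  ref_rng <- sort(round(apply(R, 1L, function(v) diff(range(v))), 8))
  mod_rng <- round(apply(sc$rates, 1L, function(v) diff(range(v))), 8)
  expect_true(all(mod_rng %in% ref_rng))
  # affine map preserves the response shape exactly
  k <- sc$kept[1L]
  expect_equal(cor(sc$rates[1, ], sim$rates[k, ]), 1, tolerance = 1e-12)
})

test_that("generate_model_trials adds rate-matched reference noise", {
  va <- small_va(n_per_axis = 8L)
  fu <- build_forearm_units(1000L, seed = 18L)
  sim <- simulate_m1(posture_network(va, fu, n_inputs = 1000L), 10L,
                     seed = 19L)
  cal <- calibrate_threshold(sim, 0.85)
  sim <- apply_threshold(sim, cal$threshold)
  R <- small_responses()$mean
  sim <- scale_to_reference_ranges(sim, R, seed = 20L)
  # noise-free reference: trials equal the model means exactly
  M0 <- matrix(runif(3 * 54, 5, 40), 3, 54)
  ct <- condition_table()
  ref0 <- as_recording(do.call(rbind, lapply(1:3, function(i) data.frame(
    neuron_id = sprintf("r%d", i),
    target_index = rep(ct$target_index, each = 2L),
    forearm_angle = rep(ct$forearm_angle, each = 2L),
    trial_index = rep(1:2, 54L),
    rate_hz = rep(M0[i, ], each = 2L), stringsAsFactors = FALSE))))
  tr0 <- generate_model_trials(sim, ref0, trials_per_condition = 4L,
                               seed = 21L)
  rs0 <- response_from_trials(tr0)
  expect_equal(unname(rs0$mean), unname(sim$rates), tolerance = 1e-9)
  expect_equal(unname(rs0$sem), matrix(0, nrow(sim$rates), 54L),
               tolerance = 1e-12)
  # noisy reference: trial means are unbiased around the model means
  syn <- small_synth()
  tr <- generate_model_trials(sim, syn$recording,
                              trials_per_condition = 40L, seed = 22L)
  rs <- response_from_trials(tr)
  expect_true(all(tr$rate_hz >= 0))
  # trial means track the model means; the zero-clamp biases strongly
  # noisy low-rate conditions upward, so only near-unbiasedness holds
  big <- sim$rates > 10
  expect_lt(abs(mean(rs$mean[big] - sim$rates[big])),
            0.15 * mean(sim$rates[big]))
  # determinism
  tr2 <- generate_model_trials(sim, syn$recording,
                               trials_per_condition = 40L, seed = 22L)
  expect_identical(tr$rate_hz, tr2$rate_hz)
})

test_that("model statistics are robust to array resolution", {
  g <- test_grid()
  stat_at <- function(npa) {
    sim <- simulate_m1(
      posture_network(small_va(width = 3.5, n_per_axis = npa),
                      build_forearm_units(2000L, seed = 23L),
                      n_inputs = 2000L), 40L, seed = 24L)
    cal <- calibrate_threshold(sim, 0.85)
    sim <- apply_threshold(sim, cal$threshold)
    c(cx = mean(complexity_distribution(sim$rates, g)),
      r2 = mean(.pooled_linear_r2(sim$rates, g)))
  }
  a <- stat_at(16L); b <- stat_at(22L)
  expect_lt(abs(a[["cx"]] - b[["cx"]]), 0.15 * a[["cx"]])
  expect_lt(abs(a[["r2"]] - b[["r2"]]), 0.1)
})
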
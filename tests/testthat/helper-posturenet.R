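# shared fixtures, memoized so expensive objects are built once per run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

test_grid <- function() fixture("grid", function() make_target_grid())

# a small default-config synthetic recording shared by many tests
small_synth <- function() fixture("small_synth", function()
  generate_recording(synthetic_config(n_neurons = 60L, seed = 101L),
                     test_grid()))

small_responses <- function() fixture("small_responses", function()
  response_from_trials(small_synth()$recording))

# build a purely linear noise-free recording: rates = a0 + PP.x, one
# trial per condition repeated k times
linear_recording <- function(n = 20L, k = 3L, seed = 1L,
                             shared_a0 = NULL) {
  g <- test_grid()
  set.seed(seed)
  ct <- condition_table()
  rows <- list()
  M <- matrix(0, n, 54L)
  for (i in seq_len(n)) {
    if (is.null(shared_a0)) {
      a0 <- runif(1, 20, 40)
      pp <- rnorm(3)
      m27 <- a0 + drop(g$positions %*% pp)
      m27 <- m27 - min(m27) + 5        # keep nonnegative
    } else {
      # truly shared offset: bound |PP| so rates stay positive without
      # any per-neuron shift (which would add a 4th population dimension)
      pp <- rnorm(3)
      pp <- pp / sqrt(sum(pp^2)) * runif(1, 1, 3)
      m27 <- shared_a0 + drop(g$positions %*% pp)
      stopifnot(all(m27 > 0))
    }
    m54 <- m27[ct$target_index + 1L]
    M[i, ] <- m54
    rows[[i]] <- data.frame(
      neuron_id = sprintf("lin%03d", i),
      target_index = rep(ct$target_index, each = k),
      forearm_angle = rep(ct$forearm_angle, each = k),
      trial_index = rep(seq_len(k), 54L),
      rate_hz = rep(m54, each = k),
      stringsAsFactors = FALSE)
  }
  list(recording = as_recording(do.call(rbind, rows)), mean = M)
}

# the calibrated network chain used by the acceptance blocks; built once
calibrated_model <- function() fixture("calibrated_model", function() {
  g <- test_grid()
  syn <- generate_recording(synthetic_config(seed = 11L), g)
  rs <- response_from_trials(syn$recording)
  ref_cx <- complexity_distribution(rs$mean, g, "cm")
  cal <- calibrate_width(mean(ref_cx), g, n_neurons = 150L, seed = 9L)
  sim <- simulate_m1(cal$network, 400L, seed = 123L)
  thr <- calibrate_threshold(sim, 0.85)
  sim <- apply_threshold(sim, thr$threshold)
  list(synthetic = syn, responses = rs, reference_cx = ref_cx,
       calibration = cal, simulation = sim, threshold = thr)
})
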
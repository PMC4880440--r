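# recording over all 54 conditions whose trial rates are condition means
# plus Gaussian noise; means given as neurons x 54
mk_rec54 <- function(M, k = 6L, sd = 0, seed = 1L) {
  set.seed(seed)
  ct <- condition_table()
  rows <- lapply(seq_len(nrow(M)), function(i) data.frame(
    neuron_id = sprintf("d%03d", i),
    target_index = rep(ct$target_index, each = k),
    forearm_angle = rep(ct$forearm_angle, each = k),
    trial_index = rep(seq_len(k), 54L),
    rate_hz = pmax(0, rep(M[i, ], each = k) + rnorm(54L * k, sd = sd)),
    stringsAsFactors = FALSE))
  as_recording(do.call(rbind, rows))
}

test_that("pseudo-population has the right shape and drops short neurons", {
  set.seed(50)
  M <- matrix(runif(10 * 54, 5, 40), 10, 54)
  rec <- mk_rec54(M, k = 6L, sd = 1, seed = 51L)
  # remove trials from one neuron in one EMG condition
  cut <- with(rec, neuron_id == "d004" & target_index == 0 &
                forearm_angle == "pronation" & trial_index > 2)
  pop <- build_pseudo_population(as_recording(rec[!cut, ]),
                                 n_trials = 6L, seed = 1L)
  expect_s3_class(pop, "pseudo_population")
  expect_equal(dim(pop$rates), c(6L, 9L, 18L))
  expect_false("d004" %in% pop$neuron_id)
  expect_equal(nrow(pop$conditions), 18L)
  # per-neuron condition sets of trial values survive the shuffling
  byc <- trials_by_condition(as_recording(rec[!cut, ]), "d001")
  expect_setequal(pop$rates[, "d001", 1],
                  byc[[pop$conditions$condition[1]]])
  expect_error(build_pseudo_population(rec, n_trials = 7L), "trials")
})

test_that("cv splits hold out one valid trial per condition", {
  sp <- make_cv_splits(6L, 18L, n_splits = 200L, seed = 2L)
  expect_equal(dim(sp), c(200L, 18L))
  expect_true(all(sp >= 1L & sp <= 6L))
  # all trials appear as held-out somewhere
  expect_setequal(unique(as.vector(sp)), 1:6)
  expect_error(make_cv_splits(1L, 18L), "n_trials")
})

test_that("pinv decoder is exact on noise-free linearly decodable data", {
  set.seed(52)
  n <- 12L
  M <- matrix(runif(n * 54, 5, 40), n, 54)
  rec <- mk_rec54(M, k = 4L, sd = 0, seed = 53L)
  pop <- build_pseudo_population(rec, n_trials = 4L, seed = 3L)
  A <- matrix(runif(5 * n, 0, 1), 5, n)
  Mc <- t(sapply(pop$neuron_id, function(id)
    M[as.integer(sub("d", "", id)), pop$conditions$condition]))
  emg_means <- A %*% Mc
  emg_means <- emg_means / max(emg_means)
  e <- emg_set(emg_means)
  res <- evaluate_decoding(pop, e, "pinv", n_splits = 20L, seed = 4L)
  expect_s3_class(res, "decoding_result")
  expect_equal(unname(res$median_cc), rep(1, 5), tolerance = 1e-6)
  expect_lt(max(res$error_sd_pct), 1e-6)
  expect_equal(unname(res$n_missing_cc), rep(0, 5))
})

test_that("decoding from condition-free rates shows no leakage", {
  set.seed(54)
  # rates carry no condition information at all: any above-chance CC on
  # held-out trials would indicate train/test leakage
  M <- matrix(rep(runif(15, 10, 40), 54), 15, 54)
  rec <- mk_rec54(M, k = 5L, sd = 8, seed = 55L)
  pop <- build_pseudo_population(rec, n_trials = 5L, seed = 5L)
  e <- emg_set(matrix(runif(90), 5, 18))   # unrelated to the rates
  res <- evaluate_decoding(pop, e, "pinv", n_splits = 40L, seed = 6L)
  expect_lt(abs(median(as.vector(res$cc), na.rm = TRUE)), 0.3)
})

test_that("lasso decoder selects the informative neurons", {
  set.seed(56)
  n <- 30L
  M <- matrix(20, n, 54)
  info <- 1:3
  M[info, ] <- matrix(runif(3 * 54, 5, 40), 3, 54)
  rec <- mk_rec54(M, k = 6L, sd = 1, seed = 57L)
  pop <- build_pseudo_population(rec, n_trials = 6L, seed = 7L)
  Mc <- t(sapply(pop$neuron_id, function(id)
    M[as.integer(sub("d", "", id)), pop$conditions$condition]))
  W <- matrix(0, 5, n)
  W[cbind(1:5, c(1, 2, 3, 1, 2))] <- c(1, 1, 1, 0.5, 0.8)
  emg_means <- W %*% Mc
  e <- emg_set(emg_means / max(emg_means))
  res <- evaluate_decoding(pop, e, "lasso", n_splits = 4L, seed = 8L,
                           keep_weights = TRUE)
  expect_gt(min(res$median_cc), 0.95)
  # sparse solutions: far fewer neurons used than available
  expect_lt(median(res$n_nonzero), n / 2)
  ss <- subset_selection_summary(res, alpha = 0.05)
  # the planted informative neuron of each muscle is always selected
  for (m in 1:5) {
    planted <- sprintf("d%03d", c(1, 2, 3, 1, 2)[m])
    expect_equal(unname(ss$selection_freq[planted, m]), 1)
  }
  expect_equal(dim(ss$pct_selected_per_split), c(4L, 5L))
  expect_equal(sum(ss$n_muscles_per_neuron), mean(rowSums(ss$selection_freq > 0) > 0))
})

test_that("lasso solutions satisfy the KKT conditions", {
  set.seed(58)
  n_obs <- 90L; p <- 20L
  x <- matrix(rnorm(n_obs * p), n_obs, p)
  beta <- c(3, -2, 1.5, rep(0, p - 3))
  y <- drop(x %*% beta) + rnorm(n_obs, sd = 0.3)
  dec <- fit_linear_decoder(x, y, "lasso", seed = 9L)
  lam <- dec$lambda
  r <- y - predict(dec, x)
  grad <- drop(crossprod(x, r)) / n_obs
  act <- dec$weights != 0
  expect_true(any(act))
  # active coordinates: gradient equals lambda * sign(weight)
  expect_equal(unname(grad[act]), unname(lam * sign(dec$weights[act])),
               tolerance = 0.02)
  # inactive coordinates: |gradient| below lambda
  if (any(!act)) expect_lt(max(abs(grad[!act])), lam * 1.05)
  # and the planted support is recovered
  expect_true(all(which(abs(beta) > 0) %in% which(act)))
})

test_that("subset_selection_summary requires stored weights", {
  set.seed(59)
  M <- matrix(runif(6 * 54, 5, 40), 6, 54)
  rec <- mk_rec54(M, k = 4L, sd = 1, seed = 60L)
  pop <- build_pseudo_population(rec, n_trials = 4L, seed = 10L)
  e <- emg_set(matrix(runif(90), 5, 18))
  res <- evaluate_decoding(pop, e, "pinv", n_splits = 3L, seed = 11L)
  expect_error(subset_selection_summary(res), "keep_weights")
})

test_that("component decomposition obeys its algebraic identity", {
  syn <- small_synth()
  rs <- small_responses()
  pop <- build_pseudo_population(syn$recording, n_trials = 14L,
                                 seed = 12L)
  dc <- decompose_components(pop, rs$mean, test_grid(), alpha = 0.05)
  expect_gt(length(dc$linear$neuron_id), 2L)
  expect_equal(dc$n_excluded + length(dc$linear$neuron_id),
               length(pop$neuron_id))
  # per neuron/condition: raw - lin = nl_mean and raw - nl = lin_pred,
  # so 2*raw - lin - nl equals the condition mean of the raw trials
  raw <- pop$rates[, pop$neuron_id %in% dc$linear$neuron_id, ,
                   drop = FALSE]
  lhs <- 2 * raw - dc$linear$rates - dc$nonlinear$rates
  cond_means <- apply(raw, c(2L, 3L), mean)
  expect_lt(max(abs(sweep(lhs, c(2L, 3L), cond_means))), 1e-9)
  expect_error(decompose_components(pop, rs$mean, test_grid(),
                                    alpha = 0.2), "alpha")
})

test_that("PC-projection decoding saturates and matches full rank", {
  set.seed(61)
  n <- 10L
  M <- matrix(runif(n * 54, 5, 40), n, 54)
  rec <- mk_rec54(M, k = 5L, sd = 2, seed = 62L)
  pop <- build_pseudo_population(rec, n_trials = 5L, seed = 13L)
  A <- matrix(runif(5 * n), 5, n)
  Mc <- t(sapply(pop$neuron_id, function(id)
    M[as.integer(sub("d", "", id)), pop$conditions$condition]))
  e <- emg_set((A %*% Mc) / max(A %*% Mc))
  pcc <- pc_projection_decoding(pop, e, k_values = c(1L, 3L, n),
                                n_splits = 15L, seed = 14L)
  expect_s3_class(pcc, "pc_decoding_curve")
  expect_equal(pcc$curve$k, c(1L, 3L, n))
  # more components never hurt much; rank-1 is clearly worse
  expect_gt(pcc$curve$median_cc[3], pcc$curve$median_cc[1])
  # full-rank projection reproduces the unprojected pinv decode
  full <- evaluate_decoding(pop, e, "pinv", n_splits = 15L, seed = 14L)
  expect_equal(unname(pcc$results[[as.character(n)]]$median_cc),
               unname(full$median_cc), tolerance = 1e-6)
  # over-rank request is capped with a warning
  expect_warning(pc_projection_decoding(pop, e, k_values = 100L,
                                        n_splits = 2L, seed = 15L),
                 "capped")
})
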
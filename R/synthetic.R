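#' Configuration of the surrogate-recording generator
#'
#' The generator emulates the statistical structure of single-unit M1
#' recordings during static arm posture: each neuron's mean response over
#' the 54 conditions is a rectified sum of a linear-in-position component,
#' an irregular smooth nonlinear field, and forearm-angle gain and offset
#' effects; single trials add rate-dependent noise.  Defaults are anchored
#' to the published population statistics this suite is designed around
#' (see the methods vignette): ~14 trials per condition, population coding
#' level 0.85, a broad linear-fit R-squared distribution with median near
#' 0.5, pronation/supination correlations with median near 0.55, and
#' additive-shift / gain-change dispersions of a few spikes/s.
#'
#' @param n_neurons Number of neurons.
#' @param trials_per_condition Trials per condition (default 14).
#' @param coding_level_target Mean fraction of conditions driving a neuron
#'   (default 0.85); per-neuron coding levels are drawn from a Beta
#'   distribution with this mean.
#' @param linear_fraction Mean share of a neuron's signal variance carried
#'   by the linear component (default 0.42); per-neuron shares are drawn
#'   from a Beta distribution around this mean.
#' @param linear_fraction_conc Concentration of that Beta (larger =
#'   narrower; default 2.2).
#' @param nonlinear_smoothness Correlation length of the nonlinear random
#'   field, in units of the lattice constant (default 0.8).
#' @param angle_correlation Fraction of nonlinear-field variance shared
#'   between the two forearm angles (default 0.55): sets the width of the
#'   pronation/supination correlation distribution.
#' @param noise_scale Single-trial noise SD as a fraction of the neuron's
#'   rate range (default 0.65; cortical trial-to-trial variability is of
#'   the order of the response range itself), tapering to zero below the
#'   activity floor so silent conditions stay silent.
#' @param noise_model \code{"gamma"} (default): trial rates drawn from a
#'   gamma law with the condition's mean and the scaled SD — the
#'   nonnegative-support stand-in for additive Gaussian noise, avoiding
#'   the upward bias that zero-clamping a Gaussian puts on low-rate
#'   conditions; \code{"gaussian"}: additive Gaussian clamped at zero;
#'   \code{"poisson"}: counts over the 200 ms window.
#' @param gain_sd SD of the supination/pronation gain ratio around 1
#'   (default 0.25).
#' @param shift_sd SD of the additive supination offset, spikes/s
#'   (default 4).
#' @param rate_range Global range of firing rates (spikes/s); per-neuron
#'   amplitudes are drawn within it (default c(0, 60)).
#' @param seed Integer seed.
#' @return A list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_neurons = 200L,
                             trials_per_condition = 14L,
                             coding_level_target = 0.85,
                             linear_fraction = 0.50,
                             linear_fraction_conc = 2.2,
                             nonlinear_smoothness = 0.8,
                             angle_correlation = 0.35,
                             noise_scale = 0.54,
                             noise_model = c("gamma", "gaussian",
                                             "poisson"),
                             gain_sd = 0.25,
                             shift_sd = 4,
                             rate_range = c(0, 60),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_neurons >= 1L, trials_per_condition >= 1L,
            coding_level_target > 0, coding_level_target <= 1,
            linear_fraction >= 0, linear_fraction <= 1,
            nonlinear_smoothness > 0, angle_correlation >= 0,
            angle_correlation <= 1, noise_scale >= 0,
            gain_sd >= 0, shift_sd >= 0, length(rate_range) == 2L,
            rate_range[2L] > rate_range[1L])
  structure(as.list(environment()), class = "synthetic_config")
}

# squared-exponential covariance over the 27 targets, length in D_min units
.grf_chol <- function(grid, smoothness) {
  D <- as.matrix(stats::dist(grid$positions / grid$d_min))
  K <- exp(-D^2 / (2 * smoothness^2))
  chol(K + diag(1e-8, nrow(K)))
}

.std <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Generate a surrogate recording with stored ground truth
#'
#' Draws a population of synthetic neurons under a
#' \code{\link{synthetic_config}} and samples single-trial firing rates
#' for every condition.  Each neuron's noise-free mean response is
#' \deqn{m_\theta(x) = [\,b + A(\sqrt f\, L(x) + \sqrt{1-f}\, N_\theta(x))
#'   \cdot g_\theta + \delta_\theta\,]_+}
#' with \eqn{L} a unit-variance linear field along a random preferred
#' direction (shared by both angles), \eqn{N_\theta} a unit-variance
#' Gaussian random field with squared-exponential correlation that shares
#' a fraction \code{angle_correlation} of its variance across angles,
#' a supination gain \eqn{g} and offset \eqn{\delta}, and a baseline set so
#' the neuron's coding level matches its drawn target.  The returned
#' ground truth stores every planted quantity for recovery tests.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param grid Target grid.
#' @return A list of class \code{"synthetic_recording"}:
#'   \item{recording}{long-format single-trial recording
#'     (\code{\link{as_recording}});}
#'   \item{ground_truth}{list with \code{mean} (neurons x 54 noise-free
#'     mean rates), \code{pp} (neurons x 3 true PP vectors, spikes/s/cm),
#'     \code{linear_fraction}, \code{gain}, \code{shift},
#'     \code{coding_target}, \code{noise_sd} (neurons x 54).}
#' @export
generate_recording <- function(config = synthetic_config(),
                               grid = make_target_grid()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_neurons)
  if (n < 1L) stop("n_neurons must be >= 1")
  ch <- .grf_chol(grid, config$nonlinear_smoothness)
  pos <- grid$positions
  floor_hz <- 5
  cl_mean <- config$coding_level_target
  cl_a <- 12 * cl_mean; cl_b <- 12 * (1 - cl_mean)
  lf_a <- config$linear_fraction_conc * config$linear_fraction
  lf_b <- config$linear_fraction_conc * (1 - config$linear_fraction)

  M <- matrix(0, n, 54L)
  PP <- matrix(0, n, 3L)
  f_i <- g_i <- d_i <- c_i <- A_i <- numeric(n)
  pcols <- angle_columns("pronation"); scols <- angle_columns("supination")
  for (i in seq_len(n)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    L <- .std(drop(pos %*% u))
    rho <- config$angle_correlation
    S  <- .std(drop(crossprod(ch, stats::rnorm(27))))
    Ep <- .std(drop(crossprod(ch, stats::rnorm(27))))
    Es <- .std(drop(crossprod(ch, stats::rnorm(27))))
    Np <- .std(sqrt(rho) * S + sqrt(1 - rho) * Ep)
    Ns <- .std(sqrt(rho) * S + sqrt(1 - rho) * Es)
    f <- stats::rbeta(1, lf_a, lf_b)
    A <- stats::runif(1, 0.12, 0.30) * diff(config$rate_range)
    shp_p <- sqrt(f) * L + sqrt(1 - f) * Np
    shp_s <- sqrt(f) * L + sqrt(1 - f) * Ns
    g <- max(0.2, stats::rnorm(1, 1, config$gain_sd))
    dl <- stats::rnorm(1, 0, config$shift_sd)
    cl <- stats::rbeta(1, cl_a, cl_b)
    raw <- c(A * shp_p, A * g * shp_s + dl)
    # baseline: the drawn fraction of conditions sits above the floor,
    # with a small margin so trial noise does not push borderline
    # conditions below the measured-activity criterion
    b <- floor_hz + 2.5 - stats::quantile(raw, 1 - cl, names = FALSE)
    m <- pmax(raw + b, 0)
    # keep within the global rate range by affine rescaling (preserves
    # response shape exactly), never by clipping
    fac <- if (max(m) > config$rate_range[2L])
      config$rate_range[2L] / max(m) else 1
    m <- m * fac
    M[i, pcols] <- m[1:27]; M[i, scols] <- m[28:54]
    PP[i, ] <- fac * A * sqrt(f) * u / stats::sd(drop(pos %*% u))
    f_i[i] <- f; g_i[i] <- g; d_i[i] <- dl; c_i[i] <- cl; A_i[i] <- A
  }
  ids <- sprintf("syn%04d", seq_len(n))
  rownames(M) <- ids

  rng_i <- apply(M, 1L, function(v) diff(range(v)))
  sd_base <- config$noise_scale * rng_i       # per-trial SD, spikes/s
  taper <- pmin(1, M / floor_hz)
  SD <- sd_base * taper                       # neurons x 54
  K <- as.integer(config$trials_per_condition)
  ct <- condition_table()
  rows <- n * 54L * K
  mu <- rep(as.vector(t(M)), each = K)
  sg <- rep(as.vector(t(SD)), each = K)
  rate <- switch(config$noise_model,
    gamma = {
      r <- numeric(rows)
      pos <- mu > 0 & sg > 0
      r[pos] <- stats::rgamma(sum(pos), shape = (mu[pos] / sg[pos])^2,
                              rate = mu[pos] / sg[pos]^2)
      r[mu > 0 & sg == 0] <- mu[mu > 0 & sg == 0]
      r
    },
    gaussian = pmax(mu + sg * stats::rnorm(rows), 0),
    poisson = stats::rpois(rows, mu * 0.2) / 0.2
  )
  rec <- data.frame(
    neuron_id     = rep(ids, each = 54L * K),
    target_index  = rep(rep(ct$target_index, each = K), n),
    forearm_angle = rep(rep(ct$forearm_angle, each = K), n),
    trial_index   = rep(seq_len(K), n * 54L),
    rate_hz       = rate,
    stringsAsFactors = FALSE
  )
  structure(list(
    recording = as_recording(rec),
    ground_truth = list(mean = M, pp = PP, linear_fraction = f_i,
                        gain = g_i, shift = d_i, coding_target = c_i,
                        amplitude = A_i, noise_sd = SD),
    config = config
  ), class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "synthetic recording: %d neurons, %d trials/condition, seed %d\n",
    x$config$n_neurons, x$config$trials_per_condition, x$config$seed))
  invisible(x)
}

#' Spatial-linear control dataset
#'
#' Builds artificial responses with perfectly linear spatial tuning: each
#' response is a linear tuning-curve prediction plus one resampled noise
#' trace, repeated \code{n_resamples} times.  Re-fitting these controls
#' shows how much of the shortfall from R-squared = 1 is attributable to
#' residual trial-averaging noise alone.
#'
#' @param fits List of \code{"tuning_fit"} objects (model kind
#'   \code{"linear"}, 27 points each).
#' @param noise_pool Matrix of noise traces (rows = traces, 27 columns),
#'   e.g. one angle's columns of \code{\link{extract_noise_traces}}
#'   output.  An all-zero pool gives noise-free controls.
#' @param n_resamples Resamples per fit (default 1).
#' @param grid Target grid.
#' @param seed Integer seed.
#' @return Matrix (fits x resamples) x 27 of control responses, with
#'   attribute \code{fit_index}.
#' @export
generate_linear_control <- function(fits, noise_pool, n_resamples = 1L,
                                    grid = make_target_grid(), seed = 1L) {
  if (is.null(dim(noise_pool)) || nrow(noise_pool) < 1L)
    stop("'noise_pool' must be a non-empty matrix of noise traces")
  set.seed(seed)
  preds <- t(vapply(fits, predict, numeric(27L), grid = grid))
  nr <- nrow(preds) * n_resamples
  idx <- rep(seq_len(nrow(preds)), times = n_resamples)
  tr <- sample.int(nrow(noise_pool), nr, replace = TRUE)
  out <- preds[idx, , drop = FALSE] + noise_pool[tr, , drop = FALSE]
  attr(out, "fit_index") <- idx
  out
}

#' Uniformly random control dataset
#'
#' Responses drawn i.i.d. uniformly within each neuron's firing-rate
#' range, plus resampled noise traces: the no-spatial-structure null
#' against which the linear component of real-like data is judged.
#'
#' @param rate_ranges n x 2 matrix of per-neuron (min, max) rates.
#' @inheritParams generate_linear_control
#' @return Matrix (neurons x resamples) x 27, attribute \code{fit_index}.
#' @export
generate_random_control <- function(rate_ranges, noise_pool,
                                    n_resamples = 1L, seed = 1L) {
  rate_ranges <- as.matrix(rate_ranges)
  if (nrow(rate_ranges) < 1L || ncol(rate_ranges) != 2L)
    stop("'rate_ranges' must be an n x 2 matrix")
  set.seed(seed)
  n <- nrow(rate_ranges) * n_resamples
  idx <- rep(seq_len(nrow(rate_ranges)), times = n_resamples)
  lo <- rate_ranges[idx, 1L]; hi <- rate_ranges[idx, 2L]
  out <- matrix(stats::runif(n * 27L), n, 27L) * (hi - lo) + lo
  if (!is.null(noise_pool) && nrow(noise_pool) > 0L) {
    tr <- sample.int(nrow(noise_pool), n, replace = TRUE)
    out <- out + noise_pool[tr, , drop = FALSE]
  }
  attr(out, "fit_index") <- idx
  out
}

#' Regular-nonlinear control dataset
#'
#' Passes each linear tuning-curve prediction through a conventional
#' parametric nonlinearity (threshold-linear, exponential, or sigmoidal),
#' rescales the result to the prediction's original range, and adds
#' resampled noise.  Such controls carry more high-spatial-frequency power
#' than linear tuning but far less than unstructured responses.
#'
#' @inheritParams generate_linear_control
#' @param kind One of \code{"threshold-linear"}, \code{"exponential"},
#'   \code{"sigmoid"}.
#' @param shape_param Curvature/steepness: threshold quantile (default
#'   0.5 = median), exponential curvature (0 = linear), or sigmoid slope
#'   (0 = identity-like).
#' @export
generate_regular_nonlinear_control <- function(fits,
                                               kind = c("threshold-linear",
                                                        "exponential",
                                                        "sigmoid"),
                                               noise_pool,
                                               shape_param = NULL,
                                               n_resamples = 1L,
                                               grid = make_target_grid(),
                                               seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(shape_param))
    shape_param <- switch(kind, "threshold-linear" = 0.5,
                          exponential = 1, sigmoid = 2)
  preds <- t(vapply(fits, predict, numeric(27L), grid = grid))
  warped <- t(apply(preds, 1L, function(p) {
    rng <- range(p)
    if (diff(rng) == 0) return(p)
    z <- .std(p)
    w <- switch(kind,
      "threshold-linear" = pmax(p - stats::quantile(p, shape_param,
                                                    names = FALSE), 0),
      exponential = if (shape_param == 0) z else exp(shape_param * z),
      sigmoid = if (shape_param == 0) z else 1 / (1 + exp(-shape_param * z))
    )
    if (diff(range(w)) == 0) return(rep(mean(p), length(p)))
    (w - min(w)) / diff(range(w)) * diff(rng) + rng[1L]
  }))
  set.seed(seed)
  nr <- nrow(warped) * n_resamples
  idx <- rep(seq_len(nrow(warped)), times = n_resamples)
  out <- warped[idx, , drop = FALSE]
  if (!is.null(noise_pool) && nrow(noise_pool) > 0L) {
    tr <- sample.int(nrow(noise_pool), nr, replace = TRUE)
    out <- out + noise_pool[tr, , drop = FALSE]
  }
  attr(out, "fit_index") <- idx
  out
}

#' Generate a surrogate mean-EMG set
#'
#' Builds mean EMG for five muscles over the 18 EMG conditions (9 key
#' targets x 2 forearm angles): each muscle is a rectified linear-in-
#' posture term plus a smooth nonlinear field, with three of the five
#' muscles constructed linear-dominated (mirroring the finding that 3/5
#' recorded muscles had a significant linear fit).
#'
#' @param grid Target grid.
#' @param seed Integer seed.
#' @param nonlinear_fraction Nonlinear variance share for the two
#'   nonlinear-dominated muscles (default 0.6; the linear-dominated three
#'   use \code{nonlinear_fraction / 3}).
#' @return List with \code{emg} (an \code{\link{emg_set}}) and
#'   \code{ground_truth} (per-muscle linear coefficients and components).
#' @export
generate_emg_set <- function(grid = make_target_grid(), seed = 1L,
                             nonlinear_fraction = 0.6) {
  stopifnot(nonlinear_fraction >= 0, nonlinear_fraction <= 1)
  set.seed(seed)
  cond <- emg_conditions()
  pos <- grid$positions[cond$target_index + 1L, , drop = FALSE]
  sup <- as.numeric(cond$forearm_angle == "supination")
  ch <- .grf_chol(grid, 1.2)
  nlf <- c(rep(nonlinear_fraction / 3, 3L), rep(nonlinear_fraction, 2L))
  M <- matrix(0, 5L, 18L)
  lin_coef <- matrix(0, 5L, 5L)
  for (m in 1:5) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ang_w <- stats::rnorm(1, 0, 0.5)
    L <- .std(drop(pos %*% u) + ang_w * (sup - 0.5))
    Nfull <- .std(drop(crossprod(ch, stats::rnorm(27))))
    N <- .std(Nfull[cond$target_index + 1L] +
              0.3 * stats::rnorm(18))
    y <- sqrt(1 - nlf[m]) * L + sqrt(nlf[m]) * N
    y <- pmax(y - min(y) + 0.05, 0)          # rectified, normalized units
    M[m, ] <- y / max(y)
    lin_coef[m, ] <- c(mean(y), u * sqrt(1 - nlf[m]), ang_w)
  }
  list(emg = emg_set(M),
       ground_truth = list(nonlinear_fraction = nlf,
                           linear_coef = lin_coef, seed = seed))
}

#' Single-trial EMG targets
#'
#' The decoding protocol decodes each condition's mean EMG from
#' single-trial neural activity, so the per-trial EMG target is the
#' condition mean repeated for every trial.
#'
#' @param emg An \code{"emg_set"}.
#' @param n_trials Trials per condition.
#' @return Matrix muscles x (conditions * n_trials), trials
#'   condition-major in the ordering of \code{emg$conditions}.
#' @export
emg_trial_targets <- function(emg, n_trials) {
  stopifnot(inherits(emg, "emg_set"), n_trials >= 1L)
  out <- emg$mean_emg[, rep(seq_len(ncol(emg$mean_emg)),
                            each = n_trials), drop = FALSE]
  rownames(out) <- emg$muscles
  out
}
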
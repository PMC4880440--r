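#' Visual-input array of the random-connectivity network
#'
#' A dense lattice of 3D Gaussian "hand-position" units tiling the
#' workspace.  Unit centres form an \code{n_per_axis}^3 grid spanning the
#' target cube extended by \code{extent_factor} cube widths beyond the
#' outermost targets on every side.  Each unit's response to a target is
#' a Gaussian of its centre-to-target distance; responses are normalized
#' so the array's summed activity is 1 at every target.
#'
#' @param grid Target grid.
#' @param width Gaussian tuning width (SD, cm); either a scalar (all
#'   units share it) or a length-2 vector \code{c(mean, range)} giving a
#'   uniform distribution of widths on
#'   \code{[mean - range/2, mean + range/2]}.
#' @param n_per_axis Units per axis (default 50, i.e. 125,000 units).
#' @param extent_factor How many cube widths the array extends past the
#'   outermost targets (default 3).
#' @param seed Integer seed (used only when widths are distributed).
#' @return Object of class \code{"visual_array"}: \code{tuning}
#'   (units x 27 normalized responses), \code{widths}, \code{centers}
#'   (units x 3), \code{extent} (cm, half-width of the centre lattice).
#' @export
build_visual_array <- function(grid = make_target_grid(), width,
                               n_per_axis = 50L, extent_factor = 3,
                               seed = 1L) {
  if (length(width) == 1L) width <- c(width, 0)
  stopifnot(length(width) == 2L, width[1L] > 0, width[2L] >= 0,
            width[1L] - width[2L] / 2 > 0, n_per_axis >= 2L,
            extent_factor >= 0)
  s <- grid$spacing
  half <- s + extent_factor * 2 * s      # outermost target + k cube widths
  ax <- seq(-half, half, length.out = n_per_axis)
  centers <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rownames(centers) <- NULL
  n <- nrow(centers)
  if (width[2L] > 0) {
    set.seed(seed)
    w <- stats::runif(n, width[1L] - width[2L] / 2,
                      width[1L] + width[2L] / 2)
  } else w <- rep(width[1L], n)
  V <- matrix(0, n, 27L)
  for (t in 1:27) {
    d2 <- (centers[, 1L] - grid$positions[t, 1L])^2 +
          (centers[, 2L] - grid$positions[t, 2L])^2 +
          (centers[, 3L] - grid$positions[t, 3L])^2
    V[, t] <- exp(-d2 / (2 * w^2))
  }
  cs <- colSums(V)
  if (any(cs == 0)) stop("width too small for the array resolution")
  V <- sweep(V, 2L, cs, "/")
  structure(list(tuning = V, widths = w, centers = centers,
                 extent = half, n_per_axis = n_per_axis,
                 extent_factor = extent_factor),
            class = "visual_array")
}

#' @export
print.visual_array <- function(x, ...) {
  cat(sprintf(
    "visual array: %d Gaussian units (%d/axis), extent +/- %.1f cm, width %s cm\n",
    nrow(x$tuning), x$n_per_axis, x$extent,
    if (stats::sd(x$widths) > 0)
      sprintf("%.2f-%.2f", min(x$widths), max(x$widths))
    else sprintf("%.2f", x$widths[1L])))
  invisible(x)
}

#' Forearm-angle input units
#'
#' Each unit is tuned to one forearm angle: its gain for the preferred
#' angle is drawn uniformly from \code{preferred_gain} and for the other
#' angle from \code{other_gain}; half the units prefer pronation.
#'
#' @param n Number of units (default 10,000).
#' @param preferred_gain,other_gain Length-2 uniform ranges (defaults
#'   c(1, 2) and c(0, 1)).
#' @param seed Integer seed.
#' @return Object of class \code{"forearm_units"}: \code{gain}
#'   (n x 2 matrix, columns pronation/supination).
#' @export
build_forearm_units <- function(n = 10000L, preferred_gain = c(1, 2),
                                other_gain = c(0, 1), seed = 1L) {
  stopifnot(n >= 1L, length(preferred_gain) == 2L,
            length(other_gain) == 2L)
  set.seed(seed)
  pref_sup <- stats::runif(n) < 0.5
  gp <- ifelse(pref_sup,
               stats::runif(n, other_gain[1L], other_gain[2L]),
               stats::runif(n, preferred_gain[1L], preferred_gain[2L]))
  gs <- ifelse(pref_sup,
               stats::runif(n, preferred_gain[1L], preferred_gain[2L]),
               stats::runif(n, other_gain[1L], other_gain[2L]))
  g <- cbind(pronation = gp, supination = gs)
  structure(list(gain = g, n = n), class = "forearm_units")
}

#' @export
print.forearm_units <- function(x, ...) {
  cat(sprintf("forearm units: %d, mean gains %.2f (pron) / %.2f (sup)\n",
              x$n, mean(x$gain[, 1L]), mean(x$gain[, 2L])))
  invisible(x)
}

#' Random-connectivity network model of posture tuning
#'
#' The model M1 neuron sums \code{n_inputs} premotor inputs, each the
#' product of one randomly chosen visual unit and one randomly chosen
#' forearm unit, through a random weight uniform on [0, 1]; its output
#' is the thresholded linear response
#' \deqn{r(x, \theta) = [\,h(x, \theta) - \phi\,]_+ ,\qquad
#'   h = \sum_i J_i\, v_i(x)\, g_i(\theta).}
#' The object stores the input arrays and connectivity statistics; use
#' \code{\link{simulate_m1}} to draw a population.
#'
#' @param visual A \code{"visual_array"}.
#' @param forearm A \code{"forearm_units"}.
#' @param n_inputs Inputs per M1 neuron (default 10,000).
#' @param threshold Activation threshold \eqn{\phi} (default 0; usually
#'   set afterwards by \code{\link{calibrate_threshold}}).
#' @return Object of class \code{"posture_network"}.
#' @export
posture_network <- function(visual, forearm, n_inputs = 10000L,
                            threshold = 0) {
  stopifnot(inherits(visual, "visual_array"),
            inherits(forearm, "forearm_units"), n_inputs >= 1L,
            is.finite(threshold))
  structure(list(visual = visual, forearm = forearm,
                 n_inputs = as.integer(n_inputs),
                 threshold = threshold),
            class = "posture_network")
}

#' @export
print.posture_network <- function(x, ...) {
  cat("random-connectivity posture network\n")
  print(x$visual)
  print(x$forearm)
  cat(sprintf("  %d inputs per M1 neuron, threshold %.4g\n",
              x$n_inputs, x$threshold))
  invisible(x)
}

#' Simulate an M1 population from the network model
#'
#' Draws \code{n_neurons} output neurons, each with its own random
#' connectivity, and returns the summed premotor input \code{h} over the
#' 54 conditions together with the thresholded rates.
#'
#' @param network A \code{"posture_network"}.
#' @param n_neurons Number of output neurons.
#' @param seed Integer seed.
#' @return Object of class \code{"m1_simulation"}: \code{h} (neurons x
#'   54, condition ordering of \code{\link{condition_table}}),
#'   \code{rates} (\code{pmax(h - threshold, 0)}), \code{threshold},
#'   \code{seed}.
#' @export
simulate_m1 <- function(network, n_neurons, seed = 1L) {
  stopifnot(inherits(network, "posture_network"), n_neurons >= 1L)
  set.seed(seed)
  V <- network$visual$tuning
  G <- network$forearm$gain
  ni <- network$n_inputs
  H <- matrix(0, n_neurons, 54L)
  pcols <- angle_columns("pronation"); scols <- angle_columns("supination")
  for (j in seq_len(n_neurons)) {
    iv <- sample.int(nrow(V), ni, replace = TRUE)
    ig <- sample.int(nrow(G), ni, replace = TRUE)
    J <- stats::runif(ni)
    H[j, pcols] <- crossprod(V[iv, , drop = FALSE], J * G[ig, 1L])
    H[j, scols] <- crossprod(V[iv, , drop = FALSE], J * G[ig, 2L])
  }
  structure(list(h = H, rates = pmax(H - network$threshold, 0),
                 threshold = network$threshold, seed = seed),
            class = "m1_simulation")
}

#' @export
print.m1_simulation <- function(x, ...) {
  cat(sprintf(
    "M1 simulation: %d neurons x 54 conditions, threshold %.4g, coding %.3f\n",
    nrow(x$h), x$threshold, mean(x$rates > 0)))
  invisible(x)
}

#' Re-apply a threshold to a simulation
#'
#' @param sim An \code{"m1_simulation"}.
#' @param threshold New threshold; scalar, or one value per neuron.
#' @return The simulation with updated \code{rates} and
#'   \code{threshold}.
#' @export
apply_threshold <- function(sim, threshold) {
  stopifnot(inherits(sim, "m1_simulation"))
  sim$rates <- pmax(sim$h - threshold, 0)
  sim$threshold <- threshold
  sim
}

#' Calibrate the network threshold to a target coding level
#'
#' Fixed mode (default): finds, by bisection, the single threshold
#' \eqn{\phi} at which the fraction of neuron-condition pairs with
#' above-threshold input equals the target coding level.  The fraction
#' is monotonically non-increasing in the threshold, so bisection on the
#' bracket [min(h), max(h)] always converges.  Per-neuron mode (when
#' \code{reference_coding} is supplied): each neuron's threshold is set
#' so its own coding level matches a randomly drawn reference value.
#'
#' @param sim An \code{"m1_simulation"}.
#' @param coding_target Target fraction of active conditions (default
#'   0.85).
#' @param tol Convergence tolerance on the coding level (default 1e-3);
#'   iteration also stops when the bracket is narrower than 1e-12 of the
#'   input range.
#' @param max_iter Maximum bisection steps (default 100).
#' @param reference_coding Optional numeric vector of per-neuron coding
#'   levels (in (0, 1]) to resample from, switching to per-neuron mode.
#' @param seed Integer seed for the per-neuron resampling.
#' @return List of class \code{"threshold_calibration"}:
#'   \code{threshold} (scalar, or one per neuron), \code{achieved},
#'   \code{target}, \code{iterations}, \code{converged}.
#' @export
calibrate_threshold <- function(sim, coding_target = 0.85, tol = 1e-3,
                                max_iter = 100L,
                                reference_coding = NULL, seed = 1L) {
  stopifnot(inherits(sim, "m1_simulation"),
            coding_target > 0, coding_target <= 1)
  h <- sim$h
  if (!is.null(reference_coding)) {
    stopifnot(all(reference_coding > 0), all(reference_coding <= 1))
    set.seed(seed)
    cl <- sample(reference_coding, nrow(h), replace = TRUE)
    phi <- vapply(seq_len(nrow(h)), function(j)
      stats::quantile(h[j, ], 1 - cl[j], names = FALSE), numeric(1L))
    ach <- mean(pmax(h - phi, 0) > 0)
    return(structure(list(threshold = phi, achieved = ach,
                          target = mean(cl), iterations = 0L,
                          converged = TRUE),
                     class = "threshold_calibration"))
  }
  if (coding_target == 1)
    return(structure(list(threshold = min(h) - 1e-12, achieved = 1,
                          target = 1, iterations = 0L,
                          converged = TRUE),
                     class = "threshold_calibration"))
  lo <- min(h); hi <- max(h)
  coding_at <- function(phi) mean(h > phi)
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    c_mid <- coding_at(mid)
    if (abs(c_mid - coding_target) <= tol ||
        (hi - lo) < 1e-12 * diff(range(h)) || it >= max_iter) break
    if (c_mid > coding_target) lo <- mid else hi <- mid
  }
  if (abs(c_mid - coding_target) > tol)
    stop(sprintf(
      "coding target %.3f unattainable: closest achievable %.3f",
      coding_target, c_mid))
  structure(list(threshold = mid, achieved = c_mid,
                 target = coding_target, iterations = it,
                 converged = TRUE),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "threshold calibration: phi = %.5g, coding %.4f (target %.4f), %d iterations%s\n",
    x$threshold, x$achieved, x$target, x$iterations,
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# one deterministic model evaluation: build network at width, simulate,
# calibrate threshold, return mean complexity of the rates
.model_complexity_at <- function(width, grid, coding_target, n_neurons,
                                 n_per_axis, extent_factor, n_inputs,
                                 distance_unit, seed) {
  va <- build_visual_array(grid, width, n_per_axis, extent_factor,
                           seed = seed)
  fu <- build_forearm_units(n = n_inputs, seed = seed + 1L)
  net <- posture_network(va, fu, n_inputs = n_inputs)
  sim <- simulate_m1(net, n_neurons, seed = seed + 2L)
  cal <- calibrate_threshold(sim, coding_target)
  sim <- apply_threshold(sim, cal$threshold)
  cx <- complexity_distribution(sim$rates, grid, distance_unit)
  list(value = mean(cx), sim = sim, network = net, calibration = cal)
}

#' Calibrate the visual tuning width to a target complexity
#'
#' Finds, by bisection, the shared visual-unit width at which the mean
#' complexity of a simulated population matches a reference value
#' (typically the mean complexity of the recorded data under the same
#' units).  Complexity decreases monotonically with the width; every
#' evaluation reuses the same random seed, so the objective is a
#' deterministic function of the width and the bracket argument is
#' checked before iterating.
#'
#' @param target_complexity Reference mean complexity.
#' @param grid Target grid.
#' @param bracket Width search interval in cm (default
#'   \code{c(0.4, 3) * grid$spacing}).
#' @param coding_target Coding level for the threshold calibration at
#'   each width (default 0.85).
#' @param n_neurons Population size per evaluation (default 200).
#' @param n_per_axis,extent_factor,n_inputs Network size parameters
#'   (see \code{\link{build_visual_array}},
#'   \code{\link{posture_network}}).
#' @param distance_unit Units of the complexity measure (see
#'   \code{\link{complexity_measure}}; default \code{"cm"}).
#' @param tol Relative tolerance on the complexity match (default 0.02).
#' @param max_iter Maximum bisection steps (default 30).
#' @param seed Integer seed (shared by all evaluations).
#' @return List of class \code{"width_calibration"}: \code{width},
#'   \code{achieved}, \code{target}, \code{iterations},
#'   \code{converged}, \code{simulation}, \code{network},
#'   \code{threshold_calibration}.
#' @export
calibrate_width <- function(target_complexity, grid = make_target_grid(),
                            bracket = c(0.4, 3) * grid$spacing,
                            coding_target = 0.85, n_neurons = 200L,
                            n_per_axis = 50L, extent_factor = 3,
                            n_inputs = 10000L,
                            distance_unit = c("cm", "step"),
                            tol = 0.02, max_iter = 30L, seed = 1L) {
  distance_unit <- match.arg(distance_unit)
  stopifnot(target_complexity > 0, length(bracket) == 2L,
            bracket[1L] > 0, bracket[2L] > bracket[1L])
  ev <- function(w) .model_complexity_at(w, grid, coding_target,
                                         n_neurons, n_per_axis,
                                         extent_factor, n_inputs,
                                         distance_unit, seed)
  lo <- bracket[1L]; hi <- bracket[2L]
  e_lo <- ev(lo); e_hi <- ev(hi)
  if ((e_lo$value - target_complexity) *
      (e_hi$value - target_complexity) > 0)
    stop(sprintf(
      "target complexity %.4g not bracketed: widths (%.3g, %.3g) give (%.4g, %.4g)",
      target_complexity, lo, hi, e_lo$value, e_hi$value))
  it <- 0L
  best <- if (abs(e_lo$value - target_complexity) <
              abs(e_hi$value - target_complexity)) e_lo else e_hi
  mid <- if (identical(best, e_lo)) lo else hi
  repeat {
    it <- it + 1L
    w <- (lo + hi) / 2
    e <- ev(w)
    if (abs(e$value - target_complexity) <
        abs(best$value - target_complexity)) { best <- e; mid <- w }
    if (abs(e$value - target_complexity) <=
        tol * target_complexity || it >= max_iter) break
    # complexity decreases with width
    if (e$value > target_complexity) lo <- w else hi <- w
  }
  structure(list(width = mid, achieved = best$value,
                 target = target_complexity, iterations = it,
                 converged = abs(best$value - target_complexity) <=
                   tol * target_complexity,
                 simulation = best$sim, network = best$network,
                 threshold_calibration = best$calibration),
            class = "width_calibration")
}

#' @export
print.width_calibration <- function(x, ...) {
  cat(sprintf(
    "width calibration: sigma = %.4g cm, complexity %.4g (target %.4g), %d iterations%s\n",
    x$width, x$achieved, x$target, x$iterations,
    if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

# per-angle linear-fit R2 of every row of a rates matrix, pooled
.pooled_linear_r2 <- function(rates, grid) {
  pc <- angle_columns("pronation"); sc <- angle_columns("supination")
  unlist(lapply(seq_len(nrow(rates)), function(i) c(
    fit_linear_tuning(rates[i, pc], grid, "pronation")$r_squared,
    fit_linear_tuning(rates[i, sc], grid, "supination")$r_squared)))
}

#' Fit the enhanced (distributed-width) network model
#'
#' Grid search, then one step of local refinement, over the width
#' distribution's mean and range for the four-parameter model variant:
#' visual widths uniform on \code{[mean - range/2, mean + range/2]} and
#' per-neuron thresholds set so each neuron's coding level matches a
#' reference coding-level draw.  The scalarized objective is the sum of
#' squared normalized errors of three statistics of the simulated
#' population — mean complexity, mean linear-fit R-squared, and SD of
#' the R-squared distribution — against their reference values; ties
#' prefer the smaller range.
#'
#' @param target_complexity Reference mean complexity.
#' @param target_r2_mean,target_r2_sd Reference mean and SD of the
#'   pooled per-angle linear-fit R-squared distribution.
#' @param reference_coding Numeric vector of per-neuron coding levels to
#'   resample per model neuron.
#' @param grid Target grid.
#' @param width_means,width_ranges Candidate grids (cm).
#' @param refine Run one local refinement pass at half the grid step
#'   around the best point (default TRUE).
#' @param n_neurons,n_per_axis,extent_factor,n_inputs Network size.
#' @param distance_unit Complexity units.
#' @param seed Integer seed (shared by all evaluations).
#' @return List of class \code{"enhanced_fit"}: \code{width_mean},
#'   \code{width_range}, \code{loss}, \code{model_complexity},
#'   \code{model_r2_mean}, \code{model_r2_sd}, \code{grid_loss}
#'   (matrix means x ranges of the first pass), \code{simulation}.
#' @export
fit_enhanced_widths <- function(target_complexity, target_r2_mean,
                                target_r2_sd, reference_coding,
                                grid = make_target_grid(),
                                width_means = grid$spacing *
                                  seq(0.6, 1.6, by = 0.2),
                                width_ranges = grid$spacing *
                                  c(0, 0.4, 0.8, 1.2),
                                refine = TRUE,
                                n_neurons = 200L, n_per_axis = 50L,
                                extent_factor = 3, n_inputs = 10000L,
                                distance_unit = c("cm", "step"),
                                seed = 1L) {
  distance_unit <- match.arg(distance_unit)
  stopifnot(target_complexity > 0, target_r2_mean > 0,
            target_r2_sd > 0, length(reference_coding) >= 1L)
  ev <- function(wm, wr) {
    if (wm - wr / 2 <= 0) return(NULL)
    va <- build_visual_array(grid, c(wm, wr), n_per_axis,
                             extent_factor, seed = seed)
    fu <- build_forearm_units(n = n_inputs, seed = seed + 1L)
    net <- posture_network(va, fu, n_inputs = n_inputs)
    sim <- simulate_m1(net, n_neurons, seed = seed + 2L)
    cal <- calibrate_threshold(sim, reference_coding = reference_coding,
                               seed = seed + 3L)
    sim <- apply_threshold(sim, cal$threshold)
    cx <- mean(complexity_distribution(sim$rates, grid, distance_unit))
    r2 <- .pooled_linear_r2(sim$rates, grid)
    loss <- ((cx - target_complexity) / target_complexity)^2 +
      ((mean(r2) - target_r2_mean) / target_r2_mean)^2 +
      ((stats::sd(r2) - target_r2_sd) / target_r2_sd)^2
    list(width_mean = wm, width_range = wr, loss = loss,
         model_complexity = cx, model_r2_mean = mean(r2),
         model_r2_sd = stats::sd(r2), simulation = sim)
  }
  pick <- function(best, cand) {
    if (is.null(cand)) return(best)
    if (is.null(best) || cand$loss < best$loss - 1e-12 ||
        (abs(cand$loss - best$loss) <= 1e-12 &&
         cand$width_range < best$width_range)) cand else best
  }
  L <- matrix(NA_real_, length(width_means), length(width_ranges),
              dimnames = list(sprintf("%.3g", width_means),
                              sprintf("%.3g", width_ranges)))
  best <- NULL
  for (a in seq_along(width_means)) for (b in seq_along(width_ranges)) {
    e <- ev(width_means[a], width_ranges[b])
    if (!is.null(e)) L[a, b] <- e$loss
    best <- pick(best, e)
  }
  if (is.null(best)) stop("no admissible (mean, range) grid point")
  if (refine) {
    dm <- if (length(width_means) > 1L)
      min(diff(sort(width_means))) / 2 else 0
    dr <- if (length(width_ranges) > 1L)
      min(diff(sort(width_ranges))) / 2 else 0
    for (sm in c(-dm, 0, dm)) for (sr in c(-dr, 0, dr)) {
      if (sm == 0 && sr == 0) next
      wr <- best$width_range + sr
      if (wr < 0) next
      best <- pick(best, ev(best$width_mean + sm, wr))
    }
  }
  structure(c(best, list(grid_loss = L,
                         target_complexity = target_complexity,
                         target_r2_mean = target_r2_mean,
                         target_r2_sd = target_r2_sd)),
            class = "enhanced_fit")
}

#' @export
print.enhanced_fit <- function(x, ...) {
  cat(sprintf(
    "enhanced width fit: mean %.3g cm, range %.3g cm (loss %.4g)\n  complexity %.4g (target %.4g), R2 mean %.3f (%.3f), R2 SD %.3f (%.3f)\n",
    x$width_mean, x$width_range, x$loss, x$model_complexity,
    x$target_complexity, x$model_r2_mean, x$target_r2_mean,
    x$model_r2_sd, x$target_r2_sd))
  invisible(x)
}

#' Scale model responses into reference firing-rate ranges
#'
#' Maps each model neuron's response affinely so that its minimum and
#' maximum match the minimum and maximum of a randomly sampled reference
#' neuron, putting model output into spikes/s.
#'
#' @param sim An \code{"m1_simulation"}.
#' @param reference_responses Reference neurons x conditions matrix of
#'   trial-mean rates (NA rows dropped).
#' @param seed Integer seed for the reference sampling.
#' @return The simulation with \code{rates} rescaled; flat model neurons
#'   are excluded (\code{kept} records the surviving row indices) and a
#'   \code{scaling} element records the affine maps.
#' @export
scale_to_reference_ranges <- function(sim, reference_responses,
                                      seed = 1L) {
  stopifnot(inherits(sim, "m1_simulation"))
  R <- as.matrix(reference_responses)
  R <- R[stats::complete.cases(R), , drop = FALSE]
  if (nrow(R) < 1L) stop("need reference responses")
  set.seed(seed)
  n <- nrow(sim$rates)
  flat <- apply(sim$rates, 1L, function(r) diff(range(r)) == 0)
  keep <- which(!flat)
  if (length(keep) == 0L) stop("all model neurons are flat")
  pick <- sample.int(nrow(R), length(keep), replace = TRUE)
  out <- matrix(NA_real_, length(keep), 54L)
  sc <- matrix(NA_real_, length(keep), 2L,
               dimnames = list(NULL, c("offset", "gain")))
  for (k in seq_along(keep)) {
    r <- sim$rates[keep[k], ]
    ref <- R[pick[k], ]
    g <- diff(range(ref)) / diff(range(r))
    o <- min(ref) - g * min(r)
    out[k, ] <- o + g * r
    sc[k, ] <- c(o, g)
  }
  sim$rates <- out
  sim$h <- sim$h[keep, , drop = FALSE]
  sim$scaling <- sc
  sim$kept <- keep
  sim
}

#' Generate single-trial rates from a model population
#'
#' Adds rate-matched trial noise to model mean responses.  A lookup of
#' noise samples \eqn{\eta = (r_k(c) - r_l(c))/\sqrt 2}, one row per
#' reference neuron-condition keyed by that condition's mean rate, is
#' built from the reference recording; each model trial is the model
#' mean plus a random noise sample drawn from the lookup row whose mean
#' rate is nearest the model neuron's mean at that condition.  Trials
#' are clamped at zero.
#'
#' @param sim A scaled \code{"m1_simulation"} (rates in spikes/s).
#' @param reference_recording Recording supplying the noise-sample
#'   lookup (needs at least 2 trials per condition).
#' @param trials_per_condition Trials to draw (default 14).
#' @param seed Integer seed.
#' @return A recording (\code{\link{as_recording}}) of the simulated
#'   single trials, neuron ids \code{"model0001"}, ...
#' @export
generate_model_trials <- function(sim, reference_recording,
                                  trials_per_condition = 14L,
                                  seed = 1L) {
  stopifnot(inherits(sim, "m1_simulation"), trials_per_condition >= 1L)
  rec <- as_recording(reference_recording)
  ids <- unique(rec$neuron_id)
  key <- numeric(0L)     # mean rate of each lookup row
  rows <- list()         # trial vectors
  for (id in ids) {
    byc <- trials_by_condition(rec, id)
    for (c in seq_along(byc)) {
      v <- byc[[c]]
      if (length(v) >= 2L) {
        key <- c(key, mean(v))
        rows[[length(rows) + 1L]] <- v
      }
    }
  }
  if (length(rows) == 0L) stop("empty noise lookup: need >= 2 trials per condition somewhere in the reference")
  ord <- order(key)
  key <- key[ord]; rows <- rows[ord]
  set.seed(seed)
  M <- sim$rates
  n <- nrow(M)
  K <- trials_per_condition
  # nearest lookup row per model neuron-condition mean
  pos <- matrix(findInterval(M, key, all.inside = TRUE), n, 54L)
  up <- pmin(pos + 1L, length(key))
  nearest <- ifelse(abs(M - key[pos]) <= abs(key[up] - M), pos, up)
  mu <- rep(as.vector(t(M)), each = K)
  row_of <- rep(as.vector(t(nearest)), each = K)
  eta <- vapply(row_of, function(r) {
    v <- rows[[r]]
    kl <- sample.int(length(v), 2L)
    (v[kl[1L]] - v[kl[2L]]) / sqrt(2)
  }, numeric(1L))
  rate <- pmax(mu + eta, 0)
  ct <- condition_table()
  ids <- sprintf("model%04d", seq_len(n))
  as_recording(data.frame(
    neuron_id     = rep(ids, each = 54L * K),
    target_index  = rep(rep(ct$target_index, each = K), n),
    forearm_angle = rep(rep(ct$forearm_angle, each = K), n),
    trial_index   = rep(seq_len(K), n * 54L),
    rate_hz       = rate,
    stringsAsFactors = FALSE
  ))
}
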
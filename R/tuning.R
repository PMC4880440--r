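#' Spatial linear tuning-curve fit
#'
#' Fits a neuron's trial-averaged response at one forearm angle as a linear
#' function of 3D hand position,
#' \deqn{\bar r(x) = a_0 + a_1 x_1 + a_2 x_2 + a_3 x_3,}
#' by ordinary least squares.  The preferred-position (PP) vector is
#' \eqn{(a_1, a_2, a_3)}: the direction in the workspace along which the
#' rate grows linearly, with norm equal to the rate gradient (spikes/s per
#' cm).  Linear position tuning is equivalent to cosine tuning under a
#' change of coordinates.  Significance is the overall-regression F-test
#' with (3, n - 4) degrees of freedom.
#'
#' @param resp Numeric response vector: either 27 per-target mean rates in
#'   target order, or a 54-condition vector from which one angle is taken.
#' @param grid A \code{\link{make_target_grid}} object.
#' @param forearm_angle Which angle \code{resp} refers to when \code{resp}
#'   has 54 entries.
#' @return An object of class \code{"tuning_fit"} with elements
#'   \code{model_kind}, \code{coefficients} (a0..a3), \code{pp_vector},
#'   \code{r_squared}, \code{f_pvalue}, \code{n_points}, \code{fitted},
#'   \code{residuals}.
#' @seealso \code{\link{fit_extended_tuning}},
#'   \code{\link{fit_multiplicative_tuning}}
#' @export
fit_linear_tuning <- function(resp, grid = make_target_grid(),
                              forearm_angle = c("pronation", "supination")) {
  if (length(resp) == 54L)
    resp <- resp[angle_columns(match.arg(forearm_angle))]
  ok <- which(is.finite(resp))
  if (length(ok) < 5L)
    stop("need at least 5 finite conditions to fit 4 parameters")
  X <- cbind(1, grid$positions[ok, , drop = FALSE])
  if (qr(X)$rank < 4L) stop("target positions are rank-deficient")
  y <- resp[ok]
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  names(co) <- c("a0", "a1", "a2", "a3")
  new_tuning_fit("linear", co, co[2:4], y, fit$fitted.values,
                 n_coef = 4L, df_num = 3L, which_points = ok)
}

#' Extended spatial linear tuning: shared PP, additive forearm term
#'
#' Fits all 54 conditions with a single PP vector plus an additive forearm
#' offset \eqn{a_4 \theta_f}, where \eqn{\theta_f} is coded 0 for pronation
#' and 1 for supination (only two angles were sampled, so the coding is an
#' indicator).
#'
#' @inheritParams fit_linear_tuning
#' @param resp Numeric 54-condition response vector (condition order of
#'   \code{\link{condition_table}}).
#' @return A \code{"tuning_fit"} with coefficients a0..a4.
#' @export
fit_extended_tuning <- function(resp, grid = make_target_grid()) {
  if (length(resp) != 54L) stop("'resp' must have 54 conditions")
  ct <- condition_table()
  ok <- which(is.finite(resp))
  if (length(ok) < 6L) stop("need at least 6 finite conditions")
  if (!any(ct$forearm_angle[ok] == "pronation") ||
      !any(ct$forearm_angle[ok] == "supination"))
    stop("both forearm angles must be present")
  th <- as.numeric(ct$forearm_angle[ok] == "supination")
  X <- cbind(1, grid$positions[ct$target_index[ok] + 1L, , drop = FALSE], th)
  y <- resp[ok]
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  names(co) <- c("a0", "a1", "a2", "a3", "a4")
  new_tuning_fit("extended", co, co[2:4], y, fit$fitted.values,
                 n_coef = 5L, df_num = 4L, which_points = ok)
}

#' Multiplicative forearm-gain tuning
#'
#' Fits all 54 conditions with a single PP vector whose slope is scaled by
#' a forearm-dependent gain:
#' \eqn{\bar r(x,\theta_f) = a_0 + g(\theta_f)\, PP \cdot x}, with
#' \eqn{g = 1} for pronation and \eqn{g} free for supination.  The model is
#' bilinear in (a0, PP) and g, and is fitted by alternating least squares:
#' given g the model is linear in (a0, PP); given (a0, PP) the optimal g is
#' a one-dimensional least-squares ratio.  Iteration stops when the maximal
#' parameter change is below \code{tol} (default 1e-8) or after
#' \code{max_iter} rounds, in which case the fit is flagged
#' \code{converged = FALSE}.
#'
#' @inheritParams fit_extended_tuning
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @return A \code{"tuning_fit"} with coefficients a0..a3 and \code{gain},
#'   plus \code{converged}.
#' @export
fit_multiplicative_tuning <- function(resp, grid = make_target_grid(),
                                      tol = 1e-8, max_iter = 100L) {
  if (length(resp) != 54L) stop("'resp' must have 54 conditions")
  ct <- condition_table()
  ok <- which(is.finite(resp))
  if (!any(ct$forearm_angle[ok] == "pronation") ||
      !any(ct$forearm_angle[ok] == "supination"))
    stop("both forearm angles must be present")
  pos <- grid$positions[ct$target_index[ok] + 1L, , drop = FALSE]
  sup <- ct$forearm_angle[ok] == "supination"
  y <- resp[ok]
  g <- 1
  par_old <- rep(Inf, 5L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gc_ <- ifelse(sup, g, 1)
    X <- cbind(1, pos * gc_)
    b <- stats::lm.fit(X, y)$coefficients
    u <- drop(pos %*% b[2:4])
    den <- sum(u[sup]^2)
    g <- if (den > 0) sum(u[sup] * (y[sup] - b[1])) / den else 1
    par <- c(b, g)
    if (max(abs(par - par_old)) < tol) { converged <- TRUE; break }
    par_old <- par
  }
  co <- c(b, g)
  names(co) <- c("a0", "a1", "a2", "a3", "gain")
  fitted <- b[1] + ifelse(sup, g, 1) * u
  out <- new_tuning_fit("multiplicative", co, co[2:4], y, fitted,
                        n_coef = 5L, df_num = 4L, which_points = ok)
  out$converged <- converged
  out
}

new_tuning_fit <- function(kind, coefficients, pp, y, fitted, n_coef,
                           df_num, which_points) {
  n <- length(y)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else 0
  df2 <- n - n_coef
  fstat <- if (rss > 0 && df2 > 0) ((tss - rss) / df_num) / (rss / df2)
           else Inf
  pval <- if (is.finite(fstat)) stats::pf(fstat, df_num, df2,
                                          lower.tail = FALSE)
          else 0
  pp <- unname(pp)
  structure(list(
    model_kind  = kind,
    coefficients = coefficients,
    pp_vector   = pp,
    pp_norm     = sqrt(sum(pp^2)),
    r_squared   = r2,
    f_statistic = fstat,
    f_pvalue    = max(pval, .Machine$double.xmin),
    n_points    = n,
    which_points = which_points,
    fitted      = fitted,
    residuals   = y - fitted,
    observed    = y
  ), class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("%s tuning fit: R^2 = %.3f (F p = %.2g), |PP| = %.3f, n = %d\n",
              x$model_kind, x$r_squared, x$f_pvalue, x$pp_norm, x$n_points))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) object$coefficients

#' @export
summary.tuning_fit <- function(object, ...) {
  cat(sprintf("Model: %s spatial tuning curve\n", object$model_kind))
  print(object)
  cat(sprintf("PP direction: (%s)\n",
              paste(sprintf("%.3f", object$pp_vector / max(object$pp_norm,
                                                           1e-12)),
                    collapse = ", ")))
  invisible(object)
}

#' Predict mean rates from a tuning fit
#'
#' @param object A \code{"tuning_fit"}.
#' @param grid Target grid used for the fit.
#' @param conditions Which conditions to predict: for linear fits an
#'   integer vector of target indices (0..26, default all); for extended
#'   and multiplicative fits the 1..54 condition indices (default all).
#' @param ... Unused.
#' @export
predict.tuning_fit <- function(object, grid = make_target_grid(),
                               conditions = NULL, ...) {
  co <- object$coefficients
  if (object$model_kind == "linear") {
    if (is.null(conditions)) conditions <- 0:26
    drop(cbind(1, grid$positions[conditions + 1L, , drop = FALSE]) %*%
         co[1:4])
  } else {
    if (is.null(conditions)) conditions <- 1:54
    ct <- condition_table()[conditions, , drop = FALSE]
    pos <- grid$positions[ct$target_index + 1L, , drop = FALSE]
    sup <- ct$forearm_angle == "supination"
    u <- drop(pos %*% co[2:4])
    if (object$model_kind == "extended") co[["a0"]] + u + co[["a4"]] * sup
    else co[["a0"]] + ifelse(sup, co[["gain"]], 1) * u
  }
}

#' @export
residuals.tuning_fit <- function(object, ...) object$residuals

#' Spatial complexity of a response function
#'
#' Quantifies high-spatial-frequency ("salt and pepper") structure as the
#' standard deviation of the distance-normalised absolute rate differences
#' over all nearest-neighbour target pairs.  The response is first
#' range-normalised (mean subtracted, divided by max - min so its range is
#' 1); each of the 54 axis-aligned neighbour pairs (k, l) at the minimal
#' distance contributes \eqn{|\bar r(x_k) - \bar r(x_l)| / D_{min}}, and
#' the score is the standard deviation of these values.  A constant
#' response, and any response whose neighbour differences are all equal in
#' magnitude (e.g. a perfect parity checkerboard), scores exactly 0.
#'
#' @param resp Numeric 27-vector of per-target mean rates (one forearm
#'   angle), all finite; neurons with missing targets cannot be scored.
#' @param grid Target grid.
#' @param distance_unit \code{"cm"} divides by the lattice constant in cm;
#'   \code{"step"} treats positions in units of the lattice constant
#'   (\eqn{D_{min} = 1}), i.e. a per-lattice-step discrete derivative.
#' @return An object of class \code{"complexity_score"}: list with
#'   \code{value} and \code{n_pairs}.
#' @export
complexity_measure <- function(resp, grid = make_target_grid(),
                               distance_unit = c("cm", "step")) {
  distance_unit <- match.arg(distance_unit)
  if (length(resp) != 27L || any(!is.finite(resp)))
    stop("complexity needs all 27 targets (9-target sessions are excluded)")
  dmin <- if (distance_unit == "cm") grid$d_min else 1
  v <- .complexity_values(matrix(resp, ncol = 1L), grid, dmin)
  structure(list(value = v, n_pairs = nrow(grid$neighbor_pairs)),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("spatial complexity: %.4f over %d neighbour pairs\n",
              x$value, x$n_pairs))
  invisible(x)
}

# vectorised complexity over columns of a 27 x n matrix; NA for flat columns
.complexity_values <- function(Y, grid, dmin) {
  rng <- apply(Y, 2L, function(v) diff(range(v)))
  flat <- rng <= 0
  rng[flat] <- 1
  Yn <- sweep(sweep(Y, 2L, colMeans(Y)), 2L, rng, "/")
  nb <- grid$neighbor_pairs
  D <- abs(Yn[nb[, 1L], , drop = FALSE] - Yn[nb[, 2L], , drop = FALSE]) / dmin
  out <- apply(D, 2L, stats::sd)
  out[flat] <- 0
  out
}

#' Population complexity distribution
#'
#' Applies \code{\link{complexity_measure}} to every complete 27-target
#' response at each forearm angle of a response set and pools the values.
#'
#' @param responses neurons x 54 matrix, or a \code{"response_set"}.
#' @inheritParams complexity_measure
#' @return Numeric vector of complexity values (both angles pooled,
#'   incomplete responses dropped).
#' @export
complexity_distribution <- function(responses, grid = make_target_grid(),
                                    distance_unit = c("cm", "step")) {
  distance_unit <- match.arg(distance_unit)
  if (inherits(responses, "response_set")) responses <- responses$mean
  dmin <- if (distance_unit == "cm") grid$d_min else 1
  out <- numeric(0)
  for (ang in c("pronation", "supination")) {
    Y <- t(responses[, angle_columns(ang), drop = FALSE])
    keep <- colSums(!is.finite(Y)) == 0L
    if (any(keep))
      out <- c(out, .complexity_values(Y[, keep, drop = FALSE], grid, dmin))
  }
  out
}

#' Tuning screen: one-way ANOVA across conditions
#'
#' Tests, per neuron, whether single-trial rates differ across the visited
#' conditions (one-way ANOVA), with the non-parametric Kruskal-Wallis test
#' alongside.  Neurons whose trials are all identical are reported untuned
#' with p = 1.
#'
#' @param recording A recording.
#' @param alpha Significance level (default 0.01).
#' @return Data frame with \code{neuron_id}, \code{p_anova},
#'   \code{p_kruskal}, \code{tuned}.
#' @export
screen_tuned <- function(recording, alpha = 0.01) {
  recording <- as_recording(recording)
  ids <- unique(recording$neuron_id)
  res <- lapply(ids, function(id) {
    r <- recording[recording$neuron_id == id, ]
    g <- factor(condition_index(r$target_index, r$forearm_angle))
    if (nlevels(droplevels(g)) < 2L || stats::var(r$rate_hz) == 0)
      return(c(1, 1))
    pa <- stats::anova(stats::lm(rate_hz ~ g, data = r))[["Pr(>F)"]][1L]
    pk <- stats::kruskal.test(r$rate_hz, g)$p.value
    c(pa, pk)
  })
  res <- do.call(rbind, res)
  data.frame(neuron_id = ids, p_anova = res[, 1L], p_kruskal = res[, 2L],
             tuned = res[, 1L] < alpha, stringsAsFactors = FALSE)
}

#' Coding level of a neuron
#'
#' The fraction of conditions that drive the neuron: a condition counts if
#' its mean rate is at least \code{rate_floor} spikes/s, or significantly
#' different from 0 (one-sample t-test at \code{alpha}, Bonferroni
#' corrected over the 54 conditions).
#'
#' @param recording A recording (all neurons are scored).
#' @param rate_floor Rate criterion in spikes/s (default 5).
#' @param alpha Per-family significance level (default 0.01).
#' @return Named numeric vector in [0, 1], one entry per neuron.
#' @export
coding_level <- function(recording, rate_floor = 5, alpha = 0.01) {
  recording <- as_recording(recording)
  ids <- unique(recording$neuron_id)
  out <- vapply(ids, function(id) {
    tl <- trials_by_condition(recording, id)
    tl <- tl[lengths(tl) > 0L]
    act <- vapply(tl, function(v) {
      if (mean(v) >= rate_floor) return(TRUE)
      if (length(v) < 2L || stats::sd(v) == 0) return(FALSE)
      stats::t.test(v, mu = 0)$p.value < alpha / 54
    }, logical(1L))
    mean(act)
  }, numeric(1L))
  names(out) <- as.character(ids)
  out
}

#' Detect hand-jitter segments from a speed series
#'
#' Finds maximal runs where instantaneous hand speed exceeds a threshold
#' (default 2.48 cm/s, the median of per-trial maximal jitter speeds in the
#' task this suite models), then extends each run backward to the nearest
#' preceding local speed minimum, taken as the jitter onset.
#'
#' @param speed Numeric vector of uniformly sampled speeds (cm/s).
#' @param threshold Speed threshold (cm/s).
#' @return Data frame with one row per segment: \code{onset},
#'   \code{first_above}, \code{last_above} (1-based sample indices).
#' @export
detect_jitter_segments <- function(speed, threshold = 2.48) {
  if (length(speed) == 0L)
    return(data.frame(onset = integer(0), first_above = integer(0),
                      last_above = integer(0)))
  above <- speed > threshold
  if (!any(above))
    return(data.frame(onset = integer(0), first_above = integer(0),
                      last_above = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fa <- starts[r$values]
  la <- ends[r$values]
  onset <- vapply(fa, function(i) {
    while (i > 1L && speed[i - 1L] < speed[i]) i <- i - 1L
    i
  }, integer(1L))
  data.frame(onset = onset, first_above = fa, last_above = la)
}

#' Multiplicative velocity tuning during hand jitter
#'
#' Regresses time-binned firing rates on hand speed and speed-weighted
#' movement direction,
#' \eqn{r(t-\tau) = b_0 + b_1 \|\dot x\| + b_2 \|\dot x\|\, PD' \hat x},
#' over a set of lead/lag offsets, and keeps the lag with the maximal
#' R-squared.  PD is the unit vector of the direction coefficients and
#' \eqn{b_2} their norm.
#'
#' @param rate Numeric vector of binned firing rates (e.g. 100 ms bins).
#' @param velocity T x 3 matrix of hand velocity (cm/s) in the same bins.
#' @param bin_ms Bin width in ms (default 100).
#' @param lags_ms Lags of rate relative to behaviour (negative = neural
#'   activity leads), default -300..100 by 10 ms; lags that are not a
#'   multiple of the bin width are rounded to bins.
#' @return An object of class \code{"velocity_fit"}: coefficients b0, b1,
#'   b2, unit \code{pd_vector}, \code{best_lag_ms}, \code{r_squared} and
#'   the per-lag R-squared table.
#' @export
fit_velocity_tuning <- function(rate, velocity, bin_ms = 100,
                                lags_ms = seq(-300, 100, by = 10)) {
  velocity <- as.matrix(velocity)
  stopifnot(length(rate) == nrow(velocity), ncol(velocity) == 3L)
  speed <- sqrt(rowSums(velocity^2))
  dir <- velocity / pmax(speed, 1e-12)
  lags_bin <- unique(as.integer(round(lags_ms / bin_ms)))
  res <- lapply(lags_bin, function(L) {
    # r(t - tau) ~ kin(t): rate index = t - L_bins
    t_idx <- seq_len(length(rate))
    ri <- t_idx - L
    keep <- ri >= 1L & ri <= length(rate)
    if (sum(keep) < 6L) return(NULL)
    X <- cbind(1, speed[keep], speed[keep] * dir[keep, , drop = FALSE])
    y <- rate[ri[keep]]
    f <- stats::lm.fit(X, y)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) max(0, 1 - sum(f$residuals^2) / tss) else 0
    list(lag = L * bin_ms, r2 = r2, coef = f$coefficients)
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) stop("no lag had enough samples")
  r2s <- vapply(res, `[[`, numeric(1L), "r2")
  best <- res[[which.max(r2s)]]
  bdir <- best$coef[3:5]
  b2 <- sqrt(sum(bdir^2))
  structure(list(
    coefficients = c(b0 = unname(best$coef[1L]), b1 = unname(best$coef[2L]),
                     b2 = b2),
    pd_vector   = if (b2 > 0) unname(bdir / b2) else c(0, 0, 0),
    best_lag_ms = best$lag,
    r_squared   = max(r2s),
    r2_by_lag   = data.frame(lag_ms = vapply(res, `[[`, numeric(1L), "lag"),
                             r_squared = r2s)
  ), class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf(
    "velocity tuning: best lag %d ms, R^2 = %.3f, |b2| = %.3f\n",
    x$best_lag_ms, x$r_squared, x$coefficients[["b2"]]))
  invisible(x)
}
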
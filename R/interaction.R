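with_complete_neurons <- function(recording) {
  rs <- response_from_trials(recording)
  ok <- rowSums(is.na(rs$mean)) == 0L & apply(rs$n_trials, 1L, min) >= 2L
  list(ids = rownames(rs$mean)[ok], mean = rs$mean[ok, , drop = FALSE],
       n_skipped = sum(!ok))
}

# split one angle's trials in half per condition and return the two
# half-average 27-vectors
.half_means <- function(byc, cols) {
  h <- vapply(byc[cols], function(v) {
    K <- length(v)
    idx <- sample.int(K)
    h1 <- idx[seq_len(K %/% 2L)]
    c(mean(v[h1]), mean(v[-h1]))
  }, numeric(2L))
  list(a = h[1L, ], b = h[2L, ])
}

# shared machinery of the shift and gain tests: 'stat' maps a 27-target
# response vector to a scalar (min for the shift test, range for gain)
.angle_effect_test <- function(recording, stat, n_boot, seed, class) {
  recording <- as_recording(recording)
  set.seed(seed)
  cn <- with_complete_neurons(recording)
  if (length(cn$ids) < 2L) stop("need at least 2 complete neurons")
  pcols <- angle_columns("pronation"); scols <- angle_columns("supination")
  obs <- vapply(seq_along(cn$ids), function(i)
    stat(cn$mean[i, scols]) - stat(cn$mean[i, pcols]), numeric(1L))
  byc_all <- lapply(cn$ids, function(id)
    trials_by_condition(recording, id))
  ctrl <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(length(cn$ids), 1L)
    cols <- if (stats::runif(1) < 0.5) pcols else scols
    hm <- .half_means(byc_all[[i]], cols)
    ctrl[b] <- stat(hm$a) - stat(hm$b)
  }
  fstat <- stats::var(obs) / stats::var(ctrl)
  p <- stats::pf(fstat, length(obs) - 1L, n_boot - 1L,
                 lower.tail = FALSE)
  structure(list(observed = stats::setNames(obs, cn$ids),
                 observed_sd = stats::sd(obs),
                 control = ctrl, control_sd = stats::sd(ctrl),
                 f_statistic = fstat, p_value = p,
                 n_neurons = length(cn$ids), n_skipped = cn$n_skipped),
            class = class)
}

#' Additive forearm-angle shift test
#'
#' Per neuron, the baseline (the lowest trial-mean firing rate across the
#' 27 targets) is computed for each forearm angle; the observed statistic
#' is the supination-minus-pronation baseline difference.  Its dispersion
#' across neurons is compared against a noise-only control built by
#' splitting one angle's trials in half and differencing the two
#' half-average baselines, via a variance-ratio F-test.
#'
#' @param recording A recording; neurons lacking 2 trials in any
#'   condition are skipped (count reported).
#' @param n_boot Number of control resamples (default 1000).
#' @param seed Integer seed.
#' @return Object of class \code{"shift_test"}: \code{observed}
#'   (per-neuron differences, spikes/s), \code{observed_sd},
#'   \code{control}, \code{control_sd}, \code{f_statistic},
#'   \code{p_value}, \code{n_neurons}, \code{n_skipped}.
#' @export
baseline_shift_test <- function(recording, n_boot = 1000L, seed = 1L) {
  .angle_effect_test(recording, min, n_boot, seed, "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(
    "forearm-angle baseline shift (%d neurons, %d skipped)\n  observed SD %.2f vs noise-only SD %.2f spikes/s, F = %.2f, p = %.3g\n",
    x$n_neurons, x$n_skipped, x$observed_sd, x$control_sd,
    x$f_statistic, x$p_value))
  invisible(x)
}

#' Multiplicative gain-change test
#'
#' Like \code{\link{baseline_shift_test}}, but the per-angle statistic is
#' the firing-rate range across the 27 targets (max minus min): a pure
#' gain change between angles rescales the range while an additive shift
#' leaves it untouched.
#'
#' @inheritParams baseline_shift_test
#' @return Object of class \code{"gain_test"} (fields as in
#'   \code{\link{baseline_shift_test}}).
#' @export
gain_change_test <- function(recording, n_boot = 1000L, seed = 1L) {
  .angle_effect_test(recording, function(v) max(v) - min(v), n_boot,
                     seed, "gain_test")
}

#' @export
print.gain_test <- function(x, ...) {
  cat(sprintf(
    "forearm-angle gain change (%d neurons, %d skipped)\n  observed range-difference SD %.2f vs noise-only SD %.2f spikes/s, F = %.2f, p = %.3g\n",
    x$n_neurons, x$n_skipped, x$observed_sd, x$control_sd,
    x$f_statistic, x$p_value))
  invisible(x)
}

#' Pronation/supination response correlations
#'
#' Pearson correlation, per neuron, between the 27-target trial-mean
#' response measured in pronation and in supination.
#'
#' @param responses Neurons x 54 matrix of trial means (NA rows
#'   dropped).
#' @return List of class \code{"ps_correlations"}: \code{r} (named
#'   per-neuron correlations, excluding flat responses),
#'   \code{n_excluded}, \code{median}, \code{mean}, \code{sd}.
#' @export
pronation_supination_correlations <- function(responses) {
  Y <- as.matrix(responses)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  p <- Y[, angle_columns("pronation"), drop = FALSE]
  s <- Y[, angle_columns("supination"), drop = FALSE]
  r <- vapply(seq_len(nrow(Y)), function(i) {
    if (stats::sd(p[i, ]) == 0 || stats::sd(s[i, ]) == 0)
      return(NA_real_)
    stats::cor(p[i, ], s[i, ])
  }, numeric(1L))
  names(r) <- rownames(Y)
  keep <- !is.na(r)
  structure(list(r = r[keep], n_excluded = sum(!keep),
                 median = stats::median(r[keep]),
                 mean = mean(r[keep]), sd = stats::sd(r[keep])),
            class = "ps_correlations")
}

#' @export
print.ps_correlations <- function(x, ...) {
  cat(sprintf(
    "pronation/supination correlations: %d neurons (%d excluded)\n  median %.3f, mean %.3f, SD %.3f\n",
    length(x$r), x$n_excluded, x$median, x$mean, x$sd))
  invisible(x)
}

#' Controls for the pronation/supination correlation
#'
#' Reference distributions for
#' \code{\link{pronation_supination_correlations}}:
#' \describe{
#'   \item{bootstrap}{per neuron and angle, correlates the observed mean
#'     response with the observed mean plus one resampled noise trace —
#'     the correlation expected if the two angles shared an identical
#'     underlying response and one measurement carried trial-averaging
#'     noise;}
#'   \item{splithalf}{correlates two independent half-trial averages of
#'     the same angle — a stricter ceiling in which both sides carry
#'     noise;}
#'   \item{shuffle}{correlates each neuron's pronation response with the
#'     supination response of randomly chosen other neurons — the
#'     no-relation floor, centred on zero.}
#' }
#'
#' @param recording A recording.
#' @param mode One of \code{"bootstrap"}, \code{"splithalf"},
#'   \code{"shuffle"}.
#' @param n_resamples Resamples per neuron (default 1; for shuffle, the
#'   number of partner draws per neuron).
#' @param seed Integer seed.
#' @return Numeric vector of control correlations.
#' @export
correlation_controls <- function(recording,
                                 mode = c("bootstrap", "splithalf",
                                          "shuffle"),
                                 n_resamples = 1L, seed = 1L) {
  mode <- match.arg(mode)
  recording <- as_recording(recording)
  set.seed(seed)
  cn <- with_complete_neurons(recording)
  ids <- cn$ids; M <- cn$mean
  angles <- c("pronation", "supination")

  if (mode == "shuffle") {
    n <- length(ids)
    if (n < 2L) stop("shuffle control needs at least 2 neurons")
    out <- numeric(n * n_resamples)
    k <- 0L
    for (b in seq_len(n_resamples)) {
      for (i in seq_len(n)) {
        j <- sample(setdiff(seq_len(n), i), 1L)
        k <- k + 1L
        out[k] <- stats::cor(M[i, angle_columns("pronation")],
                             M[j, angle_columns("supination")])
      }
    }
    return(out)
  }

  out <- numeric(0L)
  for (i in seq_along(ids)) {
    byc <- trials_by_condition(recording, ids[i])
    for (b in seq_len(n_resamples)) {
      for (ang in angles) {
        cols <- angle_columns(ang)
        if (mode == "bootstrap") {
          eta <- vapply(byc[cols], function(v) {
            K <- length(v)
            kl <- sample.int(K, 2L)
            (v[kl[1L]] - v[kl[2L]]) / sqrt(2 * K)
          }, numeric(1L))
          m <- M[i, cols]
          if (stats::sd(m) > 0 && stats::sd(m + eta) > 0)
            out <- c(out, stats::cor(m, m + eta))
        } else {
          hm <- .half_means(byc, cols)
          if (stats::sd(hm$a) > 0 && stats::sd(hm$b) > 0)
            out <- c(out, stats::cor(hm$a, hm$b))
        }
      }
    }
  }
  out
}

#' Bootstrap test for the difference of two medians
#'
#' Compares the medians of two distributions by resampling each with
#' replacement \code{n_boot} times and reporting the two-sided
#' probability that the resampled median difference crosses zero.
#'
#' @param x,y Numeric vectors.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with \code{difference} (median(x) - median(y)),
#'   \code{p_value}, \code{boot_differences}.
#' @export
median_difference_test <- function(x, y, n_boot = 1000L, seed = 1L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  set.seed(seed)
  d <- vapply(seq_len(n_boot), function(b)
    stats::median(sample(x, replace = TRUE)) -
      stats::median(sample(y, replace = TRUE)), numeric(1L))
  obs <- stats::median(x) - stats::median(y)
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  list(difference = obs, p_value = min(1, max(p, 1 / n_boot)),
       boot_differences = d)
}
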
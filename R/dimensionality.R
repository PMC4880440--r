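#' Noise traces of trial-averaged responses
#'
#' For each neuron, builds surrogate noise-only "response functions" that
#' carry the sampling noise of a K-trial average: for each resample two
#' distinct trials (k, l) are drawn per condition and the trace is
#' \deqn{\bar\eta(c) = (r_k(c) - r_l(c)) / \sqrt{2K},}
#' whose variance matches that of a K-trial mean.  Conditions with fewer
#' than two trials give \code{NA}.
#'
#' @param recording A recording (\code{\link{as_recording}}).
#' @param n_resamples Traces per neuron (default 1).
#' @param seed Integer seed.
#' @return A matrix (neurons x resamples) x 54 of noise traces, with
#'   attributes \code{neuron_id} and \code{resample}.
#' @export
extract_noise_traces <- function(recording, n_resamples = 1L, seed = 1L) {
  recording <- as_recording(recording)
  set.seed(seed)
  ids <- unique(recording$neuron_id)
  out <- matrix(NA_real_, length(ids) * n_resamples, 54L)
  nid <- character(nrow(out)); rsm <- integer(nrow(out))
  row <- 0L
  for (id in ids) {
    byc <- trials_by_condition(recording, id)
    for (b in seq_len(n_resamples)) {
      row <- row + 1L
      nid[row] <- id; rsm[row] <- b
      for (c in 1:54) {
        v <- byc[[c]]
        K <- length(v)
        if (K >= 2L) {
          kl <- sample.int(K, 2L)
          out[row, c] <- (v[kl[1L]] - v[kl[2L]]) / sqrt(2 * K)
        }
      }
    }
  }
  attr(out, "neuron_id") <- nid
  attr(out, "resample") <- rsm
  out
}

#' Normalize response functions
#'
#' @param responses Neurons x conditions matrix.
#' @param method \code{"range"}: subtract each neuron's mean and scale its
#'   range to 1 (flat neurons are left mean-subtracted only);
#'   \code{"sqrt"}: square-root transform then mean-subtract;
#'   \code{"none"}: mean-subtract only.
#' @return Matrix of the same shape.
#' @export
normalize_responses <- function(responses,
                                method = c("range", "sqrt", "none")) {
  method <- match.arg(method)
  Y <- as.matrix(responses)
  if (method == "sqrt") {
    if (any(Y < 0, na.rm = TRUE)) stop("sqrt normalization needs rates >= 0")
    Y <- sqrt(Y)
  }
  ctr <- Y - rowMeans(Y, na.rm = TRUE)
  if (method != "range") return(ctr)
  rng <- apply(Y, 1L, function(v) diff(range(v, na.rm = TRUE)))
  rng[!is.finite(rng) | rng == 0] <- 1
  ctr / rng
}

#' Signal and noise PCA of a neural population
#'
#' Principal-component decomposition of the population's trial-averaged
#' response matrix (neurons x 54), with a noise-derived significance
#' threshold: the same decomposition is applied to \code{n_boot}
#' populations of pure noise traces, and a signal PC counts as
#' significant if its variance exceeds the chosen quantile of (a) the
#' largest noise-PC variance across bootstraps (\code{strict_dim}) or (b)
#' the mean noise-PC variance (\code{mean_dim}).  Columns (conditions) are
#' centred across neurons before PCA in both cases.
#'
#' @param responses Neurons x conditions matrix of trial means (rows with
#'   any NA are dropped).
#' @param noise_traces Matrix of noise traces with at least
#'   \code{n_boot * nrow(responses)} usable rows, e.g. from
#'   \code{\link{extract_noise_traces}} with \code{n_resamples = n_boot}.
#' @param n_boot Number of noise bootstraps (default 100).
#' @param level Confidence level of the threshold (default 0.99).
#' @param normalize Normalization applied to both signal and noise rows
#'   before PCA (see \code{\link{normalize_responses}}; default
#'   \code{"none"}, i.e. raw rates, mean-subtracted per condition in the
#'   PCA step only).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class \code{"pc_decomposition"}: list with
#'   \code{variances} (signal PC variances), \code{prop_var},
#'   \code{rotation} (54 x p), \code{scores}, \code{strict_dim},
#'   \code{mean_dim}, \code{strict_threshold}, \code{mean_threshold},
#'   \code{noise_top} and \code{noise_mean} (the bootstrap distributions),
#'   \code{n_neurons}.
#' @export
pca_signal_noise <- function(responses, noise_traces, n_boot = 100L,
                             level = 0.99,
                             normalize = c("none", "range", "sqrt"),
                             seed = 1L) {
  normalize <- match.arg(normalize)
  Y <- as.matrix(responses)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 complete neurons")
  NT <- as.matrix(noise_traces)
  NT <- NT[stats::complete.cases(NT), , drop = FALSE]
  if (nrow(NT) < n) stop("need at least as many noise traces as neurons")
  if (normalize != "none") {
    Y <- normalize_responses(Y, normalize)
    # noise traces are differences; range-normalize against trace range
    NT <- normalize_responses(NT, if (normalize == "range") "range" else
                              "none")
  }
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  set.seed(seed)
  noise_top <- noise_mean <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(NT), n, replace = nrow(NT) < n * n_boot)
    nv <- stats::prcomp(NT[rows, , drop = FALSE], center = TRUE)$sdev^2
    noise_top[b] <- max(nv)
    noise_mean[b] <- mean(nv)
  }
  thr_top <- stats::quantile(noise_top, level, names = FALSE)
  thr_mean <- stats::quantile(noise_mean, level, names = FALSE)
  structure(list(
    variances = v, prop_var = v / sum(v),
    rotation = pc$rotation, scores = pc$x,
    strict_dim = sum(v > thr_top), mean_dim = sum(v > thr_mean),
    strict_threshold = thr_top, mean_threshold = thr_mean,
    noise_top = noise_top, noise_mean = noise_mean,
    n_neurons = n, level = level
  ), class = "pc_decomposition")
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat(sprintf("PC decomposition of %d neurons x %d conditions\n",
              x$n_neurons, nrow(x$rotation)))
  cat(sprintf("  significant dims: %d (strict, vs top noise PC), %d (vs mean noise PC)\n",
              x$strict_dim, x$mean_dim))
  cat(sprintf("  top-5 variance shares: %s\n",
              paste(sprintf("%.3f", utils::head(x$prop_var, 5L)),
                    collapse = " ")))
  invisible(x)
}

#' @export
summary.pc_decomposition <- function(object, ...) {
  cat(sprintf("PC decomposition (%d neurons, level %.2f)\n",
              object$n_neurons, object$level))
  cat(sprintf("  strict_dim %d (threshold %.4g), mean_dim %d (threshold %.4g)\n",
              object$strict_dim, object$strict_threshold,
              object$mean_dim, object$mean_threshold))
  cat(sprintf("  cumulative variance at strict_dim: %.3f\n",
              sum(object$prop_var[seq_len(max(object$strict_dim, 1L))])))
  invisible(object)
}

#' @export
plot.pc_decomposition <- function(x, n_show = 54L, ...) {
  k <- min(n_show, length(x$variances))
  graphics::plot(seq_len(k), x$variances[seq_len(k)], log = "y",
                 xlab = "PC", ylab = "variance", pch = 19, ...)
  graphics::abline(h = x$strict_threshold, lty = 2)
  graphics::abline(h = x$mean_threshold, lty = 3)
  graphics::legend("topright", c("strict threshold", "mean threshold"),
                   lty = c(2, 3), bty = "n")
  invisible(x)
}

#' Explainable-variance curve
#'
#' Cumulative fraction of population signal variance carried by the
#' leading principal components.
#'
#' @param decomposition A \code{"pc_decomposition"}.
#' @return Numeric vector of cumulative variance fractions.
#' @export
explainable_variance_curve <- function(decomposition) {
  stopifnot(inherits(decomposition, "pc_decomposition"))
  cumsum(decomposition$prop_var)
}

#' Linear tuning of principal components
#'
#' Fits the spatial-linear model (per forearm angle) to each principal
#' component's 54-condition loading pattern, quantifying how much of each
#' population mode is itself linear in hand position.
#'
#' @param decomposition A \code{"pc_decomposition"} over 54 conditions.
#' @param grid Target grid.
#' @param n_pcs Number of leading PCs to fit (default
#'   \code{strict_dim}).
#' @return Data frame with columns \code{pc}, \code{r_squared_pronation},
#'   \code{r_squared_supination}, \code{prop_var}.
#' @export
pc_linear_fit <- function(decomposition, grid = make_target_grid(),
                          n_pcs = NULL) {
  stopifnot(inherits(decomposition, "pc_decomposition"))
  if (nrow(decomposition$rotation) != 54L)
    stop("needs a 54-condition decomposition")
  if (is.null(n_pcs)) n_pcs <- max(decomposition$strict_dim, 1L)
  n_pcs <- min(n_pcs, ncol(decomposition$rotation))
  res <- data.frame(pc = seq_len(n_pcs),
                    r_squared_pronation = NA_real_,
                    r_squared_supination = NA_real_,
                    prop_var = decomposition$prop_var[seq_len(n_pcs)])
  for (j in seq_len(n_pcs)) {
    w <- decomposition$rotation[, j]
    res$r_squared_pronation[j] <-
      fit_linear_tuning(w[angle_columns("pronation")], grid,
                        "pronation")$r_squared
    res$r_squared_supination[j] <-
      fit_linear_tuning(w[angle_columns("supination")], grid,
                        "supination")$r_squared
  }
  res
}

#' Reconstruction quality from leading PCs
#'
#' Reconstructs each neuron's (mean-centred) response from the leading
#' \code{n_pcs} principal components and reports the population R-squared
#' of the reconstruction, per neuron and overall.
#'
#' @param decomposition A \code{"pc_decomposition"}.
#' @param n_pcs Number of leading PCs (default \code{strict_dim}).
#' @return List with \code{overall_r2} and per-neuron \code{r2}.
#' @export
pc_reconstruction_r2 <- function(decomposition, n_pcs = NULL) {
  stopifnot(inherits(decomposition, "pc_decomposition"))
  if (is.null(n_pcs)) n_pcs <- max(decomposition$strict_dim, 1L)
  n_pcs <- min(n_pcs, ncol(decomposition$rotation))
  S <- decomposition$scores
  R <- decomposition$rotation
  X <- S %*% t(R)                         # centred data
  Xk <- S[, seq_len(n_pcs), drop = FALSE] %*%
    t(R[, seq_len(n_pcs), drop = FALSE])
  resid <- X - Xk
  tot <- rowSums(X^2)
  r2 <- ifelse(tot > 0, 1 - rowSums(resid^2) / tot, NA_real_)
  list(overall_r2 = 1 - sum(resid^2) / sum(X^2), r2 = r2)
}
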
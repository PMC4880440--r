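#' Build a pseudo-simultaneous population
#'
#' Stacks independently recorded neurons into a pseudo-simultaneous
#' population over the EMG conditions: for each neuron, trials within
#' each condition are shuffled independently and the first
#' \code{n_trials} are kept, so trial t of the population pairs
#' unrelated trials across neurons (any common noise is destroyed by
#' construction).  Neurons lacking \code{n_trials} trials in any of the
#' conditions are dropped.
#'
#' @param recording A recording.
#' @param n_trials Trials kept per condition (default 15).
#' @param conditions Data frame of conditions (default
#'   \code{\link{emg_conditions}}, the 18 EMG conditions).
#' @param seed Integer seed for the trial shuffling.
#' @return Object of class \code{"pseudo_population"}: list with
#'   \code{rates} (array trials x neurons x conditions),
#'   \code{neuron_id}, \code{conditions}, \code{n_trials}.
#' @export
build_pseudo_population <- function(recording, n_trials = 15L,
                                    conditions = emg_conditions(),
                                    seed = 1L) {
  recording <- as_recording(recording)
  set.seed(seed)
  ids <- unique(recording$neuron_id)
  nc <- nrow(conditions)
  keep <- character(0L)
  lst <- list()
  for (id in ids) {
    byc <- trials_by_condition(recording, id)[conditions$condition]
    if (all(lengths(byc) >= n_trials)) {
      keep <- c(keep, id)
      lst[[id]] <- vapply(byc, function(v)
        v[sample.int(length(v))][seq_len(n_trials)], numeric(n_trials))
    }
  }
  if (length(keep) == 0L)
    stop("no neuron has ", n_trials, " trials in every condition")
  rates <- array(NA_real_, c(n_trials, length(keep), nc),
                 dimnames = list(NULL, keep, NULL))
  for (i in seq_along(keep)) rates[, i, ] <- lst[[keep[i]]]
  structure(list(rates = rates, neuron_id = keep,
                 conditions = conditions, n_trials = n_trials),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat(sprintf(
    "pseudo-simultaneous population: %d neurons, %d conditions x %d trials\n",
    length(x$neuron_id), nrow(x$conditions), x$n_trials))
  invisible(x)
}

#' Cross-validation splits holding out one trial per condition
#'
#' @param n_trials Trials per condition.
#' @param n_conditions Number of conditions.
#' @param n_splits Number of splits (default 1000).
#' @param seed Integer seed.
#' @return Integer matrix \code{n_splits} x \code{n_conditions}; entry
#'   (s, c) is the trial index held out from condition c in split s.
#' @export
make_cv_splits <- function(n_trials, n_conditions, n_splits = 1000L,
                           seed = 1L) {
  stopifnot(n_trials >= 2L, n_conditions >= 1L, n_splits >= 1L)
  set.seed(seed)
  matrix(sample.int(n_trials, n_splits * n_conditions, replace = TRUE),
         n_splits, n_conditions)
}

# flatten a population and a held-out trial assignment into train/test
# design matrices (rows = trials, cols = neurons) and an index of the
# condition of each row
.pop_design <- function(pop, held_out) {
  nt <- pop$n_trials; nn <- dim(pop$rates)[2L]; nc <- dim(pop$rates)[3L]
  Xall <- matrix(aperm(pop$rates, c(1L, 3L, 2L)), nt * nc, nn)
  cond <- rep(seq_len(nc), each = nt)
  trial <- rep(seq_len(nt), nc)
  test <- trial == held_out[cond]
  list(X_train = Xall[!test, , drop = FALSE],
       X_test  = Xall[test, , drop = FALSE],
       cond_train = cond[!test], cond_test = cond[test])
}

#' Fit a linear EMG decoder
#'
#' Linear readout of muscle activation from population rates, either by
#' the Moore-Penrose pseudoinverse of the (intercept-augmented) design
#' matrix, or by LASSO regression with the penalty chosen by inner
#' cross-validation on the training trials only.  The LASSO path uses 50
#' penalties log-spaced from the smallest penalty that zeroes all
#' weights down four decades.
#'
#' @param x Training design matrix (trials x neurons).
#' @param y Training target (muscle activation per trial).
#' @param method \code{"pinv"} or \code{"lasso"}.
#' @param n_folds Inner folds for the LASSO penalty search (default 5).
#' @param seed Integer seed for the inner fold assignment.
#' @return Object of class \code{"linear_decoder"}: \code{weights},
#'   \code{intercept}, \code{method}, \code{lambda} (LASSO only),
#'   \code{n_nonzero}.
#' @export
fit_linear_decoder <- function(x, y, method = c("pinv", "lasso"),
                               n_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (method == "pinv") {
    A <- cbind(1, x)
    w <- drop(MASS::ginv(A) %*% y)
    out <- list(weights = w[-1L], intercept = w[1L], method = "pinv",
                lambda = NA_real_, n_nonzero = sum(w[-1L] != 0))
  } else {
    set.seed(seed)
    n <- nrow(x)
    # lambda_max: smallest penalty with all-zero weights (centred data)
    xc <- scale(x, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    lmax <- max(abs(crossprod(xc, yc))) / n
    lambdas <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50L))
    folds <- sample(rep_len(seq_len(n_folds), n))
    cv <- glmnet::cv.glmnet(x, y, lambda = lambdas, foldid = folds,
                            standardize = FALSE)
    fit <- glmnet::glmnet(x, y, lambda = lambdas, standardize = FALSE)
    co <- as.matrix(stats::coef(fit, s = cv$lambda.min))
    out <- list(weights = co[-1L, 1L], intercept = co[1L, 1L],
                method = "lasso", lambda = cv$lambda.min,
                n_nonzero = sum(co[-1L, 1L] != 0))
  }
  structure(out, class = "linear_decoder")
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("linear decoder (%s): %d/%d nonzero weights%s\n",
              x$method, x$n_nonzero, length(x$weights),
              if (x$method == "lasso")
                sprintf(", lambda %.4g", x$lambda) else ""))
  invisible(x)
}

#' @export
predict.linear_decoder <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' Cross-validated EMG decoding
#'
#' Full decoding protocol: for each cross-validation split, a decoder per
#' muscle is trained on all trials except one held-out trial per
#' condition, and evaluated on the held-out trials.  Performance per
#' split and muscle is the Pearson correlation (CC) between predicted
#' and actual activation over the held-out conditions, and the decoding
#' error SD expressed as percent of that muscle's activation range.
#'
#' @param population A \code{"pseudo_population"}.
#' @param emg An \code{"emg_set"} (conditions must match the
#'   population's).
#' @param method \code{"pinv"} or \code{"lasso"}.
#' @param n_splits Number of CV splits (default 1000).
#' @param seed Integer seed.
#' @param keep_weights Keep each split's weight vectors (needed by
#'   \code{\link{subset_selection_summary}}; default FALSE).
#' @return Object of class \code{"decoding_result"}: \code{cc} (splits x
#'   muscles; NA where the prediction had zero variance — excluded from
#'   medians with the count in \code{n_missing_cc}), \code{error_pct}
#'   (splits x muscles), \code{median_cc}, \code{error_sd_pct} (per
#'   muscle, SD of errors across all splits as percent of range),
#'   \code{n_nonzero} (splits x muscles), \code{weights} (list over
#'   splits of neurons x muscles matrices when \code{keep_weights}),
#'   \code{method}.
#' @export
evaluate_decoding <- function(population, emg, method = c("pinv", "lasso"),
                              n_splits = 1000L, seed = 1L,
                              keep_weights = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(population, "pseudo_population"),
            inherits(emg, "emg_set"))
  if (!identical(population$conditions$condition,
                 emg$conditions$condition))
    stop("population and EMG conditions differ")
  nc <- nrow(population$conditions)
  splits <- make_cv_splits(population$n_trials, nc, n_splits,
                           seed = seed)
  nm <- length(emg$muscles)
  cc <- err <- nz <- matrix(NA_real_, n_splits, nm,
                            dimnames = list(NULL, emg$muscles))
  err_all <- vector("list", nm)
  W <- if (keep_weights) vector("list", n_splits) else NULL
  rngs <- apply(emg$mean_emg, 1L, function(v) diff(range(v)))
  for (s in seq_len(n_splits)) {
    d <- .pop_design(population, splits[s, ])
    if (keep_weights)
      W[[s]] <- matrix(NA_real_, ncol(d$X_train), nm,
                       dimnames = list(population$neuron_id,
                                       emg$muscles))
    for (m in seq_len(nm)) {
      y_tr <- emg$mean_emg[m, d$cond_train]
      y_te <- emg$mean_emg[m, d$cond_test]
      dec <- fit_linear_decoder(d$X_train, y_tr, method,
                                seed = seed + s)
      pred <- predict(dec, d$X_test)
      cc[s, m] <- if (stats::sd(pred) > 0)
        stats::cor(pred, y_te) else NA_real_
      e <- pred - y_te
      err[s, m] <- stats::sd(e) / rngs[m] * 100
      nz[s, m] <- dec$n_nonzero
      if (keep_weights) W[[s]][, m] <- dec$weights
      err_all[[m]] <- c(err_all[[m]], e / rngs[m] * 100)
    }
  }
  structure(list(
    cc = cc, error_pct = err, n_nonzero = nz, weights = W,
    median_cc = apply(cc, 2L, stats::median, na.rm = TRUE),
    n_missing_cc = colSums(is.na(cc)),
    error_sd_pct = vapply(err_all, stats::sd, numeric(1L)),
    method = method, n_splits = n_splits
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding (%s), %d splits\n", x$method, x$n_splits))
  cat(sprintf("  median CC overall: %.3f\n",
              stats::median(as.vector(x$cc), na.rm = TRUE)))
  for (m in colnames(x$cc))
    cat(sprintf("  %-15s median CC %.3f, error SD %.1f%% of range\n",
                m, stats::median(x$cc[, m], na.rm = TRUE),
                x$error_sd_pct[match(m, colnames(x$cc))]))
  invisible(x)
}

#' Split single-trial responses into linear and nonlinear components
#'
#' Decomposes each neuron's single-trial rate
#' \eqn{r(k,c) = \bar r_{lin}(c) + \bar r_{nl}(c) + \eta(k,c)}
#' into a linear dataset \eqn{r(k,c) - \bar r_{nl}(c)} and a nonlinear
#' dataset \eqn{r(k,c) - \bar r_{lin}(c)}, where \eqn{\bar r_{lin}} is
#' the per-angle spatial-linear tuning prediction.  The single-trial
#' noise stays attached to both components, and the two datasets minus
#' the raw trials equal the condition mean exactly.  Only neurons whose
#' linear fit is significant in both angles at \code{alpha} are
#' decomposed; the rest are excluded and counted.
#'
#' @param population A \code{"pseudo_population"}.
#' @param responses Neurons x 54 trial-mean matrix used to fit the
#'   tuning models (must cover the population's neurons).
#' @param grid Target grid.
#' @param alpha Significance level of the overall F-test of the linear
#'   fit (0.01 or 0.05; default 0.01).
#' @return List with pseudo-populations \code{linear} and
#'   \code{nonlinear} (over the retained neurons), \code{linear_pred}
#'   and \code{nonlinear_mean} (retained neurons x conditions),
#'   \code{n_excluded} and \code{excluded_ids}.
#' @export
decompose_components <- function(population, responses,
                                 grid = make_target_grid(),
                                 alpha = 0.01) {
  stopifnot(inherits(population, "pseudo_population"),
            alpha %in% c(0.01, 0.05))
  Y <- as.matrix(responses)
  ids <- population$neuron_id
  if (!all(ids %in% rownames(Y)))
    stop("'responses' must contain all population neurons")
  ct <- condition_table()
  condition <- population$conditions$condition
  nt <- population$n_trials
  keep <- logical(length(ids))
  preds <- matrix(NA_real_, length(ids), 54L)
  for (i in seq_along(ids)) {
    y <- Y[ids[i], ]
    fp <- fit_linear_tuning(y[angle_columns("pronation")], grid,
                            "pronation")
    fs <- fit_linear_tuning(y[angle_columns("supination")], grid,
                            "supination")
    keep[i] <- is.finite(fp$f_pvalue) && is.finite(fs$f_pvalue) &&
      fp$f_pvalue < alpha && fs$f_pvalue < alpha
    preds[i, angle_columns("pronation")] <- fp$fitted
    preds[i, angle_columns("supination")] <- fs$fitted
  }
  if (!any(keep)) stop("no neuron has a significant linear fit in both angles")
  kid <- ids[keep]
  rates <- population$rates[, keep, , drop = FALSE]
  nn <- length(kid); nc <- length(condition)
  lin <- nl <- rates
  lin_pred <- nl_mean <- matrix(NA_real_, nn, nc,
                                dimnames = list(kid, NULL))
  pk <- preds[keep, , drop = FALSE]
  for (i in seq_len(nn)) {
    cond_mean <- apply(rates[, i, , drop = FALSE], 3L, mean)
    lp <- pk[i, condition]
    lin_pred[i, ] <- lp
    nl_mean[i, ] <- cond_mean - lp
    for (c in seq_len(nc)) {
      lin[, i, c] <- rates[, i, c] - nl_mean[i, c]
      nl[, i, c] <- rates[, i, c] - lp[c]
    }
  }
  mk <- function(r) structure(list(rates = r, neuron_id = kid,
                                   conditions = population$conditions,
                                   n_trials = nt),
                              class = "pseudo_population")
  list(linear = mk(lin), nonlinear = mk(nl),
       linear_pred = lin_pred, nonlinear_mean = nl_mean,
       n_excluded = sum(!keep), excluded_ids = ids[!keep])
}

#' Decoding from leading principal components
#'
#' For each requested rank k and each split, computes PCA of the
#' training trials, projects train and test onto the leading k
#' components, and decodes with the pseudoinverse in that space.  The
#' projection (and the centring it uses) is estimated from training
#' data only.  Ranks beyond the population rank are capped with a
#' warning.
#'
#' @inheritParams evaluate_decoding
#' @param k_values Integer vector of ranks to evaluate.
#' @return Object of class \code{"pc_decoding_curve"}: \code{curve}
#'   (data frame with \code{k}, \code{median_cc}, \code{error_sd_pct}
#'   pooled over muscles) and \code{results} (one
#'   \code{"decoding_result"} per k).
#' @export
pc_projection_decoding <- function(population, emg, k_values,
                                   n_splits = 100L, seed = 1L) {
  stopifnot(inherits(population, "pseudo_population"),
            inherits(emg, "emg_set"), length(k_values) >= 1L)
  nc <- nrow(population$conditions)
  max_rank <- min(length(population$neuron_id),
                  population$n_trials * nc - nc)
  if (any(k_values > max_rank)) {
    warning("k values beyond rank ", max_rank, " capped")
    k_values <- pmin(k_values, max_rank)
  }
  k_values <- sort(unique(as.integer(k_values)))
  splits <- make_cv_splits(population$n_trials, nc, n_splits, seed = seed)
  nm <- length(emg$muscles)
  rngs <- apply(emg$mean_emg, 1L, function(v) diff(range(v)))
  results <- vector("list", length(k_values))
  names(results) <- as.character(k_values)
  acc <- lapply(k_values, function(k)
    list(cc = matrix(NA_real_, n_splits, nm,
                     dimnames = list(NULL, emg$muscles)),
         err = matrix(NA_real_, n_splits, nm), err_all = list()))
  names(acc) <- as.character(k_values)
  for (s in seq_len(n_splits)) {
    d <- .pop_design(population, splits[s, ])
    ctr <- colMeans(d$X_train)
    pc <- stats::prcomp(d$X_train, center = TRUE, scale. = FALSE)
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      R <- pc$rotation[, seq_len(k), drop = FALSE]
      Ztr <- sweep(d$X_train, 2L, ctr) %*% R
      Zte <- sweep(d$X_test, 2L, ctr) %*% R
      for (m in seq_len(nm)) {
        dec <- fit_linear_decoder(Ztr, emg$mean_emg[m, d$cond_train],
                                  "pinv")
        pred <- predict(dec, Zte)
        y_te <- emg$mean_emg[m, d$cond_test]
        acc[[ki]]$cc[s, m] <- if (stats::sd(pred) > 0)
          stats::cor(pred, y_te) else NA_real_
        e <- (pred - y_te) / rngs[m] * 100
        acc[[ki]]$err[s, m] <- stats::sd(e)
        acc[[ki]]$err_all[[length(acc[[ki]]$err_all) + 1L]] <- e
      }
    }
  }
  curve <- data.frame(k = k_values, median_cc = NA_real_,
                      error_sd_pct = NA_real_)
  for (ki in seq_along(k_values)) {
    a <- acc[[ki]]
    results[[ki]] <- structure(list(
      cc = a$cc, error_pct = a$err, n_nonzero = NULL, weights = NULL,
      median_cc = apply(a$cc, 2L, stats::median, na.rm = TRUE),
      n_missing_cc = colSums(is.na(a$cc)),
      error_sd_pct = vapply(seq_len(nm), function(m)
        stats::sd(a$err[, m], na.rm = TRUE), numeric(1L)),
      method = "pc_pinv", n_splits = n_splits, n_pcs = k_values[ki]
    ), class = "decoding_result")
    curve$median_cc[ki] <- stats::median(as.vector(a$cc), na.rm = TRUE)
    curve$error_sd_pct[ki] <- stats::sd(unlist(a$err_all), na.rm = TRUE)
  }
  structure(list(curve = curve, results = results),
            class = "pc_decoding_curve")
}

#' @export
print.pc_decoding_curve <- function(x, ...) {
  cat("decoding vs number of principal components\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Summary of LASSO neuron selection across splits
#'
#' For a LASSO decoding run with stored weights
#' (\code{\link{evaluate_decoding}} with \code{keep_weights = TRUE}),
#' reports which neurons the subset-selection decoder uses: the
#' per-muscle selection percentage per split, how many muscles each
#' neuron serves, and the pairwise correlations between muscle decoders'
#' weight vectors (averaged over splits, with a Bonferroni-corrected
#' significance filter).
#'
#' @param result A \code{"decoding_result"} with \code{weights}.
#' @param alpha Significance level of the weight-correlation filter
#'   (Bonferroni-corrected over muscle pairs; default 0.01).
#' @return List with \code{selection_freq} (neurons x muscles, fraction
#'   of splits with nonzero weight), \code{pct_selected_per_split}
#'   (splits x muscles, percent of neurons selected),
#'   \code{median_pct_selected} (per muscle),
#'   \code{n_muscles_per_neuron} (fraction of neurons ever-selected for
#'   exactly 1..n muscles), \code{weight_correlation} (muscles x
#'   muscles mean correlation, NA where not significant).
#' @export
subset_selection_summary <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "decoding_result"))
  if (is.null(result$weights))
    stop("run evaluate_decoding(..., keep_weights = TRUE) first")
  W <- result$weights
  ns <- length(W)
  muscles <- colnames(W[[1L]])
  nm <- length(muscles)
  nn <- nrow(W[[1L]])
  sel <- Reduce(`+`, lapply(W, function(w) (w != 0) * 1)) / ns
  pct <- t(vapply(W, function(w) colMeans(w != 0) * 100, numeric(nm)))
  colnames(pct) <- muscles
  ever <- sel > 0
  cnt <- rowSums(ever)
  nmus <- vapply(seq_len(nm), function(k) mean(cnt == k), numeric(1L))
  names(nmus) <- as.character(seq_len(nm))
  n_pairs <- nm * (nm - 1L) / 2L
  cors <- matrix(NA_real_, nm, nm, dimnames = list(muscles, muscles))
  for (a in seq_len(nm - 1L)) for (b in (a + 1L):nm) {
    r <- vapply(W, function(w) {
      if (stats::sd(w[, a]) == 0 || stats::sd(w[, b]) == 0)
        return(NA_real_)
      stats::cor(w[, a], w[, b])
    }, numeric(1L))
    r <- r[!is.na(r)]
    if (length(r) >= 2L) {
      # t.test refuses (near-)constant samples; a constant correlation
      # across splits is significant iff it is nonzero
      p <- tryCatch(stats::t.test(r)$p.value,
                    error = function(e) if (mean(r) == 0) 1 else 0)
      if (p < alpha / n_pairs)
        cors[a, b] <- cors[b, a] <- mean(r)
    }
  }
  list(selection_freq = sel, pct_selected_per_split = pct,
       median_pct_selected = apply(pct, 2L, stats::median),
       n_muscles_per_neuron = nmus, weight_correlation = cors)
}
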
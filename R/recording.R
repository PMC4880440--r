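#' Single-trial recordings and trial-averaged response functions
#'
#' A recording is a long-format data frame of single-trial firing rates,
#' one row per trial, with columns \code{neuron_id}, \code{target_index}
#' (0..26), \code{forearm_angle} ("pronation"/"supination"),
#' \code{trial_index} and \code{rate_hz} (mean rate over the 200 ms
#' analysis window, spikes/s).  \code{as_recording} validates the columns
#' and value ranges.
#'
#' @param x A data frame with the columns above.
#' @return The validated data frame, with class \code{"posture_recording"}
#'   prepended.
#' @export
as_recording <- function(x) {
  need <- c("neuron_id", "target_index", "forearm_angle", "trial_index",
            "rate_hz")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("a recording needs columns ", paste(need, collapse = ", "))
  if (nrow(x) == 0L) stop("empty recording")
  if (any(!is.finite(x$rate_hz)) || any(x$rate_hz < 0))
    stop("'rate_hz' must be nonnegative and finite")
  if (any(x$target_index < 0L | x$target_index > 26L))
    stop("'target_index' must be in 0..26")
  if (!all(x$forearm_angle %in% c("pronation", "supination")))
    stop("'forearm_angle' must be 'pronation' or 'supination'")
  if (!inherits(x, "posture_recording"))
    class(x) <- c("posture_recording", class(x))
  x
}

#' @export
print.posture_recording <- function(x, ...) {
  cat(sprintf("posture recording: %d neurons, %d trials, %d conditions\n",
              length(unique(x$neuron_id)), nrow(x),
              length(unique(condition_index(x$target_index,
                                            x$forearm_angle)))))
  invisible(x)
}

#' Trial-averaged response functions
#'
#' Averages single-trial rates within each of the 54 conditions, for every
#' neuron in a recording.  Conditions never visited by a neuron are
#' \code{NA}; conditions with a single trial get mean but an undefined
#' (\code{NA}) SEM.
#'
#' @param recording A recording (see \code{\link{as_recording}}).
#' @return An object of class \code{"response_set"}: a list with matrices
#'   \code{mean}, \code{sem} and \code{n_trials}, each neurons x 54 with
#'   rownames the neuron ids and columns in the ordering of
#'   \code{\link{condition_table}}.
#' @examples
#' rec <- as_recording(data.frame(
#'   neuron_id = "n1", target_index = 0, forearm_angle = "pronation",
#'   trial_index = 1:2, rate_hz = c(10, 14)))
#' r <- response_from_trials(rec)
#' r$mean[1, 1]  # 12
#' r$sem[1, 1]   # 2
#' @export
response_from_trials <- function(recording) {
  recording <- as_recording(recording)
  ids <- unique(recording$neuron_id)
  ci <- condition_index(recording$target_index, recording$forearm_angle)
  ri <- match(recording$neuron_id, ids)
  n  <- length(ids)
  cnt <- matrix(0L, n, 54L)
  s1  <- matrix(0, n, 54L)
  s2  <- matrix(0, n, 54L)
  idx <- cbind(ri, ci)
  for (k in seq_len(nrow(recording))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    cnt[i, j] <- cnt[i, j] + 1L
    s1[i, j] <- s1[i, j] + recording$rate_hz[k]
    s2[i, j] <- s2[i, j] + recording$rate_hz[k]^2
  }
  m <- ifelse(cnt > 0L, s1 / pmax(cnt, 1L), NA_real_)
  v <- (s2 - cnt * m^2) / pmax(cnt - 1L, 1L)
  v[v < 0] <- 0  # numerical guard
  sem <- ifelse(cnt >= 2L, sqrt(v / pmax(cnt, 1L)), NA_real_)
  sem[cnt == 0L] <- NA_real_
  dimnames(m) <- dimnames(sem) <- dimnames(cnt) <-
    list(as.character(ids), NULL)
  structure(list(mean = m, sem = sem, n_trials = cnt),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("response set: %d neurons x 54 conditions (%d complete)\n",
              nrow(x$mean), sum(rowSums(is.na(x$mean)) == 0L)))
  invisible(x)
}

# single-trial rates of one neuron as a list of per-condition vectors
trials_by_condition <- function(recording, neuron) {
  r <- recording[recording$neuron_id == neuron, , drop = FALSE]
  ci <- condition_index(r$target_index, r$forearm_angle)
  split(r$rate_hz, factor(ci, levels = 1:54))
}

#' Read and write recordings and EMG tables
#'
#' The on-disk format is plain CSV with the long-format recording columns,
#' and for EMG a table with columns \code{muscle}, \code{target_index},
#' \code{forearm_angle}, \code{mean_emg}.
#'
#' @param recording A recording data frame.
#' @param path File path.
#' @export
write_recording <- function(recording, path) {
  utils::write.csv(as.data.frame(unclass(as_recording(recording))), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  as_recording(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Mean-EMG container
#'
#' Mean EMG of the five recorded muscles over the 18 EMG conditions
#' (the 8 cube-corner targets plus the centre target, at both forearm
#' angles).
#'
#' @param mean_emg 5 x 18 numeric matrix (muscles x conditions), columns
#'   ordered as \code{emg_conditions()}.
#' @param muscles Character vector of 5 muscle names.
#' @return An object of class \code{"emg_set"} with elements
#'   \code{mean_emg}, \code{muscles}, \code{conditions} and
#'   \code{per_muscle_range} (2 x 5: min and max of each muscle's 18 means).
#' @export
emg_set <- function(mean_emg,
                    muscles = c("deltoid", "biceps", "triceps",
                                "flexor_carpi", "extensor_carpi")) {
  mean_emg <- as.matrix(mean_emg)
  if (!all(is.finite(mean_emg))) stop("'mean_emg' must be finite")
  if (nrow(mean_emg) != length(muscles) || ncol(mean_emg) != 18L)
    stop("'mean_emg' must be muscles x 18")
  rownames(mean_emg) <- muscles
  structure(list(
    mean_emg = mean_emg,
    muscles = muscles,
    conditions = emg_conditions(),
    per_muscle_range = apply(mean_emg, 1L, range)
  ), class = "emg_set")
}

#' @rdname emg_set
#' @export
emg_conditions <- function() {
  kt <- emg_key_targets()
  data.frame(
    target_index  = rep(kt, each = 2L),
    forearm_angle = rep(c("pronation", "supination"), length(kt)),
    condition     = condition_index(rep(kt, each = 2L),
                                    rep(c("pronation", "supination"),
                                        length(kt))),
    stringsAsFactors = FALSE
  )
}

# the 9 EMG targets: cube corners and centre, 0-based target indices
emg_key_targets <- function() c(0L, 2L, 6L, 8L, 13L, 18L, 20L, 24L, 26L)

#' @rdname write_recording
#' @param emg An \code{"emg_set"}.
#' @export
write_emg <- function(emg, path) {
  stopifnot(inherits(emg, "emg_set"))
  cond <- emg$conditions
  df <- data.frame(
    muscle        = rep(emg$muscles, each = nrow(cond)),
    target_index  = rep(cond$target_index, length(emg$muscles)),
    forearm_angle = rep(cond$forearm_angle, length(emg$muscles)),
    mean_emg      = as.vector(t(emg$mean_emg)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_emg <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  muscles <- unique(df$muscle)
  cond <- emg_conditions()
  m <- matrix(NA_real_, length(muscles), 18L)
  for (i in seq_along(muscles)) {
    d <- df[df$muscle == muscles[i], ]
    j <- match(condition_index(d$target_index, d$forearm_angle),
               cond$condition)
    m[i, j] <- d$mean_emg
  }
  emg_set(m, muscles)
}
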
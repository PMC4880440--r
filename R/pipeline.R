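#' Default pipeline configuration
#'
#' Settings for \code{\link{run_posture_pipeline}}.  Stage seeds are
#' derived from the master seed by the rule
#' \code{stage_seed = master_seed * 100 + stage_index} (stages indexed
#' in the order generate = 1, tuning = 2, pca = 3, interaction = 4,
#' decoding = 5, model = 6), keeping all seeds well below 2^31 for
#' master seeds up to 2e7.
#'
#' @param n_neurons Synthetic population size (default 150).
#' @param trials_per_condition Trials per condition (default 15, so the
#'   decoding stage has its full trial count).
#' @param n_model_neurons Model population size (default 200).
#' @param decoding_splits CV splits of the decoding stage (default 50).
#' @param decoding_method \code{"pinv"} or \code{"lasso"}.
#' @param n_boot Bootstrap count for interaction tests and PCA
#'   thresholds (default 100).
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("generate", "tuning", "pca", "interaction", "decoding",
#'   "model")}.  Later stages require \code{"generate"}.
#' @param distance_unit Units of the complexity measure.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n_neurons = 150L,
                            trials_per_condition = 15L,
                            n_model_neurons = 200L,
                            decoding_splits = 50L,
                            decoding_method = c("pinv", "lasso"),
                            n_boot = 100L,
                            stages = c("generate", "tuning", "pca",
                                       "interaction", "decoding",
                                       "model"),
                            distance_unit = c("cm", "step")) {
  decoding_method <- match.arg(decoding_method)
  distance_unit <- match.arg(distance_unit)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"generate" %in% stages)
    stop("the 'generate' stage is required")
  structure(as.list(environment()), class = "pipeline_config")
}

.write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

.write_manifest <- function(manifest, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA), path)
  } else {
    dump("manifest", file = path)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: generate a surrogate recording, fit
#' tuning curves and the complexity measure, run signal/noise PCA, the
#' forearm-angle interaction tests, EMG decoding, and the calibrated
#' network model, writing one CSV per result table plus a JSON manifest
#' into \code{out_dir}.  Given the same configuration and seed the
#' outputs are identical.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param grid Target grid.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.  On error, tables of completed stages remain in
#'   \code{out_dir}.
#' @export
run_posture_pipeline <- function(config = pipeline_config(),
                                 out_dir, seed = 1L,
                                 grid = make_target_grid()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- function(i) as.integer(seed) * 100L + i
  res <- list()
  manifest <- list(
    package = "posturenet",
    package_version = as.character(utils::packageVersion("posturenet")),
    r_version = as.character(getRversion()),
    master_seed = as.integer(seed),
    seed_rule = "stage_seed = master_seed * 100 + stage_index",
    stages = config$stages,
    parameters = config[setdiff(names(config), "stages")],
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )

  # stage 1: generate
  syn <- generate_recording(
    synthetic_config(n_neurons = config$n_neurons,
                     trials_per_condition = config$trials_per_condition,
                     seed = sseed(1L)), grid)
  write_recording(syn$recording, file.path(out_dir, "recording.csv"))
  emg <- generate_emg_set(grid, seed = sseed(1L))
  write_emg(emg$emg, file.path(out_dir, "emg.csv"))
  rs <- response_from_trials(syn$recording)
  res$recording <- syn; res$emg <- emg

  if ("tuning" %in% config$stages) {
    ids <- rownames(rs$mean)
    tun <- do.call(rbind, lapply(seq_along(ids), function(i) {
      m <- rs$mean[i, ]
      fp <- fit_linear_tuning(m[angle_columns("pronation")], grid,
                              "pronation")
      fs <- fit_linear_tuning(m[angle_columns("supination")], grid,
                              "supination")
      fe <- fit_extended_tuning(m, grid)
      cxp <- complexity_measure(m[angle_columns("pronation")], grid,
                                config$distance_unit)
      cxs <- complexity_measure(m[angle_columns("supination")], grid,
                                config$distance_unit)
      data.frame(neuron_id = ids[i],
                 r2_pronation = fp$r_squared,
                 r2_supination = fs$r_squared,
                 p_pronation = fp$f_pvalue,
                 p_supination = fs$f_pvalue,
                 r2_extended = fe$r_squared,
                 shift_coef = fe$coefficients[5L],
                 complexity = (cxp$value + cxs$value) / 2,
                 stringsAsFactors = FALSE)
    }))
    tun$coding <- coding_level(syn$recording)[tun$neuron_id]
    st <- screen_tuned(syn$recording)
    tun$tuned <- st$tuned[match(tun$neuron_id, st$neuron_id)]
    .write_table(tun, out_dir, "tuning")
    res$tuning <- tun
  }

  if ("pca" %in% config$stages) {
    nt <- extract_noise_traces(syn$recording,
                               n_resamples = max(2L,
                                 ceiling(config$n_boot / 4L)),
                               seed = sseed(3L))
    pcd <- pca_signal_noise(rs$mean, nt, n_boot = config$n_boot,
                            seed = sseed(3L))
    .write_table(data.frame(pc = seq_along(pcd$variances),
                            variance = pcd$variances,
                            prop_var = pcd$prop_var,
                            cumulative = cumsum(pcd$prop_var)),
                 out_dir, "pca_spectrum")
    .write_table(data.frame(strict_dim = pcd$strict_dim,
                            mean_dim = pcd$mean_dim,
                            strict_threshold = pcd$strict_threshold,
                            mean_threshold = pcd$mean_threshold),
                 out_dir, "pca_dims")
    res$pca <- pcd
  }

  if ("interaction" %in% config$stages) {
    sh <- baseline_shift_test(syn$recording, n_boot = config$n_boot,
                              seed = sseed(4L))
    ga <- gain_change_test(syn$recording, n_boot = config$n_boot,
                           seed = sseed(4L))
    pscc <- pronation_supination_correlations(rs$mean)
    boot <- correlation_controls(syn$recording, "bootstrap",
                                 seed = sseed(4L))
    shuf <- correlation_controls(syn$recording, "shuffle",
                                 seed = sseed(4L))
    .write_table(data.frame(
      statistic = c("shift_sd", "shift_noise_sd", "shift_p",
                    "gain_sd", "gain_noise_sd", "gain_p",
                    "cc_median", "cc_mean", "cc_sd",
                    "cc_bootstrap_median", "cc_shuffle_median"),
      value = c(sh$observed_sd, sh$control_sd, sh$p_value,
                ga$observed_sd, ga$control_sd, ga$p_value,
                pscc$median, pscc$mean, pscc$sd,
                stats::median(boot), stats::median(shuf))),
      out_dir, "interaction")
    .write_table(data.frame(neuron_id = names(pscc$r),
                            correlation = unname(pscc$r)),
                 out_dir, "correlations")
    res$interaction <- list(shift = sh, gain = ga, cc = pscc,
                            bootstrap = boot, shuffle = shuf)
  }

  if ("decoding" %in% config$stages) {
    pop <- build_pseudo_population(syn$recording,
                                   n_trials =
                                     config$trials_per_condition,
                                   seed = sseed(5L))
    dec <- evaluate_decoding(pop, emg$emg,
                             method = config$decoding_method,
                             n_splits = config$decoding_splits,
                             seed = sseed(5L))
    .write_table(data.frame(muscle = colnames(dec$cc),
                            median_cc = unname(dec$median_cc),
                            error_sd_pct = unname(dec$error_sd_pct)),
                 out_dir, "decoding")
    res$decoding <- dec
  }

  if ("model" %in% config$stages) {
    ref_cx <- complexity_distribution(rs$mean, grid,
                                      config$distance_unit)
    cal <- calibrate_width(mean(ref_cx), grid,
                           n_neurons = config$n_model_neurons,
                           distance_unit = config$distance_unit,
                           seed = sseed(6L))
    sim <- cal$simulation
    r2 <- .pooled_linear_r2(sim$rates, grid)
    mcc <- pronation_supination_correlations(sim$rates)
    mcx <- complexity_distribution(sim$rates, grid,
                                   config$distance_unit)
    .write_table(data.frame(
      statistic = c("width_cm", "threshold", "coding",
                    "complexity_target", "complexity_model",
                    "r2_mean", "r2_sd", "cc_mean", "cc_sd"),
      value = c(cal$width, cal$threshold_calibration$threshold,
                cal$threshold_calibration$achieved,
                cal$target, cal$achieved,
                mean(r2), stats::sd(r2), mcc$mean, mcc$sd)),
      out_dir, "model")
    .write_table(data.frame(r_squared = r2), out_dir, "model_r2")
    .write_table(data.frame(neuron = seq_along(mcc$r),
                            correlation = unname(mcc$r)),
                 out_dir, "model_correlations")
    .write_table(data.frame(complexity = mcx), out_dir,
                 "model_complexity")
    res$model <- cal
  }

  .write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(results = res, manifest = manifest,
                 out_dir = out_dir))
}

#' Export report figures from a pipeline run directory
#'
#' Renders the standard report panels (R-squared histogram, complexity
#' distribution, PCA spectrum, correlation histogram, decoding summary,
#' model-vs-data R-squared overlay) as PDF figures from the CSV tables
#' a pipeline run wrote.  Panels whose tables are missing are skipped
#' with a notice; every figure's underlying numbers already exist as
#' CSV in the run directory.
#'
#' @param run_dir A directory written by
#'   \code{\link{run_posture_pipeline}}.
#' @param format \code{"pdf"} (default) or \code{"png"}.
#' @return Invisibly, the paths of the figures written.
#' @export
export_report <- function(run_dir, format = c("pdf", "png")) {
  format <- match.arg(format)
  stopifnot(dir.exists(run_dir))
  written <- character(0L)
  dev_open <- function(name) {
    path <- file.path(run_dir, paste0(name, ".", format))
    if (format == "pdf") grDevices::pdf(path, width = 6, height = 4.5)
    else grDevices::png(path, width = 720, height = 540)
    path
  }
  panel <- function(table, name, fun) {
    f <- file.path(run_dir, paste0(table, ".csv"))
    if (!file.exists(f)) {
      message("panel '", name, "' skipped: missing ", basename(f))
      return(invisible(NULL))
    }
    df <- utils::read.csv(f)
    p <- dev_open(name)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun(df)
    written <<- c(written, p)
  }
  panel("tuning", "r2_histogram", function(df) {
    graphics::hist(c(df$r2_pronation, df$r2_supination), breaks = 20,
                   main = "Linear tuning fits", xlab = "R squared")
  })
  panel("tuning", "complexity_histogram", function(df) {
    graphics::hist(df$complexity, breaks = 20,
                   main = "Complexity measure", xlab = "complexity")
  })
  panel("pca_spectrum", "pca_spectrum", function(df) {
    graphics::plot(df$pc, df$variance, log = "y", pch = 19,
                   main = "PCA spectrum", xlab = "PC",
                   ylab = "variance")
  })
  panel("correlations", "correlation_histogram", function(df) {
    graphics::hist(df$correlation, breaks = seq(-1, 1, by = 0.1),
                   main = "Pronation/supination correlations",
                   xlab = "Pearson r")
  })
  panel("decoding", "decoding_summary", function(df) {
    graphics::barplot(df$median_cc, names.arg = df$muscle,
                      main = "Decoding", ylab = "median CC",
                      las = 2)
  })
  panel("model_r2", "model_r2_histogram", function(df) {
    graphics::hist(df$r_squared, breaks = 20,
                   main = "Model linear tuning fits",
                   xlab = "R squared")
  })
  invisible(written)
}
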
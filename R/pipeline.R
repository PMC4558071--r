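#' Pipeline configuration
#'
#' All thresholds and analysis choices of [run_pipeline()] in one place.
#' Unknown options are rejected. The defaults reproduce the standard
#' analysis: 11 ms Hanning position smoothing, 30 deg/s onset threshold,
#' 50 ms blink margins, divisive baseline normalization, the
#' anticipation/late/peak/deviation exclusion rules, no position-artifact
#' correction, and a condition-by-axis mixed-model sweep with the
#' |t| > 2 for >= 200 ms reliability rule.
#'
#' @param smooth_window_ms Hanning window for position smoothing, ms.
#' @param onset_threshold Saccade-onset velocity threshold, deg/s.
#' @param peak_mode Peak-velocity definition, `"component"` or `"norm"`
#'   (see [peak_velocity()]).
#' @param blink_margin_ms,max_blink_ms Blink reconstruction parameters
#'   (see [reconstruct_blinks()]).
#' @param normalization `"divisive"` or `"subtractive"`
#'   (see [epoch_and_normalize()]).
#' @param max_latency,max_peak,max_deviation,flight_halfwindow Exclusion
#'   thresholds (see [part2_exclude()]).
#' @param correct_position_artifacts Apply
#'   [position_artifact_regression()]? Off by default: gaze angle also has a
#'   real effect on pupil size, so the regression is not a safe correction.
#' @param theta Stabilization threshold, deg/s
#'   (see [stabilization_profile()]).
#' @param fixed,decimate,threshold,min_run_ms,sided Sweep settings
#'   (see [lme_sweep()]).
#' @param run_sweep Fit the mixed-model sweep? (Disable to stop after
#'   epoching.)
#' @return An object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(smooth_window_ms = 11,
                            onset_threshold = 30,
                            peak_mode = "component",
                            blink_margin_ms = 50,
                            max_blink_ms = 500,
                            normalization = "divisive",
                            max_latency = 2000,
                            max_peak = 1000,
                            max_deviation = 3.3,
                            flight_halfwindow = 100,
                            correct_position_artifacts = FALSE,
                            theta = 50,
                            fixed = ~ condition * axis,
                            decimate = 1,
                            threshold = 2,
                            min_run_ms = 200,
                            sided = "two",
                            run_sweep = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages in order: simulate (or accept) trials, smooth
#' position, estimate velocities, detect the saccade and its landmarks,
#' apply the exclusion rules, reconstruct blinks, epoch and
#' baseline-normalize the pupil signal around the mid-saccade point, compute
#' per-trial stabilization metrics, and (optionally) fit the sample-wise
#' mixed-model sweep. Deterministic given input, config and seed.
#'
#' @param input A [sim_config()] (a synthetic experiment is generated with
#'   `seed`), a `sim_experiment`, or a list of trials as returned by
#'   [read_samples()].
#' @param config A [pipeline_config()].
#' @param seed RNG seed used when `input` is a [sim_config()].
#' @return A list of class `pipeline_result` with elements
#'   \describe{
#'     \item{trials_df}{per-trial metrics for kept, epoched trials
#'       (latency, peak velocity, orthogonal peak, grating speed,
#'       peak-velocity error, stabilization minimum and percept-window
#'       duration);}
#'     \item{epochs}{list of [epoched_pupil] objects;}
#'     \item{epochs_df}{the same epochs in long format (see
#'       [write_epochs()]), with an `axis` column;}
#'     \item{report}{the [exclusion_report()];}
#'     \item{sweep}{the [lme_sweep()] result (or `NULL`);}
#'     \item{n_epoch_rejected}{epochs dropped for a fully masked baseline;}
#'     \item{calibration}{the simulator's calibration table, if available;}
#'     \item{config, seed}{the resolved configuration.}
#'   }
#' @export
run_pipeline <- function(input, config = pipeline_config(), seed = 1) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config()")
  calibration <- NULL
  if (inherits(input, "sim_config")) {
    input <- simulate_experiment(input, seed)
  }
  if (inherits(input, "sim_experiment")) {
    calibration <- input$calibration
    trials <- input$trials
  } else trials <- input
  if (!length(trials)) stop("no trials in input")

  # stage 1-2: smoothing, velocity, saccade detection
  events <- vector("list", length(trials))
  vels <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- tryCatch({
      trials[[i]]$trace <- smooth_position(trials[[i]]$trace,
                                           config$smooth_window_ms)
      vels[[i]] <- compute_velocity(trials[[i]]$trace)
      ev <- detect_saccade(trials[[i]]$trace, trials[[i]]$meta,
                           config$onset_threshold, vel = vels[[i]])
      ev$peak_velocity <- peak_velocity(vels[[i]], config$peak_mode)
      events[[i]] <- ev
      NULL
    }, error = function(e)
      stop("saccade-detection stage failed on trial ",
           trials[[i]]$meta$trial, ": ", conditionMessage(e)))
  }

  # stage 3: exclusion rules
  report <- exclusion_report(trials, events,
                             max_latency = config$max_latency,
                             max_peak = config$max_peak,
                             max_deviation = config$max_deviation,
                             flight_halfwindow = config$flight_halfwindow)
  kept <- which(report$keep)

  # stage 4: blink reconstruction + epoching; stage 5: stabilization metrics
  epochs <- list()
  rows <- list()
  n_rejected <- 0L
  for (i in kept) {
    meta <- trials[[i]]$meta
    ev <- events[[i]]
    trace <- trials[[i]]$trace
    trace$p <- reconstruct_blinks(trace$p, config$blink_margin_ms,
                                  config$max_blink_ms)
    ep <- tryCatch(
      epoch_and_normalize(trace, ev$mid_saccade_t, meta,
                          normalization = config$normalization),
      pupilsweep_epoch_rejected = function(e) NULL)
    if (is.null(ep)) { n_rejected <- n_rejected + 1L; next }
    epochs[[length(epochs) + 1L]] <- ep
    speed <- pv_err <- s_min <- win <- NA_real_
    if (!is.na(meta$spatial_frequency)) {
      stim <- grating_stimulus(orientation_for(meta$direction, meta$condition),
                               meta$spatial_frequency)
      speed <- motion_interpretations(stim)$speed[1]
      pv_err <- as.numeric(peak_velocity_error(ev$peak_velocity, speed))
      prof <- stabilization_profile(vels[[i]], stim, config$theta)
      s_min <- min(prof$s, na.rm = TRUE)
      win <- if (is.null(prof$percept_window)) 0
             else diff(prof$percept_window) + 1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      participant = meta$participant, trial = meta$trial,
      direction = meta$direction, axis = ev$axis, condition = meta$condition,
      latency = ev$latency, peak_velocity = ev$peak_velocity,
      peak_orthogonal_velocity = ev$peak_orthogonal_velocity,
      grating_speed = speed, peak_velocity_error = pv_err,
      min_stabilization = s_min, percept_window_ms = win)
  }
  if (!length(epochs)) stop("no trials survived exclusion and epoching")
  trials_df <- do.call(rbind, rows)

  if (config$correct_position_artifacts) {
    fix_xy <- do.call(rbind, lapply(epochs, function(e)
      c(e$meta$fixation_pos[1], e$meta$fixation_pos[2])))
    baseline_df <- data.frame(
      participant = vapply(epochs, function(e) e$meta$participant, ""),
      baseline = vapply(epochs, function(e) e$baseline, 0),
      x = fix_xy[, 1], y = fix_xy[, 2])
    epochs <- position_artifact_regression(baseline_df, epochs)$epochs
  }

  epochs_df <- epochs_to_df(epochs)

  sweep <- NULL
  if (config$run_sweep)
    sweep <- lme_sweep(epochs_df, fixed = config$fixed,
                       decimate = config$decimate,
                       threshold = config$threshold,
                       min_run_ms = config$min_run_ms, sided = config$sided)

  structure(list(trials_df = trials_df, epochs = epochs,
                 epochs_df = epochs_df, report = report, sweep = sweep,
                 n_epoch_rejected = n_rejected, calibration = calibration,
                 config = config, seed = seed),
            class = "pipeline_result")
}

#' Convert a list of epochs to the long analysis format
#'
#' @param epochs List of [epoched_pupil] objects on a common grid.
#' @return Long data frame: `participant`, `trial`, `condition`,
#'   `direction`, `axis`, `t_ms`, `pupil`.
#' @export
epochs_to_df <- function(epochs) {
  n_t <- length(epochs[[1]]$time)
  one <- function(get) vapply(epochs, get, "")
  data.frame(
    participant = rep(one(function(e) e$meta$participant), each = n_t),
    trial = rep(vapply(epochs, function(e) e$meta$trial, 0L), each = n_t),
    condition = rep(one(function(e) e$meta$condition), each = n_t),
    direction = rep(one(function(e) e$meta$direction), each = n_t),
    axis = rep(direction_axis(one(function(e) e$meta$direction)), each = n_t),
    t_ms = rep(epochs[[1]]$time, length(epochs)),
    pupil = unlist(lapply(epochs, function(e) e$value), use.names = FALSE))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d trials in, %d epoched (%.1f%% retained), %d rejected at baseline\n",
              nrow(x$report), length(x$epochs),
              100 * length(x$epochs) / nrow(x$report), x$n_epoch_rejected))
  if (!is.null(x$sweep)) print(x$sweep)
  invisible(x)
}
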
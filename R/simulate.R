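#' Configuration of the synthetic experiment generator
#'
#' Defaults emulate a cued-saccade pupillometry session: ten participants,
#' 17 degree saccades in four directions with main-sequence-plausible peak
#' velocities around 400 deg/s (more variable for vertical than horizontal
#' saccades), stronger curvature (orthogonal velocity) for vertical saccades,
#' pupil traces with pre-saccadic dilation and post-saccadic constriction
#' from about 220 ms after the mid-saccade point, an extra constriction
#' emerging about 300 ms after the mid-saccade point whose amplitude scales
#' with the retinal stabilization the trial actually achieves, blinks,
#' measurement noise, and eye-position-dependent pupil-size artifacts.
#'
#' Amplitude-like pupil parameters are in ratio units (fractions of the
#' participant's baseline area); velocities in deg/s; times in ms.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per direction x condition cell.
#' @param amplitude Saccade amplitude in degrees (eccentric dots at
#'   +/- amplitude/2).
#' @param peak_mean Mean peak velocity, deg/s.
#' @param peak_sd_horizontal,peak_sd_vertical Trial-to-trial SD of peak
#'   velocity per axis; the vertical SD exceeds the horizontal one, and the
#'   horizontal value keeps about 95 percent of horizontal trials inside the
#'   220-664 deg/s calibration validity band.
#' @param participant_peak_sd Between-participant SD of mean peak velocity.
#' @param curvature_mean_horizontal,curvature_sd_horizontal Peak orthogonal
#'   velocity of horizontal saccades (mean, SD), deg/s.
#' @param curvature_mean_vertical,curvature_sd_vertical Same for vertical
#'   saccades; vertical saccades are more curved, often approaching
#'   150 deg/s.
#' @param latency_mean,latency_sd Saccade latency distribution, ms (clipped
#'   to 60-450).
#' @param cue_onset Auditory-cue onset on the trial clock, ms.
#' @param trial_ms Trial duration, ms.
#' @param gaze_noise_sd Gaze position noise SD, degrees.
#' @param baseline_mean,baseline_sd Between-participant pupil baseline area,
#'   a.u.
#' @param dilation_amp Pre/peri-saccadic dilation amplitude (ratio units),
#'   impulse at the cue.
#' @param constriction_amp Post-saccadic constriction amplitude (ratio
#'   units), impulse `constriction_onset` ms after the mid-saccade point.
#' @param constriction_onset Constriction onset delay after the mid-saccade
#'   point, ms.
#' @param condition_effect Amplitude (ratio units) of the extra constriction
#'   driven by the intrasaccadic percept, at full retinal stabilization.
#' @param condition_onset Its onset delay after the mid-saccade point, ms.
#' @param condition_effect_participant_sd Between-participant SD of the
#'   multiplicative percept-response gain (gain ~ Normal(1, sd)).
#' @param kernel_tau,kernel_shape Erlang pupil response kernel: time constant
#'   (ms) and shape; the kernel peaks at `(shape - 1) * kernel_tau` ms.
#' @param noise_sd White measurement noise on normalized pupil (ratio units).
#' @param slow_noise_sd Slow pupil noise (ratio units), smooth with ~25 ms
#'   knots.
#' @param blink_rate Expected blinks per trial (Poisson).
#' @param blink_dur_mean,blink_dur_sd Blink duration, ms (clipped to 60-300).
#' @param artifact_slope_x,artifact_slope_y Position-artifact slopes,
#'   a.u. per degree of gaze.
#' @param frame_rate Display frame rate, Hz.
#' @param n_part1_trials Calibration trials drawn per participant x
#'   direction.
#' @param part1_n_required Valid calibration trials required for the median.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_participants = 10,
                       trials_per_cell = 10,
                       amplitude = 17,
                       peak_mean = 400,
                       peak_sd_horizontal = 100,
                       peak_sd_vertical = 150,
                       participant_peak_sd = 25,
                       curvature_mean_horizontal = 25,
                       curvature_sd_horizontal = 10,
                       curvature_mean_vertical = 100,
                       curvature_sd_vertical = 30,
                       latency_mean = 150,
                       latency_sd = 40,
                       cue_onset = 300,
                       trial_ms = 2100,
                       gaze_noise_sd = 0.05,
                       baseline_mean = 1200,
                       baseline_sd = 100,
                       dilation_amp = 0.05,
                       constriction_amp = 0.15,
                       constriction_onset = 220,
                       condition_effect = 0.04,
                       condition_onset = 300,
                       condition_effect_participant_sd = 0.2,
                       kernel_tau = 150,
                       kernel_shape = 3,
                       noise_sd = 0.01,
                       slow_noise_sd = 0.01,
                       blink_rate = 0.3,
                       blink_dur_mean = 120,
                       blink_dur_sd = 30,
                       artifact_slope_x = 2,
                       artifact_slope_y = 4,
                       frame_rate = 150,
                       n_part1_trials = 50,
                       part1_n_required = 40) {
  cfg <- as.list(environment())
  amps <- c(cfg$amplitude, cfg$dilation_amp, cfg$constriction_amp,
            cfg$condition_effect, cfg$noise_sd, cfg$slow_noise_sd,
            cfg$blink_rate)
  if (any(amps < 0)) stop("amplitudes, noise SDs and rates must be >= 0")
  stopifnot(cfg$peak_mean > 0, cfg$trial_ms > cfg$cue_onset + 600)
  structure(cfg, class = "sim_config")
}

# Erlang-family pupil response kernel, normalized to peak 1 at (shape-1)*tau
pupil_kernel <- function(t, tau = 150, shape = 3) {
  tp <- (shape - 1) * tau
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tp)^(shape - 1) * exp((shape - 1) - t[pos] / tau)
  out
}

#' Simulate one saccade's gaze segment
#'
#' The along-axis velocity is a raised-cosine pulse whose duration is set so
#' the displacement integrates to `amplitude` and the maximum equals
#' `peak_velocity` (duration = 2 * amplitude / peak_velocity); the orthogonal
#' velocity is a zero-integral biphasic (single-cycle sine) pulse with peak
#' `curvature`. Sampled at 1000 Hz; velocities are evaluated at sample
#' midpoints so the discrete displacement integral is exact.
#'
#' @param amplitude Saccade amplitude, degrees (> 0).
#' @param direction `"left"`, `"right"`, `"up"` or `"down"`.
#' @param peak_velocity Peak along-axis velocity, deg/s (> 0).
#' @param curvature Peak orthogonal velocity, deg/s (>= 0).
#' @return List with `duration_ms` and `dx`, `dy`: per-ms displacement
#'   increments (degrees) over the saccade.
#' @export
simulate_saccade <- function(amplitude, direction, peak_velocity,
                             curvature = 0) {
  stopifnot(amplitude > 0, peak_velocity > 0, curvature >= 0)
  dur <- round(2 * amplitude / peak_velocity * 1000)
  if (dur < 10)
    stop("kinematically impossible saccade: duration ", dur, " ms < 10 ms")
  tau <- (seq_len(dur) - 0.5) / dur
  v_along <- peak_velocity * (1 - cos(2 * pi * tau)) / 2   # deg/s
  v_orth <- curvature * sin(2 * pi * tau)
  d_along <- v_along / 1000                                # deg per 1 ms step
  d_orth <- v_orth / 1000
  sgn <- switch(direction, right = 1, left = -1, up = 1, down = -1)
  if (direction %in% c("left", "right"))
    list(duration_ms = dur, dx = sgn * d_along, dy = d_orth)
  else
    list(duration_ms = dur, dx = d_orth, dy = sgn * d_along)
}

#' Simulate one trial's pupil series
#'
#' Baseline plus smooth unimodal response components (impulse at onset
#' convolved with the Erlang kernel): a positive dilation at the cue, a
#' negative post-saccadic constriction starting `constriction_onset` ms after
#' the mid-saccade point, and a percept-driven extra constriction starting
#' `condition_onset` ms after the mid-saccade point whose amplitude is
#' `condition_effect * percept_gain` (see [percept_gain()]). Gaussian white
#' and slow noise are added, plus a position-artifact term proportional to
#' simulated gaze position; blinks are masked gaps.
#'
#' @param t Trial time grid, ms.
#' @param cue_onset,mid_t Cue onset and mid-saccade time, ms.
#' @param baseline Participant baseline pupil area, a.u.
#' @param gain Percept gain in `[0, 1]` for this trial.
#' @param effect_mult Participant's multiplicative percept-response gain.
#' @param x,y Simulated gaze position (for the artifact term), degrees.
#' @param cfg A [sim_config()].
#' @return Pupil series in a.u. (`NA` during blinks).
#' @export
simulate_pupil <- function(t, cue_onset, mid_t, baseline, gain, effect_mult,
                           x, y, cfg) {
  n <- length(t)
  ratio <- 1 +
    cfg$dilation_amp * pupil_kernel(t - cue_onset, cfg$kernel_tau, cfg$kernel_shape) -
    cfg$constriction_amp *
      pupil_kernel(t - (mid_t + cfg$constriction_onset), cfg$kernel_tau, cfg$kernel_shape) -
    cfg$condition_effect * gain * effect_mult *
      pupil_kernel(t - (mid_t + cfg$condition_onset), cfg$kernel_tau, cfg$kernel_shape)
  if (cfg$noise_sd > 0) ratio <- ratio + stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$slow_noise_sd > 0) {
    knots <- seq(t[1] - 25, t[n] + 25, by = 25)
    ratio <- ratio + stats::spline(knots, stats::rnorm(length(knots), 0, cfg$slow_noise_sd),
                                   xout = t)$y
  }
  p <- baseline * ratio + cfg$artifact_slope_x * x + cfg$artifact_slope_y * y
  n_blinks <- stats::rpois(1, cfg$blink_rate)
  if (n_blinks > 0) for (b in seq_len(n_blinks)) {
    dur <- round(min(300, max(60, stats::rnorm(1, cfg$blink_dur_mean, cfg$blink_dur_sd))))
    start <- sample.int(n - dur - 1L, 1)
    p[start:(start + dur)] <- NA_real_
  }
  p
}

#' Percept gain of one trial under the retinal-stabilization account
#'
#' The fraction by which the saccade reduces the retinal speed of the better
#' matched motion interpretation, relative to fixation:
#' `max(0, 1 - s_min / speed)`, where `speed` is the grating's motion speed
#' and `s_min` the minimal retinal speed reached. In the percept geometry
#' `s_min = |peak_velocity - speed|`; in the no-percept geometry only the
#' orthogonal (curvature) component acts along the motion axis, so
#' `s_min = speed - min(curvature, speed)` and the gain is
#' `min(curvature, speed) / speed` — zero for straight saccades, substantial
#' for strongly curved ones (partial stabilization).
#'
#' @param condition `"intrasaccadic_percept"` or `"no_percept"`.
#' @param peak_velocity Trial peak velocity, deg/s.
#' @param curvature Trial peak orthogonal velocity, deg/s.
#' @param speed Grating motion speed, deg/s.
#' @return Gain in `[0, 1]`.
#' @export
percept_gain <- function(condition, peak_velocity, curvature, speed) {
  if (condition == "intrasaccadic_percept")
    max(0, 1 - abs(peak_velocity - speed) / speed)
  else
    min(curvature, speed) / speed
}

#' Simulate a complete experiment
#'
#' Generates, per participant: a calibration phase (peak-velocity draws per
#' direction, validated against the 220-664 deg/s band, median via
#' [part1_peak_estimate()], grating spatial frequency via
#' [ideal_spatial_frequency()]), then `trials_per_cell` trials for every
#' direction x condition cell with simulated saccades ([simulate_saccade()])
#' and pupil traces ([simulate_pupil()]). Deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `sim_experiment`: list with `trials` (each
#'   `list(meta, trace, truth)`), `calibration` (data frame: participant,
#'   direction, median peak, spatial frequency, grating speed), `config`,
#'   `seed`.
#' @export
simulate_experiment <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  directions <- c("left", "right", "up", "down")
  conditions <- c("intrasaccadic_percept", "no_percept")
  trials <- list()
  calib <- list()
  trial_id <- 0L
  t_grid <- 0:(cfg$trial_ms - 1L)
  for (i in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", i)
    p_offset <- stats::rnorm(1, 0, cfg$participant_peak_sd)
    p_baseline <- max(800, stats::rnorm(1, cfg$baseline_mean, cfg$baseline_sd))
    p_mult <- stats::rnorm(1, 1, cfg$condition_effect_participant_sd)
    for (dir in directions) {
      axis <- direction_axis(dir)
      sd_axis <- if (axis == "horizontal") cfg$peak_sd_horizontal else cfg$peak_sd_vertical
      # invalid calibration trials are discarded and repeated later in the
      # session, so draw until enough valid ones have accumulated
      part1_peaks <- stats::rnorm(cfg$n_part1_trials, cfg$peak_mean + p_offset, sd_axis)
      while (sum(part1_peak_validity(part1_peaks)) < cfg$part1_n_required)
        part1_peaks <- c(part1_peaks,
                         stats::rnorm(5, cfg$peak_mean + p_offset, sd_axis))
      med <- part1_peak_estimate(part1_peaks, cfg$part1_n_required)
      sf <- ideal_spatial_frequency(med, cfg$frame_rate)
      speed <- cfg$frame_rate / (2 * sf)
      calib[[length(calib) + 1L]] <-
        data.frame(participant = pid, direction = dir, median_peak = med,
                   spatial_frequency = sf, grating_speed = speed)
      cm <- if (axis == "horizontal") cfg$curvature_mean_horizontal else cfg$curvature_mean_vertical
      cs <- if (axis == "horizontal") cfg$curvature_sd_horizontal else cfg$curvature_sd_vertical
      half <- cfg$amplitude / 2
      fix <- switch(dir, left = c(half, 0), right = c(-half, 0),
                    up = c(0, -half), down = c(0, half))
      for (cond in conditions) {
        for (k in seq_len(cfg$trials_per_cell)) {
          trial_id <- trial_id + 1L
          pv <- max(120, stats::rnorm(1, cfg$peak_mean + p_offset, sd_axis))
          curv <- abs(stats::rnorm(1, cm, cs))
          lat <- round(min(450, max(60, stats::rnorm(1, cfg$latency_mean, cfg$latency_sd))))
          sac <- simulate_saccade(cfg$amplitude, dir, pv, curv)
          onset <- cfg$cue_onset + lat
          mid_t <- onset + round(sac$duration_ms / 2)
          x <- rep(fix[1], cfg$trial_ms)
          y <- rep(fix[2], cfg$trial_ms)
          sl <- onset + seq_len(sac$duration_ms)
          x[sl] <- fix[1] + cumsum(sac$dx)
          y[sl] <- fix[2] + cumsum(sac$dy)
          if (max(sl) < cfg$trial_ms) {
            x[(max(sl) + 1L):cfg$trial_ms] <- x[max(sl)]
            y[(max(sl) + 1L):cfg$trial_ms] <- y[max(sl)]
          }
          if (cfg$gaze_noise_sd > 0) {
            x <- x + stats::rnorm(cfg$trial_ms, 0, cfg$gaze_noise_sd)
            y <- y + stats::rnorm(cfg$trial_ms, 0, cfg$gaze_noise_sd)
          }
          gain <- percept_gain(cond, pv, curv, speed)
          p <- simulate_pupil(t_grid, cfg$cue_onset, mid_t, p_baseline,
                              gain, p_mult, x, y, cfg)
          meta <- trial_meta(participant = pid, trial = trial_id,
                             direction = dir, condition = cond,
                             cue_onset = cfg$cue_onset,
                             fixation_pos = fix, target_pos = -fix,
                             spatial_frequency = sf)
          trials[[trial_id]] <- list(
            meta = meta,
            trace = gaze_trace(t_grid, x, y, p),
            truth = list(peak_velocity = pv, curvature = curv,
                         latency = lat, mid_t = mid_t, gain = gain))
        }
      }
    }
  }
  structure(list(trials = trials, calibration = do.call(rbind, calib),
                 config = cfg, seed = seed),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d trials, %d participants, seed %d\n",
              length(x$trials), x$config$n_participants, x$seed))
  invisible(x)
}
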
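#' Unit-sum Hanning window
#'
#' Hanning (raised-cosine) window of `n` samples, normalized to sum to 1 so
#' that convolution preserves the mean level of the signal.
#'
#' @param n Window length in samples (>= 3; ends of the window are zero).
#' @return Numeric vector of length `n` summing to 1.
#' @export
hanning_weights <- function(n) {
  if (n < 3) stop("Hanning window needs n >= 3")
  w <- as.numeric(signal::hanning(n))
  w / sum(w)
}

# convolve with reflection padding; NA samples poison their neighbourhood,
# which is the conservative choice for velocity estimation
convolve_reflect <- function(v, w) {
  h <- (length(w) - 1L) %/% 2L
  n <- length(v)
  padded <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  out <- stats::filter(padded, w, method = "convolution", sides = 2L)
  as.numeric(out[(h + 1L):(h + n)])
}

#' Smooth gaze position with a Hanning window
#'
#' Position smoothing applied before velocity estimation to keep noise in the
#' velocity profiles acceptable. Each coordinate is convolved with a unit-sum
#' Hanning window; edges are handled by reflection, so constants pass through
#' unchanged. The pupil channel is never smoothed.
#'
#' @param trace A [gaze_trace()].
#' @param window_ms Window length in ms (odd; default 11, i.e. 11 samples at
#'   1000 Hz).
#' @return A [gaze_trace()] with smoothed `x` and `y`.
#' @export
smooth_position <- function(trace, window_ms = 11) {
  n_w <- as.integer(window_ms)          # 1 kHz: 1 sample per ms
  if (n_w %% 2L == 0L) stop("window_ms must be an odd number of 1 ms samples")
  if (n_w > length(trace$t)) stop("smoothing window longer than trace")
  w <- hanning_weights(n_w)
  trace$x <- convolve_reflect(trace$x, w)
  trace$y <- convolve_reflect(trace$y, w)
  trace
}

#' Per-axis eye velocity
#'
#' Central finite differences on the (smoothed) position signal, scaled to
#' degrees per second; the first and last samples use one-sided differences.
#'
#' @param trace A [gaze_trace()], normally smoothed with [smooth_position()].
#' @return A list with `t` (ms), `vx`, `vy` (deg/s); `NA` where position is
#'   missing.
#' @export
compute_velocity <- function(trace) {
  n <- length(trace$t)
  if (n < 3) stop("need at least 3 samples for velocity estimation")
  if (any(diff(trace$t) != 1)) stop("non-uniform sampling; expected 1 ms grid")
  d <- function(v) {
    out <- numeric(n)
    out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    out[1] <- v[2] - v[1]
    out[n] <- v[n] - v[n - 1]
    out * 1000  # deg per ms -> deg per s
  }
  list(t = trace$t, vx = d(trace$x), vy = d(trace$y))
}

#' Peak saccade velocity of a trial
#'
#' The highest speed of the eyes at any moment in the trial. With
#' `mode = "component"` (the default) this is the maximum over time of the
#' larger of the absolute horizontal and vertical velocities, i.e. the maximum
#' of the peaks of the two per-axis velocity profiles. `mode = "norm"` uses
#' the Euclidean speed `sqrt(vx^2 + vy^2)` instead; the two agree on straight
#' saccades and differ by at most sqrt(2) on curved ones.
#'
#' @param vel Velocity list from [compute_velocity()].
#' @param mode `"component"` or `"norm"`.
#' @return Peak velocity in deg/s, or `NA` if it cannot be determined (all
#'   samples missing).
#' @export
peak_velocity <- function(vel, mode = c("component", "norm")) {
  mode <- match.arg(mode)
  s <- if (mode == "component") pmax(abs(vel$vx), abs(vel$vy))
       else sqrt(vel$vx^2 + vel$vy^2)
  s <- s[!is.na(s)]
  if (!length(s)) return(NA_real_)   # undeterminable
  max(s)
}

#' Peak orthogonal velocity
#'
#' Maximum absolute eye velocity perpendicular to the saccade direction:
#' vertical velocity for horizontal saccades, horizontal velocity for vertical
#' saccades. Nonzero orthogonal velocity reflects saccade curvature.
#'
#' @param vel Velocity list from [compute_velocity()].
#' @param axis Saccade axis, `"horizontal"` or `"vertical"`.
#' @return Peak orthogonal velocity in deg/s, or `NA` if undeterminable.
#' @export
orthogonal_velocity <- function(vel, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  v <- if (axis == "horizontal") vel$vy else vel$vx
  v <- abs(v[!is.na(v)])
  if (!length(v)) return(NA_real_)
  max(v)
}

#' Detect the saccade and its landmarks
#'
#' Finds the mid-saccade point — the first moment after the cue at which the
#' along-axis gaze coordinate crosses the meridian (0 deg) moving toward the
#' target — by linear interpolation between samples, rounded to the 1 ms
#' grid. The saccade onset is the last time before the mid-saccade point at
#' which the along-axis absolute velocity rises through `onset_threshold`;
#' latency is onset minus cue onset and may be negative (anticipatory
#' saccades).
#'
#' @param trace A smoothed [gaze_trace()].
#' @param meta A [trial_meta()]; fixation and target must lie on opposite
#'   sides of the relevant meridian.
#' @param onset_threshold Velocity threshold in deg/s for onset detection
#'   (default 30).
#' @param vel Optional precomputed [compute_velocity()] result for `trace`.
#' @return An object of class `saccade_event`: list with `onset`,
#'   `mid_saccade_t`, `latency` (ms), `peak_velocity`,
#'   `peak_orthogonal_velocity` (deg/s), `axis`.
#' @export
detect_saccade <- function(trace, meta, onset_threshold = 30, vel = NULL) {
  axis <- direction_axis(meta$direction)
  along <- if (axis == "horizontal") trace$x else trace$y
  tgt <- if (axis == "horizontal") meta$target_pos[1] else meta$target_pos[2]
  fix <- if (axis == "horizontal") meta$fixation_pos[1] else meta$fixation_pos[2]
  if (sign(tgt) == sign(fix) || tgt == 0)
    stop("fixation and target must straddle the meridian on the saccade axis")
  if (is.null(vel)) vel <- compute_velocity(trace)
  sgn <- sign(tgt)

  # meridian crossing toward the target: sample i with along[i] on the
  # fixation side (or 0) and along[i+1] strictly on the target side
  a <- along * sgn
  ok <- !is.na(a)
  cross <- which(ok[-length(a)] & ok[-1] & a[-length(a)] <= 0 & a[-1] > 0)
  if (!length(cross)) stop("no saccade: gaze never crossed the meridian toward the target")
  tc <- NA_real_
  for (i in cross) {
    # sub-ms crossing time by linear interpolation
    frac <- if (a[i + 1] == a[i]) 0 else -a[i] / (a[i + 1] - a[i])
    tt <- trace$t[i] + frac
    if (tt >= meta$cue_onset || i == cross[length(cross)]) { tc <- tt; break }
  }
  # crossings strictly before the cue are allowed only if none follow it
  mid_t <- as.integer(round(tc))

  v_along <- if (axis == "horizontal") vel$vx else vel$vy
  pre <- which(vel$t <= mid_t)
  av <- abs(v_along[pre])
  rising <- which(!is.na(av[-1]) & !is.na(av[-length(av)]) &
                  av[-length(av)] < onset_threshold & av[-1] >= onset_threshold)
  onset <- if (length(rising)) vel$t[pre][rising[length(rising)] + 1L] else mid_t

  structure(list(onset = onset,
                 mid_saccade_t = mid_t,
                 latency = onset - meta$cue_onset,
                 peak_velocity = peak_velocity(vel),
                 peak_orthogonal_velocity = orthogonal_velocity(vel, axis),
                 axis = axis),
            class = "saccade_event")
}

#' @export
print.saccade_event <- function(x, ...) {
  cat(sprintf(paste0("<saccade_event> %s axis: onset %d ms, mid-saccade %d ms, ",
                     "latency %d ms, peak %.1f deg/s, orthogonal peak %.1f deg/s\n"),
              x$axis, x$onset, x$mid_saccade_t, x$latency,
              x$peak_velocity, x$peak_orthogonal_velocity))
  invisible(x)
}
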
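#' Polarity-reversing grating stimulus
#'
#' Parameters of the full-contrast sinusoid background that reverses polarity
#' on every display frame. Viewed with static eyes above the flicker-fusion
#' rate it is perceived as a uniform gray surface, but it contains two
#' opposite ambiguous-motion interpretations of half a cycle per frame (see
#' [motion_interpretations()]). Luminance is expressed on the linearized
#' (gamma-calibrated) axis in cd/m^2.
#'
#' @param orientation Grating bar orientation: `"vertical"` (bars vary along
#'   x) or `"horizontal"` (bars vary along y).
#' @param spatial_frequency Cycles per degree (> 0).
#' @param frame_rate Display frame rate in Hz (default 150).
#' @param L_min,L_max Luminance extrema in cd/m^2 (defaults 5.2 and 95.1).
#' @param size Stimulus side length in degrees (default 22.6).
#' @param phase Phase offset in cycles; phase 0 puts a luminance maximum at
#'   the screen center.
#' @return An object of class `grating_stimulus`.
#' @export
grating_stimulus <- function(orientation = c("vertical", "horizontal"),
                             spatial_frequency, frame_rate = 150,
                             L_min = 5.2, L_max = 95.1, size = 22.6,
                             phase = 0) {
  orientation <- match.arg(orientation)
  stopifnot(spatial_frequency > 0, frame_rate > 0, L_min < L_max, size > 0)
  structure(list(orientation = orientation,
                 spatial_frequency = spatial_frequency,
                 frame_rate = frame_rate, L_min = L_min, L_max = L_max,
                 size = size, phase = phase),
            class = "grating_stimulus")
}

#' @export
print.grating_stimulus <- function(x, ...) {
  cat(sprintf(paste0("<grating_stimulus> %s, %.4g cycles/deg at %g Hz ",
                     "(motion speed %.1f deg/s), %.3g-%.3g cd/m^2, %.3g deg\n"),
              x$orientation, x$spatial_frequency, x$frame_rate,
              x$frame_rate / (2 * x$spatial_frequency), x$L_min, x$L_max,
              x$size))
  invisible(x)
}

#' Display frame interval
#'
#' @param frame_rate Frame rate in Hz.
#' @return Frame interval in ms (6.67 ms at 150 Hz).
#' @export
frame_interval_ms <- function(frame_rate = 150) 1000 / frame_rate

#' Velocity-matched spatial frequency
#'
#' The calibration rule for the flicker grating: choose the spatial frequency
#' such that the maximum distance the eyes travel between two display frames
#' equals half a grating cycle. The eyes travel `peak_velocity / frame_rate`
#' degrees per frame, so
#' `SF = frame_rate / (2 * peak_velocity)` cycles/degree. With this choice
#' the grating's ambiguous-motion speed (half a cycle per frame, see
#' [motion_interpretations()]) equals the saccade's peak velocity, and the
#' grating is momentarily stabilized on the retina at peak velocity.
#'
#' @param peak_velocity Peak saccade velocity in deg/s (> 0; vectorized).
#' @param frame_rate Display frame rate in Hz (> 0).
#' @return Spatial frequency in cycles/degree.
#' @examples
#' ideal_spatial_frequency(400, 150)    # 0.1875 cycles/deg
#' @export
ideal_spatial_frequency <- function(peak_velocity, frame_rate = 150) {
  if (any(peak_velocity <= 0) || frame_rate <= 0)
    stop("peak_velocity and frame_rate must be positive")
  frame_rate / (2 * peak_velocity)
}

#' The two ambiguous motion interpretations of a flicker grating
#'
#' A grating that reverses polarity every frame is equivalently a grating
#' that steps half a cycle per frame in either direction along the axis
#' perpendicular to its bars. Both interpretations have speed
#' `frame_rate / (2 * spatial_frequency)` deg/s, with opposite signs.
#'
#' @param stim A [grating_stimulus()].
#' @return Data frame with columns `sign` (+1 / -1), `speed` (deg/s, equal for
#'   both rows), `axis` (`"horizontal"` motion for vertical gratings and vice
#'   versa).
#' @export
motion_interpretations <- function(stim) {
  speed <- stim$frame_rate / (2 * stim$spatial_frequency)
  axis <- if (stim$orientation == "vertical") "horizontal" else "vertical"
  data.frame(sign = c(1, -1), speed = speed, axis = axis)
}

#' Render one frame of the grating as a 1-D luminance profile
#'
#' Luminance across the axis perpendicular to the bars, on the linearized
#' luminance axis. Consecutive frames are polarity-reversed: frame i and
#' frame i+1 sum pointwise to `L_min + L_max`, so their temporal mean (the
#' fused percept during fixation) is uniform at `(L_min + L_max) / 2`.
#'
#' @param stim A [grating_stimulus()].
#' @param frame_index Integer frame number (0-based).
#' @param n_pixels Number of samples across the stimulus; must give at least
#'   2 samples per grating cycle.
#' @return Numeric vector of luminances (cd/m^2) at positions
#'   `seq(-size/2, size/2, length.out = n_pixels)`.
#' @export
render_frame <- function(stim, frame_index, n_pixels) {
  cycles <- stim$size * stim$spatial_frequency
  if (n_pixels / cycles < 2)
    stop("undersampled grating: ", n_pixels, " pixels for ",
         round(cycles, 2), " cycles (need >= 2 per cycle)")
  pos <- seq(-stim$size / 2, stim$size / 2, length.out = n_pixels)
  mid <- (stim$L_min + stim$L_max) / 2
  amp <- (stim$L_max - stim$L_min) / 2
  pol <- if (frame_index %% 2 == 0) 1 else -1
  mid + pol * amp * cos(2 * pi * (stim$spatial_frequency * pos + stim$phase))
}

#' Condition implied by saccade direction and grating orientation
#'
#' A saccade perpendicular to the grating's bars moves along the grating's
#' motion axis, so the saccade can stabilize the grating on the retina: the
#' intrasaccadic-percept condition. A saccade parallel to the bars cannot:
#' the no-percept condition.
#'
#' @param saccade_direction `"left"`, `"right"`, `"up"` or `"down"`.
#' @param orientation Grating orientation, `"vertical"` or `"horizontal"`.
#' @return `"intrasaccadic_percept"` or `"no_percept"`.
#' @examples
#' condition_for("left", "vertical")    # percept
#' condition_for("left", "horizontal")  # no percept
#' @export
condition_for <- function(saccade_direction, orientation) {
  axis <- direction_axis(saccade_direction)
  orientation <- match.arg(orientation, c("vertical", "horizontal"))
  motion_axis <- if (orientation == "vertical") "horizontal" else "vertical"
  if (axis == motion_axis) "intrasaccadic_percept" else "no_percept"
}

#' Grating orientation that realizes a condition for a saccade direction
#'
#' Inverse of [condition_for()]: which grating orientation to present so that
#' a saccade in `saccade_direction` yields `condition`.
#'
#' @inheritParams condition_for
#' @param condition `"intrasaccadic_percept"` or `"no_percept"`.
#' @return `"vertical"` or `"horizontal"`.
#' @export
orientation_for <- function(saccade_direction, condition) {
  condition <- match.arg(condition, c("intrasaccadic_percept", "no_percept"))
  axis <- direction_axis(saccade_direction)
  perp <- if (axis == "horizontal") "vertical" else "horizontal"
  if (condition == "intrasaccadic_percept") perp
  else if (perp == "vertical") "horizontal" else "vertical"
}
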
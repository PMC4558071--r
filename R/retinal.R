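#' Retinal speed of one motion interpretation
#'
#' The speed at which one of the grating's ambiguous-motion interpretations
#' slips across the retina, given the eye-velocity component along the
#' motion axis: `|sign * speed - eye_velocity|`. Zero means perfect retinal
#' stabilization, at which point the normally invisible grating becomes
#' visible.
#'
#' @param eye_velocity_component Eye velocity along the interpretation's
#'   motion axis, deg/s (signed; vectorized).
#' @param speed Interpretation speed in deg/s (> 0).
#' @param sign Interpretation direction, +1 or -1.
#' @return Retinal speed in deg/s (>= 0).
#' @export
retinal_speed <- function(eye_velocity_component, speed, sign = 1) {
  abs(sign * speed - eye_velocity_component)
}

#' Retinal-stabilization profile of a trial
#'
#' For each time sample, computes the retinal speed of both motion
#' interpretations of the grating given the eye velocity along the grating's
#' motion axis, and the stabilization index `s(t)`: the smaller of the two
#' absolute retinal speeds. When the saccade is perpendicular to the grating
#' (percept geometry) the motion axis coincides with the saccade axis and
#' `s(t)` dips toward 0 around peak velocity; when the saccade is parallel to
#' the grating (no-percept geometry) only the orthogonal (curvature)
#' component of the eye movement acts along the motion axis, so a straight
#' saccade leaves `s(t)` at the interpretation speed throughout.
#'
#' The percept window is the single maximal run of samples with
#' `s(t) < theta` (earliest run on ties); it is empty when `s` never drops
#' below `theta`.
#'
#' @param vel Velocity list from [compute_velocity()].
#' @param stim A [grating_stimulus()].
#' @param theta Stabilization threshold in deg/s below which the grating is
#'   taken to be effectively stabilized (default 50; a modelling tolerance,
#'   reported with every profile).
#' @return An object of class `stabilization_profile`: list with `t`,
#'   `retinal_speed` (2-column matrix, one per interpretation), `s`,
#'   `percept_window` (`c(start, end)` ms, or `NULL`), `theta`, `stim`.
#' @export
stabilization_profile <- function(vel, stim, theta = 50) {
  interps <- motion_interpretations(stim)
  eye_v <- if (interps$axis[1] == "horizontal") vel$vx else vel$vy
  rs <- vapply(seq_len(nrow(interps)), function(i)
    retinal_speed(eye_v, interps$speed[i], interps$sign[i]),
    numeric(length(eye_v)))
  s <- pmin(rs[, 1], rs[, 2])
  below <- !is.na(s) & s < theta
  window <- NULL
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]   # which.max takes the earliest tie
    window <- c(vel$t[starts[best]], vel$t[ends[best]])
  }
  structure(list(t = vel$t, retinal_speed = rs, s = s,
                 percept_window = window, theta = theta, stim = stim),
            class = "stabilization_profile")
}

#' @export
print.stabilization_profile <- function(x, ...) {
  cat(sprintf("<stabilization_profile> min s = %.1f deg/s (theta = %g)",
              min(x$s, na.rm = TRUE), x$theta))
  if (is.null(x$percept_window)) cat(", no percept window\n")
  else cat(sprintf(", percept window [%d, %d] ms (%d ms)\n",
                   x$percept_window[1], x$percept_window[2],
                   diff(x$percept_window) + 1L))
  invisible(x)
}

#' Peak-velocity error
#'
#' Distance between a trial's actual peak saccade velocity and the peak
#' velocity the grating was calibrated for (the grating's motion speed). The
#' intrasaccadic percept is strongest when this error is near zero. The
#' signed difference is attached as attribute `"signed"`.
#'
#' @param actual Actual peak velocity, deg/s (vectorized).
#' @param optimal Optimal (calibrated) peak velocity, deg/s.
#' @return Absolute error in deg/s, with attribute `"signed"`.
#' @export
peak_velocity_error <- function(actual, optimal) {
  if (any(actual <= 0, na.rm = TRUE) || any(optimal <= 0, na.rm = TRUE))
    stop("velocities must be positive")
  structure(abs(actual - optimal), signed = actual - optimal)
}
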
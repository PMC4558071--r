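#' Construct a gaze trace
#'
#' A `gaze_trace` holds one trial's uniformly sampled (1000 Hz) monocular
#' recording: time in ms, horizontal and vertical gaze position in degrees
#' from screen center (x positive rightward, y positive upward), and pupil
#' area in arbitrary units. Missing samples (blinks, tracking loss) are `NA`;
#' a raw pupil area of 0 is an eye-tracker blink sentinel and is converted to
#' `NA` on construction.
#'
#' @param t Integer-valued time stamps in ms, strictly increasing, gap-free
#'   at 1 ms.
#' @param x,y Gaze position in degrees from screen center (`NA` = missing).
#' @param p Pupil area in arbitrary units (`NA` or 0 = missing).
#' @return An object of class `gaze_trace`: a list with elements `t`, `x`,
#'   `y`, `p`.
#' @examples
#' tr <- gaze_trace(t = 0:99, x = rep(0, 100), y = rep(0, 100),
#'                  p = rep(1200, 100))
#' tr
#' @export
gaze_trace <- function(t, x, y, p) {
  n <- length(t)
  if (length(x) != n || length(y) != n || length(p) != n)
    stop("t, x, y, p must have equal length")
  if (n >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("t must be strictly increasing")
    if (any(dt != 1)) stop("t must be gap-free at 1 ms; flag gaps as NA samples instead")
  }
  p[!is.na(p) & p <= 0] <- NA_real_  # 0 is the tracker's blink sentinel
  structure(list(t = as.integer(round(t)), x = as.numeric(x),
                 y = as.numeric(y), p = as.numeric(p)),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<gaze_trace> %d samples, t = [%d, %d] ms, %d missing pupil sample(s)\n",
              n, x$t[1], x$t[n], sum(is.na(x$p))))
  invisible(x)
}

#' @export
length.gaze_trace <- function(x) length(x$t)

#' @export
as.data.frame.gaze_trace <- function(x, ...) {
  data.frame(t = x$t, x = x$x, y = x$y, p = x$p)
}

#' Trial metadata
#'
#' Per-trial descriptors needed by the pipeline: participant id, saccade
#' direction, experimental condition, auditory-cue onset, and the fixation and
#' saccade-target positions (degrees from screen center). Fixation and target
#' must be point-symmetric about the center, as in the cued-saccade paradigm
#' where the target appears at the location opposite the fixation dot.
#'
#' @param participant Participant identifier (character).
#' @param trial Trial identifier (integer).
#' @param direction One of `"left"`, `"right"`, `"up"`, `"down"`.
#' @param condition One of `"intrasaccadic_percept"`, `"no_percept"`,
#'   `"part1"`.
#' @param cue_onset Cue (go-signal) onset time in ms on the trial clock.
#' @param fixation_pos,target_pos Length-2 numeric `(x, y)` in degrees.
#' @param spatial_frequency Grating spatial frequency in cycles/degree
#'   (`NA` for part-1 trials without a grating).
#' @return An object of class `trial_meta` (a list).
#' @export
trial_meta <- function(participant, trial, direction, condition, cue_onset,
                       fixation_pos, target_pos, spatial_frequency = NA_real_) {
  direction <- match.arg(direction, c("left", "right", "up", "down"))
  condition <- match.arg(condition,
                         c("intrasaccadic_percept", "no_percept", "part1"))
  if (length(fixation_pos) != 2 || length(target_pos) != 2)
    stop("fixation_pos and target_pos must be length-2 (x, y)")
  if (max(abs(fixation_pos + target_pos)) > 1e-6)
    stop("fixation_pos and target_pos must be point-symmetric about the center")
  if (sqrt(sum((fixation_pos - target_pos)^2)) <= 0)
    stop("fixation-target distance must be positive")
  structure(list(participant = as.character(participant),
                 trial = as.integer(trial),
                 direction = direction, condition = condition,
                 cue_onset = as.numeric(cue_onset),
                 fixation_pos = as.numeric(fixation_pos),
                 target_pos = as.numeric(target_pos),
                 spatial_frequency = as.numeric(spatial_frequency)),
            class = "trial_meta")
}

#' Saccade axis for a direction label
#'
#' @param direction `"left"`, `"right"`, `"up"` or `"down"`.
#' @return `"horizontal"` or `"vertical"`.
#' @export
direction_axis <- function(direction) {
  ifelse(direction %in% c("left", "right"), "horizontal", "vertical")
}
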
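#' Peak-velocity validity band for velocity-calibration trials
#'
#' During the velocity-calibration part of the experiment a trial's peak
#' saccade velocity is considered realistic when it lies between 220 and 664
#' deg/s — a band around the main-sequence peak velocity of roughly 400 deg/s
#' expected for 17 degree saccades. "Above"/"below" are read strictly, so the
#' bounds themselves are valid.
#'
#' @param v Peak velocity in deg/s (vectorized). `NA` is invalid.
#' @param lo,hi Band limits in deg/s.
#' @return Logical vector: `TRUE` where valid.
#' @export
part1_peak_validity <- function(v, lo = 220, hi = 664) {
  !is.na(v) & v >= lo & v <= hi
}

#' Median peak velocity over calibration trials
#'
#' Per saccade direction, the peak velocity used to calibrate the grating is
#' the median over at least `n_required` valid calibration trials.
#'
#' @param peaks Peak velocities (deg/s) of one participant x direction cell.
#' @param n_required Minimum number of valid trials (default 40).
#' @param lo,hi Validity band passed to [part1_peak_validity()].
#' @return Median of the valid peak velocities (deg/s).
#' @export
part1_peak_estimate <- function(peaks, n_required = 40, lo = 220, hi = 664) {
  valid <- peaks[part1_peak_validity(peaks, lo, hi)]
  if (length(valid) < n_required)
    stop("only ", length(valid), " valid calibration trials; need ",
         n_required, " (short by ", n_required - length(valid), ")")
  stats::median(valid)
}

#' Trial-exclusion rules for the pupillometry part
#'
#' A trial is discarded when any of the following fires (checked in this
#' order; the first matching rule is recorded as the reason):
#' \describe{
#'   \item{anticipation}{saccade latency below 0 ms;}
#'   \item{late}{saccade latency above 2,000 ms;}
#'   \item{peak_undeterminable}{peak saccade velocity could not be determined
#'     (typically data loss);}
#'   \item{peak_too_high}{peak saccade velocity above 1,000 deg/s
#'     (unrealistic; typically data loss);}
#'   \item{pre_deviation}{gaze deviated more than `max_deviation` deg
#'     (Euclidean) from the fixation dot before the saccade;}
#'   \item{post_deviation}{gaze deviated more than `max_deviation` deg from
#'     the saccade target after the saccade.}
#' }
#' The deviation checks exclude a 200 ms window centered on the mid-saccade
#' point (the eyes are legitimately in flight there); masked samples are
#' ignored.
#'
#' @param event A [detect_saccade()] result.
#' @param trace The trial's (smoothed) [gaze_trace()].
#' @param meta The trial's [trial_meta()].
#' @param max_latency Latency ceiling in ms (default 2000).
#' @param max_peak Peak-velocity ceiling in deg/s (default 1000).
#' @param max_deviation Allowed distance from the reference dot in deg
#'   (default 3.3).
#' @param flight_halfwindow Half-width in ms of the window around the
#'   mid-saccade point excluded from deviation checks (default 100).
#' @return List with `keep` (logical) and `reason` (`NA` or one of the rule
#'   names above).
#' @export
part2_exclude <- function(event, trace, meta,
                          max_latency = 2000, max_peak = 1000,
                          max_deviation = 3.3, flight_halfwindow = 100) {
  decide <- function(reason) list(keep = FALSE, reason = reason)
  if (!is.na(event$latency) && event$latency < 0) return(decide("anticipation"))
  if (!is.na(event$latency) && event$latency > max_latency) return(decide("late"))
  if (is.na(event$peak_velocity)) return(decide("peak_undeterminable"))
  if (event$peak_velocity > max_peak) return(decide("peak_too_high"))

  mid <- event$mid_saccade_t
  dev_from <- function(ref, sel) {
    dx <- trace$x[sel] - ref[1]
    dy <- trace$y[sel] - ref[2]
    d <- sqrt(dx^2 + dy^2)
    d[!is.na(d)]
  }
  pre_sel <- trace$t < mid - flight_halfwindow
  pre_dev <- dev_from(meta$fixation_pos, pre_sel)
  if (length(pre_dev) && max(pre_dev) > max_deviation)
    return(decide("pre_deviation"))
  post_sel <- trace$t > mid + flight_halfwindow
  post_dev <- dev_from(meta$target_pos, post_sel)
  if (length(post_dev) && max(post_dev) > max_deviation)
    return(decide("post_deviation"))
  list(keep = TRUE, reason = NA_character_)
}

#' Apply the exclusion rules to a set of trials
#'
#' @param trials List of trials (`list(meta =, trace =)`), traces smoothed.
#' @param events List of [detect_saccade()] results, parallel to `trials`.
#' @param ... Thresholds forwarded to [part2_exclude()].
#' @return An `exclusion_report`: data frame with one row per trial
#'   (`participant`, `trial`, `keep`, `reason`) plus attributes `retention`
#'   (kept / total) and `reason_counts` (named integer vector).
#' @export
exclusion_report <- function(trials, events, ...) {
  rows <- lapply(seq_along(trials), function(i) {
    d <- part2_exclude(events[[i]], trials[[i]]$trace, trials[[i]]$meta, ...)
    data.frame(participant = trials[[i]]$meta$participant,
               trial = trials[[i]]$meta$trial,
               keep = d$keep, reason = d$reason)
  })
  rep_df <- do.call(rbind, rows)
  reasons <- c("anticipation", "late", "peak_undeterminable", "peak_too_high",
               "pre_deviation", "post_deviation")
  counts <- table(factor(rep_df$reason, levels = reasons))
  structure(rep_df,
            retention = mean(rep_df$keep),
            reason_counts = stats::setNames(as.integer(counts), reasons),
            class = c("exclusion_report", "data.frame"))
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d trials, %d kept (%.1f%%)\n",
              nrow(x), sum(x$keep), 100 * attr(x, "retention")))
  cnt <- attr(x, "reason_counts")
  for (r in names(cnt)) if (cnt[[r]] > 0) cat(sprintf("  %-20s %d\n", r, cnt[[r]]))
  invisible(x)
}
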
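#' Reconstruct pupil size during blinks by cubic-spline interpolation
#'
#' Blinks appear in the pupil channel as runs of missing samples (the tracker
#' reports 0, ingested as `NA`). Each run is first extended by `margin_ms` on
#' both sides, because the pupil signal is distorted by the closing and
#' reopening eyelid just outside the missing run. The extended run is then
#' replaced by a cubic spline through four anchor samples straddling it (two
#' on each side, at the raw run edges minus/plus one and two margins).
#' Samples outside extended runs are never altered. Runs that are longer than
#' `max_blink_ms`, or that sit too close to the trace edges for all four
#' anchors to exist, remain masked.
#'
#' @param p Pupil series (numeric, `NA` = missing), on a 1 ms grid.
#' @param margin_ms Margin added to each side of a missing run (default 50).
#' @param max_blink_ms Longest raw run that is reconstructed (default 500).
#' @return Pupil series with reconstructable runs filled in.
#' @export
reconstruct_blinks <- function(p, margin_ms = 50, max_blink_ms = 500) {
  n <- length(p)
  m <- as.integer(margin_ms)
  r <- rle(is.na(p))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(p)
  out <- p
  for (k in seq_len(nrow(runs))) {
    i0 <- runs[k, 1]; i1 <- runs[k, 2]
    if (i1 - i0 + 1L > max_blink_ms) next          # too long: stays masked
    anchors <- c(i0 - 2L * m, i0 - m, i1 + m, i1 + 2L * m)
    if (anchors[1] < 1L || anchors[4] > n) next    # at trace edge: stays masked
    pa <- p[anchors]
    if (anyNA(pa)) next                            # anchor inside another blink
    fill <- (i0 - m + 1L):(i1 + m - 1L)
    sf <- stats::splinefun(anchors, pa, method = "natural")
    out[fill] <- sf(fill)
  }
  out
}

#' Epoch a pupil series around the mid-saccade point and normalize to baseline
#'
#' Extracts the window from 300 ms before to 1200 ms after the mid-saccade
#' point (1,501 samples on a 1 ms grid). The baseline is the mean pupil area
#' from 105 to 95 ms before the mid-saccade point, computed on the
#' blink-reconstructed series so that a blink cannot contaminate it. Values
#' are expressed relative to this baseline: divided by it
#' (`normalization = "divisive"`, the default, so 1.0 = baseline) or with it
#' subtracted (`"subtractive"`, so 0 = baseline). The pupil signal is not
#' smoothed. Samples outside the trace's coverage, and unreconstructed
#' blinks, are `NA`.
#'
#' If every baseline sample is missing the epoch cannot be normalized and an
#' error of class `pupilsweep_epoch_rejected` is signalled.
#'
#' @param trace A [gaze_trace()] whose `p` channel has been through
#'   [reconstruct_blinks()] (raw series also accepted).
#' @param mid_saccade_t Mid-saccade time in ms on the trace clock.
#' @param meta Optional [trial_meta()] attached to the epoch.
#' @param normalization `"divisive"` or `"subtractive"`.
#' @param window Epoch window relative to the mid-saccade point, ms.
#' @param baseline_window Baseline window relative to the mid-saccade point,
#'   ms (inclusive).
#' @return An object of class `epoched_pupil`: list with `time` (relative ms
#'   grid), `value` (normalized pupil), `baseline` (raw area units), `meta`.
#' @export
epoch_and_normalize <- function(trace, mid_saccade_t, meta = NULL,
                                normalization = c("divisive", "subtractive"),
                                window = c(-300, 1200),
                                baseline_window = c(-105, -95)) {
  normalization <- match.arg(normalization)
  grid <- seq.int(window[1], window[2])
  abs_t <- grid + mid_saccade_t
  idx <- match(abs_t, trace$t)
  vals <- ifelse(is.na(idx), NA_real_, trace$p[idx])
  b_idx <- match(seq.int(baseline_window[1], baseline_window[2]) + mid_saccade_t,
                 trace$t)
  b_vals <- trace$p[b_idx[!is.na(b_idx)]]
  b_vals <- b_vals[!is.na(b_vals)]
  if (!length(b_vals))
    stop(structure(class = c("pupilsweep_epoch_rejected", "error", "condition"),
                   list(message = "baseline window fully masked; epoch rejected",
                        call = sys.call(-1))))
  baseline <- mean(b_vals)
  value <- if (normalization == "divisive") vals / baseline else vals - baseline
  structure(list(time = grid, value = value, baseline = baseline,
                 normalization = normalization, meta = meta),
            class = "epoched_pupil")
}

#' @export
print.epoched_pupil <- function(x, ...) {
  cat(sprintf("<epoched_pupil> %d samples [%d, %d] ms, baseline %.1f a.u. (%s), %d masked\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$baseline,
              x$normalization, sum(is.na(x$value))))
  invisible(x)
}

#' Regression-based correction of eye-position artifacts in pupil size
#'
#' Video-based trackers record the pupil from a fixed camera, so gaze angle
#' changes the apparent (measured) pupil area even when true pupil size is
#' constant. The classical correction fits, per participant, a linear
#' regression of baseline pupil area on horizontal (X) and vertical (Y)
#' fixation position, and removes the fitted position component from the
#' measurements.
#'
#' This correction is off by default in [run_pipeline()]: gaze angle also has
#' a real (non-artifactual) effect on pupil size, with a sign that can oppose
#' the artifact, so regressing position out is not safe in general. The
#' function is provided for sensitivity analyses.
#'
#' @param baseline_df Data frame with one row per epoch: columns
#'   `participant`, `baseline` (raw area units), `x`, `y` (fixation position,
#'   deg).
#' @param epochs List of [epoched_pupil] objects matching `baseline_df` rows;
#'   epochs must use divisive normalization.
#' @return List with `epochs` (corrected: the fitted position component,
#'   relative to the participant's mean position, removed from each epoch's
#'   baseline, and values renormalized) and `slopes` (per-participant data
#'   frame with `slope_x`, `slope_y`, area units per degree).
#' @export
position_artifact_regression <- function(baseline_df, epochs) {
  stopifnot(nrow(baseline_df) == length(epochs))
  out <- epochs
  slopes <- list()
  for (pp in unique(baseline_df$participant)) {
    rows <- which(baseline_df$participant == pp)
    d <- baseline_df[rows, ]
    if (nrow(unique(d[, c("x", "y")])) < 3)
      stop("participant ", pp, ": need >= 3 distinct fixation positions")
    fit <- stats::lm(baseline ~ x + y, data = d)
    if (anyNA(stats::coef(fit)))
      stop("participant ", pp, ": fixation positions are collinear; cannot fit X and Y slopes")
    cf <- stats::coef(fit)
    slopes[[pp]] <- data.frame(participant = pp,
                               slope_x = cf[["x"]], slope_y = cf[["y"]])
    comp <- cf[["x"]] * (d$x - mean(d$x)) + cf[["y"]] * (d$y - mean(d$y))
    for (j in seq_along(rows)) {
      e <- epochs[[rows[j]]]
      b_old <- e$baseline
      b_new <- b_old - comp[j]
      # remove the position component from the raw signal, then renormalize
      e$value <- (e$value * b_old - comp[j]) / b_new
      e$baseline <- b_new
      out[[rows[j]]] <- e
    }
  }
  list(epochs = out, slopes = do.call(rbind, slopes))
}
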
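# Deterministic single-trial fixture: a noiseless cued saccade with constant
# pupil, assembled from simulate_saccade() increments.
make_clean_trial <- function(direction = "right", peak_velocity = 400,
                             curvature = 0, cue_onset = 300, latency = 150,
                             n = 2100, baseline = 1200, amplitude = 17,
                             trial = 1L, participant = "t01") {
  half <- amplitude / 2
  fix <- switch(direction, left = c(half, 0), right = c(-half, 0),
                up = c(0, -half), down = c(0, half))
  sac <- simulate_saccade(amplitude, direction, peak_velocity, curvature)
  onset <- cue_onset + latency
  x <- rep(fix[1], n); y <- rep(fix[2], n)
  sl <- onset + seq_len(sac$duration_ms)
  x[sl] <- fix[1] + cumsum(sac$dx)
  y[sl] <- fix[2] + cumsum(sac$dy)
  if (max(sl) < n) {
    x[(max(sl) + 1):n] <- x[max(sl)]
    y[(max(sl) + 1):n] <- y[max(sl)]
  }
  meta <- trial_meta(participant = participant, trial = trial,
                     direction = direction, condition = "part1",
                     cue_onset = cue_onset, fixation_pos = fix,
                     target_pos = -fix)
  list(meta = meta,
       trace = gaze_trace(0:(n - 1), x, y, rep(baseline, n)),
       true_onset = onset,
       true_mid = onset + round(sac$duration_ms / 2),
       duration = sac$duration_ms)
}

# Exhaustive run-scan oracle for the consecutive-samples reliability rule:
# walks the series sample by sample, independent of rle().
brute_force_intervals <- function(t_values, t_ms, threshold = 2,
                                  min_run_ms = 200) {
  step <- if (length(t_ms) > 1) t_ms[2] - t_ms[1] else 1
  exceed <- !is.na(t_values) & abs(t_values) > threshold
  out <- list()
  i <- 1
  n <- length(exceed)
  while (i <= n) {
    if (exceed[i]) {
      j <- i
      while (j < n && exceed[j + 1]) j <- j + 1
      if ((j - i + 1) >= ceiling(min_run_ms / step))
        out[[length(out) + 1]] <- c(t_ms[i], t_ms[j] + step)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(start_ms = m[, 1], end_ms = m[, 2])
}
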
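test_that("simulated saccades hit programmed amplitude, peak and curvature", {
  sac <- simulate_saccade(17, "right", 400, 0)
  expect_equal(sac$duration_ms, 85)
  expect_equal(sum(sac$dx), 17, tolerance = 0.1 / 17)
  expect_equal(max(sac$dx) * 1000, 400, tolerance = 0.01 * 400)
  expect_equal(sac$dy, rep(0, 85))

  sac_up <- simulate_saccade(17, "up", 430, 150)
  expect_equal(sum(sac_up$dy), 17, tolerance = 0.01)
  expect_equal(sum(sac_up$dx), 0, tolerance = 1e-9)        # zero-integral curvature
  expect_equal(max(abs(sac_up$dx)) * 1000, 150, tolerance = 0.01 * 150)

  sac_left <- simulate_saccade(17, "left", 400, 0)
  expect_equal(sum(sac_left$dx), -17, tolerance = 0.01)

  expect_error(simulate_saccade(1, "right", 400), "impossible")
})

test_that("the noiseless pupil series equals the direct kernel-sum oracle", {
  cfg <- sim_config(noise_sd = 0, slow_noise_sd = 0, blink_rate = 0,
                    artifact_slope_x = 0, artifact_slope_y = 0)
  t <- 0:2099
  # independent oracle: Erlang density normalized to unit peak
  erlang_unit <- function(t, tau, shape) {
    tp <- (shape - 1) * tau
    ifelse(t > 0, (t / tp)^(shape - 1) * exp(-(t - tp) / tau), 0)
  }
  base <- 1200
  p <- simulate_pupil(t, cue_onset = 300, mid_t = 500, baseline = base,
                      gain = 1, effect_mult = 1, x = numeric(2100),
                      y = numeric(2100), cfg = cfg)
  expected <- base * (1 +
    cfg$dilation_amp * erlang_unit(t - 300, cfg$kernel_tau, cfg$kernel_shape) -
    cfg$constriction_amp * erlang_unit(t - 720, cfg$kernel_tau, cfg$kernel_shape) -
    cfg$condition_effect * erlang_unit(t - 800, cfg$kernel_tau, cfg$kernel_shape))
  expect_equal(p, expected, tolerance = 1e-9)

  # all amplitudes zero -> flat at baseline
  cfg0 <- sim_config(noise_sd = 0, slow_noise_sd = 0, blink_rate = 0,
                     artifact_slope_x = 0, artifact_slope_y = 0,
                     dilation_amp = 0, constriction_amp = 0,
                     condition_effect = 0)
  p0 <- simulate_pupil(t, 300, 500, base, 1, 1, numeric(2100), numeric(2100), cfg0)
  expect_equal(p0, rep(base, 2100))

  # percept-trial minimum is deeper than the no-percept one by the configured
  # component (gain 1 vs gain 0)
  p_no <- simulate_pupil(t, 300, 500, base, 0, 1, numeric(2100), numeric(2100), cfg)
  expect_equal(p_no - p,
               base * cfg$condition_effect *
                 erlang_unit(t - 800, cfg$kernel_tau, cfg$kernel_shape),
               tolerance = 1e-9)
  expect_lt(min(p), min(p_no))
})

test_that("percept gain tracks retinal stabilization in both geometries", {
  expect_equal(percept_gain("intrasaccadic_percept", 400, 0, 400), 1)
  expect_equal(percept_gain("intrasaccadic_percept", 300, 0, 400), 0.75)
  expect_equal(percept_gain("intrasaccadic_percept", 900, 0, 400), 0)  # clipped
  expect_equal(percept_gain("no_percept", 400, 0, 400), 0)
  expect_equal(percept_gain("no_percept", 400, 150, 400), 0.375)
  expect_equal(percept_gain("no_percept", 400, 500, 400), 1)           # capped
})

test_that("simulated experiments are deterministic and factorially complete", {
  cfg <- sim_config(n_participants = 2, trials_per_cell = 2)
  e1 <- simulate_experiment(cfg, seed = 9)
  e2 <- simulate_experiment(cfg, seed = 9)
  expect_identical(e1, e2)
  e3 <- simulate_experiment(cfg, seed = 10)
  expect_false(identical(e1$trials[[1]]$trace$p, e3$trials[[1]]$trace$p))

  # participants x directions x conditions x trials
  expect_length(e1$trials, 2 * 4 * 2 * 2)
  meta <- do.call(rbind, lapply(e1$trials, function(tr)
    data.frame(p = tr$meta$participant, d = tr$meta$direction,
               c = tr$meta$condition)))
  expect_equal(nrow(unique(meta)), 2 * 4 * 2)
  expect_equal(nrow(e1$calibration), 2 * 4)
  # calibration obeys the half-cycle rule
  expect_equal(e1$calibration$spatial_frequency,
               150 / (2 * e1$calibration$median_peak))
})

test_that("vertical peak velocities are more variable and more curved than horizontal", {
  cfg <- sim_config(n_participants = 10, trials_per_cell = 6,
                    noise_sd = 0, slow_noise_sd = 0, blink_rate = 0)
  e <- simulate_experiment(cfg, seed = 4)
  truth <- do.call(rbind, lapply(e$trials, function(tr)
    data.frame(participant = tr$meta$participant,
               axis = direction_axis(tr$meta$direction),
               pv = tr$truth$peak_velocity, curv = tr$truth$curvature)))
  sd_by <- aggregate(pv ~ participant + axis, truth, sd)
  wide <- reshape(sd_by, idvar = "participant", timevar = "axis",
                  direction = "wide")
  expect_gte(sum(wide$pv.vertical > wide$pv.horizontal), 9)
  cv_by <- aggregate(curv ~ participant + axis, truth, mean)
  cw <- reshape(cv_by, idvar = "participant", timevar = "axis",
                direction = "wide")
  expect_true(all(cw$curv.vertical > cw$curv.horizontal))

  # the paired axis comparisons on measured kinematics come out positive
  res <- run_pipeline(e, pipeline_config(run_sweep = FALSE))
  disp <- lapply(split(res$trials_df, res$trials_df$axis), dispersion_metrics)
  tt_sd <- paired_t(disp$vertical$sd_peak_velocity,
                    disp$horizontal$sd_peak_velocity)
  expect_gt(tt_sd$t, 2)
  expect_equal(tt_sd$df, 9)
  tt_orth <- paired_t(disp$vertical$mean_orthogonal_velocity,
                      disp$horizontal$mean_orthogonal_velocity)
  expect_gt(tt_orth$t, 2)
})
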
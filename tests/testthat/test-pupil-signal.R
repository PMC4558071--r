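test_that("blink reconstruction is the identity off-blink and linear on lines", {
  p <- seq(1000, 1200, length.out = 1001)  # linear trend
  expect_identical(reconstruct_blinks(p), p)

  p2 <- p
  p2[400:480] <- NA
  rec <- reconstruct_blinks(p2, margin_ms = 50)
  expect_false(anyNA(rec))
  # a cubic spline through collinear anchors reproduces the line within 1%
  expect_lt(max(abs(rec[350:530] - p[350:530]) / p[350:530]), 0.01)
  # samples outside the extended run are untouched
  expect_identical(rec[1:349], p2[1:349])
  expect_identical(rec[531:1001], p2[531:1001])
})

test_that("unanchorable and overlong blinks stay masked", {
  p <- rep(1000, 1000)
  p[1:80] <- NA                     # at trace start: no left anchors
  rec <- reconstruct_blinks(p)
  expect_true(all(is.na(rec[1:80])))

  p2 <- rep(1000, 2000)
  p2[300:900] <- NA                 # 601 ms > default 500 ms maximum
  expect_true(all(is.na(reconstruct_blinks(p2)[300:900])))
  expect_false(anyNA(reconstruct_blinks(p2, max_blink_ms = 700)))
})

test_that("epoching normalizes to the pre-saccadic baseline", {
  n <- 2100; mid <- 600
  tr <- gaze_trace(0:(n - 1), rep(0, n), rep(0, n), rep(1200, n))
  ep <- epoch_and_normalize(tr, mid)
  expect_equal(ep$time, -300:1200)
  expect_length(ep$value, 1501)
  expect_equal(ep$value, rep(1, 1501), tolerance = 1e-12)
  expect_equal(ep$baseline, 1200)

  # step from 1000 to 900 at +300 ms -> normalized step 1.0 -> 0.9
  p <- rep(1000, n); p[(mid + 300 + 1):n] <- 900   # t[i] = i - 1
  ep2 <- epoch_and_normalize(gaze_trace(0:(n - 1), rep(0, n), rep(0, n), p), mid)
  expect_equal(ep2$value[ep2$time == 0], 1)
  expect_equal(ep2$value[ep2$time == 299], 1)
  expect_equal(ep2$value[ep2$time == 300], 0.9)
  expect_equal(ep2$value[ep2$time == 1200], 0.9)

  # subtractive alternative: 0 = baseline
  ep3 <- epoch_and_normalize(gaze_trace(0:(n - 1), rep(0, n), rep(0, n), p),
                             mid, normalization = "subtractive")
  expect_equal(ep3$value[ep3$time == 0], 0)
  expect_equal(ep3$value[ep3$time == 300], -100)
})

test_that("normalization is scale invariant and baseline-mean is exactly 1", {
  set.seed(7)
  n <- 2100; mid <- 700
  p <- 1100 + 50 * sin((0:(n - 1)) / 120) + rnorm(n, 0, 5)
  tr <- gaze_trace(0:(n - 1), rep(0, n), rep(0, n), p)
  ep <- epoch_and_normalize(tr, mid)
  base_sel <- ep$time >= -105 & ep$time <= -95
  expect_equal(mean(ep$value[base_sel]), 1, tolerance = 1e-9)

  tr_scaled <- gaze_trace(0:(n - 1), rep(0, n), rep(0, n), p * 3.7)
  ep_s <- epoch_and_normalize(tr_scaled, mid)
  expect_equal(ep_s$value, ep$value, tolerance = 1e-12)
})

test_that("epochs with a fully masked baseline are rejected with a reason", {
  n <- 2100; mid <- 700
  p <- rep(1000, n)
  p[(mid - 130):(mid - 80)] <- NA   # blink covering the whole baseline window
  tr <- gaze_trace(0:(n - 1), rep(0, n), rep(0, n), p)
  expect_error(epoch_and_normalize(tr, mid), "baseline",
               class = "pupilsweep_epoch_rejected")
})

test_that("out-of-coverage epoch samples are masked, not invented", {
  n <- 1000; mid <- 500   # trace ends 500 ms after the mid-saccade point
  tr <- gaze_trace(0:(n - 1), rep(0, n), rep(0, n), rep(1000, n))
  ep <- epoch_and_normalize(tr, mid)
  expect_true(all(is.na(ep$value[ep$time > 499])))
  expect_false(anyNA(ep$value[ep$time <= 499]))
})

test_that("position-artifact regression recovers and removes planted slopes", {
  set.seed(11)
  n <- 2100; mid <- 700
  positions <- rbind(c(-8.5, 0), c(8.5, 0), c(0, -8.5), c(0, 8.5))
  make_ep <- function(x, y, slope) {
    p0 <- 1000
    p <- rep(p0 + slope * x, n)
    meta <- trial_meta("p1", 1, "right", "part1", 300, c(-8.5, 0), c(8.5, 0))
    epoch_and_normalize(gaze_trace(0:(n - 1), rep(x, n), rep(y, n), p),
                        mid, meta)
  }
  # planted artifact: pupil = 1000 + 3 * x
  epochs <- lapply(1:4, function(i) make_ep(positions[i, 1], positions[i, 2], 3))
  bdf <- data.frame(participant = "p1",
                    baseline = vapply(epochs, function(e) e$baseline, 0),
                    x = positions[, 1], y = positions[, 2])
  res <- position_artifact_regression(bdf, epochs)
  expect_equal(res$slopes$slope_x, 3, tolerance = 1e-8)
  expect_equal(res$slopes$slope_y, 0, tolerance = 1e-8)
  # artifact removed: all corrected baselines equal
  bl <- vapply(res$epochs, function(e) e$baseline, 0)
  expect_lt(diff(range(bl)), 1e-6)

  # pupil independent of position: slopes ~ 0, output ~ input
  epochs0 <- lapply(1:4, function(i) make_ep(positions[i, 1], positions[i, 2], 0))
  res0 <- position_artifact_regression(bdf_from <- data.frame(
    participant = "p1", baseline = vapply(epochs0, function(e) e$baseline, 0),
    x = positions[, 1], y = positions[, 2]), epochs0)
  expect_equal(abs(res0$slopes$slope_x), 0, tolerance = 1e-8)
  expect_equal(res0$epochs[[1]]$value, epochs0[[1]]$value, tolerance = 1e-9)

  # collinear positions cannot identify both slopes
  bad <- data.frame(participant = "p1", baseline = c(1000, 1010, 1020),
                    x = c(-1, 0, 1), y = c(-1, 0, 1))
  expect_error(position_artifact_regression(bad, epochs0[1:3]), "collinear")
})
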
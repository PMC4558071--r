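test_that("reliable intervals respect the consecutive-samples boundary", {
  t_ms <- 0:999
  tv <- rep(0, 1000)
  tv[101:350] <- 3                       # 250 consecutive samples
  iv <- reliable_intervals(tv, t_ms)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_ms, 100)
  expect_equal(iv$end_ms, 350)           # half-open: covers all 250 samples

  tv199 <- rep(0, 1000); tv199[101:299] <- 3
  expect_equal(nrow(reliable_intervals(tv199, t_ms)), 0)
  tv200 <- rep(0, 1000); tv200[101:300] <- 3
  expect_equal(nrow(reliable_intervals(tv200, t_ms)), 1)

  # two-sided by default: strong negative t counts; one-sided does not
  tvneg <- rep(0, 1000); tvneg[1:400] <- -5
  expect_equal(nrow(reliable_intervals(tvneg, t_ms)), 1)
  expect_equal(nrow(reliable_intervals(tvneg, t_ms, sided = "one")), 0)

  expect_equal(nrow(reliable_intervals(numeric(0), numeric(0))), 0)
})

test_that("reliable intervals match exhaustive run enumeration on random series", {
  set.seed(101)
  for (r in 1:200) {
    n <- sample(50:400, 1)
    step <- sample(c(1, 5, 10), 1)
    t_ms <- seq(0, by = step, length.out = n)
    tv <- runif(n, -4, 4)
    tv[sample(n, n %/% 10)] <- NA
    min_run <- sample(c(20, 50, 100), 1)
    got <- reliable_intervals(tv, t_ms, threshold = 2, min_run_ms = min_run)
    want <- brute_force_intervals(tv, t_ms, threshold = 2, min_run_ms = min_run)
    expect_equal(got, want)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start_ms) > 0))
      expect_true(all(got$start_ms[-1] >= got$end_ms[-nrow(got)]))
    }
  }
})

test_that("decimation preserves interval boundaries on smooth t-series", {
  t_ms <- 0:1500
  tv <- 5 * exp(-((t_ms - 700) / 250)^2)    # smooth bump exceeding 2 for a while
  full <- reliable_intervals(tv, t_ms)
  k <- 10
  sel <- t_ms %% k == 0
  dec <- reliable_intervals(tv[sel], t_ms[sel])
  expect_equal(nrow(dec), nrow(full))
  expect_lte(abs(dec$start_ms - full$start_ms), k)
  expect_lte(abs(dec$end_ms - full$end_ms), k)
})

test_that("median-split selection keeps strictly-below-median trials per group", {
  df <- data.frame(participant = rep("p1", 3), direction = "up",
                   m = c(1, 2, 3))
  expect_equal(median_split_select(df, "m")$m, 1)
  df2 <- data.frame(participant = rep("p1", 4), direction = "up",
                    m = c(1, 2, 3, 4))
  expect_equal(median_split_select(df2, "m")$m, c(1, 2))   # median 2.5
  df3 <- data.frame(participant = rep("p1", 4), direction = "up",
                    m = rep(7, 4))
  expect_equal(nrow(median_split_select(df3, "m")), 0)     # strict inequality
  # groups are independent
  df4 <- rbind(df2, transform(df2, participant = "p2", m = m * 100))
  sel <- median_split_select(df4, "m")
  expect_equal(sel$m, c(1, 2, 100, 200))
  expect_warning(median_split_select(
    data.frame(participant = "p3", direction = "up", m = 1), "m"), "skipped")
})

test_that("paired t-test matches the textbook formula on a worked example", {
  a <- c(410, 395, 430, 402)
  b <- c(380, 390, 400, 385)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  res <- paired_t(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)

  res10 <- paired_t(rnorm(10, 50, 5), rnorm(10, 40, 5))
  expect_equal(res10$df, 9)                       # n = 10 pairs
  expect_error(paired_t(1:5, 1:5), "zero variance")
  expect_error(paired_t(1:5, (1:5) + 2), "zero variance")
})

test_that("dispersion metrics use the n-1 standard deviation and the mean", {
  df <- data.frame(participant = rep(c("p1", "p2"), each = 2),
                   peak_velocity = c(390, 410, 400, 400),
                   peak_orthogonal_velocity = c(100, 200, 50, 70))
  m <- dispersion_metrics(df)
  expect_equal(m$sd_peak_velocity, c(sqrt(sum((c(390, 410) - 400)^2) / 1), 0))
  expect_equal(m$sd_peak_velocity[1], 14.1421356, tolerance = 1e-6)
  expect_equal(m$mean_orthogonal_velocity, c(150, 60))
  df1 <- rbind(df, data.frame(participant = "p3", peak_velocity = 1,
                              peak_orthogonal_velocity = 1))
  expect_warning(dispersion_metrics(df1), "skipped")
})

test_that("the sweep recovers an injected condition effect and is null on duplicated groups", {
  set.seed(21)
  # small synthetic epochs table: 6 participants, effect from +300 ms
  grid <- seq(-300, 1200, by = 50)
  rows <- list()
  for (p in 1:6) for (cond in c("no_percept", "intrasaccadic_percept"))
    for (tr in 1:4) {
      eff <- ifelse(grid >= 300 & cond == "intrasaccadic_percept", -0.04, 0)
      rows[[length(rows) + 1]] <- data.frame(
        participant = sprintf("p%d", p), trial = tr, condition = cond,
        direction = "right", t_ms = grid,
        pupil = 1 + eff + rnorm(length(grid), 0, 0.01))
    }
  df <- do.call(rbind, rows)
  sw <- lme_sweep(df, fixed = ~ condition, decimate = 50)
  iv <- sw$intervals$conditionintrasaccadic_percept
  expect_gte(nrow(iv), 1)
  expect_lte(iv$start_ms[1], 350)
  expect_gte(iv$end_ms[nrow(iv)], 1200)
  est <- sw$table[sw$table$t_ms >= 300, "estimate"]
  expect_true(all(est < 0))
  expect_equal(mean(est), -0.04, tolerance = 0.2 * 0.04)
  est_pre <- sw$table[sw$table$t_ms < 300, ]
  expect_equal(nrow(reliable_intervals(est_pre$t, est_pre$t_ms,
                                       min_run_ms = 200)), 0)

  # duplicating every epoch under both condition labels nulls the effect
  dup <- rbind(transform(df, condition = "no_percept"),
               transform(df, condition = "intrasaccadic_percept"))
  sw0 <- lme_sweep(dup, fixed = ~ condition, decimate = 150)
  expect_true(all(abs(sw0$table$estimate) < 1e-6))

  expect_error(lme_sweep(df[df$participant == "p1", ], fixed = ~ condition),
               "participants")
  expect_error(lme_sweep(df[df$condition == "no_percept" |
                            df$participant == "p1", ], fixed = ~ condition),
               "both condition levels")
})
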
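test_that("noise-free pulse trains are segmented at the constructed events", {
  tr <- generate_trial(quiet_profile(n = 5, duration = 6, stance = 0.5),
                       seed = 4, leading_side = "left", turn_direction = "ccw")
  gt <- tr$ground_truth
  fs <- tr$traces$shank_left$fs
  g <- tr$traces$shank_left$gyro[, "flexext"]   # unfiltered: zero noise
  ev <- detect_swings(g, fs)

  expect_identical(n_cycles(ev), 5L)
  centers <- rowMeans(gt$swing_intervals)
  expect_true(all(abs(ev$mid_swing_idx - (centers * fs + 1)) <= 1))
  # toe-off / heel-strike land at the pulse bases (one-sample quantization)
  expect_true(all(abs(ev$toe_off_idx - (gt$swing_intervals[, 1] * fs + 1)) <= 1.5))
  expect_true(all(abs(ev$heel_strike_idx - (gt$swing_intervals[, 2] * fs + 1)) <= 1.5))

  expect_equal(turn_duration(ev), gt$turn_duration, tolerance = 2.5 / fs / gt$turn_duration)

  st <- stance_fraction(ev)
  expect_length(st$per_cycle, 4)
  quant <- 100 * 2 / (gt$params$cycle_period * fs)   # 2-sample quantization
  expect_lt(abs(st$mean - 100 * gt$stance_fraction[1]), quant)
})

test_that("a recovered 53% stance trial reads back near 53%", {
  tr <- generate_trial(quiet_profile(n = 6, duration = 7.67, stance = 0.5328),
                       seed = 9, leading_side = "left", turn_direction = "ccw")
  g <- tr$traces$shank_left$gyro[, "flexext"]
  ev <- detect_swings(g, 60)
  quant <- 100 * 2 / (tr$ground_truth$params$cycle_period * 60)
  expect_lt(abs(stance_fraction(ev)$mean - 53.28), quant)
})

test_that("raw threshold crossings sit at the analytic 10%-height points", {
  fs <- 200
  w <- 1
  t <- seq(0, 3, by = 1 / fs)
  x <- ifelse(t >= 1 & t <= 1 + w, 0.5 * (1 - cos(2 * pi * (t - 1) / w)), 0)
  ev <- suppressWarnings(
    detect_swings(x, fs, detection_params(extrapolate_base = FALSE))
  )
  u <- acos(1 - 2 * 0.1) / (2 * pi)     # analytic 10% crossing offset
  expect_lt(abs(ev$toe_off_idx - ((1 + u * w) * fs + 1)), 1.5)
  expect_lt(abs(ev$heel_strike_idx - ((1 + w - u * w) * fs + 1)), 1.5)
  # with base extrapolation the same pulse is bounded at its support
  ev2 <- suppressWarnings(detect_swings(x, fs, detection_params()))
  expect_lt(abs(ev2$toe_off_idx - (1 * fs + 1)), 2.5)
  expect_lt(abs(ev2$heel_strike_idx - ((1 + w) * fs + 1)), 2.5)
})

test_that("event ordering holds across noisy trials of both groups", {
  for (seed in 1:8) {
    for (prof in list(ss_profile(), hi_profile())) {
      tr <- generate_trial(prof, seed * 31)
      lead <- tr$traces[[leading_placement(tr)]]
      ev <- detect_swings(lowpass(lead$gyro[, "flexext"], lead$fs), lead$fs)
      n <- n_cycles(ev)
      expect_true(all(ev$toe_off_idx < ev$mid_swing_idx))
      expect_true(all(ev$mid_swing_idx < ev$heel_strike_idx))
      if (n >= 2) {
        expect_true(all(ev$heel_strike_idx[-n] < ev$toe_off_idx[-1]))
        expect_true(all(ev$stance_fraction > 0 & ev$stance_fraction < 1,
                        na.rm = TRUE))
      }
    }
  }
})

test_that("recovered stance is monotone in the generated stance fraction", {
  recover <- function(sf) {
    tr <- generate_trial(
      ss_profile(stance = dist_spec(sf, 0, 0.05, 0.95)), seed = 123,
      leading_side = "left", turn_direction = "ccw"
    )
    lead <- tr$traces$shank_left
    ev <- detect_swings(lowpass(lead$gyro[, "flexext"], lead$fs), lead$fs)
    stance_fraction(ev)$mean
  }
  got <- vapply(c(0.35, 0.45, 0.55, 0.65, 0.75), recover, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("degenerate detection inputs are reported", {
  expect_error(detect_swings(rep(0, 100), 60), "no swings")
  fs <- 60
  t <- seq(0, 3, by = 1 / fs)
  one <- ifelse(t >= 1 & t <= 2, 0.5 * (1 - cos(2 * pi * (t - 1))), 0)
  expect_warning(ev <- detect_swings(one, fs), "fewer than 2 swings")
  expect_identical(n_cycles(ev), 1L)
  expect_error(stance_fraction(ev), "at least 2 swings")
  # single swing of width w has duration ~ w
  expect_equal(turn_duration(ev), 1, tolerance = 0.05)
})

test_that("turn duration is last heel-strike minus first toe-off", {
  ev <- structure(
    list(mid_swing_idx = c(150L, 500L), toe_off_idx = c(101L, 450L),
         heel_strike_idx = c(200L, 868L),
         cycle_bounds = cbind(start = 101L, end = 450L),
         stance_fraction = 0.5, fs = 100),
    class = "gait_events"
  )
  expect_equal(turn_duration(ev), 7.67)
})
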
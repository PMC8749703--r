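test_that("mean absolute angular velocity matches analytic values", {
  expect_equal(mean_abs_angular_velocity(rep(2, 50), c(1, 50)), 2)
  expect_equal(mean_abs_angular_velocity(rep(-2, 50), c(10, 20)), 2)
  # sine of amplitude A over whole periods averages 2A/pi
  A <- 3.2
  n_per <- 1000
  x <- A * sin(2 * pi * seq(0, 4 - 1 / n_per, by = 1 / n_per))
  expect_equal(mean_abs_angular_velocity(x, c(1, length(x))), 2 * A / pi,
               tolerance = 1e-4)
  expect_error(mean_abs_angular_velocity(x, c(50, 10)), "interval")
  expect_error(mean_abs_angular_velocity(x, c(1, length(x) + 1)), "interval")
})

test_that("range of motion is max minus min and monotone under inclusion", {
  expect_equal(range_of_motion(rep(7.3, 40), c(1, 40)), 0)
  ramp <- seq(3, 14.51, length.out = 100)
  expect_equal(range_of_motion(ramp, c(1, 100)), 11.51)
  set.seed(21)
  for (i in 1:20) {
    x <- cumsum(rnorm(200))
    a <- sort(sample(200, 2)); b <- sort(sample(200, 2))
    un <- c(min(a[1], b[1]), max(a[2], b[2]))
    expect_gte(range_of_motion(x, un),
               max(range_of_motion(x, a), range_of_motion(x, b)))
  }
})

test_that("relative sternum-sacrum traces are per-sample differences", {
  tr <- tiny_trial()
  same <- relative_trace(tr$traces$sternum, tr$traces$sternum, "flexext")
  expect_equal(same, rep(0, length(same)))
  d <- relative_trace(tr$traces$sternum, tr$traces$sacrum, "lateral", "angle")
  expect_equal(d, tr$traces$sternum$angle[, "lateral"] -
                 tr$traces$sacrum$angle[, "lateral"])
  # anti-phase oscillations double in the difference signal
  s1 <- tr$traces$sternum; s2 <- tr$traces$sacrum
  tt <- s1$t
  A <- 1.7
  s1$angle[, "flexext"] <- A * sin(tt); s2$angle[, "flexext"] <- -A * sin(tt)
  expect_equal(relative_trace(s1, s2, "flexext", "angle"), 2 * A * sin(tt))
})

test_that("leg ratios behave like ratios", {
  expect_equal(leg_ratio(1.4, 1.4), 1)
  expect_equal(leg_ratio(0.95 * 2.2, 2.2), 0.95)
  expect_equal(leg_ratio(3, 4) * leg_ratio(4, 3), 1)
  expect_warning(out <- leg_ratio(1, 0), "undefined")
  expect_true(is.na(out))
})

test_that("extract_all emits the full parameter cross-product", {
  tr <- generate_trial(ss_profile(), seed = 17)
  pr <- process_trial(tr, pipeline_config(ks = 2:7))
  feats <- pr$features
  # 25 records per interval; temporal adds cycle count, duration, stance
  per_interval <- 25L
  expected <- (per_interval + 3L) + per_interval * sum(2:7)
  expect_identical(nrow(feats), expected)   # 703 for the full k set
  key <- with(feats, paste(parameter, placement, direction, scheme,
                           partition_index))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(feats$value[feats$parameter %in%
                                c("angular_velocity", "range_of_motion")] >= 0))
  expect_error(extract_all(pr$trial, pr$events, list("2" = NULL)),
               "missing partition")
})

test_that("noise-free extraction recovers the generator's ground truth", {
  tr <- generate_trial(quiet_profile(n = 5, duration = 6, stance = 0.5),
                       seed = 8, leading_side = "left", turn_direction = "ccw")
  pr <- process_trial(tr, pipeline_config(ks = c(2, 4)))
  gt <- tr$ground_truth
  feats <- pr$features
  tmp <- feats[feats$scheme == "temporal", ]

  expect_identical(tmp$value[tmp$parameter == "n_cycles"], 5)
  expect_equal(tmp$value[tmp$parameter == "turn_duration"], gt$turn_duration,
               tolerance = 0.02)
  expect_equal(tmp$value[tmp$parameter == "stance_pct"],
               100 * gt$stance_fraction[1], tolerance = 3)

  role_to_placement <- c(sternum = "sternum", sacrum = "sacrum",
                         leading = "shank_leading", trailing = "shank_trailing")
  for (r in seq_len(nrow(gt$segments))) {
    seg <- gt$segments[r, ]
    pl <- role_to_placement[[seg$segment]]
    got_av <- tmp$value[tmp$parameter == "angular_velocity" &
                          tmp$placement == pl & tmp$direction == seg$direction]
    if (length(got_av)) {
      expect_equal(got_av, seg$mean_abs_av, tolerance = 0.05 * seg$mean_abs_av + 1e-3)
    }
    got_rom <- tmp$value[tmp$parameter == "range_of_motion" &
                           tmp$placement == pl & tmp$direction == seg$direction]
    if (length(got_rom) && !(seg$segment == "trailing" && seg$direction == "rotation")) {
      expect_equal(got_rom, seg$rom, tolerance = 0.05 * seg$rom + 1e-3)
    }
  }
})
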
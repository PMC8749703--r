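test_that("t-test matches the closed-form pooled oracle on random samples", {
  set.seed(99)
  for (i in 1:1000) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -2, 2))
    got <- ttest_unpaired(a, b)
    ora <- pooled_t_oracle(a, b)
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }
})

test_that("t-test conventions and invariances hold", {
  a <- c(1, 2, 3)
  expect_equal(ttest_unpaired(a, a), list(t = 0, p = 1, significant = FALSE))
  # textbook case: pooled SD 1, df 4
  got <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  ora <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, ora$t, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  # location invariance
  set.seed(5)
  x <- rnorm(6); y <- rnorm(8)
  base <- ttest_unpaired(x, y)
  shifted <- ttest_unpaired(x + 17.3, y + 17.3)
  expect_equal(shifted$t, base$t, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
  # degenerate inputs
  expect_equal(ttest_unpaired(c(2, 2), c(2, 2))$p, 1)
  expect_equal(ttest_unpaired(c(2, 2), c(3, 3))$p, 0)
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
  expect_error(ttest_unpaired(c(1, NA, 2), c(1, 2)), "non-finite")
  # Welch variant agrees with stats::t.test default behaviour
  w <- ttest_unpaired(x, y, variant = "welch")
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})

test_that("reference-anchored percent differences reproduce the published values", {
  ref <- reference_temporal_summary()
  cyc <- ref[ref$parameter == "n_cycles", ]
  expect_equal(round(pct_diff_reference(cyc$mean_ss, cyc$mean_hi)), 67)
  dur <- ref[ref$parameter == "turn_duration", ]
  expect_equal(round(pct_diff_reference(dur$mean_ss, dur$mean_hi)), 106)
  sac <- ref[ref$parameter == "angular_velocity" & ref$placement == "sacrum", ]
  expect_equal(round(pct_diff_reference(sac$mean_hi, sac$mean_ss)), 46)
  ste <- ref[ref$parameter == "angular_velocity" & ref$placement == "sternum", ]
  expect_equal(round(pct_diff_reference(ste$mean_hi, ste$mean_ss)), 61)
  led <- ref[ref$parameter == "angular_velocity" &
               ref$placement == "shank_leading", ]
  expect_equal(round(pct_diff_reference(led$mean_hi, led$mean_ss)), 31)

  expect_equal(pct_diff_reference(4, 4), 0)
  expect_warning(out <- pct_diff_reference(1, 0), "zero reference")
  expect_true(is.na(out))
})

test_that("symmetric percent change reproduces the printed comparison cells", {
  expect_equal(round(pct_change_symmetric(0.77, 0.67)), -14)
  expect_equal(round(pct_change_symmetric(2.26, 1.13)), -67)
  expect_equal(round(pct_change_symmetric(0.38, 1.80)), 130)
  expect_equal(round(pct_change_symmetric(0.34, 0.10)), -109)
  expect_equal(round(pct_change_symmetric(10.64, 14.98)), 34)
  expect_equal(pct_change_symmetric(5, 5), 0)
  expect_warning(out <- pct_change_symmetric(-1, 1), "undefined")
  expect_true(is.na(out))

  # antisymmetry and the 200-magnitude bound for same-sign inputs
  set.seed(41)
  x1 <- runif(200, 0.01, 50); x2 <- runif(200, 0.01, 50)
  expect_equal(pct_change_symmetric(x1, x2), -pct_change_symmetric(x2, x1))
  expect_true(all(abs(pct_change_symmetric(x1, x2)) <= 200))
})

test_that("every printed comparison cell is reproduced within one unit", {
  ref <- reference_partition_means()
  expect_identical(nrow(ref), 50L)
  err2 <- abs(pct_change_symmetric(ref$k2_p1, ref$k2_p2) - ref$cmp2_2v1)
  err4 <- cbind(
    abs(pct_change_symmetric(ref$k4_p1, ref$k4_p2) - ref$cmp4_2v1),
    abs(pct_change_symmetric(ref$k4_p2, ref$k4_p3) - ref$cmp4_3v2),
    abs(pct_change_symmetric(ref$k4_p3, ref$k4_p4) - ref$cmp4_4v3)
  )
  expect_true(all(err2 <= 1))
  expect_true(all(err4 <= 1))
})

test_that("comparison tables summarize a cohort with the expected structure", {
  co <- generate_cohort(4, 4, seed = 77)
  feats <- do.call(rbind, lapply(co, function(tr) {
    process_trial(tr, pipeline_config(ks = c(2, 4)))$features
  }))
  tabs <- build_tables(feats)

  # 25 interval records + 3 scalars in the temporal table
  expect_identical(nrow(tabs$temporal), 28L)
  expect_identical(nrow(tabs$angular_velocity), 10L * (2L + 4L))
  expect_identical(nrow(tabs$range_of_motion), 6L * 6L)
  expect_identical(nrow(tabs$relative), 9L * 6L)
  expect_true(all(tabs$all$n_ss == 4 & tabs$all$n_hi == 4))
  expect_true(all(tabs$all$significant == (tabs$all$p_value < 0.05),
                  na.rm = TRUE))
  expect_true(all(is.na(tabs$temporal$cmp_ss)))
  # first spatial partition has no predecessor; later ones are recomputable
  av <- tabs$angular_velocity
  k2 <- av[av$scheme == "spatial_k2", ]
  expect_true(all(is.na(k2$cmp_ss[k2$partition_index == 1])))
  p1 <- k2[k2$partition_index == 1, ]
  p2 <- k2[k2$partition_index == 2, ]
  ord <- match(paste(p1$placement, p1$direction),
               paste(p2$placement, p2$direction))
  expect_equal(p2$cmp_hi[ord],
               pct_change_symmetric(p1$mean_hi, p2$mean_hi[ord]))

  # a single-parameter feature set yields a single-row table
  single <- feats[feats$parameter == "turn_duration", ]
  one <- build_tables(single)
  expect_identical(nrow(one$all), 1L)
  expect_false(one$all$missing_group)

  # one-group-only parameters are flagged, not dropped
  lop <- single[single$group == "SS", ]
  flagged <- build_tables(rbind(lop, feats[feats$parameter == "n_cycles", ]))
  expect_true(flagged$all$missing_group[flagged$all$parameter == "turn_duration"])
})
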
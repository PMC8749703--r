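# Noise-free profiles with point-mass draws, for constructive oracles.
quiet_profile <- function(group = "SS", n = 5, duration = 6, stance = 0.5,
                          peak = 8, total = c(360, 360), ...) {
  fun <- if (group == "SS") ss_profile else hi_profile
  fun(
    n_cycles = dist_spec(n, 0, min(n, 2), 12),
    duration = dist_spec(duration, 0, 1, 30),
    stance = dist_spec(stance, 0, 0.05, 0.95),
    swing_peak = dist_spec(peak, 0, 1, 30),
    total_rotation = total,
    noise_sd_gyro = 0, noise_sd_angle = 0,
    ...
  )
}

# Minimal hand-built trial for I/O tests: arbitrary smooth channels.
tiny_trial <- function(n = 150, fs = 60, id = "p1", group = "SS",
                       leading_side = "left", turn_direction = "ccw") {
  t <- seq(0, by = 1 / fs, length.out = n)
  placements <- c("sternum", "sacrum", "shank_left", "shank_right")
  mk <- function(k) {
    sensor_trace(
      placements[k], fs, t,
      gyro = cbind(sin(t + k), cos(2 * t + k), 0.1 * t),
      angle = cbind(cos(t) * k, sin(t) * k, t * k)
    )
  }
  traces <- setNames(lapply(1:4, mk), placements)
  turn_trial(id, group, leading_side, turn_direction, traces)
}

# Independent closed-form pooled-variance Student t oracle.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# True angle of the generator's S-curve rotation ramp at time t (absolute).
true_ramp_angle <- function(t, gt) {
  tau <- pmin(pmax((t - gt$turn_start) / gt$turn_duration, 0), 1)
  abs(gt$total_rotation) * (tau - sin(2 * pi * tau) / (2 * pi))
}
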
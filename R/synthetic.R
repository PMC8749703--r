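#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators have no hidden
#' side effects on the session.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# truncated-normal draw by rejection; the generator's error contract is that a
# profile whose bounds exclude essentially all mass is reported, not looped on
rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 1000L) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("profile inconsistent: degenerate draw outside truncation bounds",
           call. = FALSE)
    }
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop(sprintf(
    "profile inconsistent: %d rejections drawing N(%g, %g) in [%g, %g]",
    max_tries, mean, sd, lower, upper
  ), call. = FALSE)
}

#' Truncated-normal distribution specification
#'
#' @param mean,sd Location and spread (sd >= 0; 0 gives a point mass).
#' @param lower,upper Truncation bounds.
#' @return A list usable in [group_profile()] fields.
#' @export
dist_spec <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("SD must be >= 0", call. = FALSE)
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

#' Group generator profile
#'
#' Describes the distributions (truncated normals) from which a synthetic
#' turning trial's construction parameters are drawn. [ss_profile()] and
#' [hi_profile()] give the two study groups; their cycle-count, turn-duration
#' and stance-fraction distributions use the group means and SDs reported for
#' stroke survivors and healthy individuals in the temporal-segmentation
#' summary of the reference turning study (see `reference_temporal_summary()`),
#' and the trunk range-of-motion / angular-velocity scales are anchored to the
#' same source. Truncation bounds keep draws physical.
#'
#' @param group `"SS"` or `"HI"`.
#' @param fs Sampling rate in Hz.
#' @param pad_s Quiet-standing padding before and after the turn (s).
#' @param n_cycles,duration,stance,swing_peak [dist_spec]-style lists
#'   (`mean`, `sd`, `lower`, `upper`) for the cycle count, turn duration (s),
#'   stance fraction (0-1), and peak swing angular velocity (deg/s).
#' @param total_rotation Length-2 numeric: uniform bounds (deg) for the total
#'   covered rotation magnitude.
#' @param channels Named list of per-channel (`rom`, `av`) distribution pairs
#'   for the oscillatory channels; see the default for the structure.
#' @param noise_sd_gyro,noise_sd_angle Zero-mean Gaussian noise SD added to
#'   each gyro (deg/s) / angle (deg) channel.
#' @return A `group_profile` object.
#' @export
group_profile <- function(group,
                          fs = 60,
                          pad_s = 1.5,
                          n_cycles = dist_spec(4, 1, 2, 12),
                          duration = dist_spec(5, 2, 1.5, 20),
                          stance = dist_spec(0.45, 0.12, 0.05, 0.95),
                          swing_peak = dist_spec(7, 1.5, 3, 15),
                          total_rotation = c(340, 380),
                          channels = default_channels(group),
                          noise_sd_gyro = 0.1,
                          noise_sd_angle = 0.1) {
  group <- match.arg(group, c("SS", "HI"))
  stopifnot(fs > 0, pad_s >= 1,
            length(total_rotation) == 2L, all(total_rotation >= 90),
            noise_sd_gyro >= 0, noise_sd_angle >= 0)
  if (n_cycles$lower < 1) stop("n_cycles truncation must keep >= 1 cycle",
                               call. = FALSE)
  if (duration$lower <= 0) stop("duration truncation must keep > 0",
                                call. = FALSE)
  if (stance$lower < 0.05 || stance$upper > 0.95) {
    stop("stance truncation must stay inside (0.05, 0.95)", call. = FALSE)
  }
  structure(
    list(group = group, fs = fs, pad_s = pad_s, n_cycles = n_cycles,
         duration = duration, stance = stance, swing_peak = swing_peak,
         total_rotation = total_rotation, channels = channels,
         noise_sd_gyro = noise_sd_gyro, noise_sd_angle = noise_sd_angle),
    class = "group_profile"
  )
}

# Oscillatory-channel scales per group. Where the reference study prints a
# group mean (SD) for a ROM or angular velocity it is used directly; the
# remaining scales (trunk rotation ROM, shank auxiliary channels) are chosen
# as small plausible amplitudes of the same order as the printed velocities.
default_channels <- function(group) {
  if (group == "SS") {
    list(
      sternum = list(
        flexext  = list(rom = dist_spec(8.69, 2.90, 1, 30),
                        av  = dist_spec(0.89, 0.41, 0.05, 10)),
        lateral  = list(rom = dist_spec(11.51, 5.03, 1, 40),
                        av  = dist_spec(0.13, 0.10, 0.02, 5)),
        rotation = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.23, 0.20, 0.02, 5))
      ),
      sacrum = list(
        flexext  = list(rom = dist_spec(7.56, 2.73, 1, 30),
                        av  = dist_spec(0.97, 0.44, 0.05, 10)),
        lateral  = list(rom = dist_spec(8.88, 2.36, 1, 30),
                        av  = dist_spec(0.05, 0.03, 0.01, 5)),
        rotation = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.15, 0.10, 0.02, 5))
      ),
      leading = list(
        lateral  = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.13, 0.05, 0.02, 5)),
        rotation = list(rom = dist_spec(1.0, 0.3, 0.2, 10),
                        av  = dist_spec(0.06, 0.05, 0.01, 5))
      ),
      trailing = list(
        flexext  = list(rom = dist_spec(19.11, 6.49, 2, 50),
                        av  = dist_spec(0.86, 0.36, 0.05, 10)),
        lateral  = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.06, 0.04, 0.01, 5))
      )
    )
  } else {
    list(
      sternum = list(
        flexext  = list(rom = dist_spec(5.24, 1.84, 1, 30),
                        av  = dist_spec(1.43, 0.35, 0.05, 10)),
        lateral  = list(rom = dist_spec(7.30, 3.48, 1, 30),
                        av  = dist_spec(0.15, 0.09, 0.02, 5)),
        rotation = list(rom = dist_spec(3.5, 1.0, 0.5, 15),
                        av  = dist_spec(0.40, 0.24, 0.02, 5))
      ),
      sacrum = list(
        flexext  = list(rom = dist_spec(5.07, 1.28, 1, 30),
                        av  = dist_spec(1.42, 0.34, 0.05, 10)),
        lateral  = list(rom = dist_spec(7.31, 1.56, 1, 30),
                        av  = dist_spec(0.14, 0.14, 0.01, 5)),
        rotation = list(rom = dist_spec(3.5, 1.0, 0.5, 15),
                        av  = dist_spec(0.39, 0.26, 0.02, 5))
      ),
      leading = list(
        lateral  = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.15, 0.05, 0.02, 5)),
        rotation = list(rom = dist_spec(2.0, 0.5, 0.2, 10),
                        av  = dist_spec(0.23, 0.17, 0.01, 5))
      ),
      trailing = list(
        flexext  = list(rom = dist_spec(23.10, 11.45, 2, 60),
                        av  = dist_spec(1.70, 0.60, 0.05, 10)),
        lateral  = list(rom = dist_spec(2.0, 0.5, 0.5, 10),
                        av  = dist_spec(0.12, 0.08, 0.01, 5))
      )
    )
  }
}

#' Default stroke-survivor profile
#'
#' Cycle count 5.86 (1.56), turn duration 7.67 (3.17) s, stance fraction
#' 53.28 (13.59) %, per the reference study's stroke-survivor group.
#' @param ... Overrides passed to [group_profile()].
#' @return A `group_profile`.
#' @export
ss_profile <- function(...) {
  defaults <- list(
    group = "SS",
    n_cycles = dist_spec(5.86, 1.56, 2, 12),
    duration = dist_spec(7.67, 3.17, 2.5, 20),
    stance = dist_spec(0.5328, 0.1359, 0.05, 0.95),
    swing_peak = dist_spec(7.3, 1.5, 3, 15)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(group_profile, args)
}

#' Default healthy-individual profile
#'
#' Cycle count 3.5 (0.94), turn duration 3.72 (1.74) s, stance fraction
#' 38.96 (12.57) %, per the reference study's healthy group.
#' @param ... Overrides passed to [group_profile()].
#' @return A `group_profile`.
#' @export
hi_profile <- function(...) {
  defaults <- list(
    group = "HI",
    n_cycles = dist_spec(3.5, 0.94, 2, 12),
    duration = dist_spec(3.72, 1.74, 1.8, 15),
    stance = dist_spec(0.3896, 0.1257, 0.05, 0.95),
    swing_peak = dist_spec(7.0, 1.5, 3, 15)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(group_profile, args)
}

# -- channel construction ----------------------------------------------------

# Oscillatory angle channel: R/2 * cos(2*pi*fp*(t - t0)) inside the turn,
# clamped to its endpoint values outside. fp is snapped so an integer number of
# half-periods spans the turn: ROM then equals `rom` exactly and the mean
# absolute angular velocity equals 2 * rom * fp analytically.
make_sinusoid <- function(t, t0, D, rom, av) {
  f <- av / (2 * rom)
  m <- max(1L, round(2 * f * D))
  fp <- m / (2 * D)
  w <- 2 * pi * fp
  tau <- pmin(pmax(t - t0, 0), D)
  list(
    angle = (rom / 2) * cos(w * tau),
    gyro = -(rom / 2) * w * sin(w * tau),   # zero at both ends: C1 continuous
    rom = rom, av = 2 * rom * fp, freq = fp, half_periods = m
  )
}

# Leading-shank swing train: n raised-cosine pulses of width `width` and peak
# `peak`, one per cycle of period `period`, first toe-off at t0. The angle
# channel is the running integral (piecewise analytic), so gyro and angle are
# mutually consistent.
make_pulse_train <- function(t, t0, n, period, width, peak) {
  rel <- t - t0
  i <- floor(rel / period)          # cycle index
  x <- rel - i * period             # time into current cycle
  in_pulse <- rel >= 0 & i < n & x < width
  gyro <- numeric(length(t))
  gyro[in_pulse] <- (peak / 2) * (1 - cos(2 * pi * x[in_pulse] / width))
  pulse_area <- peak * width / 2
  angle <- numeric(length(t))
  done <- pmax(pmin(i, n), 0)       # completed pulses before current cycle
  angle <- done * pulse_area
  angle[in_pulse] <- i[in_pulse] * pulse_area +
    (peak / 2) * (x[in_pulse] - (width / (2 * pi)) *
                    sin(2 * pi * x[in_pulse] / width))
  D <- (n - 1) * period + width
  list(gyro = gyro, angle = angle,
       rom = n * pulse_area, av = n * pulse_area / D)
}

# Monotone S-curve rotation ramp covering `total` degrees over [t0, t0 + D]:
# theta(tau) = total * (tau - sin(2*pi*tau)/(2*pi)), tau in [0, 1]. Its rate is
# total/D * (1 - cos(2*pi*tau)) >= 0, zero at both ends.
make_rotation_ramp <- function(t, t0, D, total) {
  tau <- pmin(pmax((t - t0) / D, 0), 1)
  list(
    angle = total * (tau - sin(2 * pi * tau) / (2 * pi)),
    gyro = (total / D) * (1 - cos(2 * pi * tau)),
    rom = abs(total), av = abs(total) / D
  )
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Generate one synthetic turning trial with ground truth
#'
#' Constructs a four-sensor trial whose leading-shank flexion-extension
#' angular velocity is a train of raised-cosine (bell-shaped) swing pulses
#' separated by stance intervals, whose trailing-shank axial rotation is a
#' monotone S-curve ramp covering the drawn total rotation (stored wrapped to
#' +/-180 deg, as an orientation sensor would report it), and whose remaining
#' channels are smooth oscillations achieving the drawn range of motion and
#' mean absolute angular velocity. Zero-mean Gaussian noise is added per
#' channel and at least one second of quiet standing pads the turn on each
#' side. Every construction quantity is recorded exactly in the returned
#' trial's `ground_truth`.
#'
#' @param profile A [group_profile()].
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param participant_id Identifier; default derives from the seed.
#' @param leading_side `"left"`/`"right"`, or `NULL` to draw at random.
#' @param turn_direction `"cw"`/`"ccw"`, or `NULL` to draw at random.
#' @return A `turn_trial` with a `ground_truth` list: `n_cycles`,
#'   `swing_intervals` (toe-off / heel-strike times, s), `turn_start`,
#'   `turn_duration`, `stance_fraction` (per cycle), `total_rotation` (signed
#'   deg), `segments` (analytic per-segment, per-direction ROM and mean
#'   absolute angular velocity over the turn), and the drawn `params`.
#' @export
generate_trial <- function(profile, seed, participant_id = NULL,
                           leading_side = NULL, turn_direction = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  with_seed(seed, {
    side <- leading_side %||% sample(c("left", "right"), 1L)
    dir <- turn_direction %||% sample(c("cw", "ccw"), 1L)

    draw <- function(d) rtrunc_norm(d$mean, d$sd, d$lower, d$upper)
    n <- max(round(draw(profile$n_cycles)), round(profile$n_cycles$lower))
    D <- draw(profile$duration)
    sf <- draw(profile$stance)
    peak <- draw(profile$swing_peak)
    total_mag <- stats::runif(1L, profile$total_rotation[1L],
                              profile$total_rotation[2L])
    total <- if (dir == "cw") -total_mag else total_mag

    fs <- profile$fs
    t0 <- profile$pad_s
    period <- D / (n - sf)          # toe-off to toe-off
    width <- (1 - sf) * period      # swing (pulse) width
    n_samp <- ceiling((D + 2 * profile$pad_s) * fs) + 1L
    t <- seq(0, by = 1 / fs, length.out = n_samp)

    draw_pair <- function(pair) {
      list(rom = draw(pair$rom), av = draw(pair$av))
    }

    # --- construct channels --------------------------------------------
    pr <- profile$channels
    built <- list()   # per role: list(flexext=, lateral=, rotation=)
    for (role in c("sternum", "sacrum")) {
      built[[role]] <- lapply(pr[[role]], function(pair) {
        p <- draw_pair(pair)
        make_sinusoid(t, t0, D, p$rom, p$av)
      })
    }
    pulses <- make_pulse_train(t, t0, n, period, width, peak)
    built$leading <- list(
      flexext = pulses,
      lateral = {
        p <- draw_pair(pr$leading$lateral); make_sinusoid(t, t0, D, p$rom, p$av)
      },
      rotation = {
        p <- draw_pair(pr$leading$rotation); make_sinusoid(t, t0, D, p$rom, p$av)
      }
    )
    ramp <- make_rotation_ramp(t, t0, D, total)
    built$trailing <- list(
      flexext = {
        p <- draw_pair(pr$trailing$flexext); make_sinusoid(t, t0, D, p$rom, p$av)
      },
      lateral = {
        p <- draw_pair(pr$trailing$lateral); make_sinusoid(t, t0, D, p$rom, p$av)
      },
      rotation = ramp
    )

    # --- assemble traces ------------------------------------------------
    add_noise <- function(x, sd) if (sd > 0) x + stats::rnorm(length(x), 0, sd) else x
    role_of <- c(sternum = "sternum", sacrum = "sacrum")
    role_of[[if (side == "left") "shank_left" else "shank_right"]] <- "leading"
    role_of[[if (side == "left") "shank_right" else "shank_left"]] <- "trailing"

    traces <- lapply(stats::setNames(PLACEMENTS, PLACEMENTS), function(pl) {
      role <- role_of[[pl]]
      ch <- built[[role]]
      gyro <- cbind(flexext = ch$flexext$gyro, lateral = ch$lateral$gyro,
                    rotation = ch$rotation$gyro)
      angle <- cbind(flexext = ch$flexext$angle, lateral = ch$lateral$angle,
                     rotation = ch$rotation$angle)
      gyro <- apply(gyro, 2L, add_noise, sd = profile$noise_sd_gyro)
      angle <- apply(angle, 2L, add_noise, sd = profile$noise_sd_angle)
      if (role %in% c("leading", "trailing")) {
        # orientation sensors report yaw wrapped to +/-180 deg
        angle[, "rotation"] <- wrap180(angle[, "rotation"])
      }
      sensor_trace(pl, fs, t, gyro, angle)
    })

    toe_off <- t0 + (seq_len(n) - 1L) * period
    segments <- do.call(rbind, lapply(names(built), function(role) {
      data.frame(
        segment = role,
        direction = DIRECTIONS,
        rom = vapply(built[[role]][DIRECTIONS], `[[`, numeric(1), "rom"),
        mean_abs_av = vapply(built[[role]][DIRECTIONS], `[[`, numeric(1), "av"),
        row.names = NULL
      )
    }))

    gt <- list(
      n_cycles = n,
      swing_intervals = cbind(toe_off = toe_off, heel_strike = toe_off + width),
      turn_start = t0,
      turn_duration = D,
      stance_fraction = rep(sf, max(n - 1L, 1L)),
      total_rotation = total,
      segments = segments,
      params = list(seed = seed, cycle_period = period, swing_width = width,
                    swing_peak = peak, stance = sf,
                    channel_freqs = lapply(built, function(b)
                      vapply(b, function(ch) ch$freq %||% NA_real_, numeric(1))))
    )

    turn_trial(
      participant_id = participant_id %||% sprintf("sim%08d", abs(seed) %% 1e8),
      group = profile$group, leading_side = side, turn_direction = dir,
      traces = traces, ground_truth = gt
    )
  })
}

#' Generate a two-group synthetic cohort
#'
#' Draws independent trials with per-trial seeds derived deterministically
#' from the master seed, so the whole cohort is reproducible.
#'
#' @param n_ss,n_hi Number of stroke-survivor / healthy trials (>= 1).
#' @param seed Master integer seed.
#' @param profile_ss,profile_hi Group profiles.
#' @return List of `turn_trial` objects (SS first), with participant ids
#'   `SS01, ..., HI01, ...`.
#' @export
generate_cohort <- function(n_ss, n_hi, seed,
                            profile_ss = ss_profile(),
                            profile_hi = hi_profile()) {
  stopifnot(n_ss >= 1L, n_hi >= 1L)
  n <- n_ss + n_hi
  trial_seeds <- with_seed(seed, sample.int(2147483646L, n))
  ids <- c(sprintf("SS%02d", seq_len(n_ss)), sprintf("HI%02d", seq_len(n_hi)))
  profs <- c(rep(list(profile_ss), n_ss), rep(list(profile_hi), n_hi))
  lapply(seq_len(n), function(i) {
    generate_trial(profs[[i]], trial_seeds[i], participant_id = ids[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
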
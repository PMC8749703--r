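#' Swing-detection parameters
#'
#' @param prominence_frac Minimum peak prominence as a fraction of the global
#'   signal maximum for a local maximum to count as mid-swing.
#' @param onset_frac Fraction of a peak's height at which the swing onset /
#'   offset threshold is placed on each side.
#' @param min_separation_s Minimum time between mid-swing peaks (s).
#' @param extrapolate_base Extrapolate from the two threshold crossings to the
#'   pulse base using the bell-pulse geometry the detector assumes: for a
#'   raised-cosine swing, the crossings at fraction `q` of the peak sit
#'   `acos(1 - 2q) / (2 * pi)` of the pulse width inside each edge, so the
#'   base is recovered by widening the crossing interval accordingly. This
#'   counteracts the inward bias of raw threshold crossings; without it,
#'   toe-off / heel-strike are placed at the crossings themselves.
#' @return A `detection_params` list.
#' @export
detection_params <- function(prominence_frac = 0.3, onset_frac = 0.1,
                             min_separation_s = 0.3, extrapolate_base = TRUE) {
  stopifnot(prominence_frac > 0, prominence_frac < 1,
            onset_frac > 0, onset_frac < 1, min_separation_s >= 0)
  structure(list(prominence_frac = prominence_frac, onset_frac = onset_frac,
                 min_separation_s = min_separation_s,
                 extrapolate_base = isTRUE(extrapolate_base)),
            class = "detection_params")
}

# local maxima with their topographic prominence
find_peaks <- function(x) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(data.frame(idx = integer(), prominence = numeric()))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    hi_l <- which(left > h)
    base_l <- min(left[seq.int(if (length(hi_l)) max(hi_l) else 1L, i - 1L)])
    right <- x[seq.int(i + 1L, n)]
    hi_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) else n - i)])
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(idx = cand, prominence = prom)
}

#' Detect swing cycles of the leading shank
#'
#' Mid-swing events are local maxima of the (sign-normalized, filtered)
#' flexion-extension angular velocity whose prominence is at least
#' `prominence_frac` of the global maximum and that are separated by at least
#' `min_separation_s`. Toe-off and heel-strike bound each swing: the nearest
#' samples on each side of the peak where the signal falls below
#' `onset_frac` times that peak's height, by default widened to the estimated
#' pulse base via the bell-pulse geometry (see [detection_params()]).
#' Overlapping assignments between adjacent swings are resolved at the
#' midpoint between their peaks.
#'
#' @param gyro_flexext Filtered flexion-extension angular velocity (deg/s) of
#'   the leading shank.
#' @param fs Sampling rate in Hz.
#' @param params A [detection_params()].
#' @return A `gait_events` list: `mid_swing_idx`, `toe_off_idx`,
#'   `heel_strike_idx`, `cycle_bounds` (toe-off to toe-off), `stance_fraction`
#'   (per cycle, in (0,1)), `fs`.
#' @export
detect_swings <- function(gyro_flexext, fs, params = detection_params()) {
  x <- as.numeric(gyro_flexext)
  if (max(x) < -min(x)) x <- -x   # swings are positive maxima by convention
  pk <- find_peaks(x)
  pk <- pk[pk$prominence >= params$prominence_frac * max(x), , drop = FALSE]
  if (!nrow(pk)) stop("no swings detected", call. = FALSE)

  # enforce minimum separation, keeping the taller peak
  min_gap <- round(params$min_separation_s * fs)
  keep <- pk$idx[order(-x[pk$idx])]
  sel <- integer()
  for (i in keep) if (!length(sel) || all(abs(sel - i) >= min_gap)) {
    sel <- c(sel, i)
  }
  mid <- sort(sel)
  n <- length(mid)
  if (n < 2L) {
    warning("fewer than 2 swings detected: stance fraction undefined",
            call. = FALSE)
  }

  bound_one <- function(p, side) {
    thr <- params$onset_frac * x[p]
    if (side == "left") {
      below <- which(x[seq_len(p - 1L)] < thr)
      if (length(below)) max(below) else 1L
    } else {
      below <- which(x[seq.int(p + 1L, length(x))] < thr)
      if (length(below)) p + min(below) else length(x)
    }
  }
  toe_off <- vapply(mid, bound_one, numeric(1), side = "left")
  heel_strike <- vapply(mid, bound_one, numeric(1), side = "right")
  if (params$extrapolate_base) {
    # raised-cosine geometry: crossings at fraction q of peak height sit
    # u = acos(1 - 2q) / (2*pi) of the pulse width inside each edge
    u <- acos(1 - 2 * params$onset_frac) / (2 * pi)
    ext <- u / (1 - 2 * u)
    span <- heel_strike - toe_off
    toe_off <- pmax(1, round(toe_off - ext * span))
    heel_strike <- pmin(length(x), round(heel_strike + ext * span))
    toe_off <- pmin(toe_off, mid - 1L)        # keep toe-off < mid-swing
    heel_strike <- pmax(heel_strike, mid + 1L)
  }
  toe_off <- as.integer(toe_off); heel_strike <- as.integer(heel_strike)

  # midpoint rule for overlapping adjacent assignments
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (heel_strike[i] >= toe_off[i + 1L]) {
        m <- (mid[i] + mid[i + 1L]) %/% 2L
        heel_strike[i] <- m
        toe_off[i + 1L] <- m + 1L
      }
    }
  }

  cycle_bounds <- if (n >= 2L) {
    cbind(start = toe_off[-n], end = toe_off[-1L])
  } else {
    cbind(start = integer(), end = integer())
  }
  stance <- if (n >= 2L) {
    num <- toe_off[-1L] - heel_strike[-n]
    den <- toe_off[-1L] - toe_off[-n]
    frac <- num / den
    bad <- which(frac <= 0)
    if (length(bad)) {
      message(sprintf("excluding %d cycle(s) with heel-strike at/after next toe-off",
                      length(bad)))
      frac[bad] <- NA_real_
    }
    frac
  } else {
    numeric()
  }

  ev <- structure(
    list(mid_swing_idx = mid, toe_off_idx = toe_off,
         heel_strike_idx = heel_strike, cycle_bounds = cycle_bounds,
         stance_fraction = stance, fs = fs),
    class = "gait_events"
  )
  validate_gait_events(ev, length(x))
  ev
}

validate_gait_events <- function(ev, n_samples) {
  with(ev, {
    stopifnot(length(toe_off_idx) == length(mid_swing_idx),
              length(heel_strike_idx) == length(mid_swing_idx))
    if (any(toe_off_idx >= mid_swing_idx) ||
        any(mid_swing_idx >= heel_strike_idx)) {
      stop("event ordering violated: need toe-off < mid-swing < heel-strike",
           call. = FALSE)
    }
    if (is.unsorted(c(rbind(toe_off_idx, mid_swing_idx, heel_strike_idx)),
                    strictly = TRUE)) {
      stop("events must be strictly increasing across cycles", call. = FALSE)
    }
    if (any(c(toe_off_idx, heel_strike_idx) < 1L) ||
        any(c(toe_off_idx, heel_strike_idx) > n_samples)) {
      stop("event index out of signal bounds", call. = FALSE)
    }
  })
  invisible(ev)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d swing(s); mean stance %.1f%%\n",
              length(x$mid_swing_idx),
              100 * mean(x$stance_fraction, na.rm = TRUE)))
  invisible(x)
}

#' Number of gait cycles in the turn
#'
#' @param events A `gait_events` object.
#' @return Integer count of mid-swing events.
#' @export
n_cycles <- function(events) length(events$mid_swing_idx)

#' Turn duration
#'
#' Time from the first toe-off to the last heel-strike.
#'
#' @param events A `gait_events` object.
#' @param fs Sampling rate in Hz (defaults to the rate stored in `events`).
#' @return Duration in seconds.
#' @export
turn_duration <- function(events, fs = events$fs) {
  (events$heel_strike_idx[length(events$heel_strike_idx)] -
     events$toe_off_idx[1L]) / fs
}

#' Stance-phase portion per cycle
#'
#' A cycle runs toe-off to toe-off; its stance phase is the interval from the
#' heel-strike closing the swing to the next toe-off. With n swings this gives
#' n - 1 stance values.
#'
#' @param events A `gait_events` object.
#' @return List with `per_cycle` (percent, invalid cycles `NA`) and `mean`
#'   (percent).
#' @export
stance_fraction <- function(events) {
  if (length(events$mid_swing_idx) < 2L) {
    stop("stance fraction needs at least 2 swings", call. = FALSE)
  }
  pct <- 100 * events$stance_fraction
  list(per_cycle = pct, mean = mean(pct, na.rm = TRUE))
}
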
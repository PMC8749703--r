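#' Low-pass filter specification
#'
#' Defaults follow common practice for human-movement IMU signals: a 4th-order
#' Butterworth low-pass at 5 Hz, applied forward-backward (zero phase) so that
#' detected event times are not lag-shifted. Forward-backward application
#' squares the magnitude response, doubling the effective attenuation.
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cut-off frequency in Hz.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single-pass.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(order = 4L, cutoff = 5, zero_phase = TRUE) {
  stopifnot(order >= 1L, cutoff > 0, is.logical(zero_phase))
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth low-pass filter
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, fs, spec = filter_spec()) {
  if (spec$cutoff >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 spec$cutoff, fs / 2), call. = FALSE)
  }
  if (length(x) <= 3L * spec$order) {
    stop("signal too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  n <- length(x)
  # Odd-reflection padding long enough for the slowest pole's start-up
  # transient to decay below 1e-12, so edges are handled cleanly even for
  # signals with a large offset or net drift (e.g. a 360-degree rotation ramp).
  pmax <- max(Mod(polyroot(rev(bf$a))))
  npad <- min(n - 1L, max(3L * spec$order, ceiling(log(1e-12) / log(pmax))))
  z <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  pass <- function(v) {
    # subtracting the first sample makes the zero-initial-condition start
    # exact for the filter's unit DC gain
    as.numeric(signal::filter(bf, v - v[1L])) + v[1L]
  }
  y <- pass(z)
  if (spec$zero_phase) y <- rev(pass(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Magnitude response of the low-pass filter at given frequencies
#'
#' Evaluates the designed digital filter's transfer function on the unit
#' circle; for zero-phase application the single-pass magnitude is squared.
#' Used as the analytic reference for filter checks.
#'
#' @inheritParams lowpass
#' @param f Frequencies in Hz.
#' @return Magnitude gain at each frequency.
#' @export
lowpass_gain <- function(f, fs, spec = filter_spec()) {
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * f / fs)
  h <- vapply(z, function(zi) {
    sum(bf$b * zi^(seq_along(bf$b) - 1L)) /
      sum(bf$a * zi^(seq_along(bf$a) - 1L))
  }, complex(1))
  g <- Mod(h)
  if (spec$zero_phase) g^2 else g
}

#' Unwrap angle discontinuities (degrees)
#'
#' Removes jumps larger than 180 deg between consecutive samples by adding the
#' appropriate multiple of 360 deg.
#'
#' @param x Angle series in degrees.
#' @return Unwrapped series.
#' @export
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1L], x[1L] + cumsum(d))
}

#' Cumulative rotation of a shank during the turn
#'
#' Unwraps +/-180 deg discontinuities, subtracts the initial value, and flips
#' the sign so the turn is positive regardless of its direction. The result
#' starts at 0 and ends near the total covered rotation.
#'
#' @param angle_rotation Axial-rotation angle series (degrees) from a shank
#'   trace.
#' @param turn_direction `"cw"`, `"ccw"`, or `"auto"` (sign of the net
#'   displacement decides the flip).
#' @return Numeric series starting at 0, non-decreasing up to noise.
#' @export
cumulative_rotation <- function(angle_rotation, turn_direction = "auto") {
  turn_direction <- match.arg(turn_direction, c("auto", "cw", "ccw"))
  u <- unwrap_deg(angle_rotation)
  u <- u - u[1L]
  flip <- switch(turn_direction,
    auto = u[length(u)] < 0,
    cw = TRUE,   # clockwise turns accumulate negative yaw in this convention
    ccw = FALSE
  )
  if (flip) -u else u
}

#' Axis map: raw device axes to anatomical channels
#'
#' Declares, per placement, which raw column (with optional sign flip) carries
#' each anatomical direction. The identity map is the default, matching the
#' synthetic generator's output. A mapping entry is a named character vector,
#' e.g. `c(flexext = "-2", lateral = "1", rotation = "3")` maps the negated
#' second raw column to flexion-extension.
#'
#' @param ... Named per-placement mapping entries; unnamed placements use the
#'   identity.
#' @return An `axis_map` object (named list of 3-element integer vectors with
#'   signs encoded).
#' @export
axis_map <- function(...) {
  entries <- list(...)
  maps <- stats::setNames(
    rep(list(c(flexext = 1L, lateral = 2L, rotation = 3L)), length(PLACEMENTS)),
    PLACEMENTS
  )
  for (nm in names(entries)) {
    if (!nm %in% PLACEMENTS) {
      stop("unknown placement in axis map: ", nm, call. = FALSE)
    }
    ent <- entries[[nm]]
    if (!all(DIRECTIONS %in% names(ent))) {
      stop("axis map entry for ", nm, " must name all of: ",
           paste(DIRECTIONS, collapse = ", "), call. = FALSE)
    }
    idx <- as.integer(ent[DIRECTIONS])
    if (any(is.na(idx)) || any(abs(idx) < 1L) || any(abs(idx) > 3L)) {
      stop("axis map entries must be signed column indices in -3..3",
           call. = FALSE)
    }
    if (length(unique(abs(idx))) != 3L) {
      stop("axis map entry for ", nm, " must be a permutation of columns 1..3",
           call. = FALSE)
    }
    maps[[nm]] <- stats::setNames(idx, DIRECTIONS)
  }
  structure(maps, class = "axis_map")
}

#' Apply an axis map to raw 3-axis channels
#'
#' @param placement Sensor placement.
#' @param m Numeric matrix with 3 raw columns.
#' @param map An [axis_map()].
#' @return Matrix with columns relabeled/permuted to
#'   (`flexext`, `lateral`, `rotation`).
#' @export
apply_axis_map <- function(placement, m, map = axis_map()) {
  if (!placement %in% PLACEMENTS) {
    stop("unknown placement: ", placement, call. = FALSE)
  }
  idx <- map[[placement]]
  out <- m[, abs(idx), drop = FALSE]
  out <- sweep(out, 2L, sign(idx), `*`)
  colnames(out) <- DIRECTIONS
  out
}

#' Filter all channels of a trial
#'
#' Applies the low-pass filter to every gyro and angle channel of every trace.
#' Shank axial-rotation angles are unwrapped before filtering so that the
#' +/-180 deg representation does not smear across wrap points; unwrapping is
#' the identity for channels that never wrap.
#'
#' @param trial A `turn_trial`.
#' @param spec A [filter_spec()].
#' @return The trial with filtered channels (ground truth carried over).
#' @export
preprocess_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "turn_trial"))
  trial$traces <- lapply(trial$traces, function(tr) {
    for (j in seq_len(3L)) {
      tr$gyro[, j] <- lowpass(tr$gyro[, j], tr$fs, spec)
      tr$angle[, j] <- lowpass(unwrap_deg(tr$angle[, j]), tr$fs, spec)
    }
    tr
  })
  trial
}
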
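#' Anatomical channel labels
#'
#' All sensor channels are stored with anatomical semantics (flexion-extension,
#' lateral bending, axial rotation) rather than raw device axes, so downstream
#' code is placement-agnostic.
#' @keywords internal
DIRECTIONS <- c("flexext", "lateral", "rotation")

#' Sensor placements of the four-IMU configuration
#' @keywords internal
PLACEMENTS <- c("sternum", "sacrum", "shank_left", "shank_right")

#' Construct a sensor trace
#'
#' A `sensor_trace` holds one placement's synchronized angular-velocity and
#' orientation-angle channels, each a numeric matrix with columns
#' `flexext`, `lateral`, `rotation` (degrees/s and degrees respectively).
#'
#' @param placement One of `"sternum"`, `"sacrum"`, `"shank_left"`,
#'   `"shank_right"`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t Time vector in seconds, strictly increasing with spacing
#'   approximately `1/fs` (1% tolerance).
#' @param gyro Numeric matrix (`length(t)` x 3) of angular velocity in deg/s.
#' @param angle Numeric matrix (`length(t)` x 3) of orientation angles in deg.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(placement, fs, t, gyro, angle) {
  placement <- match.arg(placement, PLACEMENTS)
  gyro <- as_channel_matrix(gyro, "gyro")
  angle <- as_channel_matrix(angle, "angle")
  x <- structure(
    list(placement = placement, fs = fs, t = as.numeric(t),
         gyro = gyro, angle = angle),
    class = "sensor_trace"
  )
  validate_sensor_trace(x)
  x
}

as_channel_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) {
    stop(sprintf("'%s' must have exactly 3 columns, got %d", what, ncol(m)),
         call. = FALSE)
  }
  colnames(m) <- DIRECTIONS
  storage.mode(m) <- "double"
  m
}

validate_sensor_trace <- function(x) {
  stopifnot(inherits(x, "sensor_trace"))
  n <- length(x$t)
  if (n < 2L) stop("sensor_trace needs at least 2 samples", call. = FALSE)
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (nrow(x$gyro) != n || nrow(x$angle) != n) {
    stop("all channels must have the same length as the time vector",
         call. = FALSE)
  }
  dt <- diff(x$t)
  if (any(dt <= 0)) {
    stop("time vector must be strictly increasing (dropped/duplicated samples?)",
         call. = FALSE)
  }
  if (any(abs(dt - 1 / x$fs) > 0.01 / x$fs)) {
    bad <- which(abs(dt - 1 / x$fs) > 0.01 / x$fs)[1L]
    stop(sprintf(
      "time spacing deviates from 1/fs by more than 1%% at sample %d", bad + 1L
    ), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %s: %d samples @ %g Hz (%.2f s)\n",
              x$placement, length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

#' Construct a turning trial
#'
#' A `turn_trial` bundles one participant's four sensor traces with trial
#' metadata and, for synthetic trials, the construction ground truth.
#'
#' @param participant_id Character scalar.
#' @param group `"SS"` (stroke survivor) or `"HI"` (healthy individual).
#' @param leading_side `"left"` or `"right"`: the leg initiating the turn
#'   (the unaffected side in stroke survivors).
#' @param turn_direction `"cw"` or `"ccw"`.
#' @param traces Named list with exactly one `sensor_trace` per placement.
#' @param ground_truth Optional list recording the generator's construction
#'   parameters (see [generate_trial()]); `NULL` for measured data.
#' @return An object of class `turn_trial`.
#' @export
turn_trial <- function(participant_id, group, leading_side, turn_direction,
                       traces, ground_truth = NULL) {
  group <- match.arg(group, c("SS", "HI"))
  leading_side <- match.arg(leading_side, c("left", "right"))
  turn_direction <- match.arg(turn_direction, c("cw", "ccw"))
  missing_tr <- setdiff(PLACEMENTS, names(traces))
  if (length(missing_tr)) {
    stop("missing trace(s) for placement: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  traces <- traces[PLACEMENTS]
  for (tr in traces) validate_sensor_trace(tr)
  fs <- vapply(traces, function(tr) tr$fs, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("all traces must share one sampling rate", call. = FALSE)
  }
  n <- vapply(traces, function(tr) length(tr$t), integer(1))
  if (length(unique(n)) != 1L ||
      max(vapply(traces, function(tr) max(abs(tr$t - traces[[1L]]$t)),
                 numeric(1))) > 1e-9) {
    stop("all traces must share an identical time base", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         leading_side = leading_side, turn_direction = turn_direction,
         traces = traces, ground_truth = ground_truth),
    class = "turn_trial"
  )
}

#' @export
print.turn_trial <- function(x, ...) {
  cat(sprintf(
    "<turn_trial> %s [%s] leading=%s dir=%s, %d samples @ %g Hz%s\n",
    x$participant_id, x$group, x$leading_side, x$turn_direction,
    length(x$traces[[1L]]$t), x$traces[[1L]]$fs,
    if (is.null(x$ground_truth)) "" else ", with ground truth"
  ))
  invisible(x)
}

#' Leading / trailing shank placement of a trial
#'
#' @param trial A `turn_trial`.
#' @return Placement string (`"shank_left"` or `"shank_right"`).
#' @export
leading_placement <- function(trial) {
  if (trial$leading_side == "left") "shank_left" else "shank_right"
}

#' @rdname leading_placement
#' @export
trailing_placement <- function(trial) {
  if (trial$leading_side == "left") "shank_right" else "shank_left"
}
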
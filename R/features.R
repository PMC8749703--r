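#' Parameter names emitted by [extract_all()]
#'
#' Angular velocities are summarized as the mean of the absolute signal (the
#' published group values are all positive; signed means would cancel over an
#' oscillation), range of motion as max minus min of the angle.
#' @keywords internal
PARAMETERS <- c(
  "n_cycles", "turn_duration", "stance_pct",
  "angular_velocity", "range_of_motion",
  "rel_angular_velocity", "rel_range_of_motion",
  "ratio_angular_velocity", "ratio_range_of_motion"
)

as_interval <- function(interval, n) {
  interval <- as.integer(interval)
  if (length(interval) != 2L || interval[1L] > interval[2L] ||
      interval[1L] < 1L || interval[2L] > n) {
    stop("empty or out-of-bounds interval", call. = FALSE)
  }
  interval
}

#' Mean absolute angular velocity over an interval
#'
#' @param gyro Angular velocity channel (deg/s).
#' @param interval Inclusive sample-index pair `c(start, end)`.
#' @return Mean of `|gyro|` over the interval (deg/s).
#' @export
mean_abs_angular_velocity <- function(gyro, interval) {
  iv <- as_interval(interval, length(gyro))
  mean(abs(gyro[iv[1L]:iv[2L]]))
}

#' Range of motion over an interval
#'
#' @param angle Orientation angle channel (deg).
#' @param interval Inclusive sample-index pair `c(start, end)`.
#' @return `max - min` of the angle over the interval (deg).
#' @export
range_of_motion <- function(angle, interval) {
  iv <- as_interval(interval, length(angle))
  diff(range(angle[iv[1L]:iv[2L]]))
}

#' Relative sternum-minus-sacrum signal
#'
#' Computes the per-sample difference of the named channel, which downstream
#' operations treat as a derived channel for ROM and mean absolute angular
#' velocity. Summaries of the difference signal are not differences of the
#' per-segment summaries.
#'
#' @param sternum,sacrum Two time-aligned `sensor_trace` objects.
#' @param direction One of `"flexext"`, `"lateral"`, `"rotation"`.
#' @param what `"gyro"` or `"angle"`.
#' @return Numeric difference signal (sternum - sacrum).
#' @export
relative_trace <- function(sternum, sacrum, direction, what = c("gyro", "angle")) {
  what <- match.arg(what)
  direction <- match.arg(direction, DIRECTIONS)
  a <- sternum[[what]][, direction]
  b <- sacrum[[what]][, direction]
  if (length(a) != length(b)) stop("trace length mismatch", call. = FALSE)
  a - b
}

#' Leading-to-trailing leg ratio
#'
#' @param leading,trailing Non-negative summary values (e.g. mean absolute
#'   angular velocities of the two shanks).
#' @param eps Values of `trailing` at or below this are treated as undefined.
#' @return `leading / trailing`, or `NA` (with a warning) when undefined.
#' @export
leg_ratio <- function(leading, trailing, eps = 1e-9) {
  if (!is.finite(trailing) || trailing <= eps) {
    warning("leg ratio undefined: trailing value at or below epsilon",
            call. = FALSE)
    return(NA_real_)
  }
  leading / trailing
}

# the 25 per-interval records shared by every scheme
interval_records <- function(trial, interval) {
  tr <- trial$traces
  lead <- tr[[leading_placement(trial)]]
  trail <- tr[[trailing_placement(trial)]]
  rec <- list()
  add <- function(parameter, placement, direction, value) {
    rec[[length(rec) + 1L]] <<- data.frame(
      parameter = parameter, placement = placement,
      direction = direction, value = value
    )
  }
  for (seg in c("sternum", "sacrum")) {
    for (d in DIRECTIONS) {
      add("angular_velocity", seg, d,
          mean_abs_angular_velocity(tr[[seg]]$gyro[, d], interval))
    }
    for (d in c("flexext", "lateral")) {
      add("range_of_motion", seg, d,
          range_of_motion(tr[[seg]]$angle[, d], interval))
    }
  }
  for (d in DIRECTIONS) {
    add("rel_angular_velocity", "sternum_sacrum", d,
        mean_abs_angular_velocity(
          relative_trace(tr$sternum, tr$sacrum, d, "gyro"), interval))
    add("rel_range_of_motion", "sternum_sacrum", d,
        range_of_motion(
          relative_trace(tr$sternum, tr$sacrum, d, "angle"), interval))
  }
  shank <- list(shank_leading = lead, shank_trailing = trail)
  for (pl in names(shank)) {
    for (d in c("flexext", "rotation")) {
      add("angular_velocity", pl, d,
          mean_abs_angular_velocity(shank[[pl]]$gyro[, d], interval))
    }
    add("range_of_motion", pl, "flexext",
        range_of_motion(shank[[pl]]$angle[, "flexext"], interval))
  }
  for (d in c("flexext", "rotation")) {
    add("ratio_angular_velocity", "leading_trailing", d,
        leg_ratio(mean_abs_angular_velocity(lead$gyro[, d], interval),
                  mean_abs_angular_velocity(trail$gyro[, d], interval)))
  }
  add("ratio_range_of_motion", "leading_trailing", "flexext",
      leg_ratio(range_of_motion(lead$angle[, "flexext"], interval),
                range_of_motion(trail$angle[, "flexext"], interval)))
  do.call(rbind, rec)
}

#' Extract the full kinematic parameter set of one trial
#'
#' Emits one record per parameter, placement, direction, scheme, and
#' partition. The temporal scheme covers the whole turn (first toe-off to
#' last heel-strike) plus the scalar cycle count, turn duration, and mean
#' stance percentage; each spatial scheme `spatial_k<k>` emits the
#' per-interval records for each of its k partitions. Channels are expected to
#' be filtered already (see [preprocess_trial()]).
#'
#' @param trial A (preprocessed) `turn_trial`.
#' @param events `gait_events` from [detect_swings()].
#' @param partitions Named list of `partition_set` objects, e.g.
#'   `list("2" = ..., "4" = ...)`.
#' @return A data frame of feature records with columns `participant_id`,
#'   `group`, `parameter`, `placement`, `direction`, `scheme`,
#'   `partition_index`, `value`.
#' @export
extract_all <- function(trial, events, partitions) {
  out <- list()
  push <- function(df, scheme, partition_index) {
    df$scheme <- scheme
    df$partition_index <- partition_index
    out[[length(out) + 1L]] <<- df
  }

  turn_iv <- c(events$toe_off_idx[1L],
               events$heel_strike_idx[length(events$heel_strike_idx)])
  push(interval_records(trial, turn_iv), "temporal", NA_integer_)
  scalars <- data.frame(
    parameter = c("n_cycles", "turn_duration", "stance_pct"),
    placement = "shank_leading",
    direction = NA_character_,
    value = c(n_cycles(events), turn_duration(events),
              if (n_cycles(events) >= 2L) stance_fraction(events)$mean
              else NA_real_)
  )
  push(scalars, "temporal", NA_integer_)

  for (nm in names(partitions)) {
    ps <- partitions[[nm]]
    if (is.null(ps)) stop("missing partition set for k=", nm, call. = FALSE)
    scheme <- paste0("spatial_k", ps$k)
    for (j in seq_len(ps$k)) {
      push(interval_records(trial, partition_interval(ps, j)), scheme, j)
    }
  }

  res <- do.call(rbind, out)
  res <- cbind(
    data.frame(participant_id = trial$participant_id, group = trial$group),
    res
  )
  res <- res[, c("participant_id", "group", "parameter", "placement",
                 "direction", "scheme", "partition_index", "value")]
  rownames(res) <- NULL
  res
}
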
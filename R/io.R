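TRIAL_HEADER <- c("time", "gyro_flexext", "gyro_lateral", "gyro_rotation",
                  "ang_flexext", "ang_lateral", "ang_rotation")

# full-precision, locale-independent numeric formatting for stable CSV output
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  df
}

#' Write a turning trial to a directory
#'
#' One CSV per placement (header
#' `time,gyro_flexext,gyro_lateral,gyro_rotation,ang_flexext,ang_lateral,ang_rotation`),
#' a `meta.yaml` metadata sidecar, and, when present, the synthetic ground
#' truth as `ground_truth.json`.
#'
#' @param trial A `turn_trial`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "turn_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pl in PLACEMENTS) {
    tr <- trial$traces[[pl]]
    df <- data.frame(tr$t, tr$gyro, tr$angle)
    names(df) <- TRIAL_HEADER
    utils::write.csv(format_num_df(df), file.path(dir, paste0(pl, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- list(participant_id = trial$participant_id, group = trial$group,
               leading_side = trial$leading_side,
               turn_direction = trial$turn_direction,
               fs = trial$traces[[1L]]$fs)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(trial$ground_truth)) {
    jsonlite::write_json(trial$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                         dataframe = "columns")
  }
  invisible(dir)
}

#' Read a turning trial from a directory
#'
#' Expects one CSV per placement as written by [write_trial()]. Channels are
#' relabeled to anatomical axes through the axis map at ingest so downstream
#' code never sees device axes.
#'
#' @param dir Directory containing the four placement CSVs.
#' @param meta Optional metadata list (`participant_id`, `group`,
#'   `leading_side`, `turn_direction`, `fs`); read from `meta.yaml` when
#'   `NULL`.
#' @param map An [axis_map()] (identity by default).
#' @return A validated `turn_trial` (with ground truth when
#'   `ground_truth.json` is present).
#' @export
read_trial <- function(dir, meta = NULL, map = axis_map()) {
  if (is.null(meta)) {
    mpath <- file.path(dir, "meta.yaml")
    if (!file.exists(mpath)) {
      stop("no metadata: supply `meta` or provide ", mpath, call. = FALSE)
    }
    meta <- yaml::read_yaml(mpath)
  }
  traces <- list()
  for (pl in PLACEMENTS) {
    path <- file.path(dir, paste0(pl, ".csv"))
    if (!file.exists(path)) {
      stop("missing placement file: ", pl, " (expected ", path, ")",
           call. = FALSE)
    }
    df <- utils::read.csv(path)
    if (!identical(names(df), TRIAL_HEADER)) {
      stop("unexpected header in ", path, "; expected: ",
           paste(TRIAL_HEADER, collapse = ","), call. = FALSE)
    }
    bad <- which(!stats::complete.cases(df) |
                   apply(is.nan(as.matrix(df)), 1L, any))
    if (length(bad)) {
      stop(sprintf("NaN/missing cell in %s at data row %d", path, bad[1L]),
           call. = FALSE)
    }
    if (any(diff(df$time) <= 0)) {
      stop("non-monotone time vector in ", path, call. = FALSE)
    }
    gyro <- apply_axis_map(pl, as.matrix(df[, 2:4]), map)
    angle <- apply_axis_map(pl, as.matrix(df[, 5:7]), map)
    traces[[pl]] <- sensor_trace(pl, meta$fs, df$time, gyro, angle)
  }
  gt <- NULL
  gpath <- file.path(dir, "ground_truth.json")
  if (file.exists(gpath)) {
    gt <- jsonlite::read_json(gpath, simplifyVector = TRUE)
    if (!is.null(gt$swing_intervals)) {
      gt$swing_intervals <- matrix(unlist(gt$swing_intervals), ncol = 2L,
                                   byrow = FALSE,
                                   dimnames = list(NULL,
                                                   c("toe_off", "heel_strike")))
    }
  }
  turn_trial(meta$participant_id, meta$group, meta$leading_side,
             meta$turn_direction, traces, ground_truth = gt)
}

FEATURE_KEY <- c("participant_id", "parameter", "placement", "direction",
                 "scheme", "partition_index")
FEATURE_COLS <- c("participant_id", "group", "parameter", "placement",
                  "direction", "scheme", "partition_index", "value")

#' Write feature records as long-format CSV
#'
#' One row per (participant, parameter, placement, direction, scheme,
#' partition); rows are sorted by all key columns so output is deterministic,
#' and duplicate key tuples are rejected.
#'
#' @param records Feature data frame (see [extract_all()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  missing_cols <- setdiff(FEATURE_COLS, names(records))
  if (length(missing_cols)) {
    stop("feature records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[FEATURE_COLS]
  key <- do.call(paste, c(records[FEATURE_KEY], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate feature key tuple: ",
         gsub("\r", "/", key[duplicated(key)][1L]), call. = FALSE)
  }
  ord <- do.call(order, records[FEATURE_KEY])
  utils::write.csv(format_num_df(records[ord, , drop = FALSE]), path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read feature records written by [write_features()]
#'
#' @param path CSV path.
#' @return Feature data frame.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    participant_id = "character", group = "character",
    parameter = "character", placement = "character",
    direction = "character", scheme = "character",
    partition_index = "integer", value = "numeric"
  ))
  df
}
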
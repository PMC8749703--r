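#' Published reference summaries for 360-degree turning
#'
#' Group-level summary statistics transcribed from a published wearable-sensor
#' study of on-spot 360-degree turning that compared 14 stroke survivors (SS)
#' with 14 healthy individuals (HI) using the same four-sensor configuration
#' this package models. `reference_temporal_summary()` returns the
#' temporal-segmentation table (group mean, SD, and printed p-value per
#' parameter); `reference_partition_means()` returns the spatial-segmentation
#' tables: group means per partition for the 2-partition (180 deg) and
#' 4-partition (90 deg) divisions together with the printed partition-
#' comparison percentages (`cmp2_2v1`, `cmp4_2v1`, `cmp4_3v2`, `cmp4_4v3`).
#'
#' These values seed the synthetic generator's group profiles and serve as
#' inputs for the worked-example percent-difference computations; the printed
#' comparison columns are reproduced by [pct_change_symmetric()] applied to
#' the printed means.
#'
#' @return A data frame.
#' @export
reference_temporal_summary <- function() {
  utils::read.csv(
    system.file("extdata", "reference_temporal_summary.csv",
                package = "turnkin"),
    colClasses = c(parameter = "character", placement = "character",
                   direction = "character")
  )
}

#' @rdname reference_temporal_summary
#' @export
reference_partition_means <- function() {
  utils::read.csv(
    system.file("extdata", "reference_partition_means.csv",
                package = "turnkin"),
    colClasses = c(parameter = "character", placement = "character",
                   direction = "character", group = "character")
  )
}
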
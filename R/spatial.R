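#' Divide the turn into k equal angular partitions
#'
#' Operates on the trailing shank's cumulative rotation (see
#' [cumulative_rotation()]). Noise dips are removed by taking the running
#' maximum before crossing detection. The turn interval runs from the first
#' sample where the rotation exceeds `angle_eps` to the first sample within
#' `angle_eps` of the total covered rotation; internal boundary j is placed at
#' the crossing of `j * total / k`. Crossings are located with sub-sample
#' linear interpolation (at 60 Hz a brisk turn sweeps several degrees per
#' sample) and then snapped to the nearest sample index.
#'
#' @param rotation Cumulative rotation series (deg), non-decreasing up to
#'   noise.
#' @param k Number of partitions, 2..7.
#' @param fs Sampling rate in Hz.
#' @param angle_eps Plateau tolerance in degrees.
#' @param backtrack_tol Maximum tolerated dip (deg) of the raw series below
#'   its running maximum before the input is rejected as non-monotone.
#' @return A `partition_set`: `k`, `boundaries_idx` (k+1 sample indices),
#'   `boundaries_t` (sub-sample crossing times, s), `boundary_angles` (series
#'   values at the indices), `total_rotation` (deg).
#' @export
partition_turn <- function(rotation, k, fs, angle_eps = 2,
                           backtrack_tol = 10) {
  k <- as.integer(k)
  if (k < 2L || k > 7L) stop("k must be in 2..7", call. = FALSE)
  r <- cummax(as.numeric(rotation))
  total <- r[length(r)]
  if (total < 90) {
    stop(sprintf("no turn detected: total rotation %.1f deg < 90 deg", total),
         call. = FALSE)
  }
  backtrack <- max(r - rotation)
  if (backtrack > backtrack_tol) {
    stop(sprintf(
      "rotation series non-monotone beyond tolerance (max backtrack %.1f deg)",
      backtrack
    ), call. = FALSE)
  }

  targets <- c(angle_eps, seq_len(k - 1L) * total / k, total - angle_eps)
  cross <- vapply(targets, function(tg) {
    i <- which(r >= tg)[1L]
    if (i == 1L) return(1)
    frac <- (tg - r[i - 1L]) / (r[i] - r[i - 1L])
    (i - 1L) + frac
  }, numeric(1))
  idx <- as.integer(round(cross))
  # nearest-sample snapping can tie on very fast sweeps; keep indices strict
  for (j in seq_along(idx)[-1L]) {
    if (idx[j] <= idx[j - 1L]) idx[j] <- idx[j - 1L] + 1L
  }
  if (idx[length(idx)] > length(r)) {
    stop("partition boundaries exceed the signal: turn too fast for fs",
         call. = FALSE)
  }

  structure(
    list(k = k, boundaries_idx = idx, boundaries_t = (cross - 1) / fs,
         boundary_angles = r[idx], total_rotation = total),
    class = "partition_set"
  )
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> k=%d over %.1f deg; boundaries at %s s\n",
              x$k, x$total_rotation,
              paste(sprintf("%.2f", x$boundaries_t), collapse = ", ")))
  invisible(x)
}

#' Sample-index interval of one partition
#'
#' Partitions tile the turn with no gaps or overlaps: partition j covers
#' samples `boundaries_idx[j]` up to (but excluding) `boundaries_idx[j+1]`,
#' and the last partition closes the interval.
#'
#' @param ps A `partition_set`.
#' @param j Partition number in 1..k.
#' @return Integer `c(start, end)`, inclusive.
#' @export
partition_interval <- function(ps, j) {
  stopifnot(j >= 1L, j <= ps$k)
  start <- ps$boundaries_idx[j]
  end <- if (j == ps$k) ps$boundaries_idx[j + 1L] else ps$boundaries_idx[j + 1L] - 1L
  c(start = start, end = end)
}
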
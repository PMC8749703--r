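#' Unpaired two-tailed t-test
#'
#' Pooled-variance Student's t by default; Welch's correction selectable.
#' When both groups have zero variance the p-value is 1 if the means agree
#' (nothing to distinguish) and 0 otherwise, by convention.
#'
#' @param a,b Numeric samples, each with at least 2 finite values.
#' @param alpha Significance level.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `p`, `significant` (`p < alpha`).
#' @export
ttest_unpaired <- function(a, b, alpha = 0.05,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite values in t-test input", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, significant = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, significant = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  p <- unname(ht$p.value)
  list(t = unname(ht$statistic), p = p, significant = p < alpha)
}

#' Percent difference relative to a reference value
#'
#' `(a - ref) / ref * 100`: the convention behind statements like "the cycle
#' count was 67% larger in one group", with the other group's mean as the
#' reference.
#'
#' @param a Value of interest.
#' @param ref Reference value (non-zero).
#' @return Percent difference; `NA` with a warning when `ref` is 0.
#' @export
pct_diff_reference <- function(a, ref) {
  out <- (a - ref) / ref * 100
  bad <- ref == 0
  if (any(bad)) {
    warning("percent difference undefined for zero reference", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Symmetric percent change between consecutive partitions
#'
#' `(x2 - x1) / ((x1 + x2) / 2) * 100`: the midpoint-referenced change used in
#' the partition-comparison columns of the spatial tables. Antisymmetric in
#' its arguments and bounded by 200 in magnitude for same-sign inputs.
#'
#' @param x1,x2 Values in the earlier / later partition.
#' @return Symmetric percent change; `NA` with a warning when `x1 + x2` is 0.
#' @export
pct_change_symmetric <- function(x1, x2) {
  mid <- (x1 + x2) / 2
  out <- (x2 - x1) / mid * 100
  bad <- mid == 0
  if (any(bad)) {
    warning("symmetric percent change undefined when x1 + x2 = 0",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Build group-comparison tables from cohort feature records
#'
#' Summarizes every (parameter, placement, direction, scheme, partition) key
#' as group means and SDs with an unpaired two-tailed t-test, and, for spatial
#' schemes, adds per-group symmetric percent changes between consecutive
#' partitions (`cmp_ss`, `cmp_hi`, versus the previous partition). The result
#' mirrors the published table family: `temporal` (cycle count, duration,
#' stance, whole-turn per-segment parameters), `angular_velocity` and
#' `range_of_motion` (per-partition per-segment values), and `relative`
#' (sternum-sacrum and leading/trailing measures), plus the complete row set
#' under `all`.
#'
#' @param features Feature records for a cohort (rbind of [extract_all()]
#'   outputs) containing both groups.
#' @param alpha Significance level.
#' @param variant t-test variant, see [ttest_unpaired()].
#' @return List of data frames: `temporal`, `angular_velocity`,
#'   `range_of_motion`, `relative`, `all`.
#' @export
build_tables <- function(features, alpha = 0.05,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(features), nrow(features) > 0)
  f <- features
  f$direction[is.na(f$direction)] <- ""
  f$partition_index[is.na(f$partition_index)] <- 0L
  key_cols <- c("parameter", "placement", "direction", "scheme",
                "partition_index")
  keys <- unique(f[key_cols])
  keys <- keys[order(keys$scheme, keys$parameter, keys$placement,
                     keys$direction, keys$partition_index), , drop = FALSE]

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, , drop = FALSE]
    sub <- merge(f, k, by = key_cols)
    a <- sub$value[sub$group == "SS"]
    b <- sub$value[sub$group == "HI"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    row <- cbind(k, data.frame(
      mean_ss = if (length(a)) mean(a) else NA_real_,
      sd_ss = if (length(a) > 1L) stats::sd(a) else NA_real_,
      n_ss = length(a),
      mean_hi = if (length(b)) mean(b) else NA_real_,
      sd_hi = if (length(b) > 1L) stats::sd(b) else NA_real_,
      n_hi = length(b),
      t_stat = NA_real_, p_value = NA_real_, significant = NA,
      missing_group = (length(a) < 2L || length(b) < 2L)
    ))
    if (!row$missing_group) {
      tt <- ttest_unpaired(a, b, alpha = alpha, variant = variant)
      row$t_stat <- tt$t; row$p_value <- tt$p; row$significant <- tt$significant
    }
    row
  })
  all_rows <- do.call(rbind, rows)
  rownames(all_rows) <- NULL

  # symmetric percent change versus the previous partition, per group
  all_rows$cmp_ss <- NA_real_
  all_rows$cmp_hi <- NA_real_
  spatial <- grepl("^spatial_k", all_rows$scheme)
  sp_key <- interaction(all_rows$parameter, all_rows$placement,
                        all_rows$direction, all_rows$scheme, drop = TRUE)
  for (g in split(which(spatial), droplevels(sp_key[spatial]))) {
    g <- g[order(all_rows$partition_index[g])]
    if (length(g) < 2L) next
    prev <- g[-length(g)]; cur <- g[-1L]
    all_rows$cmp_ss[cur] <- pct_change_symmetric(all_rows$mean_ss[prev],
                                                 all_rows$mean_ss[cur])
    all_rows$cmp_hi[cur] <- pct_change_symmetric(all_rows$mean_hi[prev],
                                                 all_rows$mean_hi[cur])
  }

  sp <- all_rows[spatial, , drop = FALSE]
  list(
    temporal = all_rows[all_rows$scheme == "temporal", , drop = FALSE],
    angular_velocity = sp[sp$parameter == "angular_velocity", , drop = FALSE],
    range_of_motion = sp[sp$parameter == "range_of_motion", , drop = FALSE],
    relative = sp[sp$parameter %in% c("rel_angular_velocity",
                                      "rel_range_of_motion",
                                      "ratio_angular_velocity",
                                      "ratio_range_of_motion"), , drop = FALSE],
    all = all_rows
  )
}

#' Write comparison tables as CSV files
#'
#' @param tables Output of [build_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_comparison_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(setdiff(names(tables), "all"), function(nm) {
    p <- file.path(dir, paste0("comparison_", nm, ".csv"))
    utils::write.csv(format_num_df(tables[[nm]]), p, row.names = FALSE,
                     quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
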
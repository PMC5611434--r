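# Per-segment 3-SD quality control.

#' Flag outlying segment volumes
#'
#' Within every (hemisphere, segment) cell, computes the mean and SD of
#' `volume_mm3` over the whole sample in a single pass and flags records more
#' than `z_threshold` SDs from the cell mean. Flagged volumes are set missing
#' (never imputed); downstream models use listwise deletion. The pass is not
#' iterated: re-running on the filtered table could flag more records, which
#' is deliberately not done.
#'
#' @param cohort Long-format tibble with at least `hemisphere`, `segment`,
#'   `volume_mm3` (one row per participant x hemisphere x segment).
#' @param z_threshold SD multiple beyond which a record is excluded
#'   (default 3).
#' @return Object of class `qc_result`: a list with `cohort` (input plus an
#'   `excluded` flag and `volume_mm3` set to `NA` on excluded rows) and
#'   `report` (counts, excluded fraction, and the excluded records).
#' @export
flag_outlier_segments <- function(cohort, z_threshold = 3) {
  stopifnot(all(c("hemisphere", "segment", "volume_mm3") %in% names(cohort)))
  if (z_threshold <= 0) abort("`z_threshold` must be positive.")
  cohort <- cohort |>
    group_by(.data$hemisphere, .data$segment) |>
    mutate(
      .cell_n = sum(!is.na(.data$volume_mm3)),
      .cell_mean = mean(.data$volume_mm3, na.rm = TRUE),
      .cell_sd = sd(.data$volume_mm3, na.rm = TRUE)
    ) |>
    ungroup()
  if (any(cohort$.cell_n < 3)) {
    abort("need at least 3 non-missing volumes per (hemisphere, segment) cell.")
  }
  degenerate <- cohort$.cell_sd == 0 | is.na(cohort$.cell_sd)
  if (any(degenerate)) {
    warn("cells with zero volume SD: no exclusions applied there.")
  }
  cohort <- cohort |>
    mutate(excluded = !is.na(.data$volume_mm3) & !degenerate &
             abs(.data$volume_mm3 - .data$.cell_mean) >
               z_threshold * .data$.cell_sd)
  n_meas <- sum(!is.na(cohort$volume_mm3))
  excluded_records <- cohort |>
    filter(.data$excluded) |>
    select(any_of(c("participant_id", "hemisphere", "segment", "volume_mm3")))
  cohort <- cohort |>
    mutate(volume_mm3 = ifelse(.data$excluded, NA_real_, .data$volume_mm3)) |>
    select(-".cell_n", -".cell_mean", -".cell_sd")
  structure(
    list(
      cohort = cohort,
      report = list(
        n_measurements = n_meas,
        n_excluded = nrow(excluded_records),
        excluded_fraction = nrow(excluded_records) / n_meas,
        z_threshold = z_threshold,
        excluded_records = excluded_records
      )
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qc_result> %d of %d measurements (%.2f%%) beyond %.3g SD excluded\n",
              r$n_excluded, r$n_measurements, 100 * r$excluded_fraction,
              r$z_threshold))
  invisible(x)
}

#' @rdname flag_outlier_segments
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$report$excluded_records
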
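# Cohort-table transforms: per-segment z-scores, anterior/posterior halves,
# partial correlation.

#' Standardize segment volumes within (hemisphere, segment)
#'
#' z = (v - mean) / SD over the analysis sample, computed separately for
#' every (hemisphere, segment) cell. This is the scale on which segment
#' profiles are plotted.
#'
#' @param cohort Long tibble with `hemisphere`, `segment`, `volume_mm3`.
#' @return The input with an added `volume_z` column.
#' @export
zscore_by_segment <- function(cohort) {
  stopifnot(all(c("hemisphere", "segment", "volume_mm3") %in% names(cohort)))
  out <- cohort |>
    group_by(.data$hemisphere, .data$segment) |>
    mutate(.n = sum(!is.na(.data$volume_mm3)),
           .m = mean(.data$volume_mm3, na.rm = TRUE),
           .s = sd(.data$volume_mm3, na.rm = TRUE)) |>
    ungroup()
  if (any(out$.n < 3)) abort("need >= 3 non-missing volumes per (hemisphere, segment).")
  if (any(out$.s == 0)) abort("zero volume SD in a (hemisphere, segment) cell.")
  out |>
    mutate(volume_z = (.data$volume_mm3 - .data$.m) / .data$.s) |>
    select(-".n", -".m", -".s")
}

#' Aggregate segments into posterior and anterior halves
#'
#' posterior50 = sum of segments 1--5, anterior50 = sum of segments 6--10
#' (for 10 segments; generally the posterior and anterior halves of the
#' segment range). Participants missing any segment in a hemisphere are
#' dropped from that hemisphere's aggregate. Bilateral rows are the *sums*
#' of left + right halves, computed for participants complete on both sides.
#'
#' @param cohort Long tibble with `participant_id`, `hemisphere`, `segment`,
#'   `volume_mm3`; participant-level columns (group, age, ...) are carried
#'   through.
#' @return Tibble with one row per participant x hemisphere (including
#'   `hemisphere = "bilateral"`): `posterior50`, `anterior50`, `total_mm3`.
#' @export
aggregate_halves <- function(cohort) {
  stopifnot(all(c("participant_id", "hemisphere", "segment", "volume_mm3")
                %in% names(cohort)))
  n_seg <- max(cohort$segment)
  half <- n_seg %/% 2
  per_hemi <- cohort |>
    group_by(.data$participant_id, .data$hemisphere) |>
    summarise(
      .complete = sum(!is.na(.data$volume_mm3)) == n_seg && n() == n_seg,
      posterior50 = sum(.data$volume_mm3[.data$segment <= half]),
      anterior50 = sum(.data$volume_mm3[.data$segment > half]),
      .groups = "drop"
    )
  n_inc <- sum(!per_hemi$.complete)
  if (n_inc > 0) {
    inform(sprintf("dropping %d participant-hemispheres with missing segments.", n_inc))
  }
  per_hemi <- per_hemi |>
    filter(.data$.complete) |>
    select(-".complete") |>
    mutate(total_mm3 = .data$posterior50 + .data$anterior50)
  bilateral <- per_hemi |>
    group_by(.data$participant_id) |>
    filter(n() == 2L) |>
    summarise(hemisphere = "bilateral",
              posterior50 = sum(.data$posterior50),
              anterior50 = sum(.data$anterior50),
              total_mm3 = sum(.data$total_mm3),
              .groups = "drop")
  out <- bind_rows(per_hemi, bilateral)
  subj_cols <- cohort |>
    select(-any_of(c("hemisphere", "segment", "volume_mm3", "volume_z",
                     "excluded", "total_mm3"))) |>
    distinct(.data$participant_id, .keep_all = TRUE)
  out |>
    left_join(subj_cols, by = "participant_id") |>
    arrange(.data$participant_id, .data$hemisphere)
}

#' Partial correlation with covariate residualization
#'
#' Residualizes `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals. The p-value comes from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - q` for q covariates.
#' With no covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of numeric covariates, or `NULL`.
#' @return One-row tibble: `r`, `df`, `statistic`, `p.value`, `n`,
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
  }
  x <- x[ok]; y <- y[ok]
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(x)
  if (n <= q + 3L) abort("need n > n_covariates + 3 complete observations.")
  if (q > 0L) {
    Z <- cbind(1, covariates[ok, , drop = FALSE])
    qz <- qr(Z)
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  }
  if (sd(x) == 0 || sd(y) == 0) abort("constant residuals; correlation undefined.")
  r <- cor(x, y)
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, df = df, statistic = tstat,
         p.value = 2 * pt(-abs(tstat), df), n = n, n_covariates = q)
}
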
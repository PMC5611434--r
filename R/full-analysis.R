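# Orchestration: the four standard analysis designs on a QC'd cohort table.

#' Run the full subfield analysis bundle
#'
#' Given a QC'd long cohort table, runs the four standard designs:
#' \describe{
#'   \item{abeta_segments / ptau_segments}{per hemisphere, split-plot ANCOVA
#'     of the 10 z-scored segment volumes with biomarker status and sex as
#'     factors, age and ICV as covariates; the group x segment interaction is
#'     the effect of interest, and z-scored adjusted cell means are returned
#'     for plotting.}
#'   \item{ptau_correlations}{per hemisphere and segment, partial correlation
#'     of segment volume with continuous P-tau controlling age and ICV.}
#'   \item{memory_halves}{memory-error bins (0-1/2-3/4-5/6-10) against the
#'     bilateral posterior-50% and anterior-50% sums, with sex, age and ICV
#'     adjustment; pairwise post hocs.}
#'   \item{scd_interaction}{within the SCD group, 2-level location
#'     (posterior/anterior) x biomarker-status interaction.}
#' }
#'
#' @param cohort Long cohort tibble (see [generate_cohort()] for the
#'   schema), ideally after [flag_outlier_segments()].
#' @param abeta_cutoff,ptau_cutoff Dichotomization cutoffs in ng/l.
#' @param posthoc Post hoc method for the memory-bin analysis.
#' @return Object of class `subaxis_report`: a named list of result tables
#'   and fitted models.
#' @export
run_full_analysis <- function(cohort, abeta_cutoff = 527, ptau_cutoff = 52,
                              posthoc = c("bonferroni", "fisher_lsd")) {
  posthoc <- match.arg(posthoc)
  cohort <- cohort |>
    mutate(abeta_status = classify_abeta(.data$abeta42, abeta_cutoff),
           ptau_status = classify_ptau(.data$ptau, ptau_cutoff),
           memory_bin = bin_memory_errors(.data$memory_errors))
  zc <- zscore_by_segment(cohort)

  fit_status <- function(status_col) {
    res <- list()
    for (h in unique(zc$hemisphere)) {
      fit <- rm_glm(filter(zc, .data$hemisphere == h),
                    outcome = "volume_z", subject = "participant_id",
                    within = "segment",
                    between = c(status_col, "sex"),
                    covariates = c("age", "icv"),
                    adjusted_means_for = status_col)
      res[[h]] <- fit
    }
    res
  }
  abeta_fits <- fit_status("abeta_status")
  ptau_fits <- fit_status("ptau_status")

  ptau_corr <- zc |>
    filter(!is.na(.data$volume_mm3)) |>
    group_by(.data$hemisphere, .data$segment) |>
    group_modify(~ partial_correlation(.x$ptau, .x$volume_mm3,
                                       covariates = .x[, c("age", "icv")])) |>
    ungroup()

  halves <- aggregate_halves(cohort) |>
    filter(.data$hemisphere == "bilateral")
  halves_long <- halves |>
    pivot_longer(c("posterior50", "anterior50"),
                 names_to = "location", values_to = "half_volume")
  memory_fit <- rm_glm(halves_long,
                       outcome = "half_volume", subject = "participant_id",
                       within = "location",
                       between = c("memory_bin", "sex"),
                       covariates = c("age", "icv"),
                       adjusted_means_for = "memory_bin")
  memory_posthoc <- posthoc_pairwise(memory_fit, method = posthoc)

  scd <- cohort |> filter(.data$group == "SCD")
  scd_fits <- list()
  if (nrow(scd) > 0 &&
      all(table(distinct(scd, .data$participant_id, .data$abeta_status)$abeta_status) >= 5)) {
    for (h in c("left", "right")) {
      hl <- aggregate_halves(filter(scd, .data$hemisphere == h)) |>
        filter(.data$hemisphere == h) |>
        pivot_longer(c("posterior50", "anterior50"),
                     names_to = "location", values_to = "half_volume") |>
        mutate(abeta_status = classify_abeta(.data$abeta42, abeta_cutoff),
               ptau_status = classify_ptau(.data$ptau, ptau_cutoff))
      scd_fits[[paste0(h, "_abeta")]] <- rm_glm(
        hl, outcome = "half_volume", subject = "participant_id",
        within = "location", between = c("abeta_status", "sex"),
        covariates = c("age", "icv"))
      scd_fits[[paste0(h, "_ptau")]] <- rm_glm(
        hl, outcome = "half_volume", subject = "participant_id",
        within = "location", between = c("ptau_status", "sex"),
        covariates = c("age", "icv"))
    }
  }

  structure(
    list(abeta_segments = abeta_fits,
         ptau_segments = ptau_fits,
         ptau_correlations = ptau_corr,
         memory_halves = list(fit = memory_fit, posthoc = memory_posthoc),
         scd_interaction = scd_fits,
         cutoffs = c(abeta = abeta_cutoff, ptau = ptau_cutoff)),
    class = "subaxis_report"
  )
}

#' @export
print.subaxis_report <- function(x, ...) {
  cat("<subaxis_report>\n")
  cat("  abeta_segments / ptau_segments: split-plot ANCOVA per hemisphere\n")
  cat("  ptau_correlations:", nrow(x$ptau_correlations), "segment-wise partial correlations\n")
  cat("  memory_halves: 4-bin analysis +", nrow(x$memory_halves$posthoc), "post hoc rows\n")
  cat("  scd_interaction:", length(x$scd_interaction), "location x status fits\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits machine-readable JSON (test tables), CSVs (correlations, post
#' hocs, adjusted means) and figure files.
#'
#' @param report A `subaxis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tests <- list()
  for (nm in names(report$abeta_segments)) {
    tests[[paste0("abeta_", nm)]] <- tidy(report$abeta_segments[[nm]])
  }
  for (nm in names(report$ptau_segments)) {
    tests[[paste0("ptau_", nm)]] <- tidy(report$ptau_segments[[nm]])
  }
  tests$memory_halves <- tidy(report$memory_halves$fit)
  for (nm in names(report$scd_interaction)) {
    tests[[paste0("scd_", nm)]] <- tidy(report$scd_interaction[[nm]])
  }
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       dataframe = "rows", digits = 10)
  write.csv(report$ptau_correlations,
            file.path(dir, "ptau_correlations.csv"), row.names = FALSE)
  write.csv(report$memory_halves$posthoc,
            file.path(dir, "memory_posthoc.csv"), row.names = FALSE)
  for (nm in names(report$abeta_segments)) {
    p <- autoplot(report$abeta_segments[[nm]])
    ggplot2::ggsave(file.path(dir, paste0("abeta_segments_", nm, ".png")),
                    p, width = 6, height = 4, dpi = 150)
  }
  ggplot2::ggsave(file.path(dir, "ptau_correlations.png"),
                  plot_correlation_profile(report$ptau_correlations),
                  width = 6, height = 4, dpi = 150)
  invisible(dir)
}
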
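# Figures: z-scored segment profiles, segment-wise correlation profiles,
# memory-bin half-volume plots.

#' Plot adjusted segment profiles from a split-plot fit
#'
#' Adjusted cell means per factor level against segment index (posterior on
#' the left), with 95% confidence bars - the standard way segment-wise group
#' contrasts are displayed.
#'
#' @param object An [rm_glm()] fit with adjusted means.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rm_glm <- function(object, ...) {
  am <- object$adjusted_means
  if (is.null(am)) abort("fit has no adjusted means; refit with `adjusted_means_for`.")
  ggplot2::ggplot(am, ggplot2::aes(x = .data$within_level, y = .data$mean,
                                   colour = .data$level, group = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$k)) +
    ggplot2::labs(x = "segment (posterior → anterior)",
                  y = "adjusted volume",
                  colour = am$factor[1]) +
    ggplot2::theme_minimal()
}

#' Plot a segment-wise correlation profile
#'
#' @param corr Tibble from the segment-wise partial correlations (columns
#'   `hemisphere`, `segment`, `r`).
#' @return A ggplot.
#' @export
plot_correlation_profile <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$segment, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::scale_x_continuous(breaks = unique(corr$segment)) +
    ggplot2::labs(x = "segment (posterior → anterior)",
                  y = "partial correlation r") +
    ggplot2::theme_minimal()
}

#' Plot memory-bin means for posterior and anterior halves
#'
#' @param fit The memory-bin [rm_glm()] fit (within = location).
#' @return A ggplot.
#' @export
plot_memory_halves <- function(fit) {
  am <- fit$adjusted_means
  if (is.null(am)) abort("fit has no adjusted means.")
  lv <- fit$within_levels %||% as.character(seq_len(fit$k))
  am <- mutate(am, location = lv[.data$within_level])
  ggplot2::ggplot(am, ggplot2::aes(x = .data$level, y = .data$mean,
                                   colour = .data$location,
                                   group = .data$location)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.15) +
    ggplot2::labs(x = "forgotten items", y = "adjusted half volume (mm³)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
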
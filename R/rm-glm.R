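# Split-plot repeated-measures ANCOVA.
#
# The design matches the "GLM repeated measures" convention of the major
# statistics packages: between-subject factors are effect-coded (sum to
# zero), covariates are centered, sums of squares are Type III, and the
# within-subject factor (segment, or anterior/posterior location) enters
# through k-1 orthonormal polynomial contrasts. For each between-subject
# term, the term x within interaction is tested by pooling its Type III SS
# over the k-1 contrast columns:
#
#   F = (SS_term / df_num) / (SS_err / df_den),
#   df_num = df_term * (k - 1),  df_den = (n - p) * (k - 1),
#
# so with 10 segments the interaction denominator df is 9 * (n - p), the
# printed shape of classical subfield analyses (e.g. F(9, 5598) at n - p =
# 622). Between-subject main effects are tested on the subject means across
# within levels. The uncorrected univariate F is primary;
# Greenhouse-Geisser epsilon is computed and reported alongside.

#' Split-plot repeated-measures ANCOVA on a long cohort table
#'
#' @param data Long-format tibble: one row per subject x within level.
#' @param outcome Name of the outcome column (e.g. `"volume_mm3"`).
#' @param subject Name of the subject identifier column.
#' @param within Name of the within-subject factor column (e.g. `"segment"`).
#' @param between Character vector of between-subject factor columns
#'   (e.g. biomarker status and sex).
#' @param covariates Character vector of numeric covariate columns
#'   (e.g. age and intracranial volume); centered internally.
#' @param adjusted_means_for Between factor for which covariate-adjusted cell
#'   means per within level are returned; defaults to the first factor in
#'   `between`.
#' @return An object of class `rm_glm`; see [tidy.rm_glm()].
#' @export
rm_glm <- function(data, outcome, subject, within,
                   between = character(), covariates = character(),
                   adjusted_means_for = between[1]) {
  cols <- c(subject, within, outcome, between, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  d <- data |>
    select(all_of(cols)) |>
    rename(.subject = all_of(subject), .within = all_of(within),
           .y = all_of(outcome))
  wide <- d |>
    pivot_wider(id_cols = ".subject", names_from = ".within",
                values_from = ".y", names_sort = TRUE)
  subj_info <- d |>
    select(-".within", -".y") |>
    distinct(.data$.subject, .keep_all = TRUE)
  wide <- left_join(wide, subj_info, by = ".subject")
  complete <- complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  k <- length(unique(d$.within))
  Y <- as.matrix(wide[, 2:(k + 1)])
  between_df <- wide |>
    select(all_of(c(between, covariates))) |>
    mutate(across(all_of(between), as.factor))
  fit <- rm_splitplot(Y, between_df,
                      between = between, covariates = covariates,
                      adjusted_means_for = adjusted_means_for)
  fit$n_dropped <- n_dropped
  fit$within <- within
  fit$within_levels <- names(wide)[2:(k + 1)]
  fit
}

#' Split-plot repeated-measures ANCOVA on a wide outcome matrix
#'
#' Lower-level interface used by [rm_glm()] and by simulation studies: the
#' within-subject measurements are supplied as an n x k matrix whose columns
#' are already ordered along the within factor.
#'
#' @param Y Numeric n x k matrix of within-subject measurements.
#' @param between_df Data frame with n rows holding the between-subject
#'   factors and covariates.
#' @param between,covariates Column names in `between_df`.
#' @param adjusted_means_for Factor for which adjusted means are computed
#'   (`NULL` to skip).
#' @return An `rm_glm` object.
#' @export
rm_splitplot <- function(Y, between_df,
                         between = names(Filter(is.factor, between_df)),
                         covariates = setdiff(names(between_df), between),
                         adjusted_means_for = if (length(between)) between[1] else NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) abort("need at least 2 within-subject levels.")
  for (f in between) {
    lv <- unique(between_df[[f]])
    if (length(lv[!is.na(lv)]) < 2L) abort(paste0("factor `", f, "` needs >= 2 levels."))
  }
  # effect coding + centered covariates
  for (cv in covariates) {
    between_df[[cv]] <- between_df[[cv]] - mean(between_df[[cv]])
  }
  rhs <- c(between, covariates)
  form <- if (length(rhs)) {
    stats::reformulate(sprintf("`%s`", rhs))
  } else {
    ~1
  }
  contr <- setNames(replicate(length(between), "contr.sum", simplify = FALSE),
                    between)
  mf <- stats::model.frame(form, data = between_df, na.action = stats::na.fail)
  X <- stats::model.matrix(form, mf,
                           contrasts.arg = if (length(between)) contr else NULL)
  asg <- attr(X, "assign")
  term_labels <- attr(stats::terms(form), "term.labels")
  p <- ncol(X)
  if (qr(X)$rank < p) abort("rank-deficient between-subject design (aliased terms).")
  qr_full <- qr(X)
  df_err <- n - p
  if (df_err < 1L) abort("no residual degrees of freedom.")

  # between stratum: subject means
  ybar <- rowMeans(Y)
  res_b <- qr.resid(qr_full, ybar)
  rss_b <- sum(res_b^2)

  # within stratum: orthonormal polynomial contrast scores
  M <- contr.poly(k)
  Yc <- Y %*% M
  res_c <- qr.resid(qr_full, Yc)
  rss_c <- sum(res_c^2)

  drop_rss <- function(keep_cols, Z) {
    if (length(keep_cols) == 0L) return(sum(Z^2))
    sum(qr.resid(qr(X[, keep_cols, drop = FALSE]), Z)^2)
  }

  rows <- list()
  for (ti in seq_along(term_labels)) {
    keep <- which(asg != ti)
    df_t <- sum(asg == ti)
    ss_b <- drop_rss(keep, ybar) - rss_b
    Fb <- (ss_b / df_t) / (rss_b / df_err)
    ss_w <- drop_rss(keep, Yc) - rss_c
    Fw <- (ss_w / (df_t * (k - 1))) / (rss_c / (df_err * (k - 1)))
    rows[[length(rows) + 1L]] <- tibble(
      term = term_labels[ti], stratum = "between",
      df_num = df_t, df_den = df_err, statistic = Fb,
      p.value = pf(Fb, df_t, df_err, lower.tail = FALSE))
    rows[[length(rows) + 1L]] <- tibble(
      term = paste0(term_labels[ti], ":within"), stratum = "within",
      df_num = df_t * (k - 1), df_den = df_err * (k - 1), statistic = Fw,
      p.value = pf(Fw, df_t * (k - 1), df_err * (k - 1), lower.tail = FALSE))
  }
  # within-factor main effect: intercept term in the contrast-score model
  keep0 <- which(asg != 0L)
  ss_w0 <- drop_rss(keep0, Yc) - rss_c
  F0 <- (ss_w0 / (k - 1)) / (rss_c / (df_err * (k - 1)))
  rows[[length(rows) + 1L]] <- tibble(
    term = "within", stratum = "within",
    df_num = k - 1, df_den = df_err * (k - 1), statistic = F0,
    p.value = pf(F0, k - 1, df_err * (k - 1), lower.tail = FALSE))
  anova_tbl <- list_rbind(rows)

  # Greenhouse-Geisser epsilon from the residual contrast-score covariance
  S <- crossprod(res_c) / df_err
  eps <- sum(diag(S))^2 / ((k - 1) * sum(S^2))

  adj <- NULL
  if (!is.null(adjusted_means_for) && adjusted_means_for %in% between) {
    adj <- adjusted_cell_means(Y, X, qr_full, asg, term_labels,
                               between_df, adjusted_means_for, df_err)
  }

  structure(
    list(anova = anova_tbl, epsilon_gg = eps, n_subjects = n, k = k,
         p_between = p, adjusted_means = adj, term_labels = term_labels,
         model = list(X = X, Y = Y, asg = asg, df_err = df_err,
                      between_df = between_df, between = between)),
    class = "rm_glm"
  )
}

#' Pairwise post hoc comparisons of covariate-adjusted means
#'
#' Pairwise contrasts of the adjusted cell means of a between-subject factor
#' with at least 3 levels, computed separately at each within level with the
#' pooled residual error of that level's model. Bonferroni multiplies each
#' raw p by the number of comparisons (capped at 1); Fisher's LSD leaves p
#' unadjusted.
#'
#' @param fit An [rm_glm()] / [rm_splitplot()] result.
#' @param method `"bonferroni"` or `"fisher_lsd"`.
#' @param factor Between factor to compare; defaults to the first.
#' @return Tibble: `within_level`, `level_1`, `level_2`, `estimate`, `se`,
#'   `statistic`, `df`, `p.value` (raw), `p.adj`.
#' @export
posthoc_pairwise <- function(fit, method = c("bonferroni", "fisher_lsd"),
                             factor = NULL) {
  stopifnot(inherits(fit, "rm_glm"))
  method <- match.arg(method)
  m <- fit$model
  factor <- factor %||% m$between[1]
  lv <- levels(m$between_df[[factor]])
  if (length(lv) < 3L) {
    abort("post hoc requires >= 3 factor levels; use the rm_glm main effect for 2 levels.")
  }
  ti <- match(factor, fit$term_labels)
  cols_f <- which(m$asg == ti)
  C <- contr.sum(length(lv))
  qr_full <- qr(m$X)
  B <- qr.coef(qr_full, m$Y)
  res <- qr.resid(qr_full, m$Y)
  sigma2 <- colSums(res^2) / m$df_err
  XtX_inv <- chol2inv(chol(crossprod(m$X)))
  pairs <- utils::combn(seq_along(lv), 2)
  n_comp <- ncol(pairs)
  out <- list()
  for (pc in seq_len(n_comp)) {
    a <- pairs[1, pc]; b <- pairs[2, pc]
    cvec <- numeric(ncol(m$X))
    cvec[cols_f] <- C[a, ] - C[b, ]
    est <- as.vector(cvec %*% B)
    se <- sqrt(sigma2 * as.numeric(t(cvec) %*% XtX_inv %*% cvec))
    tstat <- est / se
    p_raw <- 2 * pt(-abs(tstat), m$df_err)
    out[[pc]] <- tibble(
      within_level = seq_len(fit$k),
      level_1 = lv[a], level_2 = lv[b],
      estimate = est, se = se, statistic = tstat, df = m$df_err,
      p.value = p_raw,
      p.adj = if (method == "bonferroni") pmin(1, n_comp * p_raw) else p_raw)
  }
  mutate(list_rbind(out), method = method)
}

# Covariate-adjusted cell means per (factor level, within level): model
# prediction at the factor level's effect codes with all other factors at
# their (zero-sum) average and covariates at their means.
adjusted_cell_means <- function(Y, X, qr_full, asg, term_labels,
                                between_df, factor_name, df_err) {
  k <- ncol(Y)
  B <- qr.coef(qr_full, Y)                      # p x k coefficients
  res <- qr.resid(qr_full, Y)
  sigma2 <- colSums(res^2) / df_err             # per within level
  XtX_inv <- chol2inv(chol(crossprod(X)))
  lv <- levels(between_df[[factor_name]])
  ti <- match(factor_name, term_labels)
  cols_f <- which(asg == ti)
  C <- contr.sum(length(lv))
  out <- list()
  for (li in seq_along(lv)) {
    xrow <- numeric(ncol(X))
    xrow[asg == 0L] <- 1
    xrow[cols_f] <- C[li, ]
    m <- as.vector(xrow %*% B)
    se <- sqrt(sigma2 * as.numeric(t(xrow) %*% XtX_inv %*% xrow))
    out[[li]] <- tibble(level = lv[li], within_level = seq_len(k),
                        mean = m, se = se)
  }
  mutate(list_rbind(out), factor = factor_name, .before = 1)
}

#' @export
print.rm_glm <- function(x, ...) {
  cat(sprintf("<rm_glm> n = %d subjects, k = %d within levels, GG epsilon = %.3f\n",
              x$n_subjects, x$k, x$epsilon_gg))
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a split-plot ANCOVA fit
#'
#' @param x An `rm_glm` object.
#' @param ... Unused.
#' @return Tibble with one row per tested term: `term`, `stratum`
#'   (`between` or `within`), `df_num`, `df_den`, `statistic` (F),
#'   `p.value`.
#' @export
tidy.rm_glm <- function(x, ...) x$anova

#' @rdname tidy.rm_glm
#' @export
glance.rm_glm <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, k = x$k, p_between = x$p_between,
         epsilon_gg = x$epsilon_gg,
         n_dropped = x$n_dropped %||% 0L)
}
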
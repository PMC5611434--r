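# Synthetic cohort generator.
#
# Two modes:
#
# * "calibration" - a structurally simple cohort whose parameters are fixed
#   so that the headline association strengths of the subfield literature
#   are reproduced by construction: total left subicular volume correlates
#   -0.34 with age, about -0.18 with CSF P-tau after adjusting for age and
#   ICV, and -0.41 with delayed-recall errors; CSF abeta42 is drawn from a
#   bimodal mixture whose analytic equal-posterior point sits at 527 ng/l.
#   Per-participant volume (in SD units) is built from independent standard
#   normal drivers A (age), P (P-tau), M (memory), I (head size) and noise:
#     V = mu_V + sigma_V * (-a*A - p*P - q*M + beta*I + e*Z),
#   with a = 0.34, p = 0.1693, beta = 0.20, q = 0.4195 (pre-calibrated for
#   the discretization of the memory score; see calibrate_memory_loading)
#   and e chosen so the loadings square-sum to 1.
#
# * "study_like" - adds CN/SCD/MCI group structure (group-specific age,
#   P-tau, memory and amyloid-positivity rates) and posterior-weighted
#   atrophy in biomarker-abnormal participants; used for power and pipeline
#   demonstrations, not for numeric calibration.
#
# Segment volumes distribute V over 10 segments with a near-uniform base
# profile; the P-tau and memory channels are loaded with posterior weights
# w_s proportional to (11 - s), so their associations attenuate from the
# posterior to the anterior segments.

#' Calibrate the memory-channel loading for discretization attenuation
#'
#' Memory errors are generated as `round(clip(3.6 + 2.8 * M, 0, 10))` from a
#' latent standard normal M. Rounding and clipping attenuate the
#' latent-scale correlation by the factor `kappa = cor(M, errors)`; to hit a
#' target observed correlation the latent loading must be inflated to
#' `q = |target| / kappa`. A 100,000-draw pilot gives kappa ~ 0.977 and
#' q ~ 0.4195 for the default target of -0.41 (the frozen package default).
#'
#' @param target Target observed correlation (default -0.41).
#' @param n Pilot sample size (default 1e5).
#' @param seed Pilot seed.
#' @return List with `kappa` and `q`.
#' @export
calibrate_memory_loading <- function(target = -0.41, n = 1e5, seed = 20260930) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  M <- rnorm(n)
  errors <- round(pmin(pmax(3.6 + 2.8 * M, 0), 10))
  kappa <- cor(M, errors)
  list(kappa = kappa, q = abs(target) / kappa)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 656
#' participants (302 CN / 183 SCD / 171 MCI), age 72.2 (5.5) years, P-tau
#' 58 (24) ng/l truncated at 0, ICV 1.45e6 (1.5e5) mm^3, memory errors from
#' a latent 3.6 (2.8) scale, abeta42 from
#' 0.393 N(395, 78^2) + 0.607 N(762, 150^2) (equal-posterior point 527.45
#' ng/l), and per-side subicular volume 500 (80) mm^3 (an invented scale:
#' subfield totals are not published, only whole-hippocampus volumes).
#'
#' @param mode `"calibration"` or `"study_like"`.
#' @param n_per_group Named counts for CN/SCD/MCI (study_like mode).
#' @param loading_age,loading_ptau,loading_memory,loading_icv Volume-model
#'   loadings a, p, q, beta on the standardized drivers.
#' @param mu_volume,sd_volume Per-side total volume mean and SD (mm^3).
#' @param segment_noise_sd Per-segment additive noise SD (mm^3).
#' @param abeta_weight_abnormal,abeta_mean_abnormal,abeta_sd_abnormal,abeta_mean_normal,abeta_sd_normal
#'   Amyloid mixture parameters (ng/l).
#' @param memory_loading_right Right-hemisphere memory loading (weaker, per
#'   the left-dominant asymmetry the literature reports).
#' @param posterior_atrophy_sd Study-like mode: size of the posterior-only
#'   atrophy in biomarker-abnormal participants, in units of the per-segment
#'   volume SD, applied to segments 1-5.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(mode = c("calibration", "study_like"),
                          n_per_group = c(CN = 302, SCD = 183, MCI = 171),
                          loading_age = 0.34,
                          loading_ptau = 0.1693,
                          loading_memory = 0.4195,
                          loading_icv = 0.20,
                          mu_volume = 500, sd_volume = 80,
                          segment_noise_sd = 4,
                          abeta_weight_abnormal = 0.393,
                          abeta_mean_abnormal = 395, abeta_sd_abnormal = 78,
                          abeta_mean_normal = 762, abeta_sd_normal = 150,
                          memory_loading_right = 0.4195 * 0.36 / 0.41,
                          posterior_atrophy_sd = 0.5) {
  mode <- match.arg(mode)
  ss <- loading_age^2 + loading_ptau^2 + loading_memory^2 + loading_icv^2
  if (ss >= 1) abort("volume-model loadings must satisfy a^2+p^2+q^2+beta^2 < 1.")
  stopifnot(sd_volume > 0, segment_noise_sd >= 0,
            abeta_sd_abnormal > 0, abeta_sd_normal > 0,
            abeta_mean_abnormal < abeta_mean_normal,
            abeta_weight_abnormal > 0, abeta_weight_abnormal < 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' @param n Total number of participants (calibration mode; study_like mode
#'   uses the per-group counts in `config`).
#' @param seed Integer seed; same config + seed gives an identical table.
#' @param config A [cohort_config()].
#' @param n_segments Number of segments per hemisphere (default 10).
#' @return Long tibble, one row per participant x hemisphere x segment:
#'   `participant_id`, `group`, `sex`, `age`, `icv`, `abeta42`, `ptau`,
#'   `memory_errors`, `hemisphere`, `segment`, `volume_mm3`.
#' @export
generate_cohort <- function(n = 656, seed = 1,
                            config = cohort_config(), n_segments = 10L) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  cfg <- config
  study_like <- cfg$mode == "study_like"
  if (study_like) {
    group <- factor(rep(names(cfg$n_per_group), cfg$n_per_group),
                    levels = names(cfg$n_per_group))
    n <- length(group)
  } else {
    group <- factor(rep("CN", n), levels = c("CN", "SCD", "MCI"))
  }

  # standardized independent drivers
  A <- rnorm(n)
  P <- rnorm(n)
  M <- rnorm(n)
  I <- rnorm(n)

  if (study_like) {
    age_mu <- c(CN = 73.7, SCD = 70.5, MCI = 71.3)[group]
    age_sd <- c(CN = 5.0, SCD = 5.7, MCI = 5.3)[group]
    ptau_mu <- c(CN = 54, SCD = 57, MCI = 67)[group]
    ptau_sd <- c(CN = 19, SCD = 25, MCI = 29)[group]
    mem_mu <- c(CN = 2, SCD = 3.4, MCI = 7)[group]
    mem_sd <- c(CN = 2, SCD = 2, MCI = 2)[group]
    p_female <- c(CN = 182 / 302, SCD = 100 / 183, MCI = 102 / 171)[group]
  } else {
    age_mu <- 72.2; age_sd <- 5.5
    ptau_mu <- 58; ptau_sd <- 24
    mem_mu <- 3.6; mem_sd <- 2.8
    p_female <- 384 / 656
  }
  # rejection-sample the P driver so ptau = mu + sd * P is non-negative
  repeat {
    bad <- ptau_mu + ptau_sd * P < 0
    if (!any(bad)) break
    P[bad] <- rnorm(sum(bad))
  }
  age <- age_mu + age_sd * A
  ptau <- ptau_mu + ptau_sd * P
  icv <- 1.45e6 + 1.5e5 * I
  memory_errors <- as.integer(round(pmin(pmax(mem_mu + mem_sd * M, 0), 10)))
  sex <- factor(ifelse(runif(n) < p_female, "F", "M"), levels = c("F", "M"))

  # amyloid: independent mixture in calibration mode; status-stratified by
  # group positivity rates in study_like mode
  if (study_like) {
    p_pos <- c(CN = 82 / 302, SCD = 69 / 183, MCI = 107 / 171)[group]
    abeta_pos <- runif(n) < p_pos
  } else {
    abeta_pos <- runif(n) < cfg$abeta_weight_abnormal
  }
  abeta42 <- ifelse(abeta_pos,
                    rnorm(n, cfg$abeta_mean_abnormal, cfg$abeta_sd_abnormal),
                    rnorm(n, cfg$abeta_mean_normal, cfg$abeta_sd_normal))
  abeta42 <- pmax(abeta42, 1)

  a <- cfg$loading_age; pl <- cfg$loading_ptau
  bI <- cfg$loading_icv
  base <- c(0.9, 1, 1.05, 1.1, 1.1, 1.1, 1.1, 1.05, 1, 0.9)
  if (n_segments != 10L) base <- rep(1, n_segments)
  u <- base / sum(base)
  w <- (n_segments + 1 - seq_len(n_segments)) / sum(seq_len(n_segments))

  make_side <- function(q_side) {
    e <- sqrt(1 - a^2 - pl^2 - q_side^2 - bI^2)
    Z <- rnorm(n)
    common <- cfg$mu_volume +
      cfg$sd_volume * (-a * A + bI * I + e * Z)       # spread uniformly
    channel <- cfg$sd_volume * (-pl * P - q_side * M) # posterior-weighted
    eps <- matrix(rnorm(n * n_segments, 0, cfg$segment_noise_sd), n, n_segments)
    V <- outer(common, u) + outer(channel, w) + eps
    if (study_like) {
      seg_sd <- apply(V, 2, sd)
      abnormal <- abeta_pos | ptau > 52
      post <- seq_len(n_segments) <= n_segments %/% 2
      V[abnormal, post] <- V[abnormal, post] -
        rep(cfg$posterior_atrophy_sd * seg_sd[post], each = sum(abnormal))
    }
    V
  }
  Vl <- make_side(cfg$loading_memory)
  Vr <- make_side(cfg$memory_loading_right)

  demo <- tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    group = group, sex = sex, age = age, icv = icv,
    abeta42 = abeta42, ptau = ptau, memory_errors = memory_errors)
  long <- bind_rows(
    tidyr::expand_grid(demo, segment = seq_len(n_segments)) |>
      mutate(hemisphere = "left", volume_mm3 = as.vector(t(Vl))),
    tidyr::expand_grid(demo, segment = seq_len(n_segments)) |>
      mutate(hemisphere = "right", volume_mm3 = as.vector(t(Vr)))
  ) |>
    relocate("hemisphere", .before = "segment") |>
    arrange(.data$participant_id, .data$hemisphere, .data$segment)
  attr(long, "config") <- cfg
  long
}
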
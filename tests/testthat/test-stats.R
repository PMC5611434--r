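test_that("z-scoring matches the direct formula per cell", {
  cohort <- toy_cohort(n = 20, seed = 3)
  z <- zscore_by_segment(cohort)
  cell <- z |> dplyr::filter(hemisphere == "left", segment == 4)
  expect_equal(cell$volume_z,
               (cell$volume_mm3 - mean(cell$volume_mm3)) / sd(cell$volume_mm3),
               tolerance = 1e-12)
  expect_equal(mean(cell$volume_z), 0, tolerance = 1e-12)

  two <- cohort |> dplyr::filter(participant_id %in% c("S001", "S002"))
  expect_error(zscore_by_segment(two), ">= 3")
  const <- toy_cohort(n = 10) |> dplyr::mutate(volume_mm3 = 5)
  expect_error(zscore_by_segment(const), "zero volume SD")
})

test_that("half aggregation sums segments 1-5 and 6-10 and conserves volume", {
  cohort <- toy_cohort(n = 12, seed = 8)
  flat <- cohort |> dplyr::mutate(volume_mm3 = 10)
  h <- aggregate_halves(flat)
  uni <- h |> dplyr::filter(hemisphere != "bilateral")
  expect_true(all(uni$posterior50 == 50 & uni$anterior50 == 50))
  expect_true(all(h$posterior50[h$hemisphere == "bilateral"] == 100))

  h2 <- aggregate_halves(cohort)
  expect_equal(h2$posterior50 + h2$anterior50, h2$total_mm3, tolerance = 1e-12)
  bil <- h2 |> dplyr::filter(hemisphere == "bilateral")
  uni <- h2 |> dplyr::filter(hemisphere != "bilateral") |>
    dplyr::group_by(participant_id) |> dplyr::summarise(tot = sum(total_mm3))
  expect_equal(bil$total_mm3, uni$tot[match(bil$participant_id, uni$participant_id)])

  # a participant missing one segment is dropped from that hemisphere
  holed <- cohort
  holed$volume_mm3[holed$participant_id == "S001" &
                     holed$hemisphere == "left" & holed$segment == 3] <- NA
  expect_message(h3 <- aggregate_halves(holed), "missing segments")
  expect_false(any(h3$participant_id == "S001" & h3$hemisphere %in% c("left", "bilateral")))
  expect_true(any(h3$participant_id == "S001" & h3$hemisphere == "right"))
})

test_that("partial correlation reduces to Pearson and kills covariate signal", {
  set.seed(41)
  x <- rnorm(80); y <- rnorm(80)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)

  z <- matrix(rnorm(160), ncol = 2)
  y_lin <- 2 + 3 * z[, 1] - z[, 2] + rnorm(80, 0, 1e-8)
  expect_lt(abs(partial_correlation(x, y_lin, z)$r), 0.05)
  expect_error(partial_correlation(x, rep(1, 80)), "constant")
})

test_that("partial correlation matches residualization and recursion oracles", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 60
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- 0.5 * z1 + rnorm(n)
    y <- -0.3 * z2 + 0.2 * x + rnorm(n)
    res <- partial_correlation(x, y, cbind(z1, z2))
    # oracle 1: explicit lm residualization
    r1 <- cor(resid(lm(x ~ z1 + z2)), resid(lm(y ~ z1 + z2)))
    # oracle 2: recursive partial-correlation formula
    pr <- function(rxy, rxz, ryz) (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    r_xy.1 <- pr(cor(x, y), cor(x, z1), cor(y, z1))
    r_xz2.1 <- pr(cor(x, z2), cor(x, z1), cor(z2, z1))
    r_yz2.1 <- pr(cor(y, z2), cor(y, z1), cor(z2, z1))
    r2 <- pr(r_xy.1, r_xz2.1, r_yz2.1)
    expect_equal(res$r, r1, tolerance = 1e-10)
    expect_equal(res$r, r2, tolerance = 1e-10)
    expect_equal(res$df, n - 4)
  }
})

test_that("with k = 2 the interaction F is the squared t on difference scores", {
  set.seed(51)
  n <- 40
  g <- factor(rep(c("a", "b"), each = n / 2))
  Y <- cbind(rnorm(n, 10), rnorm(n, 12))
  Y[g == "b", 2] <- Y[g == "b", 2] + 1.5
  fit <- rm_splitplot(Y, data.frame(g = g), between = "g", covariates = character())
  d <- Y[, 2] - Y[, 1]
  tt <- t.test(d ~ g, var.equal = TRUE)
  Fint <- fit$anova |> dplyr::filter(term == "g:within")
  expect_equal(Fint$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(Fint$p.value, tt$p.value, tolerance = 1e-10)
  expect_equal(Fint$df_num, 1)
  expect_equal(Fint$df_den, n - 2)
})

test_that("between-stratum tests match Type III ANCOVA on subject means", {
  skip_if_not_installed("car")
  set.seed(52)
  n <- 90
  df <- data.frame(g = factor(sample(c("x", "y"), n, TRUE)),
                   sex = factor(sample(c("F", "M"), n, TRUE)),
                   age = rnorm(n, 70, 5), icv = rnorm(n))
  Y <- matrix(rnorm(n * 10, 50, 5), n, 10) + 0.4 * df$age
  fit <- rm_splitplot(Y, df, between = c("g", "sex"),
                      covariates = c("age", "icv"))
  ybar <- rowMeans(Y)
  lm_fit <- lm(ybar ~ g + sex + age + icv, data = df,
               contrasts = list(g = "contr.sum", sex = "contr.sum"))
  ca <- car::Anova(lm_fit, type = "III")
  btw <- fit$anova |> dplyr::filter(stratum == "between")
  for (trm in c("g", "sex", "age", "icv")) {
    expect_equal(btw$statistic[btw$term == trm], ca[trm, "F value"],
                 tolerance = 1e-10)
  }
})

test_that("interaction df reproduce the split-plot shape (k-1 pooling)", {
  set.seed(53)
  cohort <- toy_cohort(n = 60, seed = 53) |>
    dplyr::filter(hemisphere == "left") |>
    dplyr::mutate(status = factor(rep(sample(c("n", "p"), 60, TRUE), each = 10)))
  fit <- rm_glm(cohort, outcome = "volume_mm3", subject = "participant_id",
                within = "segment", between = c("status", "sex"),
                covariates = c("age", "icv"))
  inter <- fit$anova |> dplyr::filter(term == "status:within")
  expect_equal(inter$df_num, 9)
  expect_equal(inter$df_den, 9 * (fit$n_subjects - fit$p_between))
  expect_gt(fit$epsilon_gg, 1 / 9)
  expect_lte(fit$epsilon_gg, 1 + 1e-12)
})

test_that("rm_glm is invariant to row order and rejects aliased designs", {
  cohort <- toy_cohort(n = 40, seed = 54) |>
    dplyr::filter(hemisphere == "left") |>
    dplyr::mutate(status = factor(rep(sample(c("n", "p"), 40, TRUE), each = 10)))
  f1 <- rm_glm(cohort, "volume_mm3", "participant_id", "segment",
               between = "status", covariates = "age")
  set.seed(1)
  f2 <- rm_glm(cohort[sample(nrow(cohort)), ], "volume_mm3", "participant_id",
               "segment", between = "status", covariates = "age")
  expect_equal(f1$anova, f2$anova, tolerance = 1e-12)

  aliased <- cohort |> dplyr::mutate(status2 = status)
  expect_error(rm_glm(aliased, "volume_mm3", "participant_id", "segment",
                      between = c("status", "status2")),
               "rank-deficient")
})

test_that("post hoc comparisons: 6 pairs, Bonferroni capping, LSD raw", {
  set.seed(55)
  n <- 120
  bins <- factor(sample(c("0-1", "2-3", "4-5", "6-10"), n, TRUE))
  Y <- cbind(rnorm(n, 100, 10), rnorm(n, 90, 10))
  df <- data.frame(bin = bins, age = rnorm(n))
  fit <- rm_splitplot(Y, df, between = "bin", covariates = "age")
  ph_b <- posthoc_pairwise(fit, "bonferroni")
  ph_f <- posthoc_pairwise(fit, "fisher_lsd")
  expect_equal(nrow(ph_b), 6 * 2)   # 6 pairs x 2 within levels
  expect_equal(ph_b$p.adj, pmin(1, 6 * ph_b$p.value))
  expect_equal(ph_f$p.adj, ph_f$p.value)
  two <- rm_splitplot(Y, data.frame(g = factor(rep(c("a", "b"), each = 60))),
                      between = "g", covariates = character())
  expect_error(posthoc_pairwise(two), ">= 3")
})

test_that("a monotone bin effect is detected extreme-pair-first", {
  set.seed(56)
  hits <- c(extreme = 0, adjacent = 0)
  for (r in 1:60) {
    n <- 160
    bins <- factor(rep(c("0-1", "2-3", "4-5", "6-10"), each = n / 4))
    eff <- c(`0-1` = 0, `2-3` = -2, `4-5` = -4, `6-10` = -6)[bins]
    Y <- cbind(rnorm(n, 100, 8) + eff, rnorm(n, 95, 8) + eff)
    fit <- rm_splitplot(Y, data.frame(bin = bins), between = "bin",
                        covariates = character())
    ph <- posthoc_pairwise(fit, "bonferroni") |> dplyr::filter(within_level == 1)
    sig <- function(l1, l2) ph$p.adj[ph$level_1 == l1 & ph$level_2 == l2] < 0.05
    if (sig("0-1", "6-10") | !sig("0-1", "2-3")) hits["extreme"] <- hits["extreme"] + 1
  }
  # the extreme pair should be significant whenever the adjacent one is
  expect_gte(hits[["extreme"]] / 60, 0.9)
})
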
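# Biomarker dichotomization: mixture-model amyloid cutoff, fixed P-tau
# cutoffs, and delayed-recall error bins.
#
# CSF abeta42 is bimodally distributed, so the cutoff separating amyloid-
# positive from amyloid-negative participants is estimated from the data: a
# two-component univariate Gaussian mixture is fitted by EM (unequal
# variances, multiple quantile-seeded restarts) and the cutoff is the
# equal-posterior point between the two component means, i.e. the value
# where w_a * phi(x; mu_a, sd_a) = w_n * phi(x; mu_n, sd_n).

#' Fit a two-component Gaussian mixture and derive a biomarker cutoff
#'
#' EM with `n_restarts` quantile-plus-jitter starting points; the best fit by
#' log-likelihood is kept. Components are ordered so `mean_abnormal <
#' mean_normal` (low values = pathology for amyloid). The cutoff is the
#' equal-posterior point located by bracketed root-finding strictly between
#' the two means. A variance floor of `1e-4 * var(values)` guards against
#' degenerate components.
#'
#' @param values Numeric vector of biomarker concentrations (ng/l); at least
#'   50 finite positive values required.
#' @param n_restarts EM restarts (default 10).
#' @param seed Optional integer seed for the restart jitter.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @return Object of class `mixture_cutoff` with fields `weight_abnormal`,
#'   `mean_abnormal`, `sd_abnormal`, `mean_normal`, `sd_normal`, `cutoff`,
#'   `loglik`, `n_iter`, `converged`, `n_restarts`, `separation`.
#' @export
fit_mixture_cutoff <- function(values, n_restarts = 10L, seed = NULL,
                               tol = 1e-8, max_iter = 500L) {
  values <- values[is.finite(values)]
  if (length(values) < 50L || any(values <= 0)) {
    abort("need >= 50 finite positive values.")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- length(values)
  v_floor <- 1e-4 * var(values)
  s0 <- sd(values)
  best <- NULL
  qs <- seq(0.2, 0.8, length.out = n_restarts)
  for (r in seq_len(n_restarts)) {
    split <- quantile(values, qs[r], names = FALSE) + rnorm(1, 0, 0.05 * s0)
    fit <- em_gauss2(values, split, tol, max_iter, v_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    abort("mixture EM failed to converge from any restart.")
  }
  # order components: abnormal = lower mean
  o <- order(best$mu)
  mu <- best$mu[o]; sig <- best$sigma[o]; w <- best$w[o]
  cutoff <- equal_posterior_point(w[1], mu[1], sig[1], w[2], mu[2], sig[2])
  structure(
    list(weight_abnormal = w[1], mean_abnormal = mu[1], sd_abnormal = sig[1],
         weight_normal = w[2], mean_normal = mu[2], sd_normal = sig[2],
         cutoff = cutoff, loglik = best$loglik, n_iter = best$n_iter,
         converged = best$converged, n_restarts = n_restarts, n = n,
         separation = abs(mu[2] - mu[1]) / sqrt(mean(sig^2))),
    class = "mixture_cutoff"
  )
}

# EM iterations for a 2-component univariate Gaussian mixture.
# Log-likelihood is checked to be non-decreasing every iteration.
em_gauss2 <- function(x, split, tol, max_iter, v_floor) {
  n <- length(x)
  below <- x <= split
  if (sum(below) < 2L || sum(!below) < 2L) {
    below <- x <= median(x)
  }
  mu <- c(mean(x[below]), mean(x[!below]))
  sig <- pmax(c(sd(x[below]), sd(x[!below])), sqrt(v_floor))
  w <- c(mean(below), 1 - mean(below))
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * dnorm(x, mu[1], sig[1])
    d2 <- w[2] * dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    ll <- sum(log(tot))
    if (ll < ll_old - 1e-8 * abs(ll_old)) {
      abort("EM log-likelihood decreased; numerical failure.")
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
    g <- d1 / tot
    n1 <- sum(g)
    if (n1 < 1e-8 || n - n1 < 1e-8) break   # component collapsed
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / (n - n1))
    sig <- sqrt(pmax(
      c(sum(g * (x - mu[1])^2) / n1, sum((1 - g) * (x - mu[2])^2) / (n - n1)),
      v_floor))
    w <- c(n1 / n, 1 - n1 / n)
  }
  list(mu = mu, sigma = sig, w = w, loglik = ll, n_iter = it,
       converged = converged)
}

#' Equal-posterior point between two Gaussian components
#'
#' Root of `w1 * phi(x; m1, s1) = w2 * phi(x; m2, s2)` between the two means
#' (where the posterior probability of either component is 0.5), found by
#' bracketed root-finding on the log-density difference.
#'
#' @param w1,m1,s1 Weight, mean, SD of the lower (abnormal) component.
#' @param w2,m2,s2 Weight, mean, SD of the upper (normal) component.
#' @return The crossover value.
#' @export
equal_posterior_point <- function(w1, m1, s1, w2, m2, s2) {
  if (!(m1 < m2)) abort("requires m1 < m2.")
  f <- function(x) {
    log(w1) + dnorm(x, m1, s1, log = TRUE) -
      log(w2) - dnorm(x, m2, s2, log = TRUE)
  }
  lo <- m1 + 1e-9 * (m2 - m1)
  hi <- m2 - 1e-9 * (m2 - m1)
  if (f(lo) <= 0 || f(hi) >= 0) {
    abort("no equal-posterior crossing between the component means (components may overlap too strongly).")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.mixture_cutoff <- function(x, ...) {
  cat(sprintf(
    "<mixture_cutoff> cutoff %.1f ng/l | abnormal %.1f%%: N(%.1f, %.1f^2) | normal: N(%.1f, %.1f^2)\n",
    x$cutoff, 100 * x$weight_abnormal, x$mean_abnormal, x$sd_abnormal,
    x$mean_normal, x$sd_normal))
  if (x$separation < 2) {
    cat("  warning: components poorly separated; cutoff may be unstable.\n")
  }
  invisible(x)
}

#' @rdname fit_mixture_cutoff
#' @param x A `mixture_cutoff`.
#' @param ... Unused.
#' @export
tidy.mixture_cutoff <- function(x, ...) {
  tibble(component = c("abnormal", "normal"),
         weight = c(x$weight_abnormal, x$weight_normal),
         mean = c(x$mean_abnormal, x$mean_normal),
         sd = c(x$sd_abnormal, x$sd_normal))
}

#' @rdname fit_mixture_cutoff
#' @export
glance.mixture_cutoff <- function(x, ...) {
  tibble(cutoff = x$cutoff, loglik = x$loglik, n = x$n,
         n_iter = x$n_iter, converged = x$converged,
         separation = x$separation)
}

#' Classify amyloid status from CSF abeta42
#'
#' Values at or below the cutoff are amyloid-positive (pathologically low);
#' the boundary value itself is positive.
#'
#' @param value Numeric vector of abeta42 concentrations (ng/l).
#' @param cutoff Cutoff in ng/l (default 527).
#' @return Factor with levels `positive`, `negative`.
#' @export
classify_abeta <- function(value, cutoff = 527) {
  stopifnot(all(is.finite(value) & value >= 0))
  factor(ifelse(value <= cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Classify tau status from CSF P-tau
#'
#' Values strictly above the cutoff are elevated. The default 52 ng/l is the
#' primary cutoff; 70 ng/l is a supported higher alternative.
#'
#' @param value Numeric vector of P-tau concentrations (ng/l).
#' @param cutoff Cutoff in ng/l (default 52).
#' @return Factor with levels `normal`, `elevated`.
#' @export
classify_ptau <- function(value, cutoff = 52) {
  stopifnot(all(is.finite(value) & value >= 0))
  factor(ifelse(value > cutoff, "elevated", "normal"),
         levels = c("normal", "elevated"))
}

#' Bin delayed-recall errors
#'
#' Number of forgotten items on a 10-word delayed recall list, binned into
#' 0--1, 2--3, 4--5 and 6--10 errors.
#'
#' @param errors Integer vector in `0..10`.
#' @return Ordered factor with levels `0-1`, `2-3`, `4-5`, `6-10`.
#' @export
bin_memory_errors <- function(errors) {
  if (any(!is.finite(errors)) || any(errors != round(errors)) ||
      any(errors < 0 | errors > 10)) {
    abort("`errors` must be integers in 0..10 (10-word list).")
  }
  cut(errors, breaks = c(-0.5, 1.5, 3.5, 5.5, 10.5),
      labels = c("0-1", "2-3", "4-5", "6-10"), ordered_result = TRUE)
}
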
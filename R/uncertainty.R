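# Asymptotic variance and log-normal confidence intervals.
#
# Treating the observed frequency counts as approximately multinomial with
# total S and cell probabilities E[f_k]/S, the delta method gives
#   var(S_hat) ~ sum_i sum_j (dS/df_i)(dS/df_j) cov(f_i, f_j),
#   cov(f_i, f_j) = f_i (1 - f_i/S_hat)   if i = j,
#                 = -f_i f_j / S_hat       otherwise,
# with the point estimate plugged in for S. The double sum collapses to
#   sum_i g_i^2 f_i - (sum_i g_i f_i)^2 / S_hat.

# Gradient of the estimator with respect to each stored frequency count.
# Estimators that pass the counts through S_obs only have dS/df_k = 1 for
# every observed k; analytic partials are added for the f1..f3 terms. The
# clamp and substitution pieces of the GP/LB multipliers contribute the
# one-sided derivative of the active piece (zero inside clamped regions,
# zero through substituted counts).
richness_gradient <- function(fc, estimator) {
  ks <- multiplicities(fc)
  g <- rep(1, length(ks))
  f1 <- fk(fc, 1); f2 <- fk(fc, 2); f3 <- fk(fc, 3)
  # partials of the Chao1 unseen-species term
  if (f2 > 0) {
    d01 <- f1 / f2
    d02 <- -f1^2 / (2 * f2^2)
  } else {
    d01 <- if (f1 > 0) (2 * f1 - 1) / 2 else 0
    d02 <- 0
  }
  set_g <- function(g, k, value) { g[ks == k] <- value; g }

  if (estimator == "jackknife1") {
    g <- set_g(g, 1, 2)
  } else if (estimator == "chao1") {
    g <- set_g(g, 1, 1 + d01)
    g <- set_g(g, 2, 1 + d02)
  } else if (estimator == "gp") {
    f0c <- f0_chao1(f1, f2)
    mr <- moment_ratio(f1, f2, f3)
    A <- mr$A
    active <- A > 0.5 && A < 1
    m <- 2 - (if (A >= 1) 1 else max(0.5, A))
    dm1 <- if (active && f1 > 0) A / f1 else 0
    dm2 <- if (active && f2 > 0) -2 * A / f2 else 0
    dm3 <- if (active && f3 > 0) A / f3 else 0
    g <- set_g(g, 1, 1 + d01 * m + f0c * dm1)
    g <- set_g(g, 2, 1 + d02 * m + f0c * dm2)
    g <- set_g(g, 3, 1 + f0c * dm3)
  } else if (estimator == "lb") {
    f0c <- f0_chao1(f1, f2)
    mr <- moment_ratio(f1, f2, f3, substitute_f2 = TRUE)
    M <- 1 / mr$A
    dM1 <- if (f1 > 0) M / f1 else 0
    dM2 <- if (f2 > 0) -2 * M / f2 else 0
    dM3 <- if (f3 > 0) M / f3 else 0
    g <- set_g(g, 1, 1 + d01 * M + f0c * dM1)
    g <- set_g(g, 2, 1 + d02 * M + f0c * dM2)
    g <- set_g(g, 3, 1 + f0c * dM3)
  } else {
    stop(sprintf("no analytic gradient for estimator '%s'", estimator))
  }
  stats::setNames(g, names(fc$f))
}

# Chao-Bunge point estimate as a closed function of the frequency vector;
# n and sum(X^2) are recomputed so finite differences see the full
# dependence of theta on every f_k.
cb_point_closed <- function(ks, f) {
  n <- sum(ks * f)
  ss <- sum(as.numeric(ks)^2 * f)
  f1 <- if (any(ks == 1)) f[ks == 1] else 0
  theta <- 1 - f1 * ss / n^2
  sum(f[ks >= 2]) / theta
}

cb_gradient_numeric <- function(fc) {
  ks <- multiplicities(fc)
  f <- unname(fc$f)
  g <- vapply(seq_along(ks), function(i) {
    h <- 1e-4 * max(1, f[i])
    up <- f; up[i] <- up[i] + h
    dn <- f; dn[i] <- dn[i] - h
    (cb_point_closed(ks, up) - cb_point_closed(ks, dn)) / (2 * h)
  }, numeric(1))
  stats::setNames(g, names(fc$f))
}

#' Asymptotic variance of a frequency-count richness estimator
#'
#' Delta-method variance under the multinomial approximation to the
#' frequency counts, with the point estimate plugged in for the total.
#' Gradients are analytic for `chao1`, `jackknife1`, `gp` and `lb`;
#' `chao_bunge` depends on the full spectrum through \eqn{n} and
#' \eqn{\sum X_i^2}, so its gradient is taken by central finite
#' differences (step \eqn{10^{-4}\max(1, f_k)}).
#'
#' @param fc a [freq_counts()] object.
#' @param estimator estimator id (`"chao1"`, `"jackknife1"`,
#'   `"chao_bunge"`, `"lb"`, `"gp"`).
#' @param point the point estimate the variance is evaluated at (must be
#'   `>= S_obs`); defaults to recomputing the estimator.
#' @param diagnostics unused hook for precomputed diagnostics.
#' @return A list with `variance` (floored at 0, with `clipped = TRUE`
#'   when the quadratic form went negative numerically), the `gradient`
#'   actually used (named by multiplicity), and `method`
#'   (`"analytic"` or `"numeric"`).
#' @export
variance_asymptotic <- function(fc, estimator, point = NULL,
                                diagnostics = NULL) {
  stopifnot(inherits(fc, "freq_counts"))
  if (is.null(point)) {
    point <- richness_estimator(estimator)(fc, se = FALSE)$point
  }
  if (is.na(point)) {
    stop(sprintf("point estimate for '%s' is undefined; no variance",
                 estimator))
  }
  if (point < fc$S_obs) stop("point estimate below observed richness")
  if (estimator == "chao_bunge") {
    g <- cb_gradient_numeric(fc)
    method <- "numeric"
  } else {
    g <- richness_gradient(fc, estimator)
    method <- "analytic"
  }
  f <- unname(fc$f)
  v <- sum(g^2 * f) - sum(g * f)^2 / point
  clipped <- v < 0
  list(variance = max(v, 0), gradient = g, method = method,
       clipped = clipped)
}

#' Log-normal confidence interval for a richness estimate
#'
#' Assumes \eqn{\hat S - S_{obs}} is log-normally distributed, which keeps
#' the lower bound above the observed richness:
#' \deqn{[S_{obs} + (\hat S - S_{obs})/R,\; S_{obs} + (\hat S - S_{obs}) R],
#'   \quad R = \exp\{z \sqrt{\log(1 + var(\hat S)/(\hat S - S_{obs})^2)}\}.}
#' At the default 95\% level `z` is exactly 1.96; other levels use the
#' corresponding normal quantile. When the point estimate equals the
#' observed richness the interval degenerates to `[S_obs, S_obs]`.
#'
#' @param S_obs observed richness.
#' @param point point estimate (`>= S_obs`).
#' @param variance estimated variance (`>= 0`).
#' @param level confidence level in (0, 1).
#' @return A list with `lower`, `upper`, `R`, `level`, and `degenerate`.
#' @export
ci_lognormal <- function(S_obs, point, variance, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.na(variance) || variance < 0) stop("variance must be >= 0")
  if (point < S_obs) stop("point estimate below observed richness")
  if (point == S_obs) {
    return(list(lower = S_obs, upper = S_obs, R = NA_real_, level = level,
                degenerate = TRUE))
  }
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm((1 + level) / 2)
  d <- point - S_obs
  R <- exp(z * sqrt(log(1 + variance / d^2)))
  list(lower = S_obs + d / R, upper = S_obs + d * R, R = R, level = level,
       degenerate = FALSE)
}
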
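# Point estimators of total species richness.
#
# All estimators consume a freq_counts object and return a
# richness_estimate. The headline estimator is estimate_gp(), a
# bias-corrected Chao1 under the Gamma-Poisson mixture that uses only
# singletons, doubletons and tripletons of the sample.

# Chao1 estimate of the number of unseen species, with its f2 = 0 rule.
f0_chao1 <- function(f1, f2) {
  if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
}

#' Internal constructor for richness estimates
#'
#' Assembles the result object and, when requested and defined, attaches
#' the asymptotic standard error and log-normal confidence interval.
#' @noRd
new_richness_estimate <- function(estimator, fc, point, diagnostics = list(),
                                  se = TRUE, level = 0.95) {
  f0_hat <- if (is.na(point)) NA_real_ else point - fc$S_obs
  out <- list(
    estimator = estimator,
    point = point,
    S_obs = fc$S_obs,
    n = fc$n,
    f0_hat = f0_hat,
    se = NA_real_,
    variance = NA_real_,
    ci = c(lower = NA_real_, upper = NA_real_),
    level = level,
    diagnostics = diagnostics
  )
  class(out) <- "richness_estimate"
  if (isTRUE(se) && !is.na(point)) {
    vr <- variance_asymptotic(fc, estimator, point, diagnostics = diagnostics)
    out$variance <- vr$variance
    out$se <- sqrt(vr$variance)
    ci <- ci_lognormal(fc$S_obs, point, vr$variance, level = level)
    out$ci <- c(lower = ci$lower, upper = ci$upper)
    out$diagnostics$R <- ci$R
    if (isTRUE(vr$clipped)) {
      out$diagnostics$fallbacks <- c(out$diagnostics$fallbacks,
                                     "variance_clipped")
    }
  }
  out
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("%s richness estimate\n", x$estimator))
  cat(sprintf("  S_obs = %g, n = %g\n", x$S_obs, x$n))
  if (is.na(x$point)) {
    cat("  point estimate undefined:",
        paste(x$diagnostics$fallbacks, collapse = ", "), "\n")
  } else {
    cat(sprintf("  S_hat = %.2f (f0_hat = %.2f)\n", x$point, x$f0_hat))
    if (!is.na(x$se)) {
      cat(sprintf("  s.e. = %.2f, %d%% CI [%.2f, %.2f]\n", x$se,
                  round(100 * x$level), x$ci[["lower"]], x$ci[["upper"]]))
    }
  }
  fl <- x$diagnostics$fallbacks
  if (length(fl) > 0) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Chao1 lower-bound richness estimator
#'
#' \eqn{\hat S = S_{obs} + f_1^2/(2 f_2)}, with the unseen-species part
#' replaced by \eqn{f_1 (f_1 - 1)/2} when \eqn{f_2 = 0}. This is the
#' uncorrected lower-bound form; it is exactly the baseline that the
#' Gamma-Poisson estimator corrects.
#'
#' @param fc a [freq_counts()] object.
#' @param se compute the asymptotic standard error and CI (default TRUE).
#' @param level confidence level for the log-normal interval.
#' @return A `richness_estimate` object.
#' @export
estimate_chao1 <- function(fc, se = TRUE, level = 0.95) {
  stopifnot(inherits(fc, "freq_counts"))
  f1 <- fk(fc, 1); f2 <- fk(fc, 2)
  fallbacks <- if (f2 == 0) "f2_zero_fallback" else character()
  new_richness_estimate("chao1", fc, fc$S_obs + f0_chao1(f1, f2),
                        diagnostics = list(fallbacks = fallbacks),
                        se = se, level = level)
}

#' First-order jackknife richness estimator
#'
#' \eqn{\hat S = S_{obs} + f_1}.
#'
#' @inheritParams estimate_chao1
#' @return A `richness_estimate` object.
#' @export
estimate_jackknife1 <- function(fc, se = TRUE, level = 0.95) {
  stopifnot(inherits(fc, "freq_counts"))
  new_richness_estimate("jackknife1", fc, fc$S_obs + fk(fc, 1),
                        diagnostics = list(fallbacks = character()),
                        se = se, level = level)
}

#' Chao-Bunge richness estimator
#'
#' \eqn{\hat S_{CB} = \sum_{k \ge 2} f_k / \hat\theta} with
#' \eqn{\hat\theta = 1 - f_1 \sum_i X_i^2 / n^2}, the estimated
#' probability that a species is observed at least twice. Uses the full
#' frequency spectrum. On sparse samples \eqn{\hat\theta} can be
#' non-positive, in which case the estimate is undefined and flagged
#' (`theta_nonpositive`) rather than reported.
#'
#' @inheritParams estimate_chao1
#' @param allow_nonpositive_theta if TRUE, return the raw ratio even when
#'   \eqn{\hat\theta \le 0} (used to reproduce raw-average benchmarking);
#'   default FALSE reports the estimate as undefined.
#' @return A `richness_estimate` object.
#' @export
estimate_chao_bunge <- function(fc, se = TRUE, level = 0.95,
                                allow_nonpositive_theta = FALSE) {
  stopifnot(inherits(fc, "freq_counts"))
  f1 <- fk(fc, 1)
  theta <- 1 - f1 * fc$sum_sq / fc$n^2
  ks <- multiplicities(fc)
  tail_sum <- sum(fc$f[ks >= 2])
  fallbacks <- character()
  if (theta <= 0) {
    fallbacks <- "theta_nonpositive"
    point <- if (allow_nonpositive_theta && theta != 0) tail_sum / theta
             else NA_real_
    se <- FALSE
  } else {
    point <- tail_sum / theta
  }
  new_richness_estimate("chao_bunge", fc, point,
                        diagnostics = list(theta_hat = theta,
                                           fallbacks = fallbacks),
                        se = se, level = level)
}

# Shared moment machinery for the GP and LB estimators: the ratio
# A = 2 f2^2 / (3 f1 f3) with the substitution rules that keep it defined
# (f3 -> 1 when f3 = 0, f1 -> 1 when f1 = 0; and, for the LB multiplier
# only, f2 -> 1 when f2 = 0).
moment_ratio <- function(f1, f2, f3, substitute_f2 = FALSE) {
  fallbacks <- character()
  f1s <- f1; f2s <- f2; f3s <- f3
  if (f3 == 0) { f3s <- 1; fallbacks <- c(fallbacks, "f3_substituted") }
  if (f1 == 0) { f1s <- 1; fallbacks <- c(fallbacks, "f1_substituted") }
  if (substitute_f2 && f2 == 0) {
    f2s <- 1; fallbacks <- c(fallbacks, "f2_substituted")
  }
  list(A = 2 * f2s^2 / (3 * f1s * f3s), f1s = f1s, f2s = f2s, f3s = f3s,
       fallbacks = fallbacks)
}

#' Gamma-Poisson moment richness estimator
#'
#' The package's headline estimator: a bias-corrected Chao1 under the
#' Gamma-Poisson mixture model, using only singletons, doubletons and
#' tripletons,
#' \deqn{\hat S_{GP} = S_{obs} + \hat f_{0,Chao1}
#'   \left(2 - \left(\frac{2 f_2^2}{3 f_1 f_3}\right)^{-}\right),}
#' where \eqn{(A)^-} is 1 when \eqn{A \ge 1} and \eqn{\max(1/2, A)}
#' otherwise, so the correction multiplier always lies in \eqn{[1, 1.5]}.
#' \eqn{f_3} (or \eqn{f_1}) is replaced by 1 inside the ratio when zero,
#' which makes the estimator well-defined for every sample.
#'
#' @inheritParams estimate_chao1
#' @return A `richness_estimate` object. Diagnostics carry the raw ratio
#'   `A`, its clamped value `A_clamped`, the `multiplier`, the moment
#'   estimate `alpha_hat` when computable, and any substitution flags.
#' @examples
#' fc <- freq_counts_from_table(1:3, c(61, 35, 18))
#' estimate_gp(fc, se = FALSE)$point
#' @export
estimate_gp <- function(fc, se = TRUE, level = 0.95) {
  stopifnot(inherits(fc, "freq_counts"))
  f1 <- fk(fc, 1); f2 <- fk(fc, 2); f3 <- fk(fc, 3)
  f0c <- f0_chao1(f1, f2)
  fallbacks <- if (f2 == 0) "f2_zero_fallback" else character()
  mr <- moment_ratio(f1, f2, f3)
  A <- mr$A
  A_clamped <- if (A >= 1) 1 else max(0.5, A)
  multiplier <- 2 - A_clamped
  ah <- alpha_hat_moment(fc)
  new_richness_estimate(
    "gp", fc, fc$S_obs + f0c * multiplier,
    diagnostics = list(A = A, A_clamped = A_clamped,
                       multiplier = multiplier,
                       alpha_hat = ah$alpha_hat,
                       fallbacks = unique(c(fallbacks, mr$fallbacks))),
    se = se, level = level
  )
}

#' Negative-binomial lower-bound (LB) richness estimator
#'
#' \eqn{\hat S_{LB} = S_{obs} + \frac{f_1^2}{2 f_2}
#'   \frac{3 f_1 f_3}{2 f_2^2}}, an alternative bias-corrected Chao1
#' derived from the negative-binomial reparameterisation. The same
#' substitution rules as [estimate_gp()] keep the multiplier defined
#' (additionally \eqn{f_2 \to 1} inside the multiplier when
#' \eqn{f_2 = 0}, since unlike the GP ratio it has \eqn{f_2} in the
#' denominator).
#'
#' @inheritParams estimate_chao1
#' @return A `richness_estimate` object; diagnostics carry the
#'   `multiplier` \eqn{3 f_1 f_3 / (2 f_2^2)}.
#' @export
estimate_lb <- function(fc, se = TRUE, level = 0.95) {
  stopifnot(inherits(fc, "freq_counts"))
  f1 <- fk(fc, 1); f2 <- fk(fc, 2); f3 <- fk(fc, 3)
  f0c <- f0_chao1(f1, f2)
  fallbacks <- if (f2 == 0) "f2_zero_fallback" else character()
  mr <- moment_ratio(f1, f2, f3, substitute_f2 = TRUE)
  multiplier <- 1 / mr$A
  new_richness_estimate(
    "lb", fc, fc$S_obs + f0c * multiplier,
    diagnostics = list(multiplier = multiplier,
                       fallbacks = unique(c(fallbacks, mr$fallbacks))),
    se = se, level = level
  )
}

#' Compute several richness estimators at once
#'
#' @param fc a [freq_counts()] object.
#' @param estimators character vector of estimator ids among `"chao1"`,
#'   `"jackknife1"`, `"chao_bunge"`, `"lb"`, `"gp"`, `"mle"`.
#' @param se compute standard errors and confidence intervals.
#' @param level confidence level.
#' @return A data frame with one row per estimator: `estimator`, `S_obs`,
#'   `n`, `point`, `f0_hat`, `se`, `ci_lower`, `ci_upper`, `flags`.
#' @examples
#' fc <- freq_counts_from_table(1:3, c(61, 35, 18))
#' estimate_richness(fc, c("chao1", "gp"), se = FALSE)
#' @export
estimate_richness <- function(fc,
                              estimators = c("chao1", "jackknife1",
                                             "chao_bunge", "lb", "gp"),
                              se = TRUE, level = 0.95) {
  estimators <- match.arg(estimators,
                          c("chao1", "jackknife1", "chao_bunge", "lb",
                            "gp", "mle"),
                          several.ok = TRUE)
  rows <- lapply(estimators, function(id) {
    est <- richness_estimator(id)(fc, se = se, level = level)
    data.frame(
      estimator = id, S_obs = est$S_obs, n = est$n, point = est$point,
      f0_hat = est$f0_hat, se = est$se,
      ci_lower = est$ci[["lower"]], ci_upper = est$ci[["upper"]],
      flags = paste(est$diagnostics$fallbacks, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Dispatch an estimator id to its function, with a uniform
# (fc, se, level) signature.
richness_estimator <- function(id) {
  switch(id,
    chao1 = estimate_chao1,
    jackknife1 = estimate_jackknife1,
    chao_bunge = estimate_chao_bunge,
    lb = estimate_lb,
    gp = estimate_gp,
    mle = function(fc, se = TRUE, level = 0.95) {
      fit_gamma_poisson_mle(fc)$estimate
    },
    stop(sprintf("unknown estimator '%s'", id))
  )
}
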
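# Gamma-Poisson mixture model functions.
#
# Species detection counts X_i are modelled as Poisson(lambda_i) with
# lambda_i ~ Gamma(shape alpha, scale beta); marginally X_i is negative
# binomial. The probability that a species goes undetected is
# p0 = (beta/(beta+1))^alpha.

#' Gamma-Poisson parameter set
#'
#' @param alpha gamma shape parameter (> 0). Small values mean strong
#'   heterogeneity among species detection rates; `alpha = 1` is the
#'   broken-stick (exponential) model and `alpha -> Inf` the homogeneous
#'   model.
#' @param beta gamma scale parameter (> 0).
#' @return A list of class `gp_params` with `alpha`, `beta` and the derived
#'   undetected-species probability `p0 = (beta/(beta+1))^alpha`.
#' @export
gp_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1,
            length(beta) == 1)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be finite and > 0")
  if (!is.finite(beta) || beta <= 0) stop("beta must be finite and > 0")
  structure(
    list(alpha = alpha, beta = beta,
         p0 = exp(alpha * (log(beta) - log(beta + 1)))),
    class = "gp_params"
  )
}

#' Marginal count distribution under the Gamma-Poisson mixture
#'
#' Probability that a species is observed exactly `k` times:
#' \deqn{p_k = \frac{\Gamma(\alpha+k)}{k!\,\Gamma(\alpha)}
#'   \left(\frac{\beta}{\beta+1}\right)^{\alpha}
#'   \left(\frac{1}{\beta+1}\right)^{k},}
#' i.e. a negative binomial pmf, evaluated in log space.
#'
#' @param k non-negative integer multiplicities (vectorised).
#' @param params a [gp_params()] object.
#' @return numeric vector of probabilities.
#' @examples
#' gamma_poisson_pmf(0:3, gp_params(2, 3))
#' @export
gamma_poisson_pmf <- function(k, params) {
  stopifnot(inherits(params, "gp_params"))
  if (any(!is_whole(k)) || any(k < 0)) stop("k must be integers >= 0")
  a <- params$alpha; b <- params$beta
  exp(lgamma(a + k) - lgamma(k + 1) - lgamma(a) +
        a * (log(b) - log(b + 1)) - k * log(b + 1))
}

#' Expected frequency counts E[f_k] = S p_k
#'
#' @param S true species richness (> 0).
#' @param params a [gp_params()] object.
#' @param k_max largest multiplicity to evaluate.
#' @return numeric vector `E[f_k]` for `k = 0, 1, ..., k_max` (so element
#'   `i` is `E[f_(i-1)]`).
#' @export
expected_freq_counts <- function(S, params, k_max) {
  stopifnot(S > 0, is_whole(k_max), k_max >= 0)
  S * gamma_poisson_pmf(0:k_max, params)
}

#' Moment estimator of the gamma shape parameter
#'
#' Estimates the shape \eqn{\alpha} from singletons, doubletons and
#' tripletons via
#' \eqn{\hat\alpha = (4 f_2^2 - 3 f_1 f_3) / (3 f_1 f_3 - 2 f_2^2)}.
#' When \eqn{f_3 = 0} (or \eqn{f_1 = 0}) that count is replaced by 1 so
#' the ratio stays defined; the estimate is positive exactly when
#' \eqn{3 f_1 f_3 \in (2 f_2^2,\, 4 f_2^2)}.
#'
#' @param fc a [freq_counts()] object.
#' @return A list with `alpha_hat` (NA when the denominator is exactly
#'   zero), the raw `f1`, `f2`, `f3` used, `valid` (TRUE when the estimate
#'   is positive), and `fallbacks` (character vector of substitution
#'   flags).
#' @export
alpha_hat_moment <- function(fc) {
  stopifnot(inherits(fc, "freq_counts"))
  f1 <- fk(fc, 1); f2 <- fk(fc, 2); f3 <- fk(fc, 3)
  fallbacks <- character()
  f1s <- f1; f3s <- f3
  if (f3 == 0) { f3s <- 1; fallbacks <- c(fallbacks, "f3_substituted") }
  if (f1 == 0) { f1s <- 1; fallbacks <- c(fallbacks, "f1_substituted") }
  num <- 4 * f2^2 - 3 * f1s * f3s
  den <- 3 * f1s * f3s - 2 * f2^2
  if (den == 0) {
    return(list(alpha_hat = NA_real_, f1 = f1, f2 = f2, f3 = f3,
                valid = FALSE,
                fallbacks = c(fallbacks, "alpha_denominator_zero")))
  }
  a <- num / den
  list(alpha_hat = a, f1 = f1, f2 = f2, f3 = f3,
       valid = is.finite(a) && a > 0, fallbacks = fallbacks)
}

#' Maximum-likelihood fit of the Gamma-Poisson model (experimental)
#'
#' Maximises the zero-truncated likelihood of the observed frequency
#' counts over \eqn{(\alpha, \beta)} in log-parameter space and returns
#' the Horvitz-Thompson richness estimate
#' \eqn{\hat S_{MLE} = S_{obs} / (1 - \hat p_0)}. Kept out of the default
#' simulation battery: on sparse or homogeneous-like data the likelihood
#' is flat in the \eqn{\alpha \to \infty} direction and the optimum
#' escapes to the boundary, which is reported as a flagged failure rather
#' than a silent answer.
#'
#' @param fc a [freq_counts()] object with at least two distinct observed
#'   multiplicities.
#' @param init optional [gp_params()] starting point; defaults to the
#'   moment estimate of `alpha` (clamped to a sane range) with `beta`
#'   matched to the observed mean count.
#' @param tol relative convergence tolerance passed to [stats::optim()].
#' @param max_iter maximum number of iterations.
#' @return A list with `params` (a `gp_params` object), `estimate` (a
#'   `richness_estimate`), `logLik`, `converged`, and `flags`.
#' @export
fit_gamma_poisson_mle <- function(fc, init = NULL, tol = 1e-10,
                                  max_iter = 500) {
  stopifnot(inherits(fc, "freq_counts"))
  ks <- multiplicities(fc)
  fs <- unname(fc$f)
  keep <- fs > 0
  ks <- ks[keep]; fs <- fs[keep]
  if (fc$S_obs < 2 || length(ks) < 2) {
    stop("MLE requires S_obs >= 2 and at least two distinct multiplicities")
  }
  nll <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    logp <- lgamma(a + ks) - lgamma(ks + 1) - lgamma(a) +
      a * (log(b) - log(b + 1)) - ks * log(b + 1)
    log1mp0 <- log1p(-exp(a * (log(b) - log(b + 1))))
    -sum(fs * (logp - log1mp0))
  }
  if (is.null(init)) {
    am <- alpha_hat_moment(fc)$alpha_hat
    a0 <- if (is.finite(am) && am > 0) min(max(am, 0.05), 50) else 1
    b0 <- max(a0 / (fc$n / fc$S_obs), 1e-3)  # mean of truncated NB ~ a/b
    init <- gp_params(a0, b0)
  }
  theta0 <- c(log(init$alpha), log(init$beta))
  opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
  flags <- character()
  if (opt$convergence != 0) flags <- c(flags, "mle_nonconvergence")
  if (abs(opt$par[1]) > log(1e6) || abs(opt$par[2]) > log(1e6)) {
    flags <- c(flags, "mle_boundary")
  }
  params <- gp_params(exp(opt$par[1]), exp(opt$par[2]))
  point <- if (length(flags) == 0) fc$S_obs / (1 - params$p0) else NA_real_
  est <- new_richness_estimate(
    estimator = "mle", fc = fc, point = point,
    diagnostics = list(alpha_hat = params$alpha, beta_hat = params$beta,
                       p0_hat = params$p0, fallbacks = flags),
    se = FALSE
  )
  list(params = params, estimate = est, logLik = -opt$value,
       converged = opt$convergence == 0 && length(flags) == 0,
       flags = flags)
}
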
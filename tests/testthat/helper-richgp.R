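# Shared test helpers: small constructors and independent oracles.

# Frequency counts from a compact spec, e.g. fct(f1 = 5, f2 = 3).
fct <- function(...) {
  v <- c(...)
  k <- as.integer(sub("^f", "", names(v)))
  freq_counts_from_table(k, unname(v))
}

# Independent finite-difference gradient of a point estimator with respect
# to each stored frequency count. Stays independent of the package's
# analytic gradients: it only calls the public point estimators.
fd_gradient <- function(fc, estimator, h_scale = 1e-6) {
  ks <- multiplicities(fc)
  f <- unname(fc$f)
  point_of <- function(fv) {
    fc2 <- freq_counts_from_table(ks, fv)
    richGP:::richness_estimator(estimator)(fc2, se = FALSE)$point
  }
  vapply(seq_along(ks), function(i) {
    h <- h_scale * max(1, f[i])
    up <- f; up[i] <- up[i] + h
    dn <- f; dn[i] <- dn[i] - h
    (point_of(up) - point_of(dn)) / (2 * h)
  }, numeric(1))
}

# Brute-force delta-method variance: explicit double sum over the
# multinomial covariance matrix (the independent oracle for the collapsed
# quadratic form used by the package).
brute_force_variance <- function(fc, gradient, point) {
  f <- unname(fc$f)
  m <- length(f)
  total <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      cov_ij <- if (i == j) f[i] * (1 - f[i] / point) else -f[i] * f[j] / point
      total <- total + gradient[i] * gradient[j] * cov_ij
    }
  }
  total
}

# Poisson(2) expected frequency counts: the homogeneous oracle that pins
# down the Chao-Bunge denominator convention.
poisson2_expected_fc <- function(S = 1000, k_max = 60) {
  k <- 1:k_max
  freq_counts_from_table(k, S * dpois(k, 2))
}
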
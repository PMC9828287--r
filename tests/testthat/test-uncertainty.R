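vascular <- fixture_freq_counts(richness_fixture("vascular"))

test_that("analytic gradients agree with finite differences", {
  cases <- list(
    vascular,
    fct(f1 = 20, f2 = 30, f3 = 5, f7 = 2),   # A > 1: clamped region
    fct(f1 = 50, f2 = 5, f3 = 40, f4 = 10),  # A < 1/2: clamped region
    fct(f1 = 12, f2 = 9, f3 = 7)             # A in (1/2, 1): active region
  )
  for (fc in cases) {
    for (id in c("chao1", "jackknife1", "gp", "lb")) {
      g_analytic <- richGP:::richness_gradient(fc, id)
      g_fd <- fd_gradient(fc, id)
      expect_equal(unname(g_analytic), g_fd, tolerance = 1e-6)
    }
  }
})

# Chao-Bunge needs a spectrum with enough multiply-observed mass to keep
# theta positive (heavy aggregated tails make it undefined, as on the
# packaged fixtures), so it gets its own moderate-spectrum case.
cb_defined <- fct(f1 = 50, f2 = 80, f3 = 90, f4 = 70, f5 = 40, f6 = 15)

test_that("the collapsed quadratic form equals the explicit double sum", {
  cases <- list(chao1 = vascular, jackknife1 = vascular, gp = vascular,
                lb = vascular, chao_bunge = cb_defined)
  for (id in names(cases)) {
    fc <- cases[[id]]
    est <- richGP:::richness_estimator(id)(fc, se = FALSE)
    vr <- variance_asymptotic(fc, id, est$point)
    expect_equal(vr$variance,
                 brute_force_variance(fc, unname(vr$gradient), est$point),
                 tolerance = 1e-8)
    expect_gte(vr$variance, 0)
  }
})

test_that("Chao-Bunge numeric gradient sees the full spectrum", {
  vr <- variance_asymptotic(cb_defined, "chao_bunge")
  expect_identical(vr$method, "numeric")
  # theta depends on every f_k through n and sum(X^2), so no gradient
  # entry should be exactly the pass-through value 1
  expect_false(any(abs(vr$gradient - 1) < 1e-12))
})

test_that("degenerate variance cases are handled", {
  # no singletons: estimate = S_obs, gradient all ones, variance exactly 0
  fc <- fct(f2 = 7, f3 = 4)
  vr <- variance_asymptotic(fc, "chao1")
  expect_equal(unname(vr$gradient), c(1, 1))
  expect_equal(vr$variance, 0)
  # undefined point (CB with nonpositive theta) refuses a variance
  sparse <- fct(f1 = 40, f2 = 1, f10 = 3)
  expect_error(variance_asymptotic(sparse, "chao_bunge"), "undefined")
})

test_that("log-normal interval satisfies its contract", {
  # zero variance collapses onto the point estimate
  ci0 <- ci_lognormal(100, 140, 0)
  expect_equal(ci0$R, 1)
  expect_equal(c(ci0$lower, ci0$upper), c(140, 140))
  # point at S_obs degenerates to [S_obs, S_obs]
  cid <- ci_lognormal(100, 100, 25)
  expect_true(cid$degenerate)
  expect_equal(c(cid$lower, cid$upper), c(100, 100))
  # hand-checked R at the default level (z = 1.96 exactly)
  ci <- ci_lognormal(188, 241.157, 319.05)
  R <- exp(1.96 * sqrt(log(1 + 319.05 / (241.157 - 188)^2)))
  expect_equal(ci$R, R)
  expect_equal(ci$lower, 188 + (241.157 - 188) / R)
  expect_equal(ci$upper, 188 + (241.157 - 188) * R)
  expect_error(ci_lognormal(10, 20, -1), ">= 0")
  expect_error(ci_lognormal(10, 8, 1), "below observed")
})

test_that("CI lower bound never drops below observed richness", {
  set.seed(77)
  for (rep in 1:200) {
    S_obs <- sample(5:500, 1)
    point <- S_obs + rexp(1, 1 / 50)
    v <- rexp(1, 1 / 400)
    ci <- ci_lognormal(S_obs, point, v)
    expect_gte(ci$lower, S_obs)
    expect_lte(ci$lower, point)
    expect_gte(ci$upper, point)
  }
})

test_that("wider confidence levels widen the interval", {
  lv <- c(0.80, 0.90, 0.95, 0.99)
  cis <- lapply(lv, function(l) ci_lognormal(188, 241.157, 319.05, level = l))
  lowers <- vapply(cis, `[[`, 0, "lower")
  uppers <- vapply(cis, `[[`, 0, "upper")
  expect_true(all(diff(lowers) < 0))
  expect_true(all(diff(uppers) > 0))
})

test_that("estimated s.e. tracks the sampling s.d. of the GP estimator", {
  # homogeneous assemblage: the mean estimated s.e. should agree with the
  # spread of the estimates across replicates to within sampling error
  asm <- make_assemblage("homogeneous", 1000)
  tbl <- run_simulation(asm, 2000, reps = 300, estimators = "gp", seed = 55)
  expect_equal(tbl$average_estimated_se / tbl$sample_se, 1, tolerance = 0.2)
})
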
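vascular <- fixture_freq_counts(richness_fixture("vascular"))
butterfly <- fixture_freq_counts(richness_fixture("butterfly"))

test_that("point estimators reproduce hand-computed values on the fixtures", {
  # vascular plants: S_obs 188, f1 61, f2 35, f3 18
  expect_equal(estimate_chao1(vascular, se = FALSE)$point, 188 + 3721 / 70)
  expect_equal(estimate_jackknife1(vascular, se = FALSE)$point, 249)
  gp <- estimate_gp(vascular, se = FALSE)
  expect_equal(gp$diagnostics$A, 2450 / 3294)
  expect_equal(gp$point, 188 + (3721 / 70) * (2 - 2450 / 3294))
  expect_equal(gp$point, 254.777, tolerance = 1e-4)
  lb <- estimate_lb(vascular, se = FALSE)
  expect_equal(lb$point, 188 + (3721 / 70) * 3294 / 2450)
  expect_equal(lb$point, 259.469, tolerance = 1e-4)

  # butterflies: S_obs 620, f1 118, f2 74, f3 44
  expect_equal(estimate_chao1(butterfly, se = FALSE)$point, 714.081,
               tolerance = 1e-4)
  expect_equal(estimate_jackknife1(butterfly, se = FALSE)$point, 738)
  expect_equal(estimate_gp(butterfly, se = FALSE)$point, 742.011,
               tolerance = 1e-4)
})

test_that("estimators depend only on the frequency counts, not labels", {
  set.seed(9)
  x <- sample(1:8, 40, replace = TRUE)
  a <- freq_counts(stats::setNames(x, paste0("sp", 1:40)))
  b <- freq_counts(sample(x))
  for (id in c("chao1", "jackknife1", "chao_bunge", "lb", "gp")) {
    expect_equal(richGP:::richness_estimator(id)(a, se = FALSE)$point,
                 richGP:::richness_estimator(id)(b, se = FALSE)$point)
  }
})

test_that("Chao1 fallback rules fire at f2 = 0 and f1 = 0", {
  e <- estimate_chao1(fct(f1 = 6, f3 = 2), se = FALSE)
  expect_equal(e$point, 8 + 6 * 5 / 2)
  expect_true("f2_zero_fallback" %in% e$diagnostics$fallbacks)
  # no singletons: nothing to extrapolate from
  e0 <- estimate_chao1(fct(f2 = 4, f5 = 3), se = FALSE)
  expect_equal(e0$point, 7)
})

test_that("Chao-Bunge reproduces the homogeneous Poisson oracle", {
  # expected counts of 1000 species sampled Poisson(2): theta converges to
  # P(X >= 2) and the estimate recovers S, pinning the n^2 denominator
  fc <- poisson2_expected_fc()
  e <- estimate_chao_bunge(fc, se = FALSE)
  expect_equal(e$diagnostics$theta_hat, 0.5939942, tolerance = 1e-6)
  expect_equal(e$point, 1000, tolerance = 1e-6)
})

test_that("Chao-Bunge boundary behaviour", {
  # a single species observed many times: theta = 1, estimate = 1
  e1 <- estimate_chao_bunge(fct(f9 = 1), se = FALSE)
  expect_equal(e1$diagnostics$theta_hat, 1)
  expect_equal(e1$point, 1)
  # singleton-dominated sample: f1 * sum(X^2) >= n^2 -> undefined
  sparse <- fct(f1 = 40, f2 = 1, f10 = 3)
  e2 <- estimate_chao_bunge(sparse, se = FALSE)
  expect_true(is.na(e2$point))
  expect_true("theta_nonpositive" %in% e2$diagnostics$fallbacks)
  # raw mode returns the (negative) ratio instead of NA
  e3 <- estimate_chao_bunge(sparse, se = FALSE,
                            allow_nonpositive_theta = TRUE)
  expect_true(e3$point < 0)
})

test_that("GP substitution rules keep the estimator total", {
  # f3 = 0: ratio computed with f3 -> 1
  e <- estimate_gp(fct(f1 = 10, f2 = 4, f3 = 0), se = FALSE)
  expect_true("f3_substituted" %in% e$diagnostics$fallbacks)
  expect_equal(e$diagnostics$A, 2 * 16 / (3 * 10))
  # f1 = 0: no unseen mass, point = S_obs regardless of the ratio
  e0 <- estimate_gp(fct(f2 = 5, f3 = 2), se = FALSE)
  expect_true("f1_substituted" %in% e0$diagnostics$fallbacks)
  expect_equal(e0$point, e0$S_obs)
  # f2 = 0: Chao1 fallback for the unseen term, A = 0 -> multiplier 1.5
  e2 <- estimate_gp(fct(f1 = 8, f3 = 3), se = FALSE)
  expect_equal(e2$diagnostics$multiplier, 1.5)
  expect_equal(e2$point, 11 + (8 * 7 / 2) * 1.5)
})

test_that("GP/Chao1/LB obey the ordering and multiplier bounds", {
  set.seed(31)
  for (rep in 1:500) {
    f1 <- sample(0:40, 1); f2 <- sample(0:40, 1); f3 <- sample(0:40, 1)
    if (f1 + f2 + f3 == 0) next
    fc <- freq_counts_from_table(1:3, c(f1, f2, f3))
    gp <- estimate_gp(fc, se = FALSE)
    ch <- estimate_chao1(fc, se = FALSE)
    lb <- estimate_lb(fc, se = FALSE)
    expect_gte(gp$diagnostics$multiplier, 1)
    expect_lte(gp$diagnostics$multiplier, 1.5)
    expect_gte(gp$point, fc$S_obs)
    A <- gp$diagnostics$A
    if (A >= 1) {
      expect_equal(gp$point, ch$point)
    } else {
      expect_gte(gp$point + 1e-9, ch$point)
      if (A > 0.5 && f2 > 0) expect_lte(gp$point, lb$point + 1e-9)
    }
  }
})

test_that("GP equals Chao1 on homogeneous expected counts", {
  # under homogeneity 2 E[f2]^2 = 3 E[f1] E[f3]: A -> 1, multiplier -> 1
  fc <- poisson2_expected_fc()
  gp <- estimate_gp(fc, se = FALSE)
  ch <- estimate_chao1(fc, se = FALSE)
  expect_equal(gp$diagnostics$A, 1, tolerance = 1e-12)
  expect_equal(gp$point, ch$point, tolerance = 1e-9)
})

test_that("estimate_richness assembles one row per estimator", {
  tab <- estimate_richness(vascular, se = TRUE)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$point >= tab$S_obs, na.rm = TRUE))
  expect_true(all(tab$ci_lower >= tab$S_obs, na.rm = TRUE))
  expect_true(all(tab$ci_lower <= tab$point & tab$point <= tab$ci_upper,
                  na.rm = TRUE))
})
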
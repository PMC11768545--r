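# Errors-in-both-variables (Deming/MLFR) fitting, jackknife SEs and
# model comparisons.

test_that("an exact line is recovered regardless of the SEs", {
  x <- c(19.5, 24.4, 29.2, 34.1)
  y <- 0.80 * (x - 15.23)
  for (ses in list(c(1, 0.5), c(0.1, 2), c(2, 0.1))) {
    f <- mlfr_fit(x, y, x_se = ses[1], y_se = ses[2])
    expect_equal(f$slope_phi, 0.80, tolerance = 1e-9)
    expect_equal(f$x_intercept_y, 15.23, tolerance = 1e-7)
    expect_equal(f$se_phi, 0, tolerance = 1e-9)
    expect_equal(f$se_y, 0, tolerance = 1e-6)
  }
  # x-intercept consistency: -intercept/slope
  f <- mlfr_fit(x, y, x_se = 1, y_se = 0.5)
  expect_equal(f$x_intercept_y, -f$intercept / f$slope_phi)
  expect_equal(f$df_regression, 2)
})

test_that("input degeneracies are rejected or handled", {
  expect_error(mlfr_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(mlfr_fit(rep(2, 4), 1:4), "degenerate x")
  # all-zero SEs with noisy data: unweighted Deming fallback with warning
  set.seed(2)
  x <- 1:4
  y <- 2 * x + rnorm(4, 0, 0.3)
  expect_warning(f <- mlfr_fit(x, y), "falling back")
  expect_equal(f$lambda_weighting, "unweighted_fallback")
  # ... but exact collinear data need no fallback warning
  expect_silent(f0 <- mlfr_fit(1:4, 2 * (1:4), jackknife = FALSE))
  expect_equal(f0$slope_phi, 2, tolerance = 1e-9)
})

test_that("limiting cases: vanishing errors on one axis", {
  set.seed(9)
  x <- c(10, 18, 26, 34)
  y <- 0.6 * x - 2 + rnorm(4, 0, 0.8)
  # y-error -> 0 relative to x-error: fit approaches inverse regression
  f <- mlfr_fit(x, y, x_se = 2, y_se = 1e-6, jackknife = FALSE)
  b_inv <- var(y) / cov(x, y)
  expect_equal(f$slope_phi, b_inv, tolerance = 1e-3)
  # x-error -> 0: fit approaches OLS of y on x
  ols <- cov(x, y) / var(x)
  for (xe in c(1, 0.1, 0.01, 1e-4)) {
    f <- mlfr_fit(x, y, x_se = xe, y_se = 1, jackknife = FALSE)
    if (xe == 1e-4) expect_equal(f$slope_phi, ols, tolerance = 1e-4)
  }
  # slope bracketing for positively correlated data
  f1 <- mlfr_fit(x, y, x_se = 1.3, y_se = 0.7, jackknife = FALSE)
  expect_gte(f1$slope_phi, min(ols, b_inv) - 1e-10)
  expect_lte(f1$slope_phi, max(ols, b_inv) + 1e-10)
})

test_that("pooled weighting equals the closed-form Deming slope", {
  set.seed(14)
  for (i in 1:20) {
    inst <- random_instance(1400 + i)
    f <- mlfr_fit(inst$x, inst$y, inst$x_se, inst$y_se,
                  weighting = "pooled", jackknife = FALSE)
    lam <- mean(inst$y_se^2) / mean(inst$x_se^2)
    sxx <- var(inst$x); syy <- var(inst$y); sxy <- cov(inst$x, inst$y)
    closed <- (syy - lam * sxx +
                 sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) / (2 * sxy)
    expect_equal(f$slope_phi, closed, tolerance = 1e-8)
  }
})

test_that("fit matches the brute-force objective minimiser", {
  for (i in 1:60) {
    inst <- random_instance(700 + i)
    f <- mlfr_fit(inst$x, inst$y, inst$x_se, inst$y_se, jackknife = FALSE)
    o <- oracle_mlfr(inst$x, inst$y, inst$x_se^2, inst$y_se^2)
    expect_lt(abs(f$slope_phi - o$slope), 1e-6 * max(1, abs(o$slope)))
    expect_lt(abs(f$intercept - o$intercept),
              1e-5 * max(1, abs(o$intercept)))
    expect_lte(f$objective, o$objective + 1e-8)
  }
})

test_that("the estimator is symmetric in x and y; OLS is not", {
  x <- c(19.5, 24.4, 29.2, 34.1)
  expect_true(mlfr_symmetry_check(x, 0.8 * (x - 15.23), 1, 0.5))
  for (i in 1:25) {
    inst <- random_instance(300 + i)
    expect_true(mlfr_symmetry_check(inst$x, inst$y, inst$x_se, inst$y_se))
  }
  # negative control: OLS slopes are not mutual reciprocals on noisy data
  inst <- random_instance(301)
  b_yx <- cov(inst$x, inst$y) / var(inst$x)
  b_xy <- cov(inst$x, inst$y) / var(inst$y)
  expect_gt(abs(b_yx - 1 / b_xy) / abs(b_yx), 1e-6)
})

test_that("jackknife SE follows the leave-one-out formula", {
  # hand-built replicate estimates {1,2,3,4}: SE = sqrt(3/4 * 5)
  expect_equal(wallmech:::jackknife_combine(c(1, 2, 3, 4)),
               sqrt(0.75 * 5))
  x <- c(19.5, 24.4, 29.2, 34.1)
  jk <- jackknife_se(x, 0.80 * (x - 15.23), x_se = 1, y_se = 0.5)
  expect_equal(jk$se_phi, 0, tolerance = 1e-9)
  expect_equal(jk$se_y, 0, tolerance = 1e-6)
  expect_true(jk$ok)
  # degenerate leave-one-out subset: flagged, SEs undefined
  jk2 <- jackknife_se(c(10, 10, 20), c(1, 2, 3), x_se = 1, y_se = 1)
  expect_false(jk2$ok)
  expect_true(is.na(jk2$se_phi))
})

test_that("jackknife SE tracks the ensemble SD of the slope at N = 4", {
  mu <- c(19.5, 24.4, 29.2, 34.1)
  ses <- c(1.5, 1.9, 2.3, 2.6) / 2
  fits <- lapply(1:200, function(i) {
    p <- simulate_stress_rate_points(0.80, 15.23, mu, ses, 0.5,
                                     seed = 2600 + i)
    mlfr_fit(p$x, p$y, p$x_se, p$y_se)
  })
  slopes <- vapply(fits, `[[`, numeric(1), "slope_phi")
  jk_mean <- mean(vapply(fits, `[[`, numeric(1), "se_phi"))
  expect_lt(abs(jk_mean - sd(slopes)) / sd(slopes), 0.5)
})

test_that("slope significance uses t on N - p - 1 df with ND semantics", {
  fit <- structure(list(slope_phi = 0.430265, se_phi = 0.1,
                        x_intercept_y = 1, se_y = 0.1,
                        df_regression = 2L), class = "mlfr_fit")
  s <- slope_significance(fit)
  # |t| = 4.30265 at df 2 sits exactly at p = 0.05
  expect_equal(s$p_value, 0.05, tolerance = 1e-4)
  fit$slope_phi <- 0
  expect_equal(slope_significance(fit)$p_value, 1)
  fit$slope_phi <- 0.5
  fit$se_phi <- 0
  expect_warning(s0 <- slope_significance(fit), "zero SE")
  expect_equal(s0$p_value, 0)
  expect_true(s0$significant)
})

test_that("model comparison follows the pooled-SE t-ratio formula", {
  mk <- function(coef, se) structure(
    list(slope_phi = coef, se_phi = se, x_intercept_y = coef, se_y = se,
         df_regression = 2L), class = "mlfr_fit")
  cmp <- compare_models(mk(0.80, 0.02), mk(0.31, 0.02), "phi")
  expect_equal(cmp$t_ratio, 0.49 / sqrt(0.5 * (0.0004 + 0.0004)),
               tolerance = 1e-12)
  expect_equal(cmp$t_ratio, 24.5, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_lt(cmp$p_value, 1e-4)
  # identical fits: t = 0, p = 1
  same <- compare_models(mk(0.5, 0.1), mk(0.5, 0.1), "y")
  expect_equal(same$t_ratio, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry in the order of the fits
  ab <- compare_models(mk(0.8, 0.05), mk(0.3, 0.04), "phi")
  ba <- compare_models(mk(0.3, 0.04), mk(0.8, 0.05), "phi")
  expect_equal(ab$t_ratio, -ba$t_ratio)
  expect_equal(ab$p_value, ba$p_value)
  # undefined SEs error
  bad <- mk(0.5, NA_real_)
  expect_error(compare_models(bad, mk(0.5, 0.1), "phi"), "defined")
})

test_that("jackknife-t intervals cover the generating slope at N = 4", {
  mu <- c(19.5, 24.4, 29.2, 34.1)
  ses <- c(1.5, 1.9, 2.3, 2.6) / 2
  covered <- vapply(1:200, function(i) {
    p <- simulate_stress_rate_points(0.80, 15.23, mu, ses, 0.5,
                                     seed = 5000 + i)
    f <- mlfr_fit(p$x, p$y, p$x_se, p$y_se)
    half <- qt(0.975, f$df_regression) * f$se_phi
    abs(f$slope_phi - 0.80) <= half
  }, logical(1))
  expect_gte(mean(covered), 0.80)
})
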
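# Creep-rate extraction from raw traces and per-condition summaries.

make_trace <- function(f, times = seq(0, 900, 10), ...) {
  creep_trace("s1", "g", 500, 5, FALSE, times, f(times), ...)
}

test_that("creep rate is the OLS slope over the window, in %/h", {
  tr <- make_trace(function(t) 1.0 + 2.0 * t / 3600)
  s <- creep_rate(tr, window = c(300, 900))
  expect_equal(s$creep_rate, 2.0, tolerance = 1e-12)
  expect_equal(s$fit_r2, 1)

  flat <- make_trace(function(t) rep(0.8, length(t)))
  expect_equal(creep_rate(flat)$creep_rate, 0)
  expect_equal(creep_rate(flat)$fit_r2, 1)
})

test_that("window handling rejects bad windows and sparse windows", {
  tr <- make_trace(function(t) 1 + t / 3600)
  expect_error(creep_rate(tr, c(600, 300)), "increasing")
  expect_error(creep_rate(tr, c(-100, 900)), "outside")
  expect_error(creep_rate(tr, c(0, 2000)), "outside")
  sparse <- creep_trace("s", "g", 500, 5, FALSE, c(0:8, 900),
                        c(0:8, 900) / 3600)
  expect_error(creep_rate(sparse, c(100, 900)), "fewer than 5")
})

test_that("rate is scale-equivariant and time-shift invariant", {
  set.seed(21)
  t0 <- seq(0, 900, 10)
  e <- 1 + 3 * t0 / 3600 + rnorm(length(t0), 0, 0.01)
  base <- creep_rate(creep_trace("a", "g", 500, 5, FALSE, t0, e),
                     c(300, 900))$creep_rate
  scaled <- creep_rate(creep_trace("b", "g", 500, 5, FALSE, t0, 2.5 * e),
                       c(300, 900))$creep_rate
  expect_equal(scaled, 2.5 * base, tolerance = 1e-12)
  shifted <- creep_rate(creep_trace("c", "g", 500, 5, FALSE, t0 + 120, e),
                        c(420, 1020))$creep_rate
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("simulated zero-noise trace gives the closed-form rate", {
  sc <- creep_scenario("control", phi = 0.80, y_threshold = 15.23,
                       creep_rate_noise_sd = 0)
  tr <- simulate_creep_trace(sc, 700, 34.1, seed = 2)
  expect_equal(creep_rate(tr)$creep_rate, 0.80 * (34.1 - 15.23),
               tolerance = 1e-9)
})

test_that("group summaries report mean, SE = SD/sqrt(n) and n per cell", {
  r3 <- data.frame(group = "g", load_mg = 400, ph = 5, inactivated = FALSE,
                   creep_rate = c(2, 2, 2))
  g <- group_rates(r3)
  expect_equal(g$mean_rate, 2)
  expect_equal(g$se_rate, 0)
  expect_equal(g$n, 3)

  r2 <- data.frame(group = "g", load_mg = 400, ph = 5, inactivated = FALSE,
                   creep_rate = c(1, 3))
  expect_equal(group_rates(r2)$mean_rate, 2)
  expect_equal(group_rates(r2)$se_rate, 1)

  r1 <- data.frame(group = "g", load_mg = c(400, 500), ph = 5,
                   inactivated = FALSE, creep_rate = c(1, 2))
  expect_error(group_rates(r1), ">= 2")
})

test_that("SE of a 10-specimen cell has the expected sampling spread", {
  # specimen rate noise SD 0.5 => SE of the 10-specimen mean concentrates
  # around 0.5/sqrt(10) ~ 0.16; nearly all seeds fall in [0.05, 0.5]
  sc <- creep_scenario("g", creep_rate_noise_sd = 0.5,
                       trace_sampling_interval_s = 60)
  one_se <- function(seed) {
    rates <- vapply(1:10, function(i) {
      tr <- simulate_creep_trace(sc, 700, 34.1, seed = seed * 100 + i,
                                 specimen_id = paste0("s", i))
      creep_rate(tr, c(300, 900))$creep_rate
    }, numeric(1))
    d <- data.frame(group = "g", load_mg = 700, ph = 5,
                    inactivated = FALSE, creep_rate = rates)
    group_rates(d)$se_rate
  }
  ses <- vapply(1:400, one_se, numeric(1))
  expect_gte(mean(ses >= 0.05 & ses <= 0.5), 0.95)
})
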
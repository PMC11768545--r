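# Synthetic-data generator: determinism, exactness at zero noise,
# distributional calibration.

test_that("scenario construction enforces its invariants", {
  expect_error(creep_scenario(phi = -1), "phi")
  expect_error(creep_scenario(dry_mass_mean = -1), "dry_mass_mean")
  expect_error(creep_scenario(loads_mg = numeric(0)), "loads_mg")
  expect_error(creep_scenario(n_specimens_per_load = 1),
               "n_specimens_per_load")
  expect_error(creep_scenario(n_mass_replicates = 1), "n_mass_replicates")
  expect_s3_class(creep_scenario(), "creep_scenario")
})

test_that("dry-mass simulation: zero variance is exact, draws are calibrated", {
  sc0 <- creep_scenario(dry_mass_mean = 2.30, dry_mass_sd = 0)
  expect_identical(simulate_dry_masses(sc0), rep(2.30, 4))

  sc <- creep_scenario(dry_mass_mean = 1.52, dry_mass_sd = 0.11)
  # sample mean within 3 sigma/sqrt(n) of the mean in >= 99% of seeds
  hits <- vapply(1:2000, function(s) {
    m <- simulate_dry_masses(sc, seed = s)
    abs(mean(m) - 1.52) <= 3 * 0.11 / 2
  }, logical(1))
  expect_gte(mean(hits), 0.99)
  expect_true(all(simulate_dry_masses(sc, seed = 7) > 0))
})

test_that("dry-mass moments converge to the scenario parameters", {
  sc <- creep_scenario(dry_mass_mean = 2.30, dry_mass_sd = 0.13,
                       n_mass_replicates = 1e5)
  m <- simulate_dry_masses(sc, seed = 99)
  expect_lt(abs(mean(m) - 2.30) / 2.30, 0.01)
  expect_lt(abs(sd(m) - 0.13) / 0.13, 0.01)
})

test_that("creep traces follow the generating Lockhart-type line", {
  sc <- creep_scenario("control", phi = 0.80, y_threshold = 15.23,
                       creep_rate_noise_sd = 0, elastic_jump_pct = 1)
  # at-threshold stress: flat trace at the elastic jump
  tr0 <- simulate_creep_trace(sc, 400, 15.23, seed = 1)
  expect_equal(tr0$rel_extension, rep(1, length(tr0$times)))
  # above threshold: OLS slope of the trace equals phi * (sigma - y)
  tr <- simulate_creep_trace(sc, 500, 19.5, seed = 1)
  slope <- creep_rate(tr)$creep_rate
  expect_equal(slope, 0.80 * (19.5 - 15.23), tolerance = 1e-12)
  # sub-threshold stresses creep at zero rate, not negative
  trs <- simulate_creep_trace(sc, 400, 10, seed = 1)
  expect_equal(creep_rate(trs)$creep_rate, 0)
  expect_error(simulate_creep_trace(sc, 400, 0, seed = 1), "true_stress")
})

test_that("experiment simulation is deterministic and honours the design", {
  a <- creep_scenario("control", seed = 11,
                      trace_sampling_interval_s = 30)
  b <- creep_scenario("ebl", phi = 0.31, y_threshold = 5.42,
                      dry_mass_mean = 2.30, dry_mass_sd = 0.13,
                      seed = 12, trace_sampling_interval_s = 30)
  s1 <- simulate_experiment(a, b)
  s2 <- simulate_experiment(a, b)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$masses, s2$masses)
  # 2 groups x 4 loads x 10 specimens = 80 traces
  expect_equal(length(unique(s1$traces$specimen_id)), 80)
  expect_equal(nrow(s1$masses), 8)
  # same seed, same parameters, different labels: identical numbers
  b2 <- a; b2$group <- "twin"
  s3 <- simulate_experiment(a, b2)
  ctrl <- s3$traces[s3$traces$group == "control", ]
  twin <- s3$traces[s3$traces$group == "twin", ]
  expect_identical(ctrl$rel_extension_pct, twin$rel_extension_pct)
  expect_error(simulate_experiment(a, a), "distinct group labels")
})

test_that("zero-noise experiments reproduce the generating line exactly", {
  a <- creep_scenario("control", creep_rate_noise_sd = 0, dry_mass_sd = 0,
                      seed = 3, trace_sampling_interval_s = 30)
  b <- creep_scenario("ebl", phi = 0.31, y_threshold = 5.42,
                      dry_mass_mean = 2.30, dry_mass_sd = 0,
                      creep_rate_noise_sd = 0, seed = 4,
                      trace_sampling_interval_s = 30)
  sim <- simulate_experiment(a, b)
  rates <- creep_rates(sim$traces)
  merged <- merge(rates, sim$stress[c("group", "load_mg", "stress_mean")])
  expected <- ifelse(merged$group == "control",
                     pmax(0, 0.80 * (merged$stress_mean - 15.23)),
                     pmax(0, 0.31 * (merged$stress_mean - 5.42)))
  expect_equal(merged$creep_rate, expected, tolerance = 1e-9)
})

test_that("summary-level point simulation matches its measurement model", {
  mu <- c(19.5, 24.4, 29.2, 34.1)
  p1 <- simulate_stress_rate_points(0.80, 15.23, mu, 0, 0, seed = 1)
  expect_equal(p1$x, mu)
  expect_equal(p1$y, 0.80 * (mu - 15.23))
  p2 <- simulate_stress_rate_points(0.80, 15.23, mu, 1, 0.5, seed = 1)
  p3 <- simulate_stress_rate_points(0.80, 15.23, mu, 1, 0.5, seed = 1)
  expect_identical(p2, p3)
})
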
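# Bootstrap creep rate / stress estimation and FDR-controlled
# comparisons.

test_that("constant and singleton pools give exact ratios", {
  for (s in c(1, 99)) {
    est <- bootstrap_ratio(rep(6, 5), rep(3, 4), n_boot = 200, seed = s)
    expect_equal(est$mean_ratio, 2)
    expect_equal(est$sd_ratio, 0)
  }
  est1 <- bootstrap_ratio(4, 2, n_boot = 10, seed = 1)
  expect_equal(est1$mean_ratio, 2)
  expect_equal(est1$sd_ratio, 0)
})

test_that("bootstrap is seed-deterministic and validates inputs", {
  r <- c(5, 6, 8, 7, 9)
  s <- c(18, 20, 21, 19)
  a <- bootstrap_ratio(r, s, n_boot = 500, seed = 42)
  b <- bootstrap_ratio(r, s, n_boot = 500, seed = 42)
  expect_identical(a$mean_ratio, b$mean_ratio)
  expect_identical(a$sd_ratio, b$sd_ratio)
  c <- bootstrap_ratio(r, s, n_boot = 500, seed = 43)
  expect_false(identical(a$mean_ratio, c$mean_ratio))

  expect_error(bootstrap_ratio(numeric(0), s), "non-empty")
  expect_error(bootstrap_ratio(r, c(18, -1)), "positive")
  expect_error(bootstrap_ratio(r, s, resample_size_rates = 3,
                               method = "mean_of_ratios"), "equal")
})

test_that("bootstrap mean converges to the exhaustive enumeration", {
  rates <- c(4, 6, 11)
  stresses <- c(18, 22)
  truth <- oracle_ratio_enumeration(rates, stresses, size = 2)
  est <- bootstrap_ratio(rates, stresses, n_boot = 40000,
                         resample_size_rates = 2, resample_size_stress = 2,
                         seed = 7)
  mc_se <- est$sd_ratio / sqrt(est$n_boot)
  expect_lt(abs(est$mean_ratio - truth), 3 * mc_se)
  # doubling n_boot moves the estimate closer on average; check scale
  est2 <- bootstrap_ratio(rates, stresses, n_boot = 160000,
                          resample_size_rates = 2, resample_size_stress = 2,
                          seed = 8)
  expect_lt(abs(est2$mean_ratio - truth),
            3 * est2$sd_ratio / sqrt(est2$n_boot))
})

test_that("scaling all stresses by c divides the constant-data ratio by c", {
  est <- bootstrap_ratio(rep(8, 4), rep(20, 4), n_boot = 100, seed = 1)
  est2 <- bootstrap_ratio(rep(8, 4), rep(20, 4) * 2.5, n_boot = 100,
                          seed = 1)
  expect_equal(est2$mean_ratio, est$mean_ratio / 2.5)
})

test_that("mean-of-ratios and ratio-of-means differ as Jensen predicts", {
  set.seed(5)
  r <- rnorm(10, 8, 1)
  s <- c(18, 20, 21, 19)
  rom <- bootstrap_ratio(r, s, n_boot = 20000, seed = 3,
                         method = "ratio_of_means")
  mor <- bootstrap_ratio(r, s, n_boot = 20000, seed = 3,
                         method = "mean_of_ratios")
  # 1/s is convex: elementwise ratios average higher
  expect_gt(mor$mean_ratio, rom$mean_ratio)
})

test_that("group comparisons: trivial contrasts and BH identities", {
  est <- data.frame(group = c("a", "b"), load_mg = 400, ph = 5,
                    inactivated = FALSE, mean_ratio = 0.4,
                    sd_ratio = 0.05, n_boot = 1000)
  cmp <- compare_ratio_groups(est)
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_raw, 1)
  expect_false(cmp$significant)
  # one contrast: adjusted equals raw
  expect_equal(cmp$p_adjusted, cmp$p_raw)
  # unmatched keys error
  bad <- data.frame(group_a = "a", group_b = "zzz", load_mg = 400, ph = 5,
                    inactivated = FALSE)
  expect_error(compare_ratio_groups(est, pairs = bad), "does not match")
})

test_that("BH step-up matches the hand-computed adjustment", {
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_equal(adjust_fdr(p), c(0.04, 0.04, 0.16 / 3, 0.8))
  expect_equal(adjust_fdr(p), oracle_bh(p))
  set.seed(11)
  for (i in 1:25) {
    pr <- runif(sample(2:12, 1))
    adj <- adjust_fdr(pr)
    expect_equal(adj, oracle_bh(pr))
    # monotone in the raw p ordering, never above 1, never below raw
    expect_true(all(adj[order(pr)] == cummax(adj[order(pr)])))
    expect_true(all(adj <= 1 & adj >= pr))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("ratio table pairs each cell with its group stresses", {
  masses <- data.frame(group = rep(c("a", "b"), each = 4), replicate = 1:4,
                       dry_mass_ug = rep(c(1.52, 2.30), each = 4))
  rates <- expand.grid(specimen = 1:5, group = c("a", "b"),
                       load_mg = c(400, 700))
  rates$ph <- 5
  rates$inactivated <- FALSE
  rates$creep_rate <- 8
  tab <- ratio_table(rates, masses, loads_mg = c(400, 700), n_boot = 50,
                     seed = 2)
  expect_equal(nrow(tab), 4)
  # constant rates and constant masses: ratio = rate / stress exactly
  a400 <- wall_stress(load_to_force(400), cross_section_area(1.52))
  expect_equal(tab$mean_ratio[tab$group == "a" & tab$load_mg == 400],
               8 / a400)
  expect_equal(tab$sd_ratio, rep(0, 4))
})
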
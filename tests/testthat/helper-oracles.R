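# Independent oracles used by the unit and acceptance tests.

# Brute-force minimiser of the errors-in-both-variables ML objective,
# with the latent positions profiled out analytically.  For a candidate
# slope b the objective is a weighted sum of squares in the intercept a,
#   sum_i w_i (r_i - a)^2 with r_i = y_i - b x_i, w_i = 1/(vy_i + b^2 vx_i),
# minimised at the w-weighted mean of the r_i.  The slope itself is
# found by dense grid scanning with repeated zooming — no derivatives,
# no golden section; independent of the package's optimiser.
oracle_mlfr <- function(x, y, vx, vy, zooms = 20, n = 401) {
  profile_obj <- function(b) {
    w <- 1 / (vy + b^2 * vx)
    r <- y - b * x
    a <- sum(w * r) / sum(w)
    sum(w * (r - a)^2)
  }
  b_ols <- stats::cov(x, y) / stats::var(x)
  b_rng <- c(b_ols - 6 * (abs(b_ols) + 1), b_ols + 6 * (abs(b_ols) + 1))
  best <- c(NA, Inf)
  for (z in seq_len(zooms)) {
    bs <- seq(b_rng[1], b_rng[2], length.out = n)
    vals <- vapply(bs, profile_obj, numeric(1))
    i <- which.min(vals)
    if (vals[i] < best[2]) best <- c(bs[i], vals[i])
    db <- diff(b_rng) / (n - 1)
    b_rng <- c(best[1] - 2 * db, best[1] + 2 * db)
  }
  b <- best[1]
  w <- 1 / (vy + b^2 * vx)
  a <- sum(w * (y - b * x)) / sum(w)
  list(intercept = a, slope = b, objective = best[2])
}

# Exhaustive enumeration of the bootstrap ratio-of-means expectation:
# every equally likely with-replacement resample of the given size from
# each pool.
oracle_ratio_enumeration <- function(rates, stresses, size) {
  idx_r <- do.call(expand.grid, rep(list(seq_along(rates)), size))
  idx_s <- do.call(expand.grid, rep(list(seq_along(stresses)), size))
  mr <- apply(idx_r, 1, function(i) mean(rates[i]))
  ms <- apply(idx_s, 1, function(i) mean(stresses[i]))
  mean(outer(mr, 1 / ms))
}

# Hand implementation of the Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Random noisy 4-point instance on a positive-slope line, with SEs.
random_instance <- function(seed) {
  set.seed(seed)
  x <- sort(runif(4, 5, 40))
  slope <- runif(1, 0.1, 2)
  xint <- runif(1, 0, min(x))
  x_se <- runif(4, 0.2, 2)
  y_se <- runif(4, 0.1, 1)
  y <- slope * (x - xint) + rnorm(4, 0, y_se)
  x <- x + rnorm(4, 0, x_se)
  list(x = x, y = y, x_se = x_se, y_se = y_se,
       slope = slope, xint = xint)
}
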
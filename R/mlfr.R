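# Errors-in-both-variables straight line: maximum likelihood functional
# relationship (a Deming regression variant) with per-point or pooled
# error-variance weighting, leave-one-out jackknife SEs, and t-based
# comparisons between fitted models.

# Profile objective: with the latent point positions profiled out
# analytically, the ML objective reduces to
#   S(alpha, beta) = sum_i (y_i - alpha - beta x_i)^2 / (vy_i + beta^2 vx_i)
# and alpha has a closed-form optimum (weighted mean) for each beta.
mlfr_objective <- function(beta, x, y, vx, vy) {
  w <- 1 / (vy + beta^2 * vx)
  alpha <- sum(w * (y - beta * x)) / sum(w)
  sum(w * (y - alpha - beta * x)^2)
}

# Gradient of the profile objective in beta (envelope theorem: alpha is
# at its conditional optimum, so its dependence on beta drops out).
mlfr_gradient <- function(beta, x, y, vx, vy) {
  w <- 1 / (vy + beta^2 * vx)
  alpha <- sum(w * (y - beta * x)) / sum(w)
  r <- y - alpha - beta * x
  sum(-2 * beta * vx * w^2 * r^2 - 2 * x * w * r)
}

# Core minimiser: grid scan over a bracket built from the two OLS
# orientations, golden-section refinement, then a root-finding polish
# of the gradient to near machine precision.  Robust at N = 4.
mlfr_core <- function(x, y, vx, vy, n_grid = 1001L) {
  n <- length(x)
  if (n == 2L) {  # exact line through two points, any weighting
    beta <- (y[2] - y[1]) / (x[2] - x[1])
    return(list(slope = beta, intercept = y[1] - beta * x[1], objective = 0))
  }
  sxx <- stats::var(x)
  sxy <- stats::cov(x, y)
  b_ols <- sxy / sxx
  b_inv <- if (abs(sxy) > 0) stats::var(y) / sxy else b_ols
  lo <- min(b_ols, b_inv, 0)
  hi <- max(b_ols, b_inv, 0)
  pad <- (hi - lo) + 0.5 * (abs(lo) + abs(hi)) + 1
  grid <- seq(lo - pad, hi + pad, length.out = n_grid)
  sv <- vapply(grid, mlfr_objective, numeric(1), x = x, y = y,
               vx = vx, vy = vy)
  i <- which.min(sv)
  bracket <- c(grid[max(1L, i - 2L)], grid[min(n_grid, i + 2L)])
  opt <- stats::optimize(mlfr_objective, bracket, x = x, y = y, vx = vx,
                         vy = vy, tol = 1e-12)
  beta <- opt$minimum
  # golden-section is limited to ~sqrt(eps) relative precision; polish
  # the gradient root with safeguarded Newton steps (secant curvature)
  for (iter in 1:10) {
    h <- max(abs(beta), 1) * 1e-7
    g0 <- mlfr_gradient(beta, x, y, vx, vy)
    curv <- (mlfr_gradient(beta + h, x, y, vx, vy) -
               mlfr_gradient(beta - h, x, y, vx, vy)) / (2 * h)
    if (!is.finite(g0) || !is.finite(curv) || curv <= 0) break
    step <- g0 / curv
    if (!is.finite(step) || abs(step) > h * 1e4) break
    beta_new <- beta - step
    if (mlfr_objective(beta_new, x, y, vx, vy) >
          mlfr_objective(beta, x, y, vx, vy) * (1 + 1e-12) + 1e-300) break
    beta <- beta_new
    if (abs(step) < .Machine$double.eps * max(abs(beta), 1)) break
  }
  w <- 1 / (vy + beta^2 * vx)
  alpha <- sum(w * (y - beta * x)) / sum(w)
  list(slope = beta, intercept = alpha,
       objective = mlfr_objective(beta, x, y, vx, vy))
}

# SE of leave-one-out replicate estimates:
#   sqrt( (N-1)/N * sum_i (theta_(i) - mean(theta))^2 )
jackknife_combine <- function(th) {
  if (anyNA(th)) return(NA_real_)
  n <- length(th)
  sqrt((n - 1) / n * sum((th - mean(th))^2))
}

# Resolve the error-variance weighting; returns list(vx, vy, label).
mlfr_weights <- function(x, y, x_se, y_se,
                         weighting = c("per_point", "pooled")) {
  weighting <- match.arg(weighting)
  n <- length(x)
  x_se <- rep_len(if (is.null(x_se)) 0 else x_se, n)
  y_se <- rep_len(if (is.null(y_se)) 0 else y_se, n)
  if (any(x_se < 0) || any(y_se < 0))
    stop("standard errors must be >= 0", call. = FALSE)
  vx <- x_se^2
  vy <- y_se^2
  if (weighting == "pooled") {
    vx <- rep(mean(vx), n)
    vy <- rep(mean(vy), n)
  }
  # degenerate weights: any point with zero error on both axes makes the
  # objective singular; fall back to unweighted Deming (lambda = 1)
  if (any(vx + vy == 0)) {
    exact <- {
      b <- if (stats::var(x) > 0) stats::cov(x, y) / stats::var(x) else NA
      !is.na(b) && all(abs(y - (mean(y) + b * (x - mean(x)))) <
                         1e-10 * (1 + max(abs(y))))
    }
    if (!exact)
      warning("zero error variances on both axes with noisy data; ",
              "falling back to unweighted Deming (lambda = 1)")
    return(list(vx = rep(1, n), vy = rep(1, n),
                label = "unweighted_fallback"))
  }
  list(vx = vx, vy = vy,
       label = if (weighting == "pooled")
         sprintf("pooled (lambda = %.6g)", mean(vy) / mean(vx))
       else "per_point")
}

#' Errors-in-both-variables line fit (Deming / MLFR)
#'
#' Fits a straight line to points measured with error in both
#' coordinates by minimising the maximum-likelihood functional
#' relationship objective
#' \deqn{\sum_i \frac{(y_i - \alpha - \beta\xi_i)^2}{\sigma_{y,i}^2} +
#'       \frac{(x_i - \xi_i)^2}{\sigma_{x,i}^2}}
#' over the intercept \eqn{\alpha}, slope \eqn{\beta} and latent point
#' positions \eqn{\xi_i}, with the per-point error variances taken
#' proportional to the supplied standard errors.  The latent positions
#' have closed-form optima, leaving a one-dimensional search over the
#' slope.  Unlike ordinary least squares, the estimator is symmetric:
#' regressing x on y gives the reciprocal slope.
#'
#' In creep biomechanics, with x the wall stress (MPa) and y the
#' relative creep rate (% h\eqn{^{-1}}), the slope is the in vitro
#' cell wall extensibility \eqn{\phi} and the x-intercept
#' \eqn{-\alpha/\beta} is the in vitro yield threshold \eqn{y}, the
#' minimal stress at which creep starts.
#'
#' Standard errors for the slope and x-intercept are leave-one-out
#' jackknife estimates (see [jackknife_se()]); the significance of the
#' regression is the two-tailed \eqn{t}-test of the slope on
#' \eqn{N - p - 1} degrees of freedom (one predictor, so \eqn{N - 2}).
#'
#' @param x predictor means (wall stress, MPa), length \eqn{\ge 3}, not
#'   all equal.
#' @param y response means (creep rate, % h\eqn{^{-1}}).
#' @param x_se,y_se standard errors of `x` and `y`; recycled.  If all
#'   are zero and the points are not collinear, the fit falls back to
#'   unweighted Deming regression (\eqn{\lambda = 1}) with a warning.
#' @param weighting `"per_point"` (default; error variances
#'   \eqn{\sigma_{x,i}^2 = } `x_se[i]`\eqn{^2} etc.) or `"pooled"`
#'   (a single variance ratio \eqn{\lambda} from the mean squared SEs).
#' @param jackknife logical; compute leave-one-out SEs (default TRUE).
#' @return Object of class `"mlfr_fit"` with components `slope_phi`,
#'   `intercept`, `x_intercept_y`, `se_phi`, `se_y`, `slope_p`,
#'   `df_regression`, `lambda_weighting`, `converged`, `n_points`,
#'   plus the data.
#' @examples
#' x <- c(19.5, 24.4, 29.2, 34.1)
#' fit <- mlfr_fit(x, 0.80 * (x - 15.23), x_se = 1, y_se = 0.5)
#' fit$slope_phi       # 0.80
#' fit$x_intercept_y   # 15.23
#' @export
mlfr_fit <- function(x, y, x_se = NULL, y_se = NULL,
                     weighting = c("per_point", "pooled"),
                     jackknife = TRUE) {
  weighting <- match.arg(weighting)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(y) != n) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("'x' and 'y' must be finite", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate x: all values equal",
                               call. = FALSE)
  w <- mlfr_weights(x, y, x_se, y_se, weighting)
  core <- mlfr_core(x, y, w$vx, w$vy)
  beta <- core$slope
  alpha <- core$intercept
  xint <- if (beta != 0) -alpha / beta else NA_real_

  se <- c(NA_real_, NA_real_)
  jk_ok <- NA
  if (jackknife) {
    jk <- jackknife_se(x, y, x_se = x_se, y_se = y_se, weighting = weighting)
    se <- c(jk$se_phi, jk$se_y)
    jk_ok <- jk$ok
  }
  df <- n - 2L
  slope_p <- if (!is.na(se[1])) {
    if (se[1] == 0) {
      if (beta == 0) 1 else {
        warning("zero jackknife SE with non-zero slope; p reported as 0")
        0
      }
    } else 2 * stats::pt(-abs(beta / se[1]), df)
  } else NA_real_

  structure(list(slope_phi = beta, intercept = alpha, x_intercept_y = xint,
                 se_phi = se[1], se_y = se[2], slope_p = slope_p,
                 df_regression = df, lambda_weighting = w$label,
                 converged = is.finite(core$objective),
                 jackknife_ok = jk_ok,
                 objective = core$objective, n_points = n,
                 x = x, y = y,
                 x_se = rep_len(if (is.null(x_se)) 0 else x_se, n),
                 y_se = rep_len(if (is.null(y_se)) 0 else y_se, n)),
            class = "mlfr_fit")
}

#' @export
print.mlfr_fit <- function(x, ...) {
  cat("Maximum likelihood functional relationship (Deming) fit\n")
  cat(sprintf("  slope (extensibility phi) : %.4g +/- %.3g %%/h/MPa\n",
              x$slope_phi, x$se_phi))
  cat(sprintf("  x-intercept (yield y)     : %.4g +/- %.3g MPa\n",
              x$x_intercept_y, x$se_y))
  cat(sprintf("  intercept                 : %.4g %%/h\n", x$intercept))
  cat(sprintf("  slope p (df = %d)         : %.4g%s\n", x$df_regression,
              x$slope_p,
              if (!is.na(x$slope_p) && x$slope_p >= 0.05)
                "  [not significant: phi and y are ND]" else ""))
  cat(sprintf("  weighting: %s; n = %d points\n", x$lambda_weighting,
              x$n_points))
  invisible(x)
}

#' @export
coef.mlfr_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope_phi)
}

#' Plot a stress/creep-rate fit
#'
#' Points with error bars in both coordinates and the fitted line;
#' solid if the regression is significant at `alpha`, dashed otherwise.
#'
#' @param x an [mlfr_fit()].
#' @param alpha significance level for the line style.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mlfr_fit <- function(x, alpha = 0.05, ...) {
  graphics::plot(x$x, x$y, xlab = "Wall stress (MPa)",
                 ylab = "Creep rate (%/h)", pch = 19, ...)
  graphics::arrows(x$x - x$x_se, x$y, x$x + x$x_se, x$y,
                   angle = 90, code = 3, length = 0.03)
  graphics::arrows(x$x, x$y - x$y_se, x$x, x$y + x$y_se,
                   angle = 90, code = 3, length = 0.03)
  sig <- !is.na(x$slope_p) && x$slope_p < alpha
  graphics::abline(x$intercept, x$slope_phi, lty = if (sig) 1 else 2)
  invisible(x)
}

#' Leave-one-out jackknife SEs for the MLFR slope and x-intercept
#'
#' Refits the line leaving out each point in turn; the jackknife
#' standard error of an estimate \eqn{\theta} is
#' \deqn{\mathrm{SE} = \sqrt{\frac{N-1}{N}
#'       \sum_i (\theta_{(i)} - \bar\theta_{(\cdot)})^2}.}
#' If any leave-one-out refit is degenerate (fewer than two distinct x
#' values) the SEs are reported as `NA` with `ok = FALSE`.
#'
#' @inheritParams mlfr_fit
#' @return List with `se_phi`, `se_y`, `ok`, and the leave-one-out
#'   estimates `phi_loo`, `y_loo`.
#' @examples
#' x <- c(19.5, 24.4, 29.2, 34.1)
#' jackknife_se(x, 0.80 * (x - 15.23), x_se = 1, y_se = 0.5)$se_phi # 0
#' @export
jackknife_se <- function(x, y, x_se = NULL, y_se = NULL,
                         weighting = c("per_point", "pooled")) {
  weighting <- match.arg(weighting)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  x_se <- rep_len(if (is.null(x_se)) 0 else x_se, n)
  y_se <- rep_len(if (is.null(y_se)) 0 else y_se, n)
  phi_loo <- y_loo <- rep(NA_real_, n)
  ok <- TRUE
  for (i in seq_len(n)) {
    xi <- x[-i]
    if (length(unique(xi)) < 2L) { ok <- FALSE; next }
    w <- suppressWarnings(
      mlfr_weights(xi, y[-i], x_se[-i], y_se[-i], weighting))
    core <- mlfr_core(xi, y[-i], w$vx, w$vy)
    phi_loo[i] <- core$slope
    y_loo[i] <- if (core$slope != 0) -core$intercept / core$slope else NA
  }
  ok <- ok && !anyNA(phi_loo) && !anyNA(y_loo)
  list(se_phi = jackknife_combine(phi_loo),
       se_y = jackknife_combine(y_loo), ok = ok,
       phi_loo = phi_loo, y_loo = y_loo)
}

#' Symmetry check of the MLFR estimator
#'
#' Fits both orientations (y on x, and x on y with the error roles
#' swapped) and verifies that the two slopes are mutual reciprocals and
#' that the x-intercept of the y-on-x line equals the intercept of the
#' x-on-y line, within a relative tolerance.  This symmetry is what
#' distinguishes the functional-relationship estimator from ordinary
#' least squares and is why the yield threshold may equivalently be
#' read from either orientation.
#'
#' @inheritParams mlfr_fit
#' @param tol relative tolerance (default \eqn{10^{-8}}).
#' @return `TRUE` or `FALSE`.
#' @export
mlfr_symmetry_check <- function(x, y, x_se = NULL, y_se = NULL,
                                weighting = c("per_point", "pooled"),
                                tol = 1e-8) {
  weighting <- match.arg(weighting)
  f_yx <- mlfr_fit(x, y, x_se, y_se, weighting, jackknife = FALSE)
  f_xy <- mlfr_fit(y, x, y_se, x_se, weighting, jackknife = FALSE)
  if (f_yx$slope_phi == 0 || f_xy$slope_phi == 0) return(FALSE)
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
  rel(f_yx$slope_phi, 1 / f_xy$slope_phi) < tol &&
    rel(f_yx$x_intercept_y, f_xy$intercept) < tol
}

#' Significance of the fitted slope
#'
#' Two-tailed \eqn{t}-test of the slope against zero:
#' \eqn{t = \phi / \mathrm{SE}(\phi)} on \eqn{N - p - 1} degrees of
#' freedom, where \eqn{N} is the number of points (loads) and \eqn{p}
#' the number of predictors (1), so \eqn{N - 2}.  When the regression
#' is not significant the extensibility and yield threshold should be
#' reported as not determined (ND); see [fits_table()].
#'
#' @param fit an [mlfr_fit()].
#' @param alpha significance level (default 0.05).
#' @return List with `t`, `df`, `p_value`, `significant`.
#' @export
slope_significance <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mlfr_fit"))
  if (is.na(fit$se_phi))
    stop("fit carries no jackknife SE", call. = FALSE)
  if (fit$se_phi == 0) {
    if (fit$slope_phi == 0)
      return(list(t = 0, df = fit$df_regression, p_value = 1,
                  significant = FALSE))
    warning("zero SE with non-zero slope; p reported as 0")
    return(list(t = Inf, df = fit$df_regression, p_value = 0,
                significant = TRUE))
  }
  tt <- fit$slope_phi / fit$se_phi
  p <- 2 * stats::pt(-abs(tt), fit$df_regression)
  list(t = tt, df = fit$df_regression, p_value = p,
       significant = p < alpha)
}

#' Compare a parameter between two fitted models
#'
#' Tests the difference of a parameter (extensibility `"phi"` or yield
#' threshold `"y"`) between two independent fits with the statistic
#' \deqn{t = \frac{c_1 - c_2}{\sqrt{0.5(\sigma_1^2 + \sigma_2^2)}}}
#' where \eqn{c_k} are the estimates and \eqn{\sigma_k} their jackknife
#' standard errors, referred to a two-tailed \eqn{t}-distribution with
#' \eqn{df_1 + df_2} degrees of freedom (the summed regression degrees
#' of freedom; 4 for two four-load fits).
#'
#' @param fit1,fit2 [mlfr_fit()] objects.
#' @param parameter `"phi"` or `"y"`.
#' @return List of class `"coef_comparison"` with `parameter`,
#'   `estimate_1`, `estimate_2`, `t_ratio`, `df`, `p_value`.
#' @examples
#' x <- c(19.5, 24.4, 29.2, 34.1)
#' f1 <- mlfr_fit(x, 0.8 * (x - 15) + c(0.1, -0.1, 0.1, -0.1),
#'                x_se = 1, y_se = 0.5)
#' f2 <- mlfr_fit(x, 0.3 * (x - 5) + c(-0.1, 0.1, -0.1, 0.1),
#'                x_se = 1, y_se = 0.5)
#' compare_models(f1, f2, "phi")
#' @export
compare_models <- function(fit1, fit2, parameter = c("phi", "y")) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(fit1, "mlfr_fit"), inherits(fit2, "mlfr_fit"))
  get <- function(f) {
    if (parameter == "phi") c(f$slope_phi, f$se_phi)
    else c(f$x_intercept_y, f$se_y)
  }
  a <- get(fit1)
  b <- get(fit2)
  if (anyNA(a) || anyNA(b))
    stop("both fits need defined estimates and SEs for '", parameter, "'",
         call. = FALSE)
  denom <- sqrt(0.5 * (a[2]^2 + b[2]^2))
  df <- fit1$df_regression + fit2$df_regression
  tt <- if (denom == 0) {
    if (a[1] == b[1]) 0 else Inf * sign(a[1] - b[1])
  } else (a[1] - b[1]) / denom
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
  structure(list(parameter = parameter, estimate_1 = a[1],
                 estimate_2 = b[1], se_1 = a[2], se_2 = b[2],
                 t_ratio = tt, df = df, p_value = p),
            class = "coef_comparison")
}

#' @export
print.coef_comparison <- function(x, ...) {
  cat(sprintf(
    "Comparison of %s: %.4g vs %.4g; t = %.4g on %d df, p = %.4g\n",
    x$parameter, x$estimate_1, x$estimate_2, x$t_ratio, x$df, x$p_value))
  invisible(x)
}

#' Fits table for a multi-condition experiment
#'
#' Runs [mlfr_fit()] for each (group, pH, inactivation) condition,
#' pairing the per-load creep-rate means ± SE from [group_rates()]
#' with the per-load stress means and SEs (SD/\eqn{\sqrt n}) from
#' [group_stress_table()].  Conditions whose regression is not
#' significant at `alpha` have extensibility and yield threshold
#' reported as `NA` and flagged `nd = TRUE` (not determined).
#'
#' @param rate_summary output of [group_rates()].
#' @param stress output of [group_stress_table()].
#' @param alpha significance level for the ND rule (default 0.05).
#' @param weighting passed to [mlfr_fit()].
#' @return List with `table` (one row per condition) and `fits` (the
#'   underlying `mlfr_fit` objects, named by condition).
#' @export
fits_table <- function(rate_summary, stress, alpha = 0.05,
                       weighting = "per_point") {
  rate_summary <- as.data.frame(rate_summary)
  stress <- as.data.frame(stress)
  key <- interaction(rate_summary$group, rate_summary$ph,
                     rate_summary$inactivated, drop = TRUE,
                     lex.order = TRUE)
  rows <- list()
  fits <- list()
  for (d in split(rate_summary, key)) {
    g <- d$group[1]
    st <- stress[stress$group == g, ]
    m <- merge(d, st[c("group", "load_mg", "stress_mean", "stress_sd", "n")],
               by = c("group", "load_mg"), suffixes = c("", ".st"))
    if (nrow(m) < 3L)
      stop("condition ", g, " has fewer than 3 matched loads", call. = FALSE)
    m <- m[order(m$load_mg), ]
    fit <- mlfr_fit(m$stress_mean, m$mean_rate,
                    x_se = m$stress_sd / sqrt(m$n.st %||% m$n),
                    y_se = m$se_rate, weighting = weighting)
    nd <- is.na(fit$slope_p) || fit$slope_p >= alpha
    lab <- sprintf("%s_pH%s%s", g, format(d$ph[1]),
                   if (d$inactivated[1]) "_inactivated" else "")
    fits[[lab]] <- fit
    rows[[lab]] <- data.frame(
      group = g, ph = d$ph[1], inactivated = d$inactivated[1],
      phi = if (nd) NA_real_ else fit$slope_phi,
      se_phi = if (nd) NA_real_ else fit$se_phi,
      yield_threshold = if (nd) NA_real_ else fit$x_intercept_y,
      se_yield = if (nd) NA_real_ else fit$se_y,
      slope_p = fit$slope_p, df = fit$df_regression, nd = nd)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab[order(tab$group, tab$ph, tab$inactivated), ],
       fits = fits)
}
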
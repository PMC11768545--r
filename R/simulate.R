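#' Simulate segment dry masses
#'
#' Draws `n_mass_replicates` dry masses (µg per segment) from a Gaussian
#' with the scenario mean and SD, truncated at zero by rejection.  At
#' the coefficients of variation typical of wall dry-mass measurements
#' (under 10%) the truncation is numerically irrelevant but guarantees
#' physical positivity.
#'
#' @param scenario a [creep_scenario()].
#' @param seed optional seed overriding the scenario seed.
#' @return Numeric vector of positive masses (µg), length
#'   `scenario$n_mass_replicates`.
#' @examples
#' simulate_dry_masses(creep_scenario("c", dry_mass_mean = 1.52,
#'                                    dry_mass_sd = 0.11, seed = 3))
#' @export
simulate_dry_masses <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "creep_scenario"))
  n <- scenario$n_mass_replicates
  mu <- scenario$dry_mass_mean
  sd <- scenario$dry_mass_sd
  if (sd == 0) return(rep(mu, n))
  with_seed(if (is.null(seed)) scenario$seed else seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mu, sd)
      out <- c(out, draw[draw > 0])
    }
    out[seq_len(n)]
  })
}

#' Simulate one constant-load creep trace
#'
#' Generates the relative-extension time series of a single specimen
#' under a constant load: an instantaneous elastic jump at load
#' application followed by linear creep at the Lockhart-type rate
#' \eqn{\max(0, \phi(\sigma - y))} (% h\eqn{^{-1}}), perturbed by one
#' Gaussian rate draw per specimen (SD `creep_rate_noise_sd`) and,
#' optionally, independent per-sample jitter (`trace_jitter_sd`).
#'
#' @param scenario a [creep_scenario()].
#' @param load_mg applied load (mg), recorded in the trace metadata.
#' @param true_stress_MPa the wall stress (MPa) the load generates in
#'   this group; must be positive.
#' @param seed RNG seed for this specimen.
#' @param specimen_id label for the specimen.
#' @return A [creep_trace()] object.
#' @examples
#' sc <- creep_scenario("c", creep_rate_noise_sd = 0, seed = 1)
#' tr <- simulate_creep_trace(sc, 700, true_stress_MPa = 34.1, seed = 5)
#' creep_rate(tr)
#' @export
simulate_creep_trace <- function(scenario, load_mg, true_stress_MPa, seed,
                                 specimen_id = "sim-1") {
  stopifnot(inherits(scenario, "creep_scenario"))
  stop_if_not_number(load_mg, "load_mg", positive = TRUE)
  stop_if_not_number(true_stress_MPa, "true_stress_MPa", positive = TRUE)
  stop_if_not_number(seed, "seed")

  times <- seq(0, scenario$trace_duration_s,
               by = scenario$trace_sampling_interval_s)
  base_rate <- max(0, scenario$phi * (true_stress_MPa - scenario$y_threshold))
  with_seed(seed, {
    rate <- base_rate +
      if (scenario$creep_rate_noise_sd > 0)
        stats::rnorm(1, 0, scenario$creep_rate_noise_sd) else 0
    ext <- scenario$elastic_jump_pct + rate * times / 3600
    if (scenario$trace_jitter_sd > 0)
      ext <- ext + stats::rnorm(length(times), 0, scenario$trace_jitter_sd)
    creep_trace(specimen_id = specimen_id, group = scenario$group,
                load_mg = load_mg, ph = scenario$ph,
                inactivated = scenario$inactivated,
                times = times, rel_extension = ext,
                initial_length_mm = scenario$segment_length_mm)
  })
}

#' Simulate a complete two-group creep experiment
#'
#' Produces a full synthetic data set with the measurement structure of
#' a two-group, multi-load creep study: per-group dry masses, the wall
#' stress each load generates (derived from the simulated masses via
#' [group_stress_table()]), and one creep trace per specimen per load.
#' All randomness is governed by the scenario seeds through
#' deterministic child streams, so identical inputs give identical
#' output.
#'
#' @param scenario_a,scenario_b [creep_scenario()] objects with distinct
#'   group labels.
#' @param density_g_cm3 assumed wall density used to derive stresses.
#' @param g_constant gravitational acceleration (m s\eqn{^{-2}}).
#' @param dir optional directory; when given, `traces.csv`,
#'   `masses.csv` and `provenance.json` are written there.
#' @return A list with elements `traces` (long data frame, one row per
#'   sampled time point), `masses` (one row per replicate), `stress`
#'   (the per-group [group_stress_table()] used as generating truth) and
#'   `meta` (provenance: scenario parameters and seeds).
#' @examples
#' sc <- default_scenarios(seed = 11)
#' sim <- simulate_experiment(sc$control, sc$ebl)
#' nrow(sim$masses)
#' @export
simulate_experiment <- function(scenario_a, scenario_b,
                                density_g_cm3 = 1.5,
                                g_constant = 9.80665,
                                dir = NULL) {
  stopifnot(inherits(scenario_a, "creep_scenario"),
            inherits(scenario_b, "creep_scenario"))
  if (identical(scenario_a$group, scenario_b$group))
    stop("scenarios must have distinct group labels", call. = FALSE)

  one_group <- function(sc) {
    masses <- simulate_dry_masses(sc, seed = child_seed(sc$seed, 0L))
    mass_df <- data.frame(group = sc$group,
                          replicate = seq_along(masses),
                          dry_mass_ug = masses,
                          segment_length_mm = sc$segment_length_mm)
    stress <- group_stress_table(mass_df, loads_mg = sc$loads_mg,
                                 density_g_cm3 = density_g_cm3,
                                 g_constant = g_constant)
    traces <- vector("list", length(sc$loads_mg) * sc$n_specimens_per_load)
    k <- 0L
    for (li in seq_along(sc$loads_mg)) {
      sigma <- stress$stress_mean[stress$load_mg == sc$loads_mg[li]]
      for (sp in seq_len(sc$n_specimens_per_load)) {
        k <- k + 1L
        tr <- simulate_creep_trace(
          sc, sc$loads_mg[li], sigma,
          seed = child_seed(sc$seed, 100L * li + sp),
          specimen_id = sprintf("%s-L%g-%02d", sc$group, sc$loads_mg[li], sp))
        traces[[k]] <- as.data.frame(tr)
      }
    }
    list(masses = mass_df, stress = stress,
         traces = do.call(rbind, traces))
  }

  a <- one_group(scenario_a)
  b <- one_group(scenario_b)
  out <- list(
    traces = rbind(a$traces, b$traces),
    masses = rbind(a$masses, b$masses),
    stress = rbind(a$stress, b$stress),
    meta = list(
      scenarios = list(unclass(scenario_a), unclass(scenario_b)),
      density_g_cm3 = density_g_cm3, g_constant = g_constant)
  )
  rownames(out$traces) <- rownames(out$masses) <- rownames(out$stress) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$traces, file.path(dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(out$masses, file.path(dir, "masses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$meta, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate summary-level stress/rate points on a creep-law line
#'
#' Generates the per-load summary points that enter the functional
#' relationship fit directly, bypassing trace and mass simulation:
#' observed stress means are the true means jittered by their standard
#' errors, and observed creep-rate means lie on the line
#' \eqn{\phi(\sigma - y)} evaluated at the true stresses, plus Gaussian
#' noise with SD `rate_se`.  This is the measurement model of a fitted
#' creep-rate-vs-stress line and is the basis of the parameter-recovery
#' checks.
#'
#' @param phi,y_threshold generating extensibility and yield threshold.
#' @param stress_means true per-load stress means (MPa).
#' @param stress_se per-load standard errors of the stress means (MPa);
#'   recycled to the length of `stress_means`.
#' @param rate_se standard error of each creep-rate mean
#'   (% h\eqn{^{-1}}); recycled likewise.
#' @param seed RNG seed.
#' @return A data frame with columns `x`, `x_se`, `y`, `y_se`, ready for
#'   [mlfr_fit()].
#' @examples
#' pts <- simulate_stress_rate_points(0.80, 15.23,
#'   stress_means = c(19.5, 24.4, 29.2, 34.1),
#'   stress_se = c(1.5, 1.9, 2.3, 2.6) / 2, rate_se = 0.5, seed = 2)
#' mlfr_fit(pts$x, pts$y, pts$x_se, pts$y_se)
#' @export
simulate_stress_rate_points <- function(phi, y_threshold, stress_means,
                                        stress_se, rate_se, seed) {
  stop_if_not_number(phi, "phi", nonneg = TRUE)
  stop_if_not_number(y_threshold, "y_threshold", nonneg = TRUE)
  if (length(stress_means) < 3L || any(stress_means <= 0))
    stop("'stress_means' must have >= 3 positive entries", call. = FALSE)
  stress_se <- rep_len(stress_se, length(stress_means))
  rate_se <- rep_len(rate_se, length(stress_means))
  if (any(stress_se < 0) || any(rate_se < 0))
    stop("standard errors must be >= 0", call. = FALSE)
  with_seed(seed, {
    x <- stress_means + stats::rnorm(length(stress_means), 0, stress_se)
    y <- phi * (stress_means - y_threshold) +
      stats::rnorm(length(stress_means), 0, rate_se)
    data.frame(x = x, x_se = stress_se, y = y, y_se = rate_se)
  })
}
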
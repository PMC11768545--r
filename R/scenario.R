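#' Define a simulation scenario for one experimental group
#'
#' A scenario bundles the generating parameters for one group of a
#' synthetic creep experiment: the linear creep law (extensibility
#' `phi` and yield threshold `y_threshold`), the loading design, the
#' dry-mass distribution used to derive wall stresses, and the noise
#' structure of the measurements.
#'
#' The defaults reproduce the design of a typical hypocotyl creep study:
#' four loads of 400-700 mg, ten creep specimens per load, four dry-mass
#' replicates, 15-minute tests sampled once per second, and an
#' instantaneous elastic jump of 1% at load application.
#'
#' The creep law is Lockhart-like: the expected relative creep rate at
#' wall stress \eqn{\sigma} is \eqn{\max(0, \phi(\sigma - y))} in
#' % h\eqn{^{-1}}, i.e. sub-threshold stresses do not creep.  Specimen
#' noise is a single Gaussian rate perturbation per specimen
#' (`creep_rate_noise_sd`), matching the between-specimen scatter of
#' replicated creep tests; optional per-sample jitter
#' (`trace_jitter_sd`) models sensor noise within a trace.
#'
#' @param group group label (character scalar).
#' @param phi in vitro cell wall extensibility, % h\eqn{^{-1}}
#'   MPa\eqn{^{-1}}; must be \eqn{\ge 0}.
#' @param y_threshold in vitro yield threshold, MPa; must be \eqn{\ge 0}.
#' @param loads_mg applied loads in mg; non-empty, all positive.
#' @param n_specimens_per_load creep specimens per load (\eqn{\ge 2}).
#' @param dry_mass_mean,dry_mass_sd mean and SD (µg) of the dry mass of
#'   one segment of `segment_length_mm`; masses are drawn from a
#'   Gaussian truncated at zero.
#' @param n_mass_replicates dry-mass replicates (\eqn{\ge 2}).
#' @param creep_rate_noise_sd SD (% h\eqn{^{-1}}) of the per-specimen
#'   rate perturbation.
#' @param trace_jitter_sd SD (%) of independent per-sample jitter added
#'   to each trace point; default 0 (no within-trace noise).
#' @param trace_duration_s duration of each creep test, seconds.
#' @param trace_sampling_interval_s sampling interval, seconds.
#' @param elastic_jump_pct instantaneous relative extension (%) at load
#'   application.
#' @param ph buffer pH recorded in the trace metadata.
#' @param inactivated logical; `TRUE` marks heat-inactivated walls.
#' @param segment_length_mm initial segment length, mm.
#' @param seed integer RNG seed for this group.
#'
#' @return An object of class `"creep_scenario"` (a named list).
#' @seealso [simulate_experiment()], [simulate_creep_trace()],
#'   [simulate_dry_masses()]
#' @examples
#' creep_scenario("control", phi = 0.80, y_threshold = 15.23,
#'                dry_mass_mean = 1.52, dry_mass_sd = 0.11, seed = 1)
#' @export
creep_scenario <- function(group = "control",
                           phi = 0.80,
                           y_threshold = 15.23,
                           loads_mg = c(400, 500, 600, 700),
                           n_specimens_per_load = 10,
                           dry_mass_mean = 1.52,
                           dry_mass_sd = 0.11,
                           n_mass_replicates = 4,
                           creep_rate_noise_sd = 1.6,
                           trace_jitter_sd = 0,
                           trace_duration_s = 900,
                           trace_sampling_interval_s = 1,
                           elastic_jump_pct = 1,
                           ph = 5,
                           inactivated = FALSE,
                           segment_length_mm = 5,
                           seed = 1L) {
  if (!is.character(group) || length(group) != 1L || !nzchar(group))
    stop("'group' must be a non-empty character scalar", call. = FALSE)
  stop_if_not_number(phi, "phi", nonneg = TRUE)
  stop_if_not_number(y_threshold, "y_threshold", nonneg = TRUE)
  if (length(loads_mg) < 1L || any(!is.finite(loads_mg)) || any(loads_mg <= 0))
    stop("'loads_mg' must be non-empty and all > 0", call. = FALSE)
  stop_if_not_number(n_specimens_per_load, "n_specimens_per_load")
  if (n_specimens_per_load < 2)
    stop("'n_specimens_per_load' must be >= 2", call. = FALSE)
  stop_if_not_number(dry_mass_mean, "dry_mass_mean", positive = TRUE)
  stop_if_not_number(dry_mass_sd, "dry_mass_sd", nonneg = TRUE)
  stop_if_not_number(n_mass_replicates, "n_mass_replicates")
  if (n_mass_replicates < 2)
    stop("'n_mass_replicates' must be >= 2", call. = FALSE)
  stop_if_not_number(creep_rate_noise_sd, "creep_rate_noise_sd", nonneg = TRUE)
  stop_if_not_number(trace_jitter_sd, "trace_jitter_sd", nonneg = TRUE)
  stop_if_not_number(trace_duration_s, "trace_duration_s", positive = TRUE)
  stop_if_not_number(trace_sampling_interval_s, "trace_sampling_interval_s",
                     positive = TRUE)
  stop_if_not_number(elastic_jump_pct, "elastic_jump_pct", nonneg = TRUE)
  stop_if_not_number(segment_length_mm, "segment_length_mm", positive = TRUE)
  stop_if_not_number(seed, "seed")

  structure(list(
    group = group, phi = phi, y_threshold = y_threshold,
    loads_mg = as.numeric(loads_mg),
    n_specimens_per_load = as.integer(n_specimens_per_load),
    dry_mass_mean = dry_mass_mean, dry_mass_sd = dry_mass_sd,
    n_mass_replicates = as.integer(n_mass_replicates),
    creep_rate_noise_sd = creep_rate_noise_sd,
    trace_jitter_sd = trace_jitter_sd,
    trace_duration_s = trace_duration_s,
    trace_sampling_interval_s = trace_sampling_interval_s,
    elastic_jump_pct = elastic_jump_pct,
    ph = ph, inactivated = isTRUE(inactivated),
    segment_length_mm = segment_length_mm,
    seed = as.integer(seed)
  ), class = "creep_scenario")
}

#' @export
print.creep_scenario <- function(x, ...) {
  cat("Creep simulation scenario: group '", x$group, "'\n", sep = "")
  cat(sprintf("  creep law : rate = max(0, %.3g * (stress - %.4g)) %%/h\n",
              x$phi, x$y_threshold))
  cat(sprintf("  design    : loads {%s} mg, %d specimens/load, pH %s%s\n",
              paste(x$loads_mg, collapse = ", "), x$n_specimens_per_load,
              format(x$ph), if (x$inactivated) ", heat-inactivated" else ""))
  cat(sprintf("  dry mass  : %.3g +/- %.3g ug (n = %d, %g mm segment)\n",
              x$dry_mass_mean, x$dry_mass_sd, x$n_mass_replicates,
              x$segment_length_mm))
  cat(sprintf("  noise     : specimen rate SD %.3g %%/h, trace jitter SD %.3g %%\n",
              x$creep_rate_noise_sd, x$trace_jitter_sd))
  cat(sprintf("  trace     : %g s at %g s steps, elastic jump %g %%; seed %d\n",
              x$trace_duration_s, x$trace_sampling_interval_s,
              x$elastic_jump_pct, x$seed))
  invisible(x)
}

#' Default two-group scenarios of the reference creep experiment
#'
#' Convenience constructor for the control and brassinosteroid-treated
#' (EBL) scenarios used throughout the documentation and tests: control
#' walls with \eqn{\phi = 0.80} % h\eqn{^{-1}} MPa\eqn{^{-1}},
#' \eqn{y = 15.23} MPa, mean dry mass 1.52 µg; treated walls with
#' \eqn{\phi = 0.31}, \eqn{y = 5.42}, mean dry mass 2.30 µg (thicker
#' walls, hence lower stress under the same load).  Specimen rate noise
#' is 1.6 % h\eqn{^{-1}} (control) and 0.8 % h\eqn{^{-1}} (treated),
#' i.e. a standard error of roughly 0.5 and 0.25 % h\eqn{^{-1}} on a
#' 10-specimen mean.
#'
#' @param seed master seed; the two groups receive distinct child seeds.
#' @return Named list with elements `control` and `ebl`, each a
#'   [creep_scenario()].
#' @examples
#' default_scenarios(seed = 7)$control
#' @export
default_scenarios <- function(seed = 1L) {
  stop_if_not_number(seed, "seed")
  list(
    control = creep_scenario("control", phi = 0.80, y_threshold = 15.23,
                             dry_mass_mean = 1.52, dry_mass_sd = 0.11,
                             creep_rate_noise_sd = 1.6,
                             seed = child_seed(seed, 1L)),
    ebl = creep_scenario("ebl", phi = 0.31, y_threshold = 5.42,
                         dry_mass_mean = 2.30, dry_mass_sd = 0.13,
                         creep_rate_noise_sd = 0.8,
                         seed = child_seed(seed, 2L))
  )
}
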
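#' Build an analysis configuration
#'
#' Collects every knob of the creep-biomechanics pipeline in one
#' validated object.  Data enter either as file paths (`traces_path`,
#' `masses_path`) or as a pair of simulation scenarios; exactly one of
#' the two routes must be present.
#'
#' @param traces_path,masses_path input CSVs (see [read_traces()],
#'   [read_masses()]), or `NULL` when simulating.
#' @param scenarios list of two [creep_scenario()] objects (or `NULL`).
#' @param loads_mg loads analysed, mg.
#' @param density_g_cm3 assumed wall density, g cm\eqn{^{-3}}.
#' @param g_constant gravitational acceleration, m s\eqn{^{-2}}.
#' @param creep_window creep-rate fit window, seconds.
#' @param stress_mode averaging mode of [group_stress_table()].
#' @param n_boot,resample_size_rates,resample_size_stress,ratio_method
#'   bootstrap settings, see [bootstrap_ratio()].
#' @param weighting MLFR error weighting, see [mlfr_fit()].
#' @param alpha significance / FDR level.
#' @param seed master seed.
#' @param output_dir directory for the report bundle, or `NULL` for an
#'   in-memory run.
#' @return Object of class `"analysis_config"`.
#' @seealso [run_pipeline()], [read_config()]
#' @export
analysis_config <- function(traces_path = NULL, masses_path = NULL,
                            scenarios = NULL,
                            loads_mg = c(400, 500, 600, 700),
                            density_g_cm3 = 1.5, g_constant = 9.80665,
                            creep_window = c(300, 900),
                            stress_mode = "per_replicate",
                            n_boot = 10000,
                            resample_size_rates = 4,
                            resample_size_stress = 4,
                            ratio_method = "ratio_of_means",
                            weighting = "per_point",
                            alpha = 0.05, seed = 1L,
                            output_dir = NULL) {
  has_files <- !is.null(traces_path) && !is.null(masses_path)
  has_scen <- !is.null(scenarios)
  if (has_files == has_scen)
    stop("give either both input paths or a scenario pair, not both/neither",
         call. = FALSE)
  if (has_scen) {
    if (length(scenarios) != 2L ||
        !all(vapply(scenarios, inherits, logical(1), "creep_scenario")))
      stop("'scenarios' must be a list of two creep_scenario objects",
           call. = FALSE)
  }
  stop_if_not_number(density_g_cm3, "density_g_cm3", positive = TRUE)
  stop_if_not_number(g_constant, "g_constant", positive = TRUE)
  stop_if_not_number(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) stop("'alpha' must be < 1", call. = FALSE)
  stop_if_not_number(n_boot, "n_boot", positive = TRUE)
  stop_if_not_number(seed, "seed")
  if (length(creep_window) != 2L || creep_window[2] <= creep_window[1])
    stop("'creep_window' must be an increasing pair", call. = FALSE)
  structure(list(traces_path = traces_path, masses_path = masses_path,
                 scenarios = scenarios, loads_mg = as.numeric(loads_mg),
                 density_g_cm3 = density_g_cm3, g_constant = g_constant,
                 creep_window = as.numeric(creep_window),
                 stress_mode = stress_mode,
                 n_boot = as.integer(n_boot),
                 resample_size_rates = as.integer(resample_size_rates),
                 resample_size_stress = as.integer(resample_size_stress),
                 ratio_method = ratio_method, weighting = weighting,
                 alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON or YAML
#'
#' The file mirrors the arguments of [analysis_config()]; scenarios are
#' given as named parameter lists under `scenarios`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  if (!is.null(raw$scenarios))
    raw$scenarios <- lapply(raw$scenarios, function(s)
      do.call(creep_scenario, s))
  if (!is.null(raw$creep_window)) raw$creep_window <- unlist(raw$creep_window)
  if (!is.null(raw$loads_mg)) raw$loads_mg <- unlist(raw$loads_mg)
  do.call(analysis_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full creep-biomechanics pipeline
#'
#' Orchestrates the analysis from one configuration: obtain data
#' (simulate from scenarios, or read the input CSVs), extract
#' per-specimen creep rates, summarise them per condition, derive the
#' stress table from dry masses, bootstrap creep rate per unit stress
#' with FDR-controlled group comparisons, fit the functional
#' relationship per condition and compare extensibility and yield
#' threshold between groups.  With `output_dir` set, all tables are
#' written as CSV together with a machine-readable `summary.json`
#' carrying the resolved configuration, its hash, seeds and the package
#' version; reruns with the same configuration are byte-identical.
#'
#' @param config an [analysis_config()].
#' @param quiet suppress per-stage log lines.
#' @return (Invisibly) a list of class `"wallmech_result"`: `rates`,
#'   `rate_summary`, `stress`, `ratios`, `ratio_comparisons`, `fits`
#'   (see [fits_table()]), `model_comparisons`, `config`, `summary`.
#' @examples
#' sc <- default_scenarios(seed = 5)
#' sc$control$trace_sampling_interval_s <- 30  # light example
#' sc$ebl$trace_sampling_interval_s <- 30
#' cfg <- analysis_config(scenarios = sc, n_boot = 200, seed = 5)
#' res <- run_pipeline(cfg, quiet = TRUE)
#' res$fits$table
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(stage, ...) {
    if (!quiet)
      message(sprintf("[wallmech] %-10s %s", stage, sprintf(...)))
  }

  if (!is.null(config$scenarios)) {
    sim <- simulate_experiment(config$scenarios[[1]], config$scenarios[[2]],
                               density_g_cm3 = config$density_g_cm3,
                               g_constant = config$g_constant)
    traces <- sim$traces
    masses <- sim$masses
    say("simulate", "%d trace rows, %d mass replicates (seeds %d/%d)",
        nrow(traces), nrow(masses), config$scenarios[[1]]$seed,
        config$scenarios[[2]]$seed)
  } else {
    traces <- read_traces(config$traces_path)
    masses <- read_masses(config$masses_path)
    say("read", "%d trace rows, %d mass replicates", nrow(traces),
        nrow(masses))
  }

  rates <- creep_rates(traces, window = config$creep_window)
  say("rates", "%d specimens, window %g-%g s", nrow(rates),
      config$creep_window[1], config$creep_window[2])
  rate_summary <- group_rates(rates)

  stress <- group_stress_table(masses, loads_mg = config$loads_mg,
                               density_g_cm3 = config$density_g_cm3,
                               g_constant = config$g_constant,
                               mode = config$stress_mode)
  say("stress", "%d group x load rows (%s)", nrow(stress),
      config$stress_mode)

  ratios <- ratio_table(rates, masses, loads_mg = config$loads_mg,
                        density_g_cm3 = config$density_g_cm3,
                        g_constant = config$g_constant,
                        n_boot = config$n_boot,
                        resample_size_rates = config$resample_size_rates,
                        resample_size_stress = config$resample_size_stress,
                        method = config$ratio_method, seed = config$seed)
  ratio_cmp <- compare_ratio_groups(ratios, alpha = config$alpha)
  say("ratio", "%d cells, %d contrasts (%d significant at FDR %g)",
      nrow(ratios), nrow(ratio_cmp), sum(ratio_cmp$significant),
      config$alpha)

  fits <- fits_table(rate_summary, stress, alpha = config$alpha,
                     weighting = config$weighting)
  say("mlfr", "%d condition fits (%d ND)", nrow(fits$table),
      sum(fits$table$nd))

  model_cmp <- compare_fit_groups(fits, alpha = config$alpha)
  say("compare", "%d parameter contrasts", nrow(model_cmp))

  summary <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("wallmech")),
    config = unclass(config), config_hash = config_hash(config),
    n_specimens = nrow(rates),
    conditions = nrow(fits$table),
    fits = fits$table, model_comparisons = model_cmp,
    ratio_comparisons = as.data.frame(ratio_cmp))

  result <- structure(list(rates = rates, rate_summary = rate_summary,
                           stress = stress, ratios = ratios,
                           ratio_comparisons = ratio_cmp, fits = fits,
                           model_comparisons = model_cmp,
                           config = config, summary = summary),
                      class = "wallmech_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, f) utils::write.csv(d, file.path(config$output_dir, f),
                                          row.names = FALSE)
    wr(rates, "rates.csv")
    wr(rate_summary, "rate_summary.csv")
    wr(stress, "stress_table.csv")
    wr(ratios, "ratio_table.csv")
    wr(as.data.frame(ratio_cmp), "ratio_comparisons.csv")
    wr(fits$table, "fits.csv")
    wr(model_cmp, "model_comparisons.csv")
    jsonlite::write_json(summary, file.path(config$output_dir,
                                            "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE, na = "null")
    say("write", "report bundle in %s", config$output_dir)
  }
  invisible(result)
}

#' @export
print.wallmech_result <- function(x, ...) {
  cat("wallmech pipeline result:", nrow(x$rates), "specimens,",
      nrow(x$fits$table), "condition fits\n")
  print(x$fits$table)
  invisible(x)
}

# Between-group comparisons of phi and yield threshold for every pair of
# groups sharing (ph, inactivated), skipping ND fits.
compare_fit_groups <- function(fits, alpha = 0.05) {
  tab <- fits$table
  rows <- list()
  conds <- unique(tab[c("ph", "inactivated")])
  for (i in seq_len(nrow(conds))) {
    sel <- tab$ph == conds$ph[i] & tab$inactivated == conds$inactivated[i]
    grp <- tab$group[sel]
    if (length(grp) < 2L) next
    for (a in seq_len(length(grp) - 1L)) for (b in seq((a + 1L), length(grp))) {
      la <- sprintf("%s_pH%s%s", grp[a], format(conds$ph[i]),
                    if (conds$inactivated[i]) "_inactivated" else "")
      lb <- sprintf("%s_pH%s%s", grp[b], format(conds$ph[i]),
                    if (conds$inactivated[i]) "_inactivated" else "")
      fa <- fits$fits[[la]]
      fb <- fits$fits[[lb]]
      nd <- tab$nd[sel][c(a, b)]
      for (par in c("phi", "y")) {
        if (any(nd)) {
          rows[[length(rows) + 1L]] <- data.frame(
            group_a = grp[a], group_b = grp[b], ph = conds$ph[i],
            inactivated = conds$inactivated[i], parameter = par,
            t_ratio = NA_real_, df = NA_integer_, p_value = NA_real_,
            significant = NA, note = "ND fit")
          next
        }
        cmp <- compare_models(fa, fb, par)
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = grp[a], group_b = grp[b], ph = conds$ph[i],
          inactivated = conds$inactivated[i], parameter = par,
          t_ratio = cmp$t_ratio, df = cmp$df, p_value = cmp$p_value,
          significant = cmp$p_value < alpha, note = "")
      }
    }
  }
  if (!length(rows))
    return(data.frame(group_a = character(), group_b = character(),
                      ph = numeric(), inactivated = logical(),
                      parameter = character(), t_ratio = numeric(),
                      df = integer(), p_value = numeric(),
                      significant = logical(), note = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
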
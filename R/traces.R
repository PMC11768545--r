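#' Construct a creep trace
#'
#' A creep trace is the raw record of one constant-load extensometer
#' test: relative extension (% of initial segment length) at strictly
#' increasing time points, with the specimen metadata needed downstream
#' (group, load, buffer pH, heat-inactivation flag).
#'
#' @param specimen_id specimen label.
#' @param group group label.
#' @param load_mg applied load, mg.
#' @param ph buffer pH.
#' @param inactivated logical heat-inactivation flag.
#' @param times sampling times in seconds, strictly increasing, at
#'   least 10 samples.
#' @param rel_extension relative extension (%), same length as `times`,
#'   all finite.
#' @param initial_length_mm initial segment length, mm.
#' @return An object of class `"creep_trace"`.
#' @examples
#' t <- seq(0, 900, 10)
#' creep_trace("s1", "control", 500, 5, FALSE, t, 1 + 2 * t / 3600)
#' @export
creep_trace <- function(specimen_id, group, load_mg, ph, inactivated,
                        times, rel_extension, initial_length_mm = 5) {
  stop_if_not_number(load_mg, "load_mg", positive = TRUE)
  stop_if_not_number(initial_length_mm, "initial_length_mm", positive = TRUE)
  times <- as.numeric(times)
  rel_extension <- as.numeric(rel_extension)
  if (length(times) < 10L)
    stop("a creep trace needs at least 10 samples", call. = FALSE)
  if (length(rel_extension) != length(times))
    stop("'times' and 'rel_extension' must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(rel_extension)))
    stop("'rel_extension' must be finite", call. = FALSE)
  structure(list(specimen_id = as.character(specimen_id),
                 group = as.character(group),
                 load_mg = load_mg, ph = ph,
                 inactivated = isTRUE(inactivated),
                 times = times, rel_extension = rel_extension,
                 initial_length_mm = initial_length_mm),
            class = "creep_trace")
}

#' @export
print.creep_trace <- function(x, ...) {
  cat(sprintf(
    "Creep trace '%s' (group %s, %g mg, pH %s%s): %d samples over %g s\n",
    x$specimen_id, x$group, x$load_mg, format(x$ph),
    if (x$inactivated) ", inactivated" else "",
    length(x$times), max(x$times) - min(x$times)))
  invisible(x)
}

#' @export
as.data.frame.creep_trace <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, group = x$group,
             load_mg = x$load_mg, ph = x$ph, inactivated = x$inactivated,
             time_s = x$times, rel_extension_pct = x$rel_extension)
}

#' Relative creep rate of one trace
#'
#' The relative creep rate (% h\eqn{^{-1}}) is the ordinary
#' least-squares slope of relative extension versus time over a fit
#' window, converted from % s\eqn{^{-1}} to % h\eqn{^{-1}}.  The
#' default window is the final ten minutes of a fifteen-minute test,
#' which excludes the initial viscoelastic transient after load
#' application; the window is configurable and recorded in the result.
#'
#' The goodness of fit `fit_r2` is the usual \eqn{R^2}; for a perfectly
#' fitted window (including an exactly constant trace) it is reported
#' as 1.
#'
#' @param trace a [creep_trace()].
#' @param window numeric length-2 vector `(t_start, t_end)` in seconds,
#'   inclusive; must lie within the trace and contain at least 5
#'   samples.
#' @return An object of class `"creep_rate_sample"`: a one-row list
#'   with `specimen_id`, `group`, `load_mg`, `ph`, `inactivated`,
#'   `creep_rate` (% h\eqn{^{-1}}), `fit_window` and `fit_r2`.
#' @examples
#' t <- seq(0, 900, 10)
#' tr <- creep_trace("s1", "g", 500, 5, FALSE, t, 1 + 2 * t / 3600)
#' creep_rate(tr)$creep_rate  # 2 %/h
#' @export
creep_rate <- function(trace, window = c(300, 900)) {
  stopifnot(inherits(trace, "creep_trace"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[2] <= window[1])
    stop("'window' must be an increasing (t_start, t_end) pair",
         call. = FALSE)
  if (window[1] < min(trace$times) || window[2] > max(trace$times))
    stop("fit window lies outside the trace support", call. = FALSE)
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(sel) < 5L)
    stop("fewer than 5 samples in the fit window", call. = FALSE)
  t <- trace$times[sel]
  e <- trace$rel_extension[sel]
  tc <- t - mean(t)
  slope_per_s <- sum(tc * e) / sum(tc^2)
  fitted <- mean(e) + slope_per_s * tc
  ss_res <- sum((e - fitted)^2)
  ss_tot <- sum((e - mean(e))^2)
  r2 <- if (ss_res <= 1e-24 * max(1, ss_tot)) 1 else 1 - ss_res / ss_tot
  structure(list(specimen_id = trace$specimen_id, group = trace$group,
                 load_mg = trace$load_mg, ph = trace$ph,
                 inactivated = trace$inactivated,
                 creep_rate = slope_per_s * 3600,
                 fit_window = window, fit_r2 = r2),
            class = "creep_rate_sample")
}

#' @export
print.creep_rate_sample <- function(x, ...) {
  cat(sprintf(
    "Creep rate '%s': %.4g %%/h (window %g-%g s, R2 = %.3f)\n",
    x$specimen_id, x$creep_rate, x$fit_window[1], x$fit_window[2],
    x$fit_r2))
  invisible(x)
}

#' Creep rates for every specimen in a long trace table
#'
#' Applies [creep_rate()] to each specimen of a long-format trace table
#' (columns `specimen_id`, `group`, `load_mg`, `ph`, `inactivated`,
#' `time_s`, `rel_extension_pct`, as written by
#' [simulate_experiment()] or read by [read_traces()]).
#'
#' Specimens whose fit quality falls below `r2_floor` are flagged in
#' the `flagged` column, never dropped: constant-load creep analyses
#' typically state no exclusion rule, so filtering is left to the user.
#'
#' @param traces long trace data frame.
#' @param window fit window passed to [creep_rate()].
#' @param r2_floor flag threshold on `fit_r2`; default 0 (nothing
#'   flagged).
#' @return Data frame with one row per specimen.
#' @export
creep_rates <- function(traces, window = c(300, 900), r2_floor = 0) {
  traces <- as.data.frame(traces)
  need <- c("specimen_id", "group", "load_mg", "ph", "inactivated",
            "time_s", "rel_extension_pct")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("traces table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(traces, traces$specimen_id), function(d) {
    d <- d[order(d$time_s), ]
    tr <- creep_trace(d$specimen_id[1], d$group[1], d$load_mg[1],
                      d$ph[1], d$inactivated[1], d$time_s,
                      d$rel_extension_pct)
    s <- creep_rate(tr, window = window)
    data.frame(specimen_id = s$specimen_id, group = s$group,
               load_mg = s$load_mg, ph = s$ph, inactivated = s$inactivated,
               creep_rate = s$creep_rate,
               fit_t_start = s$fit_window[1], fit_t_end = s$fit_window[2],
               fit_r2 = s$fit_r2, flagged = s$fit_r2 < r2_floor)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$load_mg, out$specimen_id), ]
  rownames(out) <- NULL
  out
}

#' Per-condition summary of creep rates
#'
#' Aggregates per-specimen creep rates into the mean, standard error
#' (SD/\eqn{\sqrt{n}}) and count per (group, load, pH, inactivation)
#' cell — the cells of a creep-rate bar chart.
#'
#' @param rates data frame from [creep_rates()] (needs columns `group`,
#'   `load_mg`, `ph`, `inactivated`, `creep_rate`).
#' @return Data frame with one row per cell, ordered by group then
#'   load, with columns `mean_rate`, `se_rate`, `n`.
#' @examples
#' r <- data.frame(group = "g", load_mg = 400, ph = 5,
#'                 inactivated = FALSE, creep_rate = c(1, 3))
#' group_rates(r)  # mean 2, SE 1
#' @export
group_rates <- function(rates) {
  rates <- as.data.frame(rates)
  need <- c("group", "load_mg", "ph", "inactivated", "creep_rate")
  miss <- setdiff(need, names(rates))
  if (length(miss))
    stop("rates table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(rates$group, rates$load_mg, rates$ph,
                     rates$inactivated, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(rates, key), function(d) {
    if (nrow(d) < 2L)
      stop("need >= 2 creep-rate samples per condition cell (group ",
           d$group[1], ", load ", d$load_mg[1], ")", call. = FALSE)
    data.frame(group = d$group[1], load_mg = d$load_mg[1], ph = d$ph[1],
               inactivated = d$inactivated[1],
               mean_rate = mean(d$creep_rate),
               se_rate = stats::sd(d$creep_rate) / sqrt(nrow(d)),
               n = nrow(d))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$load_mg, out$ph, out$inactivated), ]
  rownames(out) <- NULL
  out
}
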
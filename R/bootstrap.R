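#' Bootstrap estimate of creep rate per unit stress
#'
#' Creep rate and wall stress are measured on different specimens, so
#' the ratio creep rate \eqn{\times} stress\eqn{^{-1}} has no paired
#' observations.  It is therefore estimated by a bootstrap: in each of
#' `n_boot` replicates, `resample_size_rates` creep rates and
#' `resample_size_stress` stresses are drawn independently with
#' replacement from their pools, and the ratio of the resample means
#' (default) or the mean of elementwise ratios is computed.  The mean
#' and SD over all bootstrap replicates are reported.
#'
#' @param creep_rates pool of per-specimen creep rates
#'   (% h\eqn{^{-1}}), typically \eqn{n \approx 10}.
#' @param stresses pool of per-replicate wall stresses (MPa), all
#'   positive, typically \eqn{n = 4}.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param resample_size_rates,resample_size_stress bootstrap sample
#'   sizes (default 4, the size of the stress pool).
#' @param seed RNG seed.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`;
#'   the latter requires equal resample sizes.
#' @param meta optional named list of condition labels (`group`,
#'   `load_mg`, `ph`, `inactivated`) carried into the result.
#' @return Object of class `"ratio_estimate"`: a list with
#'   `mean_ratio`, `sd_ratio` (% h\eqn{^{-1}} MPa\eqn{^{-1}}),
#'   `n_boot`, resample sizes, `method`, `seed` and the metadata.
#' @examples
#' bootstrap_ratio(rep(6, 5), rep(3, 4), n_boot = 100, seed = 1)
#' @export
bootstrap_ratio <- function(creep_rates, stresses, n_boot = 10000,
                            resample_size_rates = 4,
                            resample_size_stress = 4,
                            seed = 1L,
                            method = c("ratio_of_means", "mean_of_ratios"),
                            meta = list()) {
  method <- match.arg(method)
  if (length(creep_rates) < 1L || length(stresses) < 1L)
    stop("rate and stress pools must be non-empty", call. = FALSE)
  if (any(!is.finite(creep_rates)) || any(!is.finite(stresses)))
    stop("rates and stresses must be finite", call. = FALSE)
  if (any(stresses <= 0))
    stop("stresses must all be positive", call. = FALSE)
  stop_if_not_number(n_boot, "n_boot", positive = TRUE)
  stop_if_not_number(resample_size_rates, "resample_size_rates",
                     positive = TRUE)
  stop_if_not_number(resample_size_stress, "resample_size_stress",
                     positive = TRUE)
  if (method == "mean_of_ratios" &&
      resample_size_rates != resample_size_stress)
    stop("'mean_of_ratios' needs equal resample sizes", call. = FALSE)

  n_boot <- as.integer(n_boot)
  kr <- as.integer(resample_size_rates)
  ks <- as.integer(resample_size_stress)
  ratios <- with_seed(seed, {
    r <- matrix(creep_rates[sample.int(length(creep_rates), n_boot * kr,
                                       replace = TRUE)], nrow = n_boot)
    s <- matrix(stresses[sample.int(length(stresses), n_boot * ks,
                                    replace = TRUE)], nrow = n_boot)
    if (method == "ratio_of_means")
      rowMeans(r) / rowMeans(s)
    else
      rowMeans(r / s)
  })
  structure(c(list(mean_ratio = mean(ratios),
                   sd_ratio = if (n_boot > 1) stats::sd(ratios) else 0,
                   n_boot = n_boot,
                   resample_size_rates = kr, resample_size_stress = ks,
                   method = method, seed = as.integer(seed)),
              meta),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  lab <- if (!is.null(x$group))
    sprintf(" [%s, %g mg]", x$group, x$load_mg %||% NA) else ""
  cat(sprintf(
    "Bootstrap creep rate / stress%s: %.4g +/- %.4g %%/h/MPa (%d draws of %d/%d, %s)\n",
    lab, x$mean_ratio, x$sd_ratio, x$n_boot, x$resample_size_rates,
    x$resample_size_stress, x$method))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted \eqn{p}-values controlling the FDR: the ordered raw
#' values are scaled by \eqn{m/i} and monotonised from the largest
#' down.  A thin, named wrapper over [stats::p.adjust()] so every
#' multiple-comparison step in the package goes through one place.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.04, 0.8))
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Bootstrap ratios for every condition cell of an experiment
#'
#' Runs [bootstrap_ratio()] for each (group, load, pH, inactivation)
#' cell, pairing the per-specimen creep rates of the cell with the
#' per-replicate stresses of its group × load.  Child seeds are derived
#' deterministically from `seed`, one per cell.
#'
#' @param rates per-specimen rate table from [creep_rates()].
#' @param masses dry-mass table (see [group_stress_table()]).
#' @param loads_mg,density_g_cm3,g_constant stress-table parameters.
#' @param n_boot,resample_size_rates,resample_size_stress,method
#'   passed to [bootstrap_ratio()].
#' @param seed master seed.
#' @return Data frame with one row per cell: condition labels,
#'   `mean_ratio`, `sd_ratio`, `n_boot`, `seed`.
#' @export
ratio_table <- function(rates, masses, loads_mg = c(400, 500, 600, 700),
                        density_g_cm3 = 1.5, g_constant = 9.80665,
                        n_boot = 10000, resample_size_rates = 4,
                        resample_size_stress = 4,
                        method = "ratio_of_means", seed = 1L) {
  rates <- as.data.frame(rates)
  # per-replicate stresses per group x load
  masses <- as.data.frame(masses)
  if (is.null(masses$segment_length_mm)) masses$segment_length_mm <- 5
  key <- interaction(rates$group, rates$load_mg, rates$ph,
                     rates$inactivated, drop = TRUE, lex.order = TRUE)
  cells <- split(rates, key)
  # child streams are keyed by the condition (load, pH, inactivation),
  # not the group, so identically generated groups stay exactly null
  conds <- unique(rates[c("load_mg", "ph", "inactivated")])
  conds <- conds[order(conds$load_mg, conds$ph, conds$inactivated), ]
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    d <- cells[[i]]
    ci <- which(conds$load_mg == d$load_mg[1] & conds$ph == d$ph[1] &
                  conds$inactivated == d$inactivated[1])
    gm <- masses[masses$group == d$group[1], ]
    if (nrow(gm) < 2L)
      stop("no dry-mass replicates for group ", d$group[1], call. = FALSE)
    areas <- cross_section_area(gm$dry_mass_ug, gm$segment_length_mm[1],
                                density_g_cm3)
    stresses <- wall_stress(load_to_force(d$load_mg[1], g_constant), areas)
    est <- bootstrap_ratio(d$creep_rate, stresses, n_boot = n_boot,
                           resample_size_rates = resample_size_rates,
                           resample_size_stress = resample_size_stress,
                           seed = child_seed(seed, ci), method = method,
                           meta = list(group = d$group[1],
                                       load_mg = d$load_mg[1],
                                       ph = d$ph[1],
                                       inactivated = d$inactivated[1]))
    out[[i]] <- data.frame(group = est$group, load_mg = est$load_mg,
                           ph = est$ph, inactivated = est$inactivated,
                           mean_ratio = est$mean_ratio,
                           sd_ratio = est$sd_ratio, n_boot = est$n_boot,
                           seed = est$seed)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$load_mg, out$ph, out$inactivated), ]
  rownames(out) <- NULL
  out
}

#' Compare bootstrap ratio estimates between groups
#'
#' Two-sample comparison of creep rate \eqn{\times} stress\eqn{^{-1}}
#' estimates: for each requested contrast a Welch \eqn{t}-statistic is
#' computed from the bootstrap means, SDs and replicate counts (the
#' bootstrap distributions are treated as the two samples), and raw
#' two-tailed \eqn{p}-values are adjusted across the whole batch by the
#' Benjamini-Hochberg step-up procedure, controlling the false
#' discovery rate at `alpha`.
#'
#' @param estimates data frame of ratio estimates (from
#'   [ratio_table()]), with columns `group`, `load_mg`, `ph`,
#'   `inactivated`, `mean_ratio`, `sd_ratio`, `n_boot`.
#' @param pairs data frame of contrasts with columns `group_a`,
#'   `group_b`, `load_mg`, `ph`, `inactivated`; default: all pairs of
#'   groups within each matching (load, pH, inactivation) cell.
#' @param alpha FDR level (default 0.05).
#' @param var_method `"welch"` (default) or `"pooled"` degrees of
#'   freedom.
#' @return Data frame of class `"ratio_comparison"`: one row per
#'   contrast with `t_stat`, `df`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
compare_ratio_groups <- function(estimates, pairs = NULL, alpha = 0.05,
                                 var_method = c("welch", "pooled")) {
  var_method <- match.arg(var_method)
  estimates <- as.data.frame(estimates)
  need <- c("group", "load_mg", "ph", "inactivated", "mean_ratio",
            "sd_ratio", "n_boot")
  miss <- setdiff(need, names(estimates))
  if (length(miss))
    stop("estimates table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  stop_if_not_number(alpha, "alpha", positive = TRUE)

  if (is.null(pairs)) {
    cells <- unique(estimates[c("load_mg", "ph", "inactivated")])
    pl <- list()
    for (i in seq_len(nrow(cells))) {
      g <- sort(unique(estimates$group[
        estimates$load_mg == cells$load_mg[i] &
        estimates$ph == cells$ph[i] &
        estimates$inactivated == cells$inactivated[i]]))
      if (length(g) >= 2L)
        for (a in seq_len(length(g) - 1L)) for (b in seq((a + 1L), length(g)))
          pl[[length(pl) + 1L]] <- data.frame(
            group_a = g[a], group_b = g[b], load_mg = cells$load_mg[i],
            ph = cells$ph[i], inactivated = cells$inactivated[i])
    }
    if (!length(pl)) stop("no comparable contrasts found", call. = FALSE)
    pairs <- do.call(rbind, pl)
  }

  pick <- function(g, row) {
    m <- estimates[estimates$group == g &
                   estimates$load_mg == row$load_mg &
                   estimates$ph == row$ph &
                   estimates$inactivated == row$inactivated, ]
    if (nrow(m) != 1L)
      stop("contrast key does not match exactly one estimate: group ", g,
           ", load ", row$load_mg, call. = FALSE)
    m
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    row <- pairs[i, ]
    a <- pick(row$group_a, row)
    b <- pick(row$group_b, row)
    va <- a$sd_ratio^2 / a$n_boot
    vb <- b$sd_ratio^2 / b$n_boot
    if (va + vb == 0) {
      tt <- if (a$mean_ratio == b$mean_ratio) 0 else Inf *
        sign(a$mean_ratio - b$mean_ratio)
      df <- a$n_boot + b$n_boot - 2
    } else {
      tt <- (a$mean_ratio - b$mean_ratio) / sqrt(va + vb)
      df <- if (var_method == "welch")
        (va + vb)^2 / (va^2 / (a$n_boot - 1) + vb^2 / (b$n_boot - 1))
      else a$n_boot + b$n_boot - 2
    }
    p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
    data.frame(group_a = row$group_a, group_b = row$group_b,
               load_mg = row$load_mg, ph = row$ph,
               inactivated = row$inactivated,
               t_stat = tt, df = df, p_raw = p)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- adjust_fdr(res$p_raw)
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  class(res) <- c("ratio_comparison", "data.frame")
  res
}
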
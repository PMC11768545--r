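#' Cell wall cross-section area from segment dry mass
#'
#' For a cylindrical organ segment the wall volume is
#' \eqn{V = l \times A}, so with an assumed wall density \eqn{\rho} the
#' wall cross-section area is \eqn{A = m / (\rho \, l)}.  Units are
#' handled exactly: mass in µg, length in mm and density in
#' g cm\eqn{^{-3}} give area in µm\eqn{^2}.
#'
#' @param mass_ug segment dry mass, µg.
#' @param length_mm segment length, mm (default 5).
#' @param density_g_cm3 assumed wall density, g cm\eqn{^{-3}}
#'   (default 1.5, the standard literature value for plant cell wall
#'   material).
#' @return Cross-section area in µm\eqn{^2}; vectorised over `mass_ug`.
#' @examples
#' cross_section_area(2.30)  # 306.7 um^2
#' @export
cross_section_area <- function(mass_ug, length_mm = 5, density_g_cm3 = 1.5) {
  if (any(!is.finite(mass_ug)) || any(mass_ug <= 0))
    stop("'mass_ug' must be positive and finite", call. = FALSE)
  stop_if_not_number(length_mm, "length_mm", positive = TRUE)
  stop_if_not_number(density_g_cm3, "density_g_cm3", positive = TRUE)
  # ug / (g cm^-3 * mm): 1e-6 g / (rho g cm^-3 * 0.1 l cm) = 1e-5/(rho l) cm^2
  # 1 cm^2 = 1e8 um^2  =>  A[um^2] = 1e3 * m / (rho * l)
  1e3 * mass_ug / (density_g_cm3 * length_mm)
}

#' Tensile force generated by a constant load
#'
#' Converts an applied load (mg) hanging in the gravity field into the
#' tensile force it exerts: \eqn{F = (m/10^6\,\mathrm{kg}) \, g}.
#'
#' @param load_mg load in mg; vectorised.
#' @param g_constant gravitational acceleration, m s\eqn{^{-2}}
#'   (default standard gravity 9.80665).
#' @return Force in newtons.
#' @examples
#' signif(load_to_force(c(400, 500, 600, 700)), 3)
#' @export
load_to_force <- function(load_mg, g_constant = 9.80665) {
  if (any(!is.finite(load_mg)) || any(load_mg <= 0))
    stop("'load_mg' must be positive and finite", call. = FALSE)
  stop_if_not_number(g_constant, "g_constant", positive = TRUE)
  load_mg * 1e-6 * g_constant
}

#' Tensile wall stress from force and cross-section area
#'
#' \eqn{\sigma = F/A} with \eqn{F} in newtons and \eqn{A} in
#' µm\eqn{^2} (\eqn{1\,\mu m^2 = 10^{-12}\,m^2}), returned in MPa.
#'
#' @param force_N tensile force, N; vectorised.
#' @param area_um2 wall cross-section area, µm\eqn{^2}.
#' @return Stress in MPa.
#' @examples
#' wall_stress(load_to_force(400), cross_section_area(2.30))  # ~12.8 MPa
#' @export
wall_stress <- function(force_N, area_um2) {
  if (any(!is.finite(force_N)) || any(force_N <= 0))
    stop("'force_N' must be positive and finite", call. = FALSE)
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop("'area_um2' must be positive and finite", call. = FALSE)
  # Pa = N / (um2 * 1e-12 m2);  MPa = Pa / 1e6
  force_N * 1e6 / area_um2
}

#' Per-group stress table from dry-mass replicates
#'
#' Builds the stress table of a creep experiment: for each group, the
#' dry-mass replicates are converted into cross-section areas and into
#' the tensile stress each load generates.
#'
#' Two averaging modes are provided because replicate-wise averaging of
#' \eqn{F/A} and applying \eqn{F/A} to the mean mass differ (Jensen's
#' inequality: \eqn{1/m} is convex, so the per-replicate mean is at
#' least the mean-mass value):
#' \describe{
#'   \item{`per_replicate` (default)}{stress is computed per mass
#'     replicate and summarised as mean ± SD across replicates;}
#'   \item{`mean_mass`}{stress is computed once from the mean mass
#'     (SD reported as 0).}
#' }
#'
#' @param masses data frame with columns `group`, `replicate`,
#'   `dry_mass_ug` and optionally `segment_length_mm` (default 5);
#'   at least 2 replicates per group.
#' @param loads_mg applied loads, mg.
#' @param density_g_cm3,g_constant physical constants, see
#'   [cross_section_area()] and [load_to_force()].
#' @param mode `"per_replicate"` or `"mean_mass"`.
#' @return Data frame with one row per group × load: `group`,
#'   `load_mg`, `force_N`, `area_mean_um2`, `area_sd_um2`,
#'   `stress_mean`, `stress_sd`, `n` (MPa for stresses).
#' @examples
#' m <- data.frame(group = "ebl", replicate = 1:4, dry_mass_ug = 2.30)
#' group_stress_table(m, loads_mg = c(400, 700))
#' @export
group_stress_table <- function(masses, loads_mg = c(400, 500, 600, 700),
                               density_g_cm3 = 1.5, g_constant = 9.80665,
                               mode = c("per_replicate", "mean_mass")) {
  mode <- match.arg(mode)
  masses <- as.data.frame(masses)
  need <- c("group", "replicate", "dry_mass_ug")
  miss <- setdiff(need, names(masses))
  if (length(miss))
    stop("masses table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(loads_mg) < 1L || any(loads_mg <= 0))
    stop("'loads_mg' must be non-empty and positive", call. = FALSE)
  if (is.null(masses$segment_length_mm)) masses$segment_length_mm <- 5

  out <- lapply(split(masses, masses$group), function(d) {
    if (nrow(d) < 2L)
      stop("need >= 2 dry-mass replicates per group (group ", d$group[1],
           ")", call. = FALSE)
    areas <- cross_section_area(d$dry_mass_ug, d$segment_length_mm[1],
                                density_g_cm3)
    force <- load_to_force(loads_mg, g_constant)
    if (mode == "per_replicate") {
      per <- outer(force, areas, wall_stress)  # loads x replicates
      s_mean <- rowMeans(per)
      s_sd <- apply(per, 1, stats::sd)
    } else {
      s_mean <- wall_stress(force,
                            cross_section_area(mean(d$dry_mass_ug),
                                               d$segment_length_mm[1],
                                               density_g_cm3))
      s_sd <- rep(0, length(force))
    }
    data.frame(group = d$group[1], load_mg = loads_mg, force_N = force,
               area_mean_um2 = mean(areas), area_sd_um2 = stats::sd(areas),
               stress_mean = s_mean, stress_sd = s_sd, n = nrow(d))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$load_mg), ]
  rownames(out) <- NULL
  out
}
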
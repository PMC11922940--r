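#' Configuration of a synthetic drought-recovery experiment
#'
#' Bundles the design of a three-treatment greenhouse drought experiment
#' (control, short drought, long drought) with the ground-truth physiological
#' parameters the generator plants: water-potential trajectories, the
#' dendrometric coupling between water potential and stem shrinkage, the
#' xylem vulnerability curve, and the linear map from stress dose to
#' post-drought recovery.
#'
#' @param n_trees Named integer vector: trees per treatment.
#' @param day_range Integer day-of-year interval covered by the simulation.
#' @param drought_windows Named list per drought treatment of
#'   `c(start_day, rewater_day)`; drought runs from `start_day` to
#'   `rewater_day - 1`, re-watering starts on `rewater_day`.
#' @param psi_baseline Well-watered midday water potential (MPa).
#' @param psi_floor Named vector of the most negative target water potential
#'   per treatment (MPa), reached on the last drought day.
#' @param psi_recovery Named vector of post-rewatering asymptotes (MPa);
#'   drought trees level off below the control baseline.
#' @param psi_relax_tau E-folding time (days) of post-rewatering relaxation.
#' @param psi_shape_knots Named list per treatment of a two-column matrix
#'   `(frac_time, frac_decline)` describing the normalised decline shape on
#'   the drought window (piecewise linear; fraction of window elapsed vs
#'   fraction of the baseline-to-floor drop). The long-drought default
#'   encodes the moderate initial decline, the mid-drought watering bump and
#'   the final intense episode.
#' @param psi_split Named list: for treatments whose mid-drought course is
#'   actively managed by the watering protocol, the fraction of the decline
#'   shape up to which all trees follow the nominal trajectory; tree-level
#'   floor and shape variation act only beyond it (the final intense
#'   episode). Treatments without an entry scale the whole decline.
#' @param psi_every Water-potential sampling cadence in days (the daily truth
#'   is thinned to this cadence; the last drought day is always sampled).
#' @param twd_psi_slope Stem shrinkage per unit water-potential deficit
#'   (mm MPa^-1).
#' @param d0 Initial stem diameter (mm).
#' @param growth_rate Stem growth rate under well-watered conditions
#'   (mm day^-1); growth pauses whenever a water-potential deficit exists.
#' @param dendro_cadence_min,chamber_cadence_min Sampling cadence of the
#'   dendrometer and chamber streams (minutes).
#' @param chamber_days Day range over which the chamber system runs.
#' @param mdot Chamber air mass flow (mol s^-1), about 14 L min^-1.
#' @param w_supply Water vapor content of supply air (mmol mol^-1).
#' @param pressure_kpa Atmospheric pressure (kPa).
#' @param t_day,t_night Daytime peak and nighttime chamber temperature (degC).
#' @param daytime Decimal hours `(start, end)` of the photoperiod.
#' @param gmax Maximum canopy conductance per tree (mmol tree^-1 s^-1).
#' @param closure_center,closure_width Midpoint (MPa) and width (MPa) of the
#'   logistic stomatal-closure response to water potential; the default
#'   centers closure near the embolism-onset pressure P12, matching
#'   isohydric behaviour.
#' @param recovery_ramp_days Days after re-watering over which the imposed
#'   conductance ramps linearly onto its recovery plateau.
#' @param vc_scale_b,vc_shape_c Ground-truth Weibull vulnerability parameters
#'   (scale in MPa, dimensionless shape). The defaults place P12 at
#'   -2.56 MPa and P50 at -3.85 MPa.
#' @param vc_pressures Xylem pressures (MPa) at which PLC is measured.
#' @param n_vc_samples Number of vulnerability-curve sample replicates.
#' @param recovery_slope,recovery_intercept Ground-truth linear map from
#'   TWD_P12 (mm) to the recovery fraction of canopy conductance (clipped to
#'   `[0, 1]`).
#' @param pla_base,pla_slope Ground-truth affine map from TWD_P12 to percent
#'   loss of conductive area.
#' @param shed_base,shed_slope Ground-truth affine map from TWD_P12 to the
#'   needle-shed fraction.
#' @param total_needle_g Total needle dry biomass per tree (g DW).
#' @param specific_needle_area Specific needle area (cm^2 g^-1 DW).
#' @param area_needle Named vector of remaining needle area per treatment
#'   (m^2), used to normalise leaf-level fluxes.
#' @param empty_chamber_offset Mean concentration differential of the empty
#'   reference chamber (mmol mol^-1).
#' @param noise_sd Named list of noise magnitudes; see Details. Use
#'   `noise_sd = "none"` for a fully deterministic experiment.
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   output.
#'
#' @details `noise_sd` components (all Gaussian, additive unless noted):
#' `psi_obs` (MPa, observation noise on sampled water potential), `psi_floor`
#' (MPa, tree-level spread of the drought floor; kept small because the
#' watering protocol aims at similar peak water potentials), `psi_shape`
#' (log-scale SD of a tree-level exponent applied to the decline shape),
#' `onset` (days; tree-level shift of the drought time axis, decorrelating
#' stress duration and dose from peak intensity), `dendro` (mm), `chamber` (mmol mol^-1 on
#' measured vapor contents), `gmax_rel` and `area_rel` (relative, tree
#' level), `rec` (on the realised recovery fraction), `vc` (PLC percent),
#' `pla` (percent, organ level), `biomass_rel` (relative), `d0` (mm).
#' Defaults mirror the between-tree standard errors a greenhouse experiment
#' of this size reports.
#'
#' @return An object of class `experiment_config` (a validated list).
#' @export
experiment_config <- function(
    n_trees = c(control = 4, short = 5, long = 9),
    day_range = c(180, 245),
    drought_windows = list(short = c(216, 233), long = c(184, 233)),
    psi_baseline = -0.8,
    psi_floor = c(control = -0.8, short = -3.22, long = -4.10),
    psi_recovery = c(control = -0.8, short = -1.15, long = -1.26),
    psi_relax_tau = 2,
    psi_shape_knots = NULL,
    psi_split = list(long = 0.35),
    psi_every = 2,
    twd_psi_slope = 0.44,
    d0 = 15,
    growth_rate = 0.02,
    dendro_cadence_min = 30,
    chamber_cadence_min = 30,
    chamber_days = c(210, 244),
    mdot = 0.0095,
    w_supply = 8.3,
    pressure_kpa = 101.325,
    t_day = 25, t_night = 22,
    daytime = c(6, 19),
    gmax = 0.95,
    closure_center = -2.3,
    closure_width = 0.35,
    recovery_ramp_days = 3,
    vc_scale_b = 4.206135,
    vc_shape_c = 4.142749,
    vc_pressures = -seq(0.5, 6.5, by = 0.75),
    n_vc_samples = 6,
    recovery_slope = -0.047134,
    recovery_intercept = 0.837164,
    pla_base = 2.9,
    pla_slope = 4.8983,
    shed_base = 0.048,
    shed_slope = 0.02867,
    total_needle_g = 24,
    specific_needle_area = 39.5,
    area_needle = c(control = 0.102, short = 0.094, long = 0.072),
    empty_chamber_offset = 0.03,
    noise_sd = NULL,
    seed = 1L) {
  default_noise <- list(
    psi_obs = 0.10, psi_floor = 0.20, psi_shape = 0.08, onset = 1.5,
    dendro = 0.005, chamber = 0.07, gmax_rel = 0.05, area_rel = 0.08,
    rec = 0.05, vc = 5, pla = 15, biomass_rel = 0.10, d0 = 0.5
  )
  if (is.null(noise_sd)) {
    noise_sd <- default_noise
  } else if (identical(noise_sd, "none")) {
    noise_sd <- lapply(default_noise, function(x) 0)
  } else {
    noise_sd <- utils::modifyList(default_noise, as.list(noise_sd))
  }
  if (is.null(psi_shape_knots)) {
    psi_shape_knots <- list(
      short = cbind(frac_time = c(0, 10, 16) / 16,
                    frac_decline = c(0, 0.53, 1)),
      long = cbind(
        frac_time = c(0, 10, 26, 30, 40, 42, 44, 48) / 48,
        frac_decline = c(0, 0.13636, 0.42, 0.33, 0.35, 0.5944, 0.95, 1)
      )
    )
  }

  cfg <- list(
    n_trees = n_trees, day_range = day_range,
    drought_windows = drought_windows,
    psi_baseline = psi_baseline, psi_floor = psi_floor,
    psi_recovery = psi_recovery, psi_relax_tau = psi_relax_tau,
    psi_shape_knots = psi_shape_knots, psi_split = psi_split,
    psi_every = psi_every,
    twd_psi_slope = twd_psi_slope, d0 = d0, growth_rate = growth_rate,
    dendro_cadence_min = dendro_cadence_min,
    chamber_cadence_min = chamber_cadence_min, chamber_days = chamber_days,
    mdot = mdot, w_supply = w_supply, pressure_kpa = pressure_kpa,
    t_day = t_day, t_night = t_night, daytime = daytime,
    gmax = gmax, closure_center = closure_center,
    closure_width = closure_width,
    recovery_ramp_days = recovery_ramp_days,
    vc_scale_b = vc_scale_b, vc_shape_c = vc_shape_c,
    vc_pressures = vc_pressures, n_vc_samples = n_vc_samples,
    recovery_slope = recovery_slope,
    recovery_intercept = recovery_intercept,
    pla_base = pla_base, pla_slope = pla_slope,
    shed_base = shed_base, shed_slope = shed_slope,
    total_needle_g = total_needle_g,
    specific_needle_area = specific_needle_area,
    area_needle = area_needle,
    empty_chamber_offset = empty_chamber_offset,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  stopifnot(all(cfg$n_trees >= 1), length(cfg$day_range) == 2,
            cfg$day_range[1] < cfg$day_range[2])
  for (tr in names(cfg$drought_windows)) {
    w <- cfg$drought_windows[[tr]]
    if (w[2] <= w[1]) {
      rlang::abort("rewater_day must exceed start_day.")
    }
    if (w[1] < cfg$day_range[1] || w[2] > cfg$day_range[2]) {
      rlang::abort("drought window outside `day_range`.")
    }
  }
  if (cfg$vc_scale_b <= 0 || cfg$vc_shape_c <= 0) {
    rlang::abort("Weibull parameters must be positive.")
  }
  if (any(unlist(cfg$noise_sd) < 0)) {
    rlang::abort("noise standard deviations must be >= 0.")
  }
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Synthetic drought-recovery experiment\n")
  cat("  trees:", paste(names(x$n_trees), x$n_trees, sep = "=",
                        collapse = ", "), "\n")
  for (tr in names(x$drought_windows)) {
    w <- x$drought_windows[[tr]]
    cat(sprintf("  %s drought: DOY %d-%d (rewatered %d), floor %.2f MPa\n",
                tr, w[1], w[2] - 1, w[2], x$psi_floor[[tr]]))
  }
  cat(sprintf("  VC truth: b = %.3f MPa, c = %.3f (P12 %.2f, P50 %.2f)\n",
              x$vc_scale_b, x$vc_shape_c,
              weibull_px(12, x$vc_scale_b, x$vc_shape_c),
              weibull_px(50, x$vc_scale_b, x$vc_shape_c)))
  cat(sprintf("  recovery truth: fraction = %.3f %+.4f x TWD_P12\n",
              x$recovery_intercept, x$recovery_slope))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
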
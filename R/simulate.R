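trunc_norm <- function(n, sd, k) {
  pmin(pmax(stats::rnorm(n, 0, sd), -k * sd), k * sd)
}

doy_time <- function(day, minute_of_day = 0) {
  as.POSIXct("2021-01-01", tz = "UTC") + (day - 1) * 86400 +
    minute_of_day * 60
}

#' Per-tree latent parameters of a synthetic experiment
#'
#' Draws the tree-level ground truth (water-potential floor, decline-shape
#' exponent, maximum conductance, needle area, initial diameter) for every
#' tree in the design. All streams of one experiment share this table so the
#' planted truth is consistent across them.
#'
#' @param config An [experiment_config()].
#' @param seed Seed for the tree-level draws (default `config$seed`).
#' @return A tibble with one row per tree: `tree_id`, `treatment`,
#'   `psi_floor`, `shape_gamma`, `gmax`, `area_needle`, `d0`,
#'   `total_needle_g`.
#' @export
simulate_trees <- function(config, seed = config$seed) {
  set.seed(seed)
  ns <- config$noise_sd
  trt <- rep(names(config$n_trees), config$n_trees)
  n <- length(trt)
  is_ctrl <- trt == "control"
  # jitters truncated at +/-2 sd: the watering protocol intervenes on
  # trees that decline too fast, so extreme floors/timings do not occur
  floor_jit <- trunc_norm(n, ns$psi_floor, 2)
  floor_jit[is_ctrl] <- 0
  gamma <- exp(stats::rnorm(n, 0, ns$psi_shape))
  gamma[is_ctrl] <- 1
  # timing jitter scales with the treatment's drought duration
  wlen <- vapply(trt, function(tr) {
    w <- config$drought_windows[[tr]]
    if (is.null(w)) 0 else diff(w)
  }, numeric(1))
  # Onset differences follow the watering schedule, so they come in whole
  # steps of the sampling cadence; this also keeps every trajectory kink on
  # the water-potential sampling grid.
  onset <- trunc_norm(n, ns$onset, 2) * wlen / max(wlen, 1)
  onset <- round(onset / config$psi_every) * config$psi_every
  onset[is_ctrl] <- 0
  tibble::tibble(
    tree_id = sprintf("%s_%02d", trt, stats::ave(seq_len(n), trt,
                                                 FUN = seq_along)),
    treatment = trt,
    psi_floor = pmin(unname(config$psi_floor[trt]) + floor_jit,
                     config$psi_baseline),
    shape_gamma = gamma,
    onset_shift = onset,
    gmax = config$gmax * exp(stats::rnorm(n, 0, ns$gmax_rel)),
    area_needle = unname(config$area_needle[trt]) *
      exp(stats::rnorm(n, 0, ns$area_rel)),
    d0 = config$d0 + stats::rnorm(n, 0, ns$d0),
    total_needle_g = config$total_needle_g *
      exp(stats::rnorm(n, 0, ns$biomass_rel))
  )
}

psi_shape <- function(day, window, knots) {
  # normalised decline fraction (0..1) over the drought window
  span <- diff(window)
  frac <- (day - window[1]) / span
  stats::approx(knots[, 1], knots[, 2], xout = pmin(pmax(frac, 0), 1),
                method = "linear", rule = 2)$y
}

psi_truth_tree <- function(day, treatment, psi_floor, shape_gamma, config,
                           onset_shift = 0) {
  base <- config$psi_baseline
  if (treatment == "control" || psi_floor >= base) {
    return(rep(base, length(day)))
  }
  w <- config$drought_windows[[treatment]]
  start <- w[1]; rewater <- w[2]
  knots <- config$psi_shape_knots[[treatment]]
  split <- config$psi_split[[treatment]]
  psi <- rep(base, length(day))
  in_drought <- day >= start & day < rewater
  s <- psi_shape(day[in_drought] - onset_shift, c(start, rewater - 1),
                 knots)
  if (is.null(split)) {
    psi[in_drought] <- base + (psi_floor - base) * s^shape_gamma
  } else {
    # managed mid-drought course at the nominal depth (the watering
    # protocol holds all trees on a common moderate trajectory); the
    # tree-specific floor is expressed only in the final intense episode
    d_nom <- unname(config$psi_floor[[treatment]]) - base
    mid_end <- base + d_nom * split
    sf <- pmax(0, (s - split) / (1 - split))
    psi[in_drought] <- ifelse(
      s <= split,
      base + d_nom * s,
      mid_end + (psi_floor - mid_end) * sf^shape_gamma
    )
  }
  post <- day >= rewater
  off <- config$psi_recovery[[treatment]]
  psi[post] <- off + (psi_floor - off) *
    exp(-(day[post] - (rewater - 1)) / config$psi_relax_tau)
  psi
}

#' Daily ground-truth water-potential trajectories
#'
#' Builds the per-tree daily midday water potential truth: control trees sit
#' at the baseline; drought trees decline piecewise-linearly (with the
#' configured mid-drought watering bump) to their floor on the last drought
#' day, then relax exponentially toward a persistent offset below the
#' control baseline.
#'
#' @inheritParams simulate_trees
#' @param trees Output of [simulate_trees()].
#' @return A tibble `tree_id`, `treatment`, `day`, `psi` (MPa) covering
#'   every day of `config$day_range`.
#' @export
simulate_psi_truth <- function(config, trees = simulate_trees(config)) {
  days <- seq(config$day_range[1], config$day_range[2])
  trees |>
    dplyr::select("tree_id", "treatment", "psi_floor", "shape_gamma",
                  "onset_shift") |>
    dplyr::rowwise() |>
    dplyr::reframe(
      tree_id = .data$tree_id, treatment = .data$treatment, day = days,
      psi = psi_truth_tree(days, .data$treatment, .data$psi_floor,
                           .data$shape_gamma, config, .data$onset_shift)
    )
}

#' Sampled water-potential observations
#'
#' Thins the daily truth to the measurement cadence (every
#' `config$psi_every` days; the last drought day of each treatment and the
#' final day are always sampled, as the campaign measures right before
#' re-watering) and adds observation noise.
#'
#' @inheritParams simulate_psi_truth
#' @param psi_truth Output of [simulate_psi_truth()].
#' @param seed Seed for observation noise.
#' @return A tibble `tree_id`, `treatment`, `day`, `psi_md` (MPa).
#' @export
simulate_psi_obs <- function(config, psi_truth, seed = config$seed + 1L) {
  set.seed(seed)
  days <- seq(config$day_range[1], config$day_range[2])
  keep <- days[(days - config$day_range[1]) %% config$psi_every == 0]
  keep <- sort(unique(c(
    keep,
    vapply(config$drought_windows, function(w) w[2] - 1L, numeric(1)),
    config$day_range[2]
  )))
  obs <- psi_truth |>
    dplyr::filter(.data$day %in% keep) |>
    dplyr::mutate(
      psi_md = .data$psi +
        stats::rnorm(dplyr::n(), 0, config$noise_sd$psi_obs),
      # soil water content emitted for completeness; no metric consumes it
      swc = pmax(2.5, 28 + 9 * (.data$psi + 0.8))
    ) |>
    dplyr::select("tree_id", "treatment", "day", "psi_md", "swc")
  obs
}

#' Dendrometer stream
#'
#' Stem diameter at the dendrometer cadence: a baseline growth ramp that
#' pauses whenever the tree carries a water-potential deficit, minus the
#' shrinkage `twd_psi_slope * max(0, psi_baseline - psi)`, plus sensor
#' noise. Because growth pauses exactly while a deficit exists, the
#' zero-growth partition of a noiseless trace recovers the planted daily
#' TWD to numerical precision.
#'
#' @inheritParams simulate_psi_obs
#' @param trees Output of [simulate_trees()].
#' @param inject_jumps Optional tibble `tree_id`, `day`, `size` (mm) of
#'   artificial step artifacts (sensor reseats) applied from the first
#'   record of `day` onward; used to exercise [clean_dendro()].
#' @return A tibble `tree_id`, `timestamp`, `d` (mm).
#' @export
simulate_dendro <- function(config, psi_truth, trees = NULL,
                            seed = config$seed + 2L,
                            inject_jumps = NULL) {
  if (is.null(trees)) trees <- simulate_trees(config)
  set.seed(seed)
  mins <- seq(0, 24 * 60 - config$dendro_cadence_min,
              by = config$dendro_cadence_min)
  days <- seq(config$day_range[1], config$day_range[2])
  slope <- config$twd_psi_slope

  out <- purrr::map_dfr(seq_len(nrow(trees)), function(i) {
    tr <- trees[i, ]
    psi_d <- psi_truth$psi[psi_truth$tree_id == tr$tree_id]
    deficit <- pmax(0, config$psi_baseline - psi_d)
    # day-step growth; an increment is laid down only between two
    # deficit-free days, so growth pauses over the whole stress episode and
    # the running maximum of the records equals the current growth level
    free <- deficit == 0
    inc <- config$growth_rate * c(0, free[-length(free)] & free[-1])
    growth_level <- cumsum(inc)
    grid <- tidyr::expand_grid(day = days, minute = mins)
    di <- match(grid$day, days)
    d <- tr$d0 + growth_level[di] - slope * deficit[di]
    if (any(d <= 0)) {
      rlang::abort("negative stem diameter generated; check `d0` and `twd_psi_slope`.")
    }
    tibble::tibble(
      tree_id = tr$tree_id,
      timestamp = doy_time(grid$day, grid$minute),
      d = d + stats::rnorm(length(d), 0, config$noise_sd$dendro)
    )
  })
  if (!is.null(inject_jumps)) {
    for (k in seq_len(nrow(inject_jumps))) {
      sel <- out$tree_id == inject_jumps$tree_id[k] &
        out$timestamp >= doy_time(inject_jumps$day[k])
      out$d[sel] <- out$d[sel] + inject_jumps$size[k]
    }
  }
  out
}

#' Invert canopy conductance to a sample-air vapor content
#'
#' Solves the conductance and mass-balance relations for the chamber
#' sample-air water vapor content `w_sample` that realises a target canopy
#' conductance under given flow and supply conditions (the generator's
#' forward model; [compute_fluxes()] is its inverse).
#'
#' @param g_c Target canopy conductance (mmol tree^-1 s^-1), >= 0.
#' @param mdot Air mass flow (mol s^-1).
#' @param w_supply Supply-air vapor content (mmol mol^-1).
#' @param w_needle Saturated vapor content at needle temperature
#'   (mmol mol^-1).
#' @return `w_sample` in mmol mol^-1, in `[w_supply, w_needle)`.
#' @export
invert_conductance <- function(g_c, mdot, w_supply, w_needle) {
  a <- 1000 * mdot
  A <- g_c + a / 2
  B <- -(g_c * (1000 + w_needle) +
           a * (1000 - w_needle / 2 + w_supply / 2))
  C <- 1000 * g_c * w_needle + a * w_supply * (1000 - w_needle / 2)
  disc <- B^2 - 4 * A * C
  if (any(disc < 0)) rlang::abort("no real solution for `w_sample`.")
  r1 <- (-B - sqrt(disc)) / (2 * A)
  r2 <- (-B + sqrt(disc)) / (2 * A)
  ws <- ifelse(r1 >= w_supply - 1e-9 & r1 < w_needle, r1, r2)
  bad <- !(ws >= w_supply - 1e-9 & ws < w_needle)
  if (any(bad)) {
    rlang::abort("target conductance infeasible: `w_sample` would reach saturation at chamber temperature.")
  }
  ws
}

stomatal_closure <- function(psi, center, width) {
  1 / (1 + exp(-(psi - center) / width))
}

#' Chamber gas-exchange stream
#'
#' Generates timestamped chamber records at the chamber cadence. The imposed
#' canopy conductance follows a diurnal course scaled by a logistic
#' stomatal-closure response to the daily water potential; after re-watering
#' it ramps onto a plateau at the tree's recovery fraction of the control
#' level. The sample-air vapor content is obtained by inverting the
#' conductance and mass-balance relations, so running [compute_fluxes()] on
#' a noiseless stream returns the imposed fluxes to numerical precision.
#' An empty reference chamber (id `"empty"`) carries the common-mode
#' concentration offset.
#'
#' @inheritParams simulate_dendro
#' @param recovery Tibble `tree_id`, `rec_frac` of realised recovery
#'   fractions (from [simulate_damage()]); control trees default to 1.
#' @return A tibble with `timestamp`, `chamber_id`, `treatment`, `t_air`,
#'   `p`, `mdot`, `w_supply`, `w_sample`, `par`, `area_needle` and the
#'   imposed truth columns `g_true` (mmol s^-1) and `e_true` (mol s^-1).
#' @export
simulate_chamber <- function(config, psi_truth, trees = NULL,
                             recovery = NULL, seed = config$seed + 3L) {
  if (is.null(trees)) trees <- simulate_trees(config)
  set.seed(seed)
  ns <- config$noise_sd
  mins <- seq(0, 24 * 60 - config$chamber_cadence_min,
              by = config$chamber_cadence_min)
  days <- seq(config$chamber_days[1], config$chamber_days[2])
  grid <- tidyr::expand_grid(day = days, minute = mins)
  hr <- grid$minute / 60
  dlen <- config$daytime[2] - config$daytime[1]
  diurnal <- ifelse(hr >= config$daytime[1] & hr < config$daytime[2],
                    sin(pi * (hr - config$daytime[1]) / dlen), 0)
  t_air <- config$t_night + (config$t_day - config$t_night) * diurnal
  w_needle <- needle_vapor_content(t_air, config$pressure_kpa)
  drift <- config$empty_chamber_offset +
    stats::rnorm(nrow(grid), 0, ns$chamber)

  rec_lookup <- function(id) {
    if (is.null(recovery)) return(1)
    r <- recovery$rec_frac[recovery$tree_id == id]
    if (length(r) == 0) 1 else r
  }
  rewaters <- vapply(config$drought_windows, function(w) w[2], numeric(1))
  closure0 <- stomatal_closure(config$psi_baseline, config$closure_center,
                               config$closure_width)

  out <- purrr::map_dfr(seq_len(nrow(trees)), function(i) {
    tr <- trees[i, ]
    psi_d <- psi_truth$psi[psi_truth$tree_id == tr$tree_id]
    psi_days <- psi_truth$day[psi_truth$tree_id == tr$tree_id]
    psi <- psi_d[match(grid$day, psi_days)]
    rewater <- if (tr$treatment %in% names(rewaters)) {
      rewaters[[tr$treatment]]
    } else Inf
    ramp <- pmin(1, pmax(0, (grid$day - rewater + 1) /
                           config$recovery_ramp_days))
    scale <- ifelse(grid$day < rewater,
                    stomatal_closure(psi, config$closure_center,
                                     config$closure_width),
                    ramp * rec_lookup(tr$tree_id) * closure0)
    g_true <- tr$gmax * scale * diurnal
    ws_true <- invert_conductance(g_true, config$mdot, config$w_supply,
                                  w_needle)
    e_true <- canopy_transpiration(config$mdot, ws_true, config$w_supply)
    tibble::tibble(
      timestamp = doy_time(grid$day, grid$minute),
      chamber_id = tr$tree_id,
      treatment = tr$treatment,
      t_air = t_air,
      p = config$pressure_kpa,
      mdot = config$mdot,
      w_supply = config$w_supply,
      w_sample = ws_true + drift +
        stats::rnorm(nrow(grid), 0, ns$chamber),
      par = round(1200 * diurnal),
      area_needle = tr$area_needle,
      g_true = g_true,
      e_true = e_true
    )
  })
  empty <- tibble::tibble(
    timestamp = doy_time(grid$day, grid$minute),
    chamber_id = "empty",
    treatment = "empty",
    t_air = t_air,
    p = config$pressure_kpa,
    mdot = config$mdot,
    w_supply = config$w_supply,
    w_sample = config$w_supply + drift,
    par = round(1200 * diurnal),
    area_needle = NA_real_,
    g_true = 0,
    e_true = 0
  )
  dplyr::bind_rows(out, empty)
}

#' Vulnerability-curve measurements
#'
#' PLC observations on sample replicates from the ground-truth Weibull
#' curve plus measurement noise.
#'
#' @inheritParams simulate_trees
#' @param seed Seed for the PLC noise.
#' @return A tibble `sample_id`, `p` (MPa), `plc` (percent).
#' @export
simulate_vc <- function(config, seed = config$seed + 4L) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    sample_id = sprintf("S%02d", seq_len(config$n_vc_samples)),
    p = config$vc_pressures
  )
  grid$plc <- weibull_plc(grid$p, config$vc_scale_b, config$vc_shape_c) +
    stats::rnorm(nrow(grid), 0, config$noise_sd$vc)
  grid
}

#' Ground-truth stress metrics per tree
#'
#' Computes the planted values of the four stress metrics directly from the
#' daily truth trajectories, using the same rules as the estimation pipeline
#' (drought window `start..rewater-1`; strict threshold; negative-only
#' differences against the control baseline).
#'
#' @inheritParams simulate_psi_obs
#' @param trees Output of [simulate_trees()].
#' @return Tibble `tree_id`, `treatment`, `psi_min`, `dp12`, `twd_p12`,
#'   `psi_cum` (true values).
#' @export
truth_metrics <- function(config, psi_truth, trees = NULL) {
  if (is.null(trees)) trees <- simulate_trees(config)
  p12 <- weibull_px(12, config$vc_scale_b, config$vc_shape_c)
  all_windows <- lapply(config$drought_windows,
                        function(w) c(w[1], w[2] - 1L))
  fallback <- range(unlist(all_windows))
  purrr::map_dfr(seq_len(nrow(trees)), function(i) {
    tr <- trees[i, ]
    df <- psi_truth[psi_truth$tree_id == tr$tree_id, ]
    win <- all_windows[[tr$treatment]]
    if (is.null(win)) win <- fallback
    sub <- df[df$day >= win[1] & df$day <= win[2], ]
    below <- sub$day[sub$psi < p12]
    deficit <- pmax(0, config$psi_baseline - sub$psi)
    tibble::tibble(
      tree_id = tr$tree_id, treatment = tr$treatment,
      psi_min = min(sub$psi),
      dp12 = length(below),
      twd_p12 = config$twd_psi_slope *
        sum(deficit[sub$day %in% below]),
      psi_cum = sum(pmin(sub$psi - config$psi_baseline, 0))
    )
  })
}

#' Damage records and recovery fractions
#'
#' Per-tree hydraulic damage (organ-level embolised areas), needle loss and
#' the realised post-drought recovery fraction of canopy conductance. The
#' planted recovery fraction is the configured linear function of the true
#' TWD_P12, clipped to `[0, 1]`; PLA and the needle-shed fraction are
#' monotone non-decreasing in the dose.
#'
#' @inheritParams simulate_trees
#' @param truth Output of [truth_metrics()].
#' @param trees Output of [simulate_trees()].
#' @param seed Seed for damage noise.
#' @return A list with `damage` (organ-level rows `tree_id`, `treatment`,
#'   `organ`, `a_native`, `a_ref` plus per-tree needle columns `retained_g`,
#'   `shed_g`, `specific_needle_area`) and `recovery` (`tree_id`,
#'   `rec_frac_true`, `rec_frac`: planted and realised recovery fractions).
#' @export
simulate_damage <- function(config, truth, trees = NULL,
                            seed = config$seed + 5L) {
  if (is.null(trees)) trees <- simulate_trees(config)
  set.seed(seed)
  ns <- config$noise_sd
  organs <- c("apical_shoot", "stem", "root")

  per_tree <- truth |>
    dplyr::mutate(
      rec_frac_true = pmin(pmax(config$recovery_intercept +
                                  config$recovery_slope * .data$twd_p12,
                                0), 1),
      # realised recovery can exceed the control mean, so only the
      # physical lower bound applies to the noisy realisation
      rec_frac = pmax(.data$rec_frac_true +
                        stats::rnorm(dplyr::n(), 0, ns$rec), 0),
      pla_true = pmin(pmax(config$pla_base +
                             config$pla_slope * .data$twd_p12, 0), 100),
      shed_frac_true = pmin(pmax(config$shed_base +
                                   config$shed_slope * .data$twd_p12,
                                 0), 1)
    ) |>
    dplyr::left_join(trees[, c("tree_id", "total_needle_g")],
                     by = "tree_id") |>
    dplyr::mutate(
      shed_g = .data$total_needle_g * .data$shed_frac_true,
      retained_g = .data$total_needle_g - .data$shed_g,
      specific_needle_area = config$specific_needle_area
    )

  damage <- per_tree |>
    dplyr::select("tree_id", "treatment", "pla_true", "retained_g",
                  "shed_g", "specific_needle_area") |>
    tidyr::expand_grid(organ = organs) |>
    dplyr::mutate(
      a_ref = 30 * exp(stats::rnorm(dplyr::n(), 0, 0.1)),
      pla_organ = pmin(pmax(.data$pla_true +
                              stats::rnorm(dplyr::n(), 0, ns$pla), 0), 100),
      a_native = .data$pla_organ / 100 * .data$a_ref
    ) |>
    dplyr::select("tree_id", "treatment", "organ", "a_native", "a_ref",
                  "retained_g", "shed_g", "specific_needle_area")

  list(
    damage = damage,
    recovery = per_tree[, c("tree_id", "treatment", "rec_frac_true",
                            "rec_frac", "pla_true", "shed_frac_true")]
  )
}

#' Simulate a complete drought-recovery experiment
#'
#' Runs every generator in sequence and returns all five input streams the
#' estimation pipeline consumes, plus the ground-truth table. Identical
#' `(config, seed)` give identical output.
#'
#' @inheritParams simulate_trees
#' @return A list of class `synthetic_experiment`: `chamber`, `dendro`,
#'   `psi` (sampled observations), `vc`, `damage`, `truth` (per-tree planted
#'   values incl. stress metrics and recovery fractions), `psi_truth`
#'   (daily truth) and `config`.
#' @export
simulate_experiment <- function(config = experiment_config(),
                                seed = config$seed) {
  config$seed <- as.integer(seed)
  trees <- simulate_trees(config)
  psi_truth <- simulate_psi_truth(config, trees)
  tm <- truth_metrics(config, psi_truth, trees)
  dmg <- simulate_damage(config, tm, trees)
  truth <- trees |>
    dplyr::left_join(tm[, setdiff(names(tm), "treatment")],
                     by = "tree_id") |>
    dplyr::left_join(dmg$recovery[, setdiff(names(dmg$recovery),
                                            "treatment")],
                     by = "tree_id")
  structure(
    list(
      chamber = simulate_chamber(config, psi_truth, trees,
                                 recovery = dmg$recovery),
      dendro = simulate_dendro(config, psi_truth, trees),
      psi = simulate_psi_obs(config, psi_truth),
      vc = simulate_vc(config),
      damage = dmg$damage,
      truth = truth,
      psi_truth = psi_truth,
      config = config
    ),
    class = "synthetic_experiment"
  )
}

#' Write the streams of a synthetic experiment to CSV
#'
#' @param experiment Output of [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (chamber, dendrometer, psi, vc,
#'   damage, truth).
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  streams <- c(chamber = "chamber", dendro = "dendrometer", psi = "psi",
               vc = "vc", damage = "damage", truth = "truth")
  paths <- character(0)
  for (nm in names(streams)) {
    path <- file.path(dir, paste0(streams[[nm]], ".csv"))
    utils::write.csv(experiment[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
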
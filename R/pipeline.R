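#' Summarise organ-level damage records per tree
#'
#' Organ-mean percent loss of conductive area and needle accounting, one row
#' per tree. Organs are averaged within tree first.
#'
#' @param damage Organ-level damage tibble (`tree_id`, `organ`, `a_native`,
#'   `a_ref`, and per-tree `retained_g`, `shed_g`, `specific_needle_area`).
#' @return A tibble `tree_id`, `pla_mean` (%), `needle_loss_pct`,
#'   `needle_area_m2`.
#' @export
damage_summary <- function(damage) {
  organ <- damage |>
    dplyr::mutate(pla = pla(.data$a_native, .data$a_ref)) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(pla_mean = mean(.data$pla), .groups = "drop")
  needles <- damage |>
    dplyr::distinct(.data$tree_id, .data$retained_g, .data$shed_g,
                    .data$specific_needle_area)
  acct <- needle_accounting(needles$retained_g, needles$shed_g,
                            needles$specific_needle_area)
  dplyr::left_join(
    organ,
    dplyr::bind_cols(needles["tree_id"], acct[, c("needle_loss_pct",
                                                  "needle_area_m2")]),
    by = "tree_id"
  )
}

#' Run the full stress-dose and recovery analysis
#'
#' End-to-end estimation pipeline on the five input streams: fits the
#' vulnerability curve (unless `p12` is supplied), computes QC-filtered
#' chamber fluxes, partitions the dendrometer traces, assembles the
#' per-tree stress-dose table, derives recovery indices, and regresses each
#' recovery index on each stress metric.
#'
#' @param streams A list with `chamber`, `dendro`, `psi`, `vc`, `damage`
#'   tibbles (see [simulate_experiment()] for the column contracts) and
#'   optionally `config`; or a `synthetic_experiment`.
#' @param p12 Embolism-onset threshold (MPa). Default: fitted from
#'   `streams$vc`.
#' @param windows Named list of dose windows `c(first_day, last_day)` per
#'   drought treatment; defaults to `start..rewater-1` from the config's
#'   drought windows.
#' @param recovery_window Day range of the recovery-index window; defaults
#'   to the last 8 days of the simulated period.
#' @param vc_boot Bootstrap replicates for the vulnerability fit.
#' @param empty_chamber_offset Passed to [compute_fluxes()]; defaults to the
#'   empty chamber in the stream when present.
#' @param metrics Stress metrics to regress recovery on.
#' @return A list of class `dose_analysis`: `vc` (the `vc_fit` or NULL),
#'   `p12`, `fluxes` (QC-filtered), `retention`, `twd_daily`, `dose`
#'   (per-tree dose table incl. damage), `recovery` (per-tree recovery
#'   indices), `table` (dose + recovery join), `fits` (named list of
#'   `dose_fit` by response then metric) and `ranking` (named list of
#'   ranking tibbles per response).
#' @export
run_pipeline <- function(streams, p12 = NULL, windows = NULL,
                         recovery_window = NULL, vc_boot = 0,
                         empty_chamber_offset = NULL,
                         metrics = c("psi_min", "dp12", "twd_p12",
                                     "psi_cum", "pla_mean")) {
  config <- streams$config
  if (is.null(windows)) {
    if (is.null(config)) rlang::abort("supply `windows` or a config.")
    windows <- lapply(config$drought_windows,
                      function(w) c(w[1], w[2] - 1L))
  }
  if (is.null(recovery_window)) {
    if (is.null(config)) rlang::abort("supply `recovery_window` or a config.")
    recovery_window <- c(config$chamber_days[2] - 7L,
                         config$chamber_days[2])
  }

  vc_fit <- NULL
  if (is.null(p12)) {
    vc_fit <- fit_vulnerability(streams$vc, n_boot = vc_boot)
    p12 <- vc_fit$p12
  }

  if (is.null(empty_chamber_offset)) {
    empty_chamber_offset <-
      if ("empty" %in% streams$chamber$chamber_id) "empty" else 0
  }
  fluxes <- compute_fluxes(streams$chamber,
                           empty_chamber_offset = empty_chamber_offset)
  qc <- qc_filter(fluxes)

  twd_daily <- streams$dendro |>
    clean_dendro() |>
    zero_growth_partition() |>
    daily_twd()

  dmg <- damage_summary(streams$damage)
  dose <- assemble_dose_table(streams$psi, twd_daily, p12, windows,
                              damage = dmg)

  recovery <- recovery_table(qc$data, recovery_window)
  tab <- dplyr::inner_join(
    dose,
    recovery[, c("tree_id", "r_ec", "r_gc")],
    by = "tree_id"
  )

  fits <- list()
  ranking <- list()
  for (resp in c("r_ec", "r_gc")) {
    fl <- list()
    for (m in metrics) {
      if (!m %in% names(tab) || all(is.na(tab[[m]]))) next
      fl[[m]] <- dose_response_fit(tab, resp, m)
    }
    fits[[resp]] <- fl
    if (length(fl) >= 2) ranking[[resp]] <- rank_metrics(fl)
  }

  structure(
    list(vc = vc_fit, p12 = p12, fluxes = qc$data,
         retention = qc$retention, twd_daily = twd_daily, dose = dose,
         recovery = recovery, table = tab, fits = fits,
         ranking = ranking),
    class = "dose_analysis"
  )
}

#' @export
print.dose_analysis <- function(x, ...) {
  cat("Drought stress-dose analysis\n")
  cat(sprintf("  P12 = %.2f MPa; QC retention %.1f%%\n",
              x$p12, 100 * x$retention))
  cat("  dose table:", nrow(x$dose), "trees\n")
  for (resp in names(x$ranking)) {
    best <- x$ranking[[resp]][1, ]
    cat(sprintf("  %s best explained by %s (R^2 = %.2f, AIC = %.1f)\n",
                resp, best$metric, best$r_squared, best$aic))
  }
  invisible(x)
}

#' Plot recovery against each stress metric
#'
#' Small-multiple dose-response panels: per-tree recovery index against
#' each stress metric with the fitted regression line.
#'
#' @param analysis A `dose_analysis` from [run_pipeline()].
#' @param response `"r_gc"` (canopy conductance, default) or `"r_ec"`.
#' @return A ggplot.
#' @export
plot_dose_response <- function(analysis, response = "r_gc") {
  fits <- analysis$fits[[response]]
  long <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(metric = f$metric, x = f$x, y = f$y,
                   slope = f$slope, intercept = f$intercept,
                   r2 = f$r_squared)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      data = dplyr::distinct(long, .data$metric, .data$slope,
                             .data$intercept),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "grey40"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "Stress metric", y = paste("Recovery index", response,
                                                 "(%)")) +
    ggplot2::theme_minimal()
}

#' Plot the partitioned dendrometer signal
#'
#' @param trace Output of [zero_growth_partition()].
#' @return A ggplot of diameter, running maximum and TWD over time.
#' @export
plot_twd <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_max), colour = "steelblue",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = min(.data$d) - 0.2 + .data$twd),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~tree_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Stem diameter (mm); TWD offset below") +
    ggplot2::theme_minimal()
}
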
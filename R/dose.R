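#' Interpolate a water-potential series onto the daily grid
#'
#' Midday water potential is typically measured every 2-3 days; stress
#' duration and dose metrics count days, so observations are linearly
#' interpolated onto every day between the first and last observation.
#' No extrapolation is performed.
#'
#' @param data Data frame with `day` (integer day of year) and `psi_md`
#'   (MPa, <= 0); optional `tree_id`/`treatment` grouping columns are
#'   carried through (interpolation is per tree).
#' @return A tibble with one row per tree and day, `psi_md`, and
#'   `interpolated` (logical; `FALSE` for observed days).
#' @export
daily_interpolate <- function(data) {
  data <- tibble::as_tibble(data)
  groups <- intersect(c("tree_id", "treatment"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        rlang::abort("need >= 2 observations per tree to interpolate.")
      }
      days <- seq(min(df$day), max(df$day))
      out <- tibble::tibble(
        day = days,
        psi_md = stats::approx(df$day, df$psi_md, xout = days,
                               method = "linear", rule = 1)$y,
        interpolated = !(days %in% df$day)
      )
      out
    }) |>
    dplyr::ungroup()
}

#' Minimum water potential in a window
#'
#' Stress-intensity metric: the minimum of the observed (non-interpolated)
#' midday water potentials inside the window.
#'
#' @param daily One tree's daily series from [daily_interpolate()] (columns
#'   `day`, `psi_md`, `interpolated`).
#' @param window Two-element integer vector `(first_day, last_day)`,
#'   inclusive.
#' @return Psi_min in MPa.
#' @export
psi_min <- function(daily, window) {
  obs <- daily[!daily$interpolated &
                 daily$day >= window[1] & daily$day <= window[2], ]
  if (nrow(obs) == 0) rlang::abort("no observed values inside `window`.")
  min(obs$psi_md)
}

#' Days below the embolism-onset threshold
#'
#' Stress-duration metric dP12: the number of daily grid points (observed or
#' interpolated) on which the water potential lies strictly below `p12`
#' inside the window.
#'
#' @inheritParams psi_min
#' @param p12 Threshold water potential (MPa, negative), typically from
#'   [fit_vulnerability()].
#' @return Integer day count.
#' @export
days_below_threshold <- function(daily, p12, window) {
  sub <- daily[daily$day >= window[1] & daily$day <= window[2], ]
  sum(sub$psi_md < p12)
}

#' Days of a tree's series below threshold (mask)
#'
#' @inheritParams days_below_threshold
#' @return Integer vector of days of year with `psi_md < p12` inside the
#'   window; feeds the TWD mask of [cumulative_twd()] so duration and dose
#'   metrics share one grid.
#' @export
days_below_mask <- function(daily, p12, window) {
  sub <- daily[daily$day >= window[1] & daily$day <= window[2], ]
  sub$day[sub$psi_md < p12]
}

#' Cumulative water potential relative to the control baseline
#'
#' Stress-dose metric Psi_cum: the sum over window days of the tree's daily
#' water potential minus the daily control-treatment mean, restricted to
#' days on which the difference is negative (the tree is more stressed than
#' the controls).
#'
#' @inheritParams psi_min
#' @param control_daily Daily control baseline: tibble with `day` and
#'   `psi_md` (mean over control trees). Must cover every window day present
#'   in `daily`.
#' @return Psi_cum in MPa (<= 0).
#' @export
cumulative_psi <- function(daily, control_daily, window) {
  sub <- daily[daily$day >= window[1] & daily$day <= window[2], ]
  m <- match(sub$day, control_daily$day)
  if (anyNA(m)) rlang::abort("control baseline does not cover `window`.")
  diffs <- sub$psi_md - control_daily$psi_md[m]
  sum(pmin(diffs, 0))
}

#' Assemble the per-tree stress-dose table
#'
#' Combines the four stress metrics (Psi_min, dP12, TWD_P12, Psi_cum) and,
#' when supplied, the organ-mean PLA into one record per tree.
#'
#' @param psi_data Water-potential observations for all trees: `tree_id`,
#'   `treatment`, `day`, `psi_md`.
#' @param twd_daily Daily TWD means for all trees: `tree_id`, `day`, `twd`
#'   (see [daily_twd()]).
#' @param p12 Embolism-onset threshold (MPa).
#' @param windows Named list mapping each treatment to its drought window
#'   `c(first_day, last_day)`; treatments with a `NULL` window (e.g.
#'   control) are evaluated over the union of all drought windows so that
#'   their metrics are defined (and near zero).
#' @param damage Optional per-tree damage summary with `tree_id` and
#'   `pla_mean` (organ-mean PLA, percent).
#' @return A tibble with one row per tree: `tree_id`, `treatment`,
#'   `psi_min`, `dp12`, `twd_p12`, `psi_cum`, and `pla_mean` when available.
#' @export
assemble_dose_table <- function(psi_data, twd_daily, p12, windows,
                                damage = NULL) {
  if (anyDuplicated(unique(psi_data[c("tree_id", "treatment")])$tree_id)) {
    rlang::abort("duplicated tree ids across treatments.")
  }
  daily <- daily_interpolate(psi_data)
  control_daily <- daily |>
    dplyr::filter(.data$treatment == "control") |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(psi_md = mean(.data$psi_md), .groups = "drop")
  fallback <- range(unlist(windows))

  out <- daily |>
    dplyr::group_by(.data$tree_id, .data$treatment) |>
    dplyr::group_modify(function(df, key) {
      win <- windows[[as.character(key$treatment)]]
      if (is.null(win)) win <- fallback
      mask <- days_below_mask(df, p12, win)
      twd_tree <- twd_daily[twd_daily$tree_id == key$tree_id, ]
      tibble::tibble(
        psi_min = psi_min(df, win),
        dp12 = length(mask),
        twd_p12 = cumulative_twd(twd_tree, mask),
        psi_cum = cumulative_psi(df, control_daily, win)
      )
    }) |>
    dplyr::ungroup()
  if (!is.null(damage)) {
    out <- dplyr::left_join(out, damage[, c("tree_id", "pla_mean")],
                            by = "tree_id")
  }
  out
}
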
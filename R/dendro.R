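#' Clean a dendrometer trace
#'
#' Removes step artifacts (sensor reseats, chamber transfers) and fills short
#' gaps in a raw stem-diameter series before growth/water-deficit
#' partitioning.
#'
#' @param data Data frame with `timestamp` (POSIXct, strictly increasing
#'   within a tree; a `tree_id` column is honoured if present) and `d`
#'   (stem diameter, mm).
#' @param jump_threshold Absolute first difference (mm) above which a step is
#'   treated as an artifact and the whole subsequent segment is offset back.
#'   Default `NULL`: 5 times the median absolute first difference of the
#'   trace (a robust scale that adapts to sensor resolution), floored at
#'   0.5 mm so that fast physiological steps (e.g. rehydration swelling)
#'   are never mistaken for sensor reseats.
#' @param max_gap Maximum gap (in seconds) bridged by linear interpolation;
#'   longer gaps are left missing and flagged. Default 6 hours.
#' @return A tibble with the input columns, `d` corrected, and a
#'   `clean_flag` column (`"ok"`, `"jump_corrected"`, `"interpolated"`,
#'   `"gap"`).
#' @details Jump correction preserves the continuity of tree water deficit
#'   across breaks: the running maximum is not reset, the post-break segment
#'   is simply shifted onto the pre-break level.
#' @export
clean_dendro <- function(data, jump_threshold = NULL, max_gap = 6 * 3600) {
  data <- tibble::as_tibble(data)
  if (!all(c("timestamp", "d") %in% names(data))) {
    rlang::abort("`data` needs `timestamp` and `d` columns.")
  }
  groups <- if ("tree_id" %in% names(data)) "tree_id" else character()
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(~ clean_one_trace(.x, jump_threshold, max_gap)) |>
    dplyr::ungroup()
}

clean_one_trace <- function(tr, jump_threshold, max_gap) {
  ts <- as.numeric(tr$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) {
    rlang::abort("timestamps must be strictly increasing within a tree.")
  }
  d <- tr$d
  flag <- rep("ok", length(d))
  dd <- diff(d)
  if (is.null(jump_threshold)) {
    mad_step <- stats::median(abs(dd), na.rm = TRUE)
    jump_threshold <- max(5 * mad_step, 0.5, na.rm = TRUE)
  }
  jumps <- which(!is.na(dd) & abs(dd) > jump_threshold)
  for (j in jumps) {
    d[(j + 1):length(d)] <- d[(j + 1):length(d)] - dd[j]
    flag[j + 1] <- "jump_corrected"
    dd <- diff(d)
  }
  # gap handling on missing values
  na_idx <- which(is.na(d))
  if (length(na_idx) > 0) {
    filled <- stats::approx(ts[!is.na(d)], d[!is.na(d)], xout = ts,
                            method = "linear", rule = 1)$y
    for (i in na_idx) {
      lo <- max(which(!is.na(tr$d[seq_len(i)])), 0)
      hi_cand <- which(!is.na(tr$d))
      hi <- hi_cand[hi_cand > i][1]
      gap <- if (lo >= 1 && !is.na(hi)) ts[hi] - ts[lo] else Inf
      if (is.finite(gap) && gap <= max_gap) {
        d[i] <- filled[i]
        flag[i] <- "interpolated"
      } else {
        flag[i] <- "gap"
      }
    }
  }
  tr$d <- d
  tr$clean_flag <- flag
  tr
}

#' Zero-growth partition of a dendrometer trace
#'
#' Splits stem-diameter variation into irreversible growth and tree water
#' deficit (TWD) under the zero-growth concept: growth occurs only while the
#' diameter exceeds its previous historical maximum; any excursion below that
#' maximum is reversible shrinkage, i.e. TWD.
#'
#' @param data Cleaned trace (tibble with `timestamp`, `d`; optional
#'   `tree_id` for grouping). Rows with missing `d` are dropped.
#' @return A tibble with the input columns plus `d_max` (running maximum,
#'   mm), `twd` (`d_max - d`, mm), `twd_rel` (percent of `d_max`) and
#'   `growth_cum` (cumulative growth since the first record, mm). The
#'   identity `d = d[1] + growth_cum - twd` holds at every row.
#' @export
zero_growth_partition <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"tree_id" %in% names(data)) {
    # single-trace fast path: no grouping machinery needed
    out <- data[!is.na(data$d), , drop = FALSE]
    out$d_max <- cummax(out$d)
    out$twd <- out$d_max - out$d
    out$twd_rel <- twd_rel(out$d, out$d_max)
    out$growth_cum <- out$d_max - out$d_max[1]
    return(out)
  }
  groups <- "tree_id"
  data |>
    dplyr::filter(!is.na(.data$d)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::mutate(
      d_max = cummax(.data$d),
      twd = .data$d_max - .data$d,
      twd_rel = twd_rel(.data$d, .data$d_max),
      growth_cum = .data$d_max - .data$d_max[1]
    ) |>
    dplyr::ungroup()
}

#' Relative tree water deficit
#'
#' @param d Current stem diameter (mm).
#' @param d_max Historical maximum diameter (mm), > 0.
#' @return `100 * (d_max - d) / d_max`, in percent of the fully hydrated
#'   diameter.
#' @export
twd_rel <- function(d, d_max) {
  if (any(d_max <= 0, na.rm = TRUE)) {
    rlang::abort("`d_max` must be positive.")
  }
  100 * (d_max - d) / d_max
}

#' Aggregate a partitioned trace to daily means
#'
#' @param trace Output of [zero_growth_partition()]; needs `timestamp`,
#'   `twd`, optional `tree_id` and `twd_rel`.
#' @return A tibble with `tree_id` (if present), `day` (integer day of year)
#'   and daily means of `twd` (and `twd_rel` when available).
#' @export
daily_twd <- function(trace) {
  groups <- intersect(c("tree_id"), names(trace))
  trace |>
    dplyr::mutate(day = as.integer(format(.data$timestamp, "%j"))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "day")))) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("twd", "twd_rel")),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Cumulative tree water deficit over masked days
#'
#' Integrates daily-mean TWD over a set of days, typically the days on which
#' midday water potential was below the embolism-onset threshold P12; the
#' result is the dendrometric stress dose TWD_P12 (mm, implicitly mm * day).
#'
#' @param daily Tibble of daily TWD means with columns `day` and `twd`
#'   (one tree; see [daily_twd()]).
#' @param day_mask Integer vector of days of year to sum over. Days absent
#'   from `daily` are an error (mask/series mismatch); an empty mask gives 0.
#' @return Cumulative TWD in mm.
#' @export
cumulative_twd <- function(daily, day_mask) {
  if (length(day_mask) == 0) return(0)
  if (!all(day_mask %in% daily$day)) {
    rlang::abort("`day_mask` contains days absent from `daily`.")
  }
  sum(daily$twd[daily$day %in% day_mask])
}
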
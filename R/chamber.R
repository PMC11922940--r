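#' Saturation vapor pressure (Tetens)
#'
#' Saturation vapor pressure of air at temperature `t_air`, using the Tetens
#' approximation common in plant ecophysiology.
#'
#' @param t_air Air temperature in degrees Celsius. Must exceed -237.3.
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vapor_pressure(25) # ~3.17 kPa
#' @export
saturation_vapor_pressure <- function(t_air) {
  if (any(t_air <= -237.3, na.rm = TRUE)) {
    rlang::abort("`t_air` must be > -237.3 degC (Tetens domain).")
  }
  0.6108 * exp(17.27 * t_air / (t_air + 237.3))
}

#' Actual vapor pressure from absolute humidity
#'
#' Converts a humidity measure `ah` (treated as a dimensionless mixing ratio;
#' see Details) and atmospheric pressure into actual vapor pressure.
#'
#' @details The formula `ea = ah * p / (0.62198 + ah)` has the algebraic form
#' of a mixing-ratio conversion (0.62198 is the ratio of molar masses of water
#' and dry air), so `ah` is treated as kg water per kg dry air even though
#' absolute humidity is often reported in g m^-3. Supply a mixing ratio here;
#' no unit conversion is attempted silently.
#'
#' @param ah Humidity measure (dimensionless mixing ratio), >= 0.
#' @param p Atmospheric pressure in kPa, > 0.
#' @return Actual vapor pressure in kPa, in `[0, p)`.
#' @export
actual_vapor_pressure <- function(ah, p) {
  if (any(ah < 0, na.rm = TRUE)) rlang::abort("`ah` must be non-negative.")
  if (any(p <= 0, na.rm = TRUE)) rlang::abort("`p` must be positive.")
  ah * p / (0.62198 + ah)
}

#' Vapor pressure deficit
#'
#' @param e_s Saturation vapor pressure (kPa).
#' @param e_a Actual vapor pressure (kPa).
#' @return `e_s - e_a` in kPa. Negative values are returned as-is; the QC
#'   filter flags them rather than clipping silently.
#' @export
vpd <- function(e_s, e_a) {
  e_s - e_a
}

#' Canopy transpiration from a flow-through chamber
#'
#' Whole-tree transpiration from the water-vapor enrichment of chamber air
#' over the supply air in an open gas-exchange system.
#'
#' @param mdot Air mass flow through the chamber (mol s^-1), > 0.
#' @param w_sample Water vapor content of the sample (chamber outlet) air, in
#'   mmol mol^-1.
#' @param w_supply Water vapor content of the supply air, in mmol mol^-1.
#' @return Canopy transpiration E_c in mol H2O tree^-1 s^-1.
#' @details Inputs are stored in mmol mol^-1 (as instruments report them) and
#'   converted to mole fractions inside the mass-balance formula
#'   `E_c = mdot (w_sample - w_supply) / (1 - w_sample)`.
#' @export
canopy_transpiration <- function(mdot, w_sample, w_supply) {
  if (any(w_sample >= 1000, na.rm = TRUE)) {
    rlang::abort("`w_sample` must be < 1000 mmol mol^-1 (mole fraction < 1).")
  }
  ws <- w_sample / 1000
  wu <- w_supply / 1000
  mdot * (ws - wu) / (1 - ws)
}

#' Leaf-area transpiration
#'
#' Canopy transpiration normalised by the needle area remaining on the tree.
#'
#' @inheritParams canopy_transpiration
#' @param area_needle Total needle area per tree (m^2), > 0.
#' @return Transpiration per unit leaf area E_la in mol m^-2 s^-1.
#' @export
leaf_transpiration <- function(mdot, w_sample, w_supply, area_needle) {
  if (any(area_needle <= 0, na.rm = TRUE)) {
    rlang::abort("`area_needle` must be positive.")
  }
  canopy_transpiration(mdot, w_sample, w_supply) / area_needle
}

#' Saturated needle water vapor content
#'
#' Water vapor mole fraction of needle intercellular air, assuming needle
#' temperature equals chamber air temperature (no leaf energy balance).
#'
#' @param t_air Air temperature (degC).
#' @param p Atmospheric pressure (kPa).
#' @return W_needle in mmol mol^-1.
#' @export
needle_vapor_content <- function(t_air, p) {
  1000 * saturation_vapor_pressure(t_air) / p
}

#' Canopy and stomatal conductance to water vapor
#'
#' Conductance from transpiration and the needle-to-air water vapor gradient,
#' neglecting boundary-layer conductance (valid under strong chamber mixing).
#'
#' @param e_flux Transpiration: E_c (mol tree^-1 s^-1) for canopy conductance,
#'   E_la (mol m^-2 s^-1) for stomatal conductance.
#' @param w_needle Saturated vapor content at needle temperature
#'   (mmol mol^-1).
#' @param w_sample Vapor content of chamber air (mmol mol^-1).
#' @return Conductance in mmol tree^-1 s^-1 (canopy) or mmol m^-2 s^-1
#'   (stomatal): `1000 * e_flux * (1000 - (w_needle + w_sample)/2) /
#'   (w_needle - w_sample)`.
#' @details Records with `w_needle <= w_sample` (condensation, ill-posed
#'   gradient) yield `NA`; [compute_fluxes()] flags and drops them rather than
#'   clipping.
#' @export
canopy_conductance <- function(e_flux, w_needle, w_sample) {
  g <- 1000 * e_flux * (1000 - (w_needle + w_sample) / 2) /
    (w_needle - w_sample)
  g[w_needle <= w_sample] <- NA_real_
  g
}

#' @rdname canopy_conductance
#' @export
stomatal_conductance <- canopy_conductance

#' Compute flux records from chamber samples
#'
#' Turns a tibble of raw chamber records into a tibble of derived fluxes:
#' VPD, canopy and leaf-level transpiration, canopy and stomatal conductance.
#'
#' @param data A data frame with columns `timestamp` (POSIXct), `chamber_id`,
#'   `t_air` (degC), `p` (kPa), `mdot` (mol s^-1), `w_supply` and `w_sample`
#'   (mmol mol^-1); optional `ah` (mixing ratio, for VPD via
#'   [actual_vapor_pressure()]; if absent, `e_a` is derived from `w_sample`),
#'   `area_needle` (m^2, per tree) and `par`.
#' @param empty_chamber_offset Constant concentration differential of the
#'   empty reference chamber (mmol mol^-1), subtracted from every
#'   `w_sample - w_supply` difference before flux computation. Alternatively
#'   the id of the empty chamber as a string, in which case its per-timestamp
#'   differential is subtracted from all other chambers and the empty chamber
#'   is dropped from the output.
#' @return A tibble with the input identifier columns plus `e_s`, `e_a`,
#'   `vpd_kpa`, `w_needle`, `e_c`, `e_la`, `g_c`, `g_s` and a `qc_flag`
#'   character column (`"ok"` or a reason; see [qc_filter()]).
#' @export
compute_fluxes <- function(data, empty_chamber_offset = 0) {
  req <- c("timestamp", "chamber_id", "t_air", "p", "mdot", "w_supply",
           "w_sample")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("`data` is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)

  if (is.character(empty_chamber_offset)) {
    empty_id <- empty_chamber_offset
    empty <- data |>
      dplyr::filter(.data$chamber_id == empty_id) |>
      dplyr::transmute(.data$timestamp,
                       offset = .data$w_sample - .data$w_supply)
    data <- data |>
      dplyr::filter(.data$chamber_id != empty_id) |>
      dplyr::left_join(empty, by = "timestamp") |>
      dplyr::mutate(offset = dplyr::coalesce(.data$offset, 0))
  } else {
    data$offset <- empty_chamber_offset
  }

  out <- data |>
    dplyr::mutate(
      w_diff = .data$w_sample - .data$w_supply - .data$offset,
      w_sample_corr = .data$w_supply + .data$w_diff,
      e_s = saturation_vapor_pressure(.data$t_air),
      e_a = if ("ah" %in% names(data)) {
        actual_vapor_pressure(.data$ah, .data$p)
      } else {
        .data$w_sample_corr / 1000 * .data$p
      },
      vpd_kpa = vpd(.data$e_s, .data$e_a),
      w_needle = needle_vapor_content(.data$t_air, .data$p),
      e_c = canopy_transpiration(.data$mdot, .data$w_sample_corr,
                                 .data$w_supply),
      e_la = if ("area_needle" %in% names(data)) {
        .data$e_c / .data$area_needle
      } else {
        NA_real_
      },
      g_c = canopy_conductance(.data$e_c, .data$w_needle,
                               .data$w_sample_corr),
      g_s = if ("area_needle" %in% names(data)) {
        stomatal_conductance(.data$e_la, .data$w_needle, .data$w_sample_corr)
      } else {
        NA_real_
      },
      qc_flag = dplyr::case_when(
        .data$w_needle <= .data$w_sample_corr ~ "condensation",
        .data$vpd_kpa < 0 ~ "negative_vpd",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select(-"offset", -"w_diff")
  out
}

#' Quality-control filter for chamber flux series
#'
#' Keeps daytime records only and removes per-chamber outliers in canopy
#' transpiration, defined as values more than `iqr_k` interquartile ranges
#' outside the quartiles (Tukey fence), computed per chamber.
#'
#' @param fluxes A tibble from [compute_fluxes()] (needs `timestamp`,
#'   `chamber_id`, `e_c`, `qc_flag`).
#' @param daytime Two-element numeric vector of decimal hours `(start, end)`
#'   defining daytime; records with hour in `[start, end)` are kept.
#' @param iqr_k Multiplier of the interquartile range for the outlier fence.
#' @return A list with `data` (the retained records) and `retention` (fraction
#'   of daytime `"ok"` records retained; `NA_real_` for an empty input).
#' @details The fence is re-applied until no further point is removed, so the
#'   filter is idempotent: running it on its own output changes nothing. On
#'   typical chamber data the fixed point is reached after one pass.
#' @export
qc_filter <- function(fluxes, daytime = c(6, 19), iqr_k = 1.5) {
  if (nrow(fluxes) == 0) {
    return(list(data = fluxes, retention = NA_real_))
  }
  hr <- as.numeric(format(fluxes$timestamp, "%H")) +
    as.numeric(format(fluxes$timestamp, "%M")) / 60
  day <- fluxes[hr >= daytime[1] & hr < daytime[2] &
                  fluxes$qc_flag == "ok", , drop = FALSE]
  n_day <- nrow(day)
  if (n_day == 0) {
    return(list(data = day, retention = 0))
  }
  kept <- day
  repeat {
    n_before <- nrow(kept)
    kept <- kept |>
      dplyr::group_by(.data$chamber_id) |>
      dplyr::filter({
        q <- stats::quantile(.data$e_c, c(0.25, 0.75), na.rm = TRUE,
                             names = FALSE)
        fence <- iqr_k * (q[2] - q[1])
        .data$e_c >= q[1] - fence & .data$e_c <= q[2] + fence
      }) |>
      dplyr::ungroup()
    if (nrow(kept) == n_before) break
  }
  list(data = kept, retention = nrow(kept) / n_day)
}
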
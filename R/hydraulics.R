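#' Percent loss of conductivity
#'
#' @param k_t Hydraulic conductance at xylem pressure P (>= 0).
#' @param k_i Initial (fully hydrated) conductance, > 0.
#' @param clamp If `TRUE`, values outside `[0, 100]` (measurement noise) are
#'   clamped; by default they are returned as-is so fitting can use them.
#' @return `100 * (1 - k_t / k_i)`, percent.
#' @export
plc <- function(k_t, k_i, clamp = FALSE) {
  if (any(k_i <= 0, na.rm = TRUE)) rlang::abort("`k_i` must be positive.")
  out <- 100 * (1 - k_t / k_i)
  if (clamp) out <- pmin(pmax(out, 0), 100)
  out
}

#' Weibull vulnerability curve
#'
#' Percent loss of conductivity at xylem pressure `p` under a two-parameter
#' Weibull curve, `PLC(p) = 100 (1 - exp(-(|p|/b)^c))`.
#'
#' @param p Xylem pressure in MPa (negative under tension; the magnitude is
#'   used).
#' @param b Scale parameter (MPa, positive magnitude).
#' @param c Shape parameter (dimensionless, > 0); larger `c` gives a steeper
#'   curve.
#' @return PLC in percent, strictly increasing in `|p|`, 0 at `p = 0`.
#' @export
weibull_plc <- function(p, b, c) {
  if (any(b <= 0) || any(c <= 0)) rlang::abort("`b` and `c` must be > 0.")
  100 * (1 - exp(-(abs(p) / b)^c))
}

#' Xylem pressure at a given conductivity loss
#'
#' Inverts the Weibull vulnerability curve: the (negative) pressure at which
#' `x` percent of conductivity is lost. `weibull_px(12, b, c)` is P12,
#' `weibull_px(50, b, c)` is P50.
#'
#' @param x Conductivity loss in percent, in (0, 100).
#' @inheritParams weibull_plc
#' @return Xylem pressure in MPa (negative).
#' @export
weibull_px <- function(x, b, c) {
  if (any(x <= 0 | x >= 100)) rlang::abort("`x` must be in (0, 100).")
  -b * (-log(1 - x / 100))^(1 / c)
}

weibull_slope_at <- function(p, b, c) {
  # dPLC/dP in %/MPa at pressure p (negative); magnitude of the derivative
  a <- abs(p)
  100 * exp(-(a / b)^c) * c * a^(c - 1) / b^c
}

fit_weibull_nls <- function(df, start = NULL) {
  # linearised start: log(-log(1 - PLC/100)) = c log|P| - c log b
  if (is.null(start)) {
    ok <- df$plc > 0.5 & df$plc < 99.5
    if (sum(ok) < 2) ok <- rep(TRUE, nrow(df))
    y <- log(-log(pmin(pmax(1 - df$plc[ok] / 100, 1e-6), 1 - 1e-6)))
    xl <- log(abs(df$p[ok]))
    cf <- stats::coef(stats::lm(y ~ xl))
    c0 <- max(cf[2], 0.2)
    b0 <- exp(-cf[1] / c0)
    start <- list(b = min(max(b0, 0.1), 20), c = min(max(c0, 0.2), 30))
  }
  fit <- tryCatch(
    stats::nls(plc ~ weibull_plc(p, b, c), data = df, start = start,
               algorithm = "port", lower = c(b = 1e-3, c = 1e-2),
               upper = c(b = 100, c = 100),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(plc ~ weibull_plc(p, b, c), data = df,
                        start = start, lower = c(1e-3, 1e-2),
                        upper = c(100, 100)),
      error = function(e) NULL
    )
  }
  fit
}

#' Fit a xylem vulnerability curve
#'
#' Nonlinear least-squares fit of the two-parameter Weibull vulnerability
#' curve to pooled PLC measurements, with bootstrap confidence intervals for
#' P12 and P50 obtained by resampling sample replicates (cases).
#'
#' @param data Data frame with columns `p` (xylem pressure, MPa), `plc`
#'   (percent loss of conductivity) and `sample_id` (replicate identifier;
#'   the bootstrap resampling unit). Out-of-range PLC values are retained in
#'   the fit but flagged in the returned object.
#' @param n_boot Number of bootstrap replicates (0 to skip CIs).
#' @param level Confidence level for the intervals.
#' @param ci_type `"t"` (default; estimate +/- t-quantile * inflated
#'   bootstrap SD, the standard small-sample correction for a cluster
#'   bootstrap: with K resampled samples the bootstrap SD is scaled by
#'   `sqrt(K/(K-1))` and the quantile taken from a t distribution with
#'   K - 1 degrees of freedom) or `"percentile"` (raw bootstrap quantiles;
#'   anti-conservative when the number of samples is small).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `vc_fit`: a list with `b`, `c`, `p12`, `p50`,
#'   `slope_at_p50` (%/MPa), `ci` (tibble with one row per quantity),
#'   `n_samples`, `n_obs`, `flagged` (row indices of out-of-range PLC),
#'   `data` and the underlying `nls` fit. Self-consistency
#'   `weibull_plc(p12) = 12` and `weibull_plc(p50) = 50` holds to numerical
#'   precision.
#' @export
fit_vulnerability <- function(data, n_boot = 1000, level = 0.95,
                              ci_type = c("t", "percentile"),
                              seed = NULL) {
  ci_type <- match.arg(ci_type)
  data <- tibble::as_tibble(data)
  if (!all(c("p", "plc") %in% names(data))) {
    rlang::abort("`data` needs `p` and `plc` columns.")
  }
  if (!"sample_id" %in% names(data)) data$sample_id <- 1L
  if (length(unique(abs(data$p))) < 2) {
    rlang::abort("need measurements at >= 2 distinct pressures.")
  }
  if (stats::sd(data$plc) == 0) {
    rlang::abort("degenerate data: all PLC values identical.")
  }
  fit <- fit_weibull_nls(data)
  if (is.null(fit)) {
    rlang::abort("vulnerability-curve fit did not converge.")
  }
  cf <- stats::coef(fit)
  b <- unname(cf["b"]); cc <- unname(cf["c"])
  p12 <- weibull_px(12, b, cc)
  p50 <- weibull_px(50, b, cc)

  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    ids <- unique(data$sample_id)
    by_id <- split(seq_len(nrow(data)), data$sample_id)
    start <- list(b = b, c = cc)
    boot <- matrix(NA_real_, n_boot, 2,
                   dimnames = list(NULL, c("p12", "p50")))
    for (i in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      rows <- unlist(by_id[as.character(take)], use.names = FALSE)
      bf <- fit_weibull_nls(data[rows, , drop = FALSE], start = start)
      if (!is.null(bf)) {
        bcf <- stats::coef(bf)
        boot[i, ] <- c(weibull_px(12, bcf["b"], bcf["c"]),
                       weibull_px(50, bcf["b"], bcf["c"]))
      }
    }
    alpha <- (1 - level) / 2
    mk_ci <- function(est, v) {
      v <- v[is.finite(v)]
      if (ci_type == "percentile") {
        q <- stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
      } else {
        k <- length(ids)
        tq <- stats::qt(1 - alpha, df = max(k - 1, 1))
        q <- est + c(-1, 1) * tq * stats::sd(v) * sqrt(k / max(k - 1, 1))
      }
      sort(q)
    }
    ci12 <- mk_ci(p12, boot[, "p12"])
    ci50 <- mk_ci(p50, boot[, "p50"])
    ci <- tibble::tibble(
      quantity = c("p12", "p50"),
      estimate = c(p12, p50),
      ci_lower = c(ci12[1], ci50[1]),
      ci_upper = c(ci12[2], ci50[2]),
      level = level,
      n_boot = sum(is.finite(boot[, 1]))
    )
  }

  structure(
    list(
      b = b, c = cc, p12 = p12, p50 = p50,
      slope_at_p50 = weibull_slope_at(p50, b, cc),
      ci = ci,
      n_samples = length(unique(data$sample_id)),
      n_obs = nrow(data),
      flagged = which(data$plc < 0 | data$plc > 100),
      data = data,
      fit = fit
    ),
    class = "vc_fit"
  )
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Weibull vulnerability curve (", x$n_obs, " obs, ",
      x$n_samples, " samples)\n", sep = "")
  cat(sprintf("  b = %.3f MPa, c = %.3f\n", x$b, x$c))
  cat(sprintf("  P12 = %.2f MPa, P50 = %.2f MPa, slope at P50 = %.1f %%/MPa\n",
              x$p12, x$p50, x$slope_at_p50))
  if (!is.null(x$ci)) {
    for (i in seq_len(nrow(x$ci))) {
      cat(sprintf("  %s 95%% CI: [%.2f, %.2f]\n", toupper(x$ci$quantity[i]),
                  x$ci$ci_lower[i], x$ci$ci_upper[i]))
    }
  }
  invisible(x)
}

#' Tidy a vulnerability-curve fit
#'
#' @param x A `vc_fit` object.
#' @param ... Unused.
#' @return One row per quantity (b, c, p12, p50, slope_at_p50) with
#'   `estimate` and, where available, bootstrap `ci_lower`/`ci_upper`.
#' @export
tidy.vc_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("b", "c", "p12", "p50", "slope_at_p50"),
    estimate = c(x$b, x$c, x$p12, x$p50, x$slope_at_p50),
    ci_lower = NA_real_, ci_upper = NA_real_
  )
  if (!is.null(x$ci)) {
    m <- match(x$ci$quantity, out$term)
    out$ci_lower[m] <- x$ci$ci_lower
    out$ci_upper[m] <- x$ci$ci_upper
  }
  out
}

#' @rdname tidy.vc_fit
#' @return For `glance()`: a one-row tibble with fit-level summaries.
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  res <- stats::resid(x$fit)
  tibble::tibble(
    n_obs = x$n_obs, n_samples = x$n_samples,
    sigma = sqrt(sum(res^2) / (x$n_obs - 2)),
    p12 = x$p12, p50 = x$p50
  )
}

#' Plot a fitted vulnerability curve
#'
#' @param object A `vc_fit` object.
#' @param ... Unused.
#' @return A ggplot: PLC measurements, the fitted Weibull curve, and dashed
#'   reference lines at P12 and P50.
#' @method autoplot vc_fit
#' @export
autoplot.vc_fit <- function(object, ...) {
  grid <- tibble::tibble(
    p = seq(min(object$data$p, -0.01), 0, length.out = 200)
  )
  grid$plc <- weibull_plc(grid$p, object$b, object$c)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$p, y = .data$plc)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$sample_id)),
                        alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::geom_vline(xintercept = c(object$p12, object$p50),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Xylem pressure (MPa)",
                  y = "Loss of conductivity (%)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Percent loss of conductive area
#'
#' Embolised conduit area of a native scan relative to the fully dried
#' reference scan of the same region, in which all conduits are embolised.
#'
#' @param a_native Embolised area in the native scan (>= 0).
#' @param a_ref Embolised area in the reference scan (> 0).
#' @return `100 * a_native / a_ref`, percent. Values where
#'   `a_native > a_ref` are returned (> 100) with a warning rather than
#'   clipped.
#' @export
pla <- function(a_native, a_ref) {
  if (any(a_ref <= 0, na.rm = TRUE)) rlang::abort("`a_ref` must be > 0.")
  if (any(a_native < 0, na.rm = TRUE)) {
    rlang::abort("`a_native` must be >= 0.")
  }
  if (any(a_native > a_ref, na.rm = TRUE)) {
    rlang::warn("`a_native` exceeds `a_ref` for some rows (PLA > 100%).")
  }
  100 * a_native / a_ref
}

#' Needle biomass and area accounting
#'
#' Needle loss and remaining needle area from dry biomass retained on the
#' tree, biomass shed during the experiment, and the specific needle area.
#'
#' @param retained_g Needle dry biomass retained on the tree (g DW).
#' @param shed_g Needle dry biomass shed (g DW). Not both zero.
#' @param specific_needle_area Specific needle area in cm^2 per g DW (area
#'   per dry mass; multiplied by biomass to give area).
#' @return A tibble with `needle_loss_pct` (`100 * shed / (retained + shed)`),
#'   `needle_area_m2` (retained biomass times specific area, converted to
#'   m^2) and `needle_area_shed_m2`.
#' @export
needle_accounting <- function(retained_g, shed_g, specific_needle_area) {
  if (any(retained_g < 0 | shed_g < 0, na.rm = TRUE)) {
    rlang::abort("biomasses must be >= 0.")
  }
  if (any(retained_g + shed_g == 0, na.rm = TRUE)) {
    rlang::abort("retained and shed biomass cannot both be zero.")
  }
  tibble::tibble(
    needle_loss_pct = 100 * shed_g / (retained_g + shed_g),
    needle_area_m2 = retained_g * specific_needle_area / 1e4,
    needle_area_shed_m2 = shed_g * specific_needle_area / 1e4
  )
}
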
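#' Recovery index
#'
#' Post-rewatering performance of a stressed tree relative to the concurrent
#' control mean: `R = 100 * x_tree / x_control`, where both are window means
#' of the same flux (canopy transpiration or conductance).
#'
#' @param x_tree Window mean of the flux for one tree (or a vector of trees).
#' @param x_control Window mean of the flux over the control trees, > 0.
#' @return Recovery index in percent; 100 means full recovery to control
#'   level. Scale-invariant: multiplying all fluxes by a constant leaves it
#'   unchanged.
#' @export
recovery_index <- function(x_tree, x_control) {
  if (any(x_control <= 0, na.rm = TRUE)) {
    rlang::abort("`x_control` must be positive.")
  }
  100 * x_tree / x_control
}

#' Per-tree recovery indices from a flux series
#'
#' Aggregates QC-filtered fluxes to daily tree means, averages them over the
#' recovery window, and expresses each drought tree relative to the control
#' mean over the same window.
#'
#' @param fluxes Flux tibble (see [compute_fluxes()]; after [qc_filter()])
#'   with `timestamp`, `chamber_id`, `e_c`, `g_c` and a `treatment` column
#'   (the chamber id is taken as the tree id).
#' @param window Two-element integer vector of days of year (inclusive);
#'   a common choice is the last 8 days of the recovery period, but a
#'   5-day window is equally defensible and configurable here.
#' @return A tibble with one row per non-control tree: `tree_id`,
#'   `treatment`, `r_ec`, `r_gc` (percent) and the window means that entered
#'   the ratio.
#' @export
recovery_table <- function(fluxes, window) {
  daily <- fluxes |>
    dplyr::mutate(day = as.integer(format(.data$timestamp, "%j"))) |>
    dplyr::filter(.data$day >= window[1], .data$day <= window[2]) |>
    dplyr::group_by(.data$chamber_id, .data$treatment, .data$day) |>
    dplyr::summarise(e_c = mean(.data$e_c, na.rm = TRUE),
                     g_c = mean(.data$g_c, na.rm = TRUE),
                     .groups = "drop")
  tree_means <- daily |>
    dplyr::group_by(tree_id = .data$chamber_id, .data$treatment) |>
    dplyr::summarise(e_c = mean(.data$e_c, na.rm = TRUE),
                     g_c = mean(.data$g_c, na.rm = TRUE),
                     .groups = "drop")
  ctrl <- tree_means |> dplyr::filter(.data$treatment == "control")
  if (nrow(ctrl) == 0) rlang::abort("no control trees in `fluxes`.")
  ec0 <- mean(ctrl$e_c)
  gc0 <- mean(ctrl$g_c)
  tree_means |>
    dplyr::filter(.data$treatment != "control") |>
    dplyr::mutate(
      r_ec = recovery_index(.data$e_c, ec0),
      r_gc = recovery_index(.data$g_c, gc0),
      ec_control = ec0,
      gc_control = gc0
    )
}

#' Linear dose-response fit of recovery on a stress metric
#'
#' Ordinary least squares of a recovery index on one stress metric across
#' trees, with the Gaussian-likelihood AIC used for metric comparison.
#'
#' @param data Data frame holding the response and metric columns.
#' @param response,metric Column names (strings) of the recovery index and
#'   the stress metric.
#' @return An object of class `dose_fit` wrapping the `lm`: fields
#'   `metric`, `response`, `slope`, `intercept`, `r_squared`,
#'   `aic` (`n log(SS_res/n) + 2k`, k = 3 for slope, intercept and error
#'   variance), `p_value` (two-sided, on the slope), `n`, `slope_se`.
#' @export
dose_response_fit <- function(data, response, metric) {
  df <- tibble::tibble(y = data[[response]], x = data[[metric]])
  df <- df[stats::complete.cases(df), ]
  n <- nrow(df)
  if (n < 3) rlang::abort("need >= 3 paired observations.")
  if (stats::sd(df$x) == 0) {
    rlang::abort(paste0("metric `", metric, "` has zero variance."))
  }
  fit <- stats::lm(y ~ x, data = df)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((df$y - mean(df$y))^2)
  sm <- summary(fit)
  structure(
    list(
      metric = metric,
      response = response,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      slope_se = sm$coefficients[2, 2],
      r_squared = 1 - ss_res / ss_tot,
      aic = n * log(ss_res / n) + 2 * 3,
      p_value = sm$coefficients[2, 4],
      n = n,
      ss_res = ss_res,
      residuals = unname(stats::resid(fit)),
      y = df$y,
      x = df$x,
      lm = fit
    ),
    class = "dose_fit"
  )
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf(
    "%s ~ %s: slope %.4g (SE %.3g), R^2 = %.3f, AIC = %.2f, p = %.3g, n = %d\n",
    x$response, x$metric, x$slope, x$slope_se, x$r_squared, x$aic,
    x$p_value, x$n))
  invisible(x)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (intercept, slope) with
#'   estimate, SE and p-value. `glance()`: one row with `r_squared`, `aic`,
#'   `p_value` and `n`.
#' @method tidy dose_fit
#' @export
tidy.dose_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$metric),
    estimate = sm[, 1],
    std_error = sm[, 2],
    statistic = sm[, 3],
    p_value = sm[, 4]
  )
}

#' @rdname tidy.dose_fit
#' @method glance dose_fit
#' @export
glance.dose_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, response = x$response,
                 r_squared = x$r_squared, aic = x$aic,
                 p_value = x$p_value, n = x$n)
}

#' Rank stress metrics by explanatory power
#'
#' Orders a set of dose-response fits (all on the identical response vector)
#' by AIC, breaking ties by descending R-squared.
#'
#' @param fits List of `dose_fit` objects sharing one response.
#' @return A tibble sorted best-first: `metric`, `r_squared`, `aic`,
#'   `delta_aic` (relative to the best model), `p_value`, `n`, and `tie`
#'   (TRUE where delta_aic == 0 is shared by several metrics).
#' @export
rank_metrics <- function(fits) {
  if (length(fits) < 2) rlang::abort("need >= 2 fits to rank.")
  ys <- lapply(fits, function(f) sort(f$y))
  same <- vapply(ys[-1], function(y) isTRUE(all.equal(y, ys[[1]])),
                 logical(1))
  if (!all(same)) {
    rlang::abort("all fits must share the same response vector.")
  }
  tab <- purrr::map_dfr(fits, glance.dose_fit) |>
    dplyr::arrange(.data$aic, dplyr::desc(.data$r_squared)) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic))
  tab$tie <- duplicated(tab$delta_aic) | duplicated(tab$delta_aic,
                                                    fromLast = TRUE)
  dplyr::relocate(tab, "metric", "r_squared", "aic", "delta_aic")
}

#' One-way ANOVA with Tukey contrasts on per-tree means
#'
#' Compares treatment groups on per-tree period means (one value per tree)
#' with one-way ANOVA, Tukey HSD pairwise contrasts, and a compact letter
#' display.
#'
#' @param data Data frame with the response and a grouping column.
#' @param response,group Column names (strings).
#' @return A list with `f` (ANOVA F), `p` (ANOVA p-value), `tukey` (tibble
#'   of pairwise contrasts with estimates and adjusted p-values) and
#'   `letters` (named character vector: groups sharing a letter do not
#'   differ at alpha = 0.05).
#' @export
group_compare <- function(data, response, group) {
  df <- data.frame(y = data[[response]],
                   g = factor(data[[group]]))
  df <- df[stats::complete.cases(df), ]
  counts <- table(df$g)
  if (length(counts) < 2) rlang::abort("need >= 2 groups.")
  if (any(counts < 2)) rlang::abort("each group needs >= 2 trees.")
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  if (stats::var(df$y) == 0) {
    # identical values everywhere: F = 0, all groups share one letter
    letters_out <- stats::setNames(rep("a", length(counts)), names(counts))
    return(list(f = 0, p = 1,
                tukey = tibble::tibble(contrast = character(),
                                       estimate = numeric(),
                                       p_adj = numeric()),
                letters = letters_out))
  }
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  sm <- summary(glht_fit)
  cld <- multcomp::cld(glht_fit)
  tukey <- tibble::tibble(
    contrast = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    p_adj = unname(sm$test$pvalues)
  )
  list(
    f = an[["F value"]][1],
    p = an[["Pr(>F)"]][1],
    tukey = tukey,
    letters = cld$mcletters$Letters
  )
}

#' Two-sample t test on per-treatment minima
#'
#' Compares minimum water potential (or any per-tree scalar) between two
#' treatments with a Student's t test.
#'
#' @param x,y Numeric vectors of per-tree values for the two treatments
#'   (each n >= 2).
#' @param var_equal Pooled-variance Student's t (default, matching the
#'   classical test) or Welch when `FALSE`.
#' @return A tibble with `t`, `df`, `p_value`, and the two group means.
#' @export
welch_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each group needs n >= 2.")
  }
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    # degenerate: no within-group variance; report rather than crash
    ident <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(t = if (ident) 0 else Inf,
                          df = length(x) + length(y) - 2,
                          p_value = if (ident) 1 else 0,
                          mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}
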
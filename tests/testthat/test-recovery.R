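# Recovery indices, dose-response fits, ranking and group statistics.

test_that("recovery index is the percent ratio and scale-invariant", {
  expect_equal(recovery_index(0.5, 1), 50)
  expect_equal(recovery_index(c(2, 1), 2), c(100, 50))
  expect_equal(recovery_index(3 * 0.5, 3 * 1), recovery_index(0.5, 1))
  expect_error(recovery_index(1, 0), "positive")
})

test_that("dose_response_fit matches the normal-equations oracle", {
  set.seed(21)
  df <- tibble::tibble(x = rnorm(18, 5, 2), y = 80 - 4 * rnorm(18) - 3 *
                         rnorm(18))
  fit <- dose_response_fit(df, "y", "x")
  orc <- oracle_ols(df$x, df$y)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(fit$ss_res, orc$ss_res, tolerance = 1e-12)
  n <- nrow(df)
  expect_equal(fit$aic, n * log(orc$ss_res / n) + 2 * 3, tolerance = 1e-12)
  expect_equal(fit$n, n)
})

test_that("dose_response_fit recovers an exact linear relation", {
  df <- tibble::tibble(x = 1:6, y = 10 - 2 * (1:6))
  # lm warns about the (intended) perfect fit
  fit <- suppressWarnings(dose_response_fit(df, "y", "x"))
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r_squared, 1)
})

test_that("dose_response_fit validates input", {
  expect_error(dose_response_fit(tibble::tibble(x = 1:2, y = 1:2), "y", "x"),
               ">= 3")
  expect_error(dose_response_fit(tibble::tibble(x = rep(1, 5), y = 1:5),
                                 "y", "x"),
               "zero variance")
})

test_that("tidy and glance on dose_fit", {
  df <- tibble::tibble(dose = c(1, 2, 4, 6, 9), r = c(90, 80, 66, 50, 30))
  fit <- dose_response_fit(df, "r", "dose")
  td <- generics::tidy(fit)
  expect_equal(td$term, c("(Intercept)", "dose"))
  expect_equal(unname(td$estimate[2]), fit$slope)
  gl <- generics::glance(fit)
  expect_equal(gl$aic, fit$aic)
  expect_output(print(fit), "AIC")
})

test_that("rank_metrics orders by AIC and demands a shared response", {
  set.seed(22)
  n <- 16
  x <- rnorm(n)
  y <- 50 + 10 * x + rnorm(n, 0, 1)
  noise <- rnorm(n)
  df <- tibble::tibble(y = y, good = x, bad = noise)
  fits <- list(good = dose_response_fit(df, "y", "good"),
               bad = dose_response_fit(df, "y", "bad"))
  rk <- rank_metrics(fits)
  expect_equal(rk$metric[1], "good")
  expect_equal(rk$delta_aic[1], 0)
  expect_true(all(diff(rk$aic) >= 0))
  expect_false(any(rk$tie))
  other <- dose_response_fit(tibble::tibble(y = rev(y) + 1, m = x), "y", "m")
  expect_error(rank_metrics(list(fits$good, other)), "same response")
  expect_error(rank_metrics(fits[1]), ">= 2 fits")
})

test_that("group_compare runs ANOVA with Tukey letters", {
  set.seed(23)
  df <- tibble::tibble(
    g = rep(c("control", "short", "long"), c(4, 5, 9)),
    y = c(rnorm(4, 100, 3), rnorm(5, 66, 3), rnorm(9, 41, 3))
  )
  out <- group_compare(df, "y", "g")
  expect_lt(out$p, 1e-6)
  expect_equal(sort(names(out$letters)), sort(unique(df$g)))
  # all three groups clearly separated: three distinct letters
  expect_equal(length(unique(out$letters)), 3)
  expect_equal(nrow(out$tukey), 3)
  expect_true(all(out$tukey$p_adj < 0.01))
})

test_that("group_compare handles the degenerate all-equal case", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = 1)
  out <- group_compare(df, "y", "g")
  expect_equal(out$p, 1)
  expect_equal(unname(unique(out$letters)), "a")
  expect_error(group_compare(df[1:3, ], "y", "g"), ">= 2 groups")
})

test_that("welch_t matches stats::t.test", {
  set.seed(24)
  x <- rnorm(5, -3.2, 0.3); y <- rnorm(9, -4.1, 0.3)
  out <- welch_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
  outw <- welch_t(x, y, var_equal = FALSE)
  refw <- t.test(x, y)
  expect_equal(outw$df, unname(refw$parameter))
  expect_error(welch_t(1, y), "n >= 2")
  deg <- welch_t(c(1, 1), c(1, 1))
  expect_equal(deg$p_value, 1)
})

test_that("recovery_table expresses drought trees against control means", {
  base <- as.POSIXct("2021-08-28", tz = "UTC")  # DOY 240
  mk <- function(id, trt, e, g) {
    tibble::tibble(timestamp = base + c(0, 86400) + 12 * 3600,
                   chamber_id = id, treatment = trt, e_c = e, g_c = g)
  }
  fl <- dplyr::bind_rows(
    mk("c1", "control", 2e-5, 1.0), mk("c2", "control", 4e-5, 3.0),
    mk("d1", "long", 1.5e-5, 0.8)
  )
  out <- recovery_table(fl, c(240, 241))
  expect_equal(nrow(out), 1)
  expect_equal(out$r_ec, 100 * 1.5e-5 / 3e-5)
  expect_equal(out$r_gc, 100 * 0.8 / 2.0)
  expect_error(recovery_table(fl[fl$treatment != "control", ],
                              c(240, 241)),
               "no control")
})
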
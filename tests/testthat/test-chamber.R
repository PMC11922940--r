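# Chamber flux equations, frozen against hand-derived values.

test_that("saturation vapor pressure matches hand-computed Tetens values", {
  expect_equal(saturation_vapor_pressure(25), 3.16777771751, tolerance = 1e-9)
  expect_equal(saturation_vapor_pressure(21), 2.48700539727, tolerance = 1e-9)
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  expect_error(saturation_vapor_pressure(-240), "Tetens")
})

test_that("saturation vapor pressure is strictly increasing in temperature", {
  t <- seq(-20, 45, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(t)) > 0))
})

test_that("actual vapor pressure matches the mixing-ratio conversion", {
  expect_equal(actual_vapor_pressure(0.005, 100), 0.797473603624,
               tolerance = 1e-9)
  expect_equal(actual_vapor_pressure(0, 100), 0)
  expect_error(actual_vapor_pressure(-0.001, 100), "non-negative")
  expect_error(actual_vapor_pressure(0.005, 0), "positive")
})

test_that("vpd is the plain difference and can be negative", {
  expect_equal(vpd(3.2, 1.1), 2.1)
  expect_equal(vpd(1.0, 1.5), -0.5)
})

test_that("canopy transpiration matches the mass-balance oracle", {
  # mdot = 0.01 mol/s, w_sample = 10.3, w_supply = 8.3 mmol/mol:
  # E = 0.01 * (0.0103 - 0.0083) / (1 - 0.0103)
  expect_equal(canopy_transpiration(0.01, 10.3, 8.3), 2.0208143882e-05,
               tolerance = 1e-9)
  expect_equal(canopy_transpiration(0.01, 8.3, 8.3), 0)
  expect_error(canopy_transpiration(0.01, 1000, 8.3), "mole fraction")
})

test_that("leaf transpiration is canopy transpiration per needle area", {
  expect_equal(leaf_transpiration(0.01, 10.3, 8.3, 0.102),
               0.000198119057667, tolerance = 1e-9)
  expect_error(leaf_transpiration(0.01, 10.3, 8.3, 0), "positive")
})

test_that("needle vapor content matches es(T)/P", {
  expect_equal(needle_vapor_content(25, 101.325), 31.2635353319,
               tolerance = 1e-9)
})

test_that("canopy conductance matches the hand-derived value", {
  e_c <- canopy_transpiration(0.01, 10.3, 8.3)
  wn <- needle_vapor_content(25, 101.325)
  expect_equal(canopy_conductance(e_c, wn, 10.3), 0.94393348343,
               tolerance = 1e-9)
})

test_that("canopy conductance returns NA under condensation", {
  expect_true(is.na(canopy_conductance(1e-5, 10, 10)))
  expect_true(is.na(canopy_conductance(1e-5, 9, 10)))
  expect_false(is.na(canopy_conductance(1e-5, 11, 10)))
})

test_that("stomatal_conductance is the same formula as canopy_conductance", {
  expect_identical(stomatal_conductance, canopy_conductance)
})

make_chamber_records <- function(w_sample, t_air = 25, mdot = 0.01,
                                 w_supply = 8.3) {
  tibble::tibble(
    timestamp = as.POSIXct("2021-08-01 12:00", tz = "UTC") +
      seq_along(w_sample) * 1800,
    chamber_id = "tree_01",
    t_air = t_air, p = 101.325, mdot = mdot,
    w_supply = w_supply, w_sample = w_sample
  )
}

test_that("compute_fluxes reproduces the elementary equations row-wise", {
  rec <- make_chamber_records(c(9.1, 10.3, 12.0))
  fl <- compute_fluxes(rec)
  expect_s3_class(fl, "tbl_df")
  expect_equal(fl$e_c, canopy_transpiration(0.01, rec$w_sample, 8.3))
  expect_equal(fl$g_c, canopy_conductance(fl$e_c, fl$w_needle, rec$w_sample))
  expect_equal(fl$vpd_kpa,
               saturation_vapor_pressure(25) - rec$w_sample / 1000 * 101.325)
  expect_true(all(fl$qc_flag == "ok"))
})

test_that("compute_fluxes subtracts a constant empty-chamber offset", {
  rec <- make_chamber_records(c(9.1, 10.3, 12.0))
  fl0 <- compute_fluxes(rec)
  fl <- compute_fluxes(dplyr::mutate(rec, w_sample = w_sample + 0.25),
                       empty_chamber_offset = 0.25)
  expect_equal(fl$e_c, fl0$e_c)
  expect_equal(fl$g_c, fl0$g_c)
})

test_that("compute_fluxes uses a named empty chamber per timestamp", {
  rec <- make_chamber_records(c(9.1, 10.3, 12.0))
  offs <- c(0.1, 0.3, 0.2)
  empty <- dplyr::mutate(rec, chamber_id = "empty",
                         w_sample = w_supply + offs)
  both <- dplyr::bind_rows(dplyr::mutate(rec, w_sample = w_sample + offs),
                           empty)
  fl <- compute_fluxes(both, empty_chamber_offset = "empty")
  expect_false("empty" %in% fl$chamber_id)
  expect_equal(fl$e_c, compute_fluxes(rec)$e_c)
})

test_that("compute_fluxes flags condensation rows", {
  rec <- make_chamber_records(c(10.3, 40), t_air = c(25, 25))
  fl <- compute_fluxes(rec)
  expect_equal(fl$qc_flag, c("ok", "condensation"))
  expect_true(is.na(fl$g_c[2]))
})

test_that("compute_fluxes errors on missing columns", {
  rec <- make_chamber_records(10.3)
  expect_error(compute_fluxes(rec[, setdiff(names(rec), "mdot")]), "mdot")
})

test_that("qc_filter keeps daytime records and removes spikes", {
  n <- 200
  set.seed(7)
  base <- as.POSIXct("2021-08-01 08:00", tz = "UTC")
  fl <- tibble::tibble(
    timestamp = base + seq_len(n) * 120,
    chamber_id = "tree_01",
    e_c = 2e-5 + rnorm(n, 0, 1e-7),
    qc_flag = "ok"
  )
  fl$e_c[c(10, 50)] <- c(5e-4, -4e-4)  # gross spikes
  out <- qc_filter(fl)
  expect_false(any(out$data$e_c > 1e-4 | out$data$e_c < 0))
  expect_equal(out$retention, nrow(out$data) / n)
  expect_gt(out$retention, 0.9)
})

test_that("qc_filter is idempotent", {
  set.seed(8)
  fl <- tibble::tibble(
    timestamp = as.POSIXct("2021-08-01 08:00", tz = "UTC") + 1:300 * 120,
    chamber_id = rep(c("a", "b"), length.out = 300),
    e_c = rnorm(300, 2e-5, 4e-6),
    qc_flag = "ok"
  )
  once <- qc_filter(fl)
  twice <- qc_filter(once$data)
  expect_equal(twice$data$e_c, once$data$e_c)
  expect_equal(twice$retention, 1)
})

test_that("qc_filter drops nighttime and non-ok records from the pool", {
  fl <- tibble::tibble(
    timestamp = as.POSIXct(c("2021-08-01 03:00", "2021-08-01 12:00",
                             "2021-08-01 12:30"), tz = "UTC"),
    chamber_id = "a",
    e_c = c(2e-5, 2e-5, 2.1e-5),
    qc_flag = c("ok", "ok", "condensation")
  )
  out <- qc_filter(fl)
  expect_equal(nrow(out$data), 1)
  expect_equal(out$retention, 1)  # the single daytime-ok record is retained
  empty <- qc_filter(fl[0, ])
  expect_true(is.na(empty$retention))
})
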
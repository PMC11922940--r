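# Generator properties: determinism, ground-truth consistency, round trips.

cfg0 <- experiment_config(noise_sd = "none",
                          dendro_cadence_min = 120,
                          chamber_cadence_min = 120)

test_that("identical (config, seed) give identical experiments", {
  e1 <- simulate_experiment(experiment_config(seed = 77))
  e2 <- simulate_experiment(experiment_config(seed = 77))
  expect_equal(e1$chamber, e2$chamber)
  expect_equal(e1$dendro, e2$dendro)
  expect_equal(e1$psi, e2$psi)
  expect_equal(e1$vc, e2$vc)
  expect_equal(e1$truth, e2$truth)
  e3 <- simulate_experiment(experiment_config(seed = 78))
  expect_false(isTRUE(all.equal(e1$psi$psi_md, e3$psi$psi_md)))
})

test_that("noiseless chamber stream round-trips through compute_fluxes", {
  ex <- simulate_experiment(cfg0)
  fl <- compute_fluxes(ex$chamber, empty_chamber_offset = "empty")
  truth <- ex$chamber[ex$chamber$chamber_id != "empty", ]
  day <- fl$qc_flag == "ok" & truth$g_true > 0
  expect_equal(fl$e_c[day], truth$e_true[day], tolerance = 1e-9)
  expect_equal(fl$g_c[day], truth$g_true[day], tolerance = 1e-9)
})

test_that("invert_conductance is the exact inverse of the flux equations", {
  wn <- needle_vapor_content(25, 101.325)
  for (g in c(0, 0.05, 0.4, 0.95)) {
    ws <- invert_conductance(g, 0.0095, 8.3, wn)
    e <- canopy_transpiration(0.0095, ws, 8.3)
    g_back <- canopy_conductance(e, wn, ws)
    if (g == 0) {
      expect_equal(ws, 8.3, tolerance = 1e-9)
    } else {
      expect_equal(g_back, g, tolerance = 1e-9)
    }
    # the solution always stays strictly inside [w_supply, w_needle)
    expect_gte(ws, 8.3 - 1e-9)
    expect_lt(ws, wn)
  }
})

test_that("noiseless dendrometer partition recovers the planted TWD", {
  ex <- simulate_experiment(cfg0)
  part <- zero_growth_partition(ex$dendro)
  daily <- daily_twd(part)
  # planted daily TWD = slope * deficit from the psi truth
  truth_twd <- ex$psi_truth |>
    dplyr::mutate(twd_true = cfg0$twd_psi_slope *
                    pmax(0, cfg0$psi_baseline - psi))
  j <- dplyr::inner_join(daily, truth_twd,
                         by = c("tree_id", "day"))
  expect_equal(j$twd, j$twd_true, tolerance = 1e-9)
})

test_that("truth metrics are internally consistent with the daily truth", {
  ex <- simulate_experiment(experiment_config(seed = 31))
  cfg <- ex$config
  p12 <- weibull_px(12, cfg$vc_scale_b, cfg$vc_shape_c)
  tr <- ex$truth[ex$truth$treatment == "long", ][1, ]
  df <- ex$psi_truth[ex$psi_truth$tree_id == tr$tree_id, ]
  w <- cfg$drought_windows$long
  sub <- df[df$day >= w[1] & df$day <= w[2] - 1, ]
  expect_equal(tr$psi_min, min(sub$psi))
  expect_equal(tr$dp12, sum(sub$psi < p12))
  expect_equal(tr$psi_cum, sum(pmin(sub$psi - cfg$psi_baseline, 0)))
  below <- sub$day[sub$psi < p12]
  expect_equal(tr$twd_p12,
               cfg$twd_psi_slope *
                 sum(pmax(0, cfg$psi_baseline - sub$psi[sub$day %in% below])))
})

test_that("planted damage is monotone in the dose and control is benign", {
  ex <- simulate_experiment(experiment_config(seed = 32))
  tr <- ex$truth
  o <- order(tr$twd_p12)
  expect_true(all(diff(tr$pla_true[o]) >= 0))
  expect_true(all(diff(tr$shed_frac_true[o]) >= 0))
  expect_true(all(diff(tr$rec_frac_true[o]) <= 0))
  ctrl <- tr[tr$treatment == "control", ]
  expect_true(all(ctrl$dp12 == 0))
  expect_true(all(ctrl$twd_p12 == 0))
  expect_true(all(ctrl$rec_frac_true == pmin(ex$config$recovery_intercept, 1)))
})

test_that("psi observations sample the truth at the configured cadence", {
  ex <- simulate_experiment(cfg0)
  obs <- ex$psi[ex$psi$tree_id == ex$psi$tree_id[1], ]
  expect_true(all(diff(obs$day) <= cfg0$psi_every))
  # last drought days are always sampled
  expect_true(all(vapply(cfg0$drought_windows,
                         function(w) (w[2] - 1) %in% obs$day, logical(1))))
  # zero noise: observations equal the truth on sampled days
  j <- dplyr::inner_join(ex$psi, ex$psi_truth,
                         by = c("tree_id", "treatment", "day"))
  expect_equal(j$psi_md, j$psi, tolerance = 1e-12)
})

test_that("injected dendrometer jumps are removed by clean_dendro", {
  jumps <- tibble::tibble(tree_id = "long_01", day = 220, size = -1.8)
  trees <- simulate_trees(cfg0)
  pt <- simulate_psi_truth(cfg0, trees)
  clean <- simulate_dendro(cfg0, pt, trees)
  broken <- simulate_dendro(cfg0, pt, trees, inject_jumps = jumps)
  fixed <- clean_dendro(broken)
  i <- clean$tree_id == "long_01"
  # correction leaves at most the concurrent daily physiological step
  expect_lt(max(abs(fixed$d[fixed$tree_id == "long_01"] - clean$d[i])),
            0.01)
  expect_true("jump_corrected" %in% fixed$clean_flag)
})

test_that("relative TWD peaks in the long drought near one tenth of diameter", {
  ex <- simulate_experiment(cfg0)
  part <- zero_growth_partition(ex$dendro)
  peaks <- part |>
    dplyr::left_join(dplyr::distinct(ex$truth, tree_id, treatment),
                     by = "tree_id") |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(peak = max(twd_rel), .groups = "drop")
  expect_equal(peaks$peak[peaks$treatment == "control"], 0)
  expect_gt(peaks$peak[peaks$treatment == "long"], 8)
  expect_lt(peaks$peak[peaks$treatment == "long"], 10)
  expect_lt(peaks$peak[peaks$treatment == "short"],
            peaks$peak[peaks$treatment == "long"])
})

test_that("write_experiment emits all six streams", {
  dir <- tempfile("streams")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ex <- simulate_experiment(experiment_config(
    n_trees = c(control = 2, short = 2, long = 2), seed = 3))
  paths <- write_experiment(ex, dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "psi.csv"))
  expect_equal(nrow(back), nrow(ex$psi))
})
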
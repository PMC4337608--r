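test_that("generators are byte-deterministic under a fixed seed", {
  d1 <- withr_tempdir_lite()
  d2 <- withr_tempdir_lite()
  cfg <- sim_config(qpcr = list(n_brains = c(AD = 1, ND = 1), n_nuclei_ctx = 3,
                                n_nuclei_cbl = 2),
                    flow = list(n_events = 1000, n_cen = 300),
                    fish = list(n_brains = c(AD = 2, ND = 2)),
                    pna = list(n_nuclei = c(AD = 5, ND = 5, DS = 5)))
  write_simulation(d1, cfg, seed = 9)
  write_simulation(d2, cfg, seed = 9)
  for (f in list.files(d1)) {
    expect_identical(readr::read_file(file.path(d1, f)),
                     readr::read_file(file.path(d2, f)),
                     info = f)
  }
  d3 <- withr_tempdir_lite()
  write_simulation(d3, cfg, seed = 10)
  expect_false(identical(readr::read_file(file.path(d1, "ct_replicates.csv")),
                         readr::read_file(file.path(d3, "ct_replicates.csv"))))
})

test_that("the noiseless forward model inverts exactly to RCN = copy number", {
  cfg <- sim_config(qpcr = list(
    groups = "G", n_brains = c(G = 1), n_nuclei_ctx = 4, n_nuclei_cbl = 2,
    ct_noise_sd = 0, target_assays = "APP_ex3",
    efficiencies = c(APP_ex3 = 1, SEMA4A = 1),
    mixtures_ctx = list(G = c(`2` = 1))
  ))
  sim <- simulate_ct_table(cfg, seed = 1)
  est <- suppressMessages(rcn_table(sim$ct_replicates, "APP_ex3",
                                    efficiencies = c(APP_ex3 = 1)))
  expect_equal(est$rcn, rep(2, nrow(est)), tolerance = 1e-12)

  # and at E = 0.973 the efficiency-aware inversion still recovers CN 3
  cfg3 <- sim_config(qpcr = list(
    groups = "G", n_brains = c(G = 1), n_nuclei_ctx = 4, n_nuclei_cbl = 2,
    ct_noise_sd = 0, target_assays = "APP_ex14",
    efficiencies = c(APP_ex14 = 0.973, SEMA4A = 1),
    mixtures_ctx = list(G = c(`3` = 1))
  ))
  sim3 <- simulate_ct_table(cfg3, seed = 1)
  est3 <- suppressMessages(rcn_table(sim3$ct_replicates, "APP_ex14",
                                     efficiencies = c(APP_ex14 = 0.973)))
  ctx3 <- est3[grepl("CTX", est3$unit_id), ]
  expect_equal(ctx3$rcn, rep(3, nrow(ctx3)), tolerance = 1e-12)
})

test_that("a 12-copy nucleus is called beyond the last bin", {
  cfg <- sim_config(qpcr = list(
    groups = "G", n_brains = c(G = 1), n_nuclei_ctx = 3, n_nuclei_cbl = 4,
    target_assays = "APP_ex3", efficiencies = c(APP_ex3 = 1, SEMA4A = 1),
    mixtures_ctx = list(G = c(`12` = 1))
  ))
  sim <- simulate_ct_table(cfg, seed = 13)
  est <- suppressMessages(rcn_table(sim$ct_replicates, "APP_ex3",
                                    efficiencies = c(APP_ex3 = 1)))
  calls <- call_copy_number(est, build_bounds_table())
  ctx <- calls[grepl("CTX", calls$unit_id), ]
  expect_true(all(ctx$bin == ">6"))
})

test_that("invalid mixtures raise a config error", {
  cfg <- sim_config(qpcr = list(mixtures_ctx = list(AD = c(`2` = 0.5, `3` = 0.4))))
  expect_error(simulate_ct_table(cfg, seed = 1), class = "nm_config_error")
})

test_that("simulated flow samples carry their configured DNA index", {
  cfg <- sim_config(flow = list(groups = list(
    LYM = list(n_samples = 1, di_mean = 1, di_sd = 0, shoulder_fraction = 0),
    T08 = list(n_samples = 2, di_mean = 1.08, di_sd = 0, shoulder_fraction = 0)
  ), n_events = 6000, n_cen = 1500))
  fl <- simulate_flow_events(cfg, seed = 17)
  d <- dcv_sample_stats(fl$events, reference_id = "LYM_1")
  t08 <- d[d$group == "T08", ]
  expect_equal(t08$di, rep(1.08, 2), tolerance = 0.005)
  lym <- d[d$sample_id == "LYM_1", ]
  expect_equal(lym$percent_change, 0)

  # a right shoulder produces positive skew
  cfg_sh <- sim_config(flow = list(groups = list(
    LYM = list(n_samples = 1, di_mean = 1, di_sd = 0, shoulder_fraction = 0),
    SH = list(n_samples = 1, di_mean = 1, di_sd = 0, shoulder_fraction = 0.3)
  ), n_events = 6000, n_cen = 1500))
  fl_sh <- simulate_flow_events(cfg_sh, seed = 18)
  d_sh <- suppressWarnings(dcv_sample_stats(fl_sh$events, reference_id = "LYM_1"))
  expect_gt(d_sh$skew[d_sh$group == "SH"], d_sh$skew[d_sh$group == "LYM"])
  expect_gt(d_sh$skew[d_sh$group == "SH"], 0)
})

test_that("simulated standard curves round-trip the efficiency", {
  sc <- suppressWarnings(
    fit_standard_curve(simulate_standard_curve(efficiency = 1, noise_sd = 0))
  )
  expect_equal(sc$efficiency, 1, tolerance = 1e-6)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
})

test_that("null FISH simulations carry no group signal", {
  fc <- simulate_fish_counts(sim_config(), seed = 19)
  r <- aneusomy_rates(fc)
  expect_equal(nrow(r), 14L)  # 9 + 5 brains
  expect_equal(sum(fc$n_nuclei), (9 + 5) * 2 * 500)
  s <- aneusomy_group_summary(r)
  wide <- tidyr::pivot_wider(s[, c("group", "class", "mean_rate")],
                             names_from = "group", values_from = "mean_rate")
  expect_equal(wide$AD, wide$ND, tolerance = 0.02)
})
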
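test_that("standard-curve efficiency follows the slope formula", {
  # slope -1/log10(2): exact doubling per cycle
  pts <- tibble::tibble(log10_copies = 1:5, ct = 38 - 3.32193 * (1:5))
  sc <- suppressWarnings(fit_standard_curve(pts))
  expect_equal(sc$slope, -3.32193, tolerance = 1e-8)
  expect_equal(sc$efficiency, 1, tolerance = 1e-5)
  expect_true(sc$usable)

  # algebraic oracle: E = 10^(1/3.38840) - 1
  pts2 <- tibble::tibble(log10_copies = 1:5, ct = 38 - 3.38840 * (1:5))
  sc2 <- suppressWarnings(fit_standard_curve(pts2))
  expect_equal(sc2$efficiency, 10^(1 / 3.38840) - 1, tolerance = 1e-10)
  expect_equal(sc2$efficiency, 0.973, tolerance = 5e-4)

  g <- glance(sc2)
  expect_s3_class(g, "tbl_df")
  expect_identical(names(g)[1:5],
                   c("assay_id", "slope", "intercept", "r_squared", "efficiency"))
})

test_that("noisy curves below the R-squared threshold are flagged unusable", {
  pts <- tibble::tibble(
    log10_copies = rep(1:4, each = 2),
    ct = 38 - 3.3 * rep(1:4, each = 2) + c(1.5, -1.5, 1.2, -1.2, 1.5, -1.5, 1, -1)
  )
  sc <- fit_standard_curve(pts)
  expect_lt(sc$r_squared, 0.99)
  expect_false(sc$usable)
  # a curve with R^2 just under the cut is unusable even if nearly linear
  expect_identical(sc$usable, sc$r_squared > 0.99)
})

test_that("degenerate dilution series are rejected", {
  expect_error(
    fit_standard_curve(tibble::tibble(log10_copies = c(1, 2), ct = c(30, 27))),
    class = "nm_invalid_input"
  )
  expect_error(
    fit_standard_curve(tibble::tibble(log10_copies = 1:4, ct = c(20, 23, 26, 29))),
    class = "nm_degenerate_curve"
  )
})

test_that("efficiency round-trips through the simulated dilution series", {
  for (e in c(0.90, 0.973, 1.0, 1.05)) {
    pts <- simulate_standard_curve(efficiency = e, noise_sd = 0)
    sc <- suppressWarnings(fit_standard_curve(pts))
    expect_equal(sc$efficiency, e, tolerance = 1e-6)
  }
})

test_that("replicate means enforce the minimum-replicate QC rule", {
  expect_equal(
    mean_ct(make_ct_rows(rep(21.37, 18)), "u1", "APP_ex3"),
    tibble::tibble(mean_ct = 21.37, n_reps = 18L)
  )
  expect_equal(
    mean_ct(make_ct_rows(rep(c(20, 21, 22), 6)), "u1", "APP_ex3"),
    tibble::tibble(mean_ct = 21, n_reps = 18L)
  )
  expect_error(
    mean_ct(make_ct_rows(rep(21, 9)), "u1", "APP_ex3"),
    class = "nm_qc_failure"
  )
  # exactly at the threshold is analyzable
  expect_equal(mean_ct(make_ct_rows(rep(21, 10)), "u1", "APP_ex3")$n_reps, 10L)
})

test_that("summarize_ct drops failing pairs and supports MAD filtering", {
  tbl <- dplyr::bind_rows(
    make_ct_rows(rep(21, 18), unit_id = "ok"),
    make_ct_rows(rep(22, 6), unit_id = "fail")
  )
  out <- suppressMessages(summarize_ct(tbl))
  expect_identical(out$unit_id, "ok")
  kept <- suppressMessages(summarize_ct(tbl, drop_failed = FALSE))
  expect_identical(kept$qc_pass, c(FALSE, TRUE))

  # one wild replicate is removed by the optional MAD filter only
  spiked <- make_ct_rows(c(rep(21, 17), 35))
  plain <- suppressMessages(summarize_ct(spiked))
  madded <- suppressMessages(summarize_ct(spiked, mad_filter = TRUE))
  expect_gt(plain$mean_ct, 21.7)
  expect_equal(madded$mean_ct, 21)
  expect_equal(madded$n_reps, 17L)
})

test_that("delta-delta-Ct is the sample delta-Ct minus the calibrator mean", {
  d <- function(dct) tibble::tibble(
    delta_ct = dct, target_assay = "APP_ex3", reference_assay = "SEMA4A"
  )
  expect_equal(delta_delta_ct(d(2.0), d(c(3.0, 3.2, 2.8))), -1.0)
  expect_equal(delta_delta_ct(d(1.5), d(1.5)), 0)
  bad <- tibble::tibble(delta_ct = 1, target_assay = "other",
                        reference_assay = "SEMA4A")
  expect_error(delta_delta_ct(d(1), bad), class = "nm_invalid_input")
  expect_error(delta_delta_ct(d(1), d(numeric(0))), class = "nm_invalid_input")
})

test_that("RCN point estimates follow 2 (1+E)^-ddct", {
  expect_equal(rcn_point_and_ci(0, efficiency = 1)$rcn, 2.00)
  expect_equal(rcn_point_and_ci(-1, efficiency = 1)$rcn, 4.00)
  expect_equal(rcn_point_and_ci(-1, efficiency = 0.973)$rcn, 3.946)
})

test_that("RCN is monotone in ddct and its CI is log-symmetric", {
  ddct <- seq(-3, 3, by = 0.25)
  est <- rcn_point_and_ci(ddct, efficiency = 0.95)
  expect_true(all(diff(est$rcn) < 0))
  expect_true(all(est$ci_low <= est$rcn & est$rcn <= est$ci_high))
  expect_equal(log(est$ci_high / est$rcn), log(est$rcn / est$ci_low),
               tolerance = 1e-12)
  # with the rounded critical value, 18 reps and sd 0.25 the multiplicative
  # half-width at E = 1 is 2^(2 * 0.25 / sqrt(18))
  e1 <- rcn_point_and_ci(0, efficiency = 1, t_mode = "rounded2")
  expect_equal(e1$ci_high / e1$rcn, 2^(2 * 0.25 / sqrt(18)), tolerance = 1e-12)
  expect_equal(e1$ci_high / e1$rcn, 1.08512, tolerance = 1e-5)
})

test_that("ratio-formula quantification matches the single-efficiency form when efficiencies agree", {
  cfg <- sim_config(qpcr = list(n_brains = c(AD = 1, ND = 1), n_nuclei_ctx = 4,
                                target_assays = "APP_ex3",
                                efficiencies = c(APP_ex3 = 0.95, SEMA4A = 0.95)))
  sim <- simulate_ct_table(cfg, seed = 11)
  eff <- c(APP_ex3 = 0.95, SEMA4A = 0.95)
  lit <- suppressMessages(rcn_table(sim$ct_replicates, "APP_ex3",
                                    efficiencies = eff, method = "literal"))
  rat <- suppressMessages(rcn_table(sim$ct_replicates, "APP_ex3",
                                    efficiencies = eff, method = "ratio"))
  expect_equal(rat$rcn, lit$rcn, tolerance = 1e-10)
  expect_equal(rat$ci_low, lit$ci_low, tolerance = 1e-10)
})

test_that("cohort-mode regional test flags a dosage difference and not a null", {
  cfg <- sim_config(qpcr = list(
    n_brains = c(AD = 1, ND = 1), n_nuclei_ctx = 3, n_nuclei_cbl = 3,
    n_replicates = 3, target_assays = "APP_ex3",
    efficiencies = c(APP_ex3 = 1, SEMA4A = 1),
    mixtures_ctx = list(AD = c(`4` = 1), ND = c(`2` = 1))
  ))
  sim <- simulate_ct_table(cfg, seed = 5)
  res <- cohort_region_test(sim$ct_replicates, "APP_ex3")
  amp <- res[res$brain_id == "AD_1", ]
  nul <- res[res$brain_id == "ND_1", ]
  expect_lt(amp$p_value, 0.01)
  expect_lt(amp$diff, 0)  # amplified cortex reaches threshold earlier
  expect_gt(nul$p_value, 0.05)
})
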
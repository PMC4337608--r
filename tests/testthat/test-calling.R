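test_that("modeled bounds reproduce the published table with the rounded critical value", {
  b <- build_bounds_table(t_mode = "rounded2")
  expect_equal(round(b$lower, 5), published_bounds$lower)
  expect_equal(round(b$upper, 5), published_bounds$upper)
  # exact Student-t quantile agrees to ~2e-4 relative
  be <- build_bounds_table(t_mode = "exact")
  expect_equal(be$lower, published_bounds$lower, tolerance = 5e-4)
  expect_equal(be$upper, published_bounds$upper, tolerance = 5e-4)
})

test_that("bounds scale multiplicatively and overlap first at 6 vs 7", {
  b <- build_bounds_table(k_max = 7, t_mode = "rounded2")
  expect_equal(b$lower, b$k * b$lower[1], tolerance = 1e-14)
  expect_equal(b$upper, b$k * b$upper[1], tolerance = 1e-14)
  # consecutive intervals disjoint through 5 vs 6, overlapping at 6 vs 7
  for (k in 1:5) expect_lt(b$upper[k], b$lower[k + 1])
  expect_gt(b$upper[6], b$lower[7])
  expect_lt(b$lower[7], 6.51070)
})

test_that("the caller assigns bins by CI overlap with the modeled intervals", {
  b <- build_bounds_table(t_mode = "rounded2")
  one <- call_copy_number(est_row(2.0, 1.9, 2.1), b)
  expect_identical(one$bin, "2")
  expect_false(one$ambiguous || one$gap_assigned)

  three <- call_copy_number(est_row(3.2, 3.1, 3.3), b)
  expect_identical(three$bin, "3")
  expect_false(three$ambiguous)

  high <- call_copy_number(est_row(12, 11.2, 13.2), b)
  expect_identical(high$bin, ">6")
  expect_identical(high$bin_numeric, 7)
  expect_identical(call_copy_number(est_row(12, 11.2, 13.2), b,
                                    gt6_rule = "point")$bin, ">6")
})

test_that("ambiguous and gap-falling estimates get nearest-k with flags", {
  b <- build_bounds_table(t_mode = "rounded2")
  amb <- call_copy_number(est_row(2.5, 2.1, 2.9), b)
  # overlaps both CN2 and CN3; 2.5 is nearer 3 on the log2 scale
  expect_identical(amb$bin, "3")
  expect_true(amb$ambiguous)

  gap <- call_copy_number(est_row(1.2, 1.15, 1.25), b)
  expect_identical(gap$bin, "1")
  expect_true(gap$gap_assigned)
  expect_false(gap$ambiguous)

  low <- call_copy_number(est_row(0.7, 0.65, 0.75), b)
  expect_identical(low$bin, "1")  # bins start at 1; below-range calls 1 with flag
  expect_true(low$gap_assigned)

  expect_error(call_copy_number(est_row(NaN, 1, 2), b), class = "nm_invalid_input")
})

test_that("the decision rule matches a brute-force interval scan on random estimates", {
  b <- build_bounds_table(t_mode = "rounded2")
  set.seed(42)
  n <- 10000
  rcn <- exp(runif(n, log(0.5), log(14)))
  half <- exp(runif(n, log(1.01), log(1.35)))
  est <- tibble::tibble(rcn = rcn, ci_low = rcn / half, ci_high = rcn * half)
  for (rule in c("ci", "point")) {
    got <- call_copy_number(est, b, gt6_rule = rule)$bin_numeric
    want <- vapply(seq_len(n), function(i) {
      oracle_call_bin(est$rcn[i], est$ci_low[i], est$ci_high[i], b, rule)
    }, numeric(1))
    expect_identical(got, want)
  }
})

test_that("exon concordance counts within-one calls and both-gain discordants", {
  calls <- function(bins) tibble::tibble(
    unit_id = sprintf("n%03d", seq_along(bins)), bin_numeric = bins
  )
  ident <- exon_concordance(calls(rep(c(2, 3, 7), length.out = 115)),
                            calls(rep(c(2, 3, 7), length.out = 115)))
  expect_equal(ident, tibble::tibble(n_within_one = 115L, n_total = 115L,
                                     n_both_gain = 0L))
  # |2-3| = 1 in; |4-2| = 2 out (one side not a gain); |7-6| = 1 in
  mixed <- exon_concordance(calls(c(2, 4, 7)), calls(c(3, 2, 6)))
  expect_equal(mixed$n_within_one, 2L)
  expect_equal(mixed$n_total, 3L)
  expect_equal(mixed$n_both_gain, 0L)
  # a discordant pair where both assays call gains
  both <- exon_concordance(calls(c(5, 2)), calls(c(3, 2)))
  expect_equal(both$n_within_one, 1L)
  expect_equal(both$n_both_gain, 1L)
  expect_error(exon_concordance(calls(2), calls(3)[0, ]),
               class = "nm_invalid_input")
})

test_that("cohort summaries report means, CIs, fractions and histograms", {
  flat <- tibble::tibble(rcn = rep(2, 10), bin = "2", bin_numeric = 2,
                         group = "ND", region = "CBL")
  s <- cohort_summary(flat)
  expect_equal(s$mean_rcn, 2)
  expect_equal(s$frac_gt2, 0)
  expect_equal(s$frac_eq2, 1)
  expect_true(is.na(s$mean_rcn_gt2))
  expect_equal(sum(s$bin_histogram[[1]]), 10L)
  expect_error(cohort_summary(flat[1, ]), class = "nm_invalid_input")
})

test_that("cohort fractions recover a known copy-number mixture", {
  cfg <- sim_config(qpcr = list(
    groups = "MIX", n_brains = c(MIX = 2), n_nuclei_ctx = 100, n_nuclei_cbl = 10,
    target_assays = "APP_ex3", efficiencies = c(APP_ex3 = 1, SEMA4A = 1),
    mixtures_ctx = list(MIX = c(`2` = 0.4, `5` = 0.6))
  ))
  sim <- simulate_ct_table(cfg, seed = 21)
  est <- suppressMessages(rcn_table(sim$ct_replicates, "APP_ex3",
                                    efficiencies = c(APP_ex3 = 1)))
  calls <- call_copy_number(est, build_bounds_table())
  ctx <- dplyr::filter(calls, .data$region == "CTX")
  s <- cohort_summary(ctx)
  truth_frac <- mean(sim$truth$true_cn[sim$truth$region == "CTX"] > 2)
  expect_equal(s$frac_gt2, truth_frac, tolerance = 0.05)
  expect_equal(s$n_units, 200L)
})
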
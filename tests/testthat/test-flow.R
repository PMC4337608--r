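flow_events <- function(x, sample_id = "s1") {
  tibble::tibble(sample_id = sample_id,
                 event_id = sprintf("e%06d", seq_along(x)),
                 pi_intensity = x)
}

test_that("G0/G1 peak detection recovers mode and CV of a clean peak", {
  set.seed(101)
  ev <- flow_events(rnorm(20000, 100, 5))
  pk <- detect_g0g1_peak(ev)
  expect_equal(pk$mode, 100, tolerance = 2)
  expect_equal(pk$cv_percent, 5, tolerance = 0.6)
  # the KDE mode estimate jitters by ~sd/5, so near-zero skew, not exact
  expect_lt(abs(pk$skew), 0.3)
  expect_true(pk$gate[1] < pk$mode && pk$mode < pk$gate[2])
})

test_that("peak detection prefers the lower-intensity (diploid) mode", {
  set.seed(102)
  ev <- flow_events(c(rnorm(18000, 100, 5), rnorm(2000, 180, 5)))
  pk <- detect_g0g1_peak(ev)
  expect_equal(pk$mode, 100, tolerance = 2)
  # near-equal modes trigger the diploid-assumption warning
  ev2 <- flow_events(c(rnorm(10000, 100, 5), rnorm(9990, 180, 5)))
  expect_warning(pk2 <- detect_g0g1_peak(ev2), "lower-intensity")
  expect_equal(pk2$mode, 100, tolerance = 2)
})

test_that("degenerate and undersized inputs are handled", {
  pk <- detect_g0g1_peak(flow_events(rep(100, 600)))
  expect_equal(pk$cv_percent, 0)
  expect_true(is.na(pk$skew))
  expect_error(detect_g0g1_peak(flow_events(rnorm(100, 100, 5))),
               class = "nm_invalid_input")
  expect_error(peak_skew(list(mean = 1, mode = 1, sd = 0)),
               class = "nm_undefined_skew")
})

test_that("the skew statistic is (mean - mode)/sd and detects right shoulders", {
  expect_equal(peak_skew(list(mean = 105, mode = 100, sd = 10)), 0.5)
  set.seed(103)
  shoulder <- flow_events(c(rnorm(16000, 100, 5), rnorm(4000, 120, 5)))
  expect_gt(peak_skew(detect_g0g1_peak(shoulder)), 0.1)
})

test_that("the DNA index is 1 for identical tubes and tracks a true shift", {
  set.seed(104)
  ref <- detect_g0g1_peak(flow_events(rnorm(10000, 100, 5)))
  ref_cen <- detect_g0g1_peak(flow_events(rnorm(3000, 35, 1.5)), min_events = 500)
  expect_equal(dna_index(ref, ref_cen, ref, ref_cen)$di, 1.0)
  smp <- detect_g0g1_peak(flow_events(rnorm(10000, 108, 5.4)))
  res <- dna_index(smp, ref_cen, ref, ref_cen)
  expect_equal(res$di, 1.08, tolerance = 0.005)
  expect_equal(res$percent_change, (res$di - 1) * 100)
  expect_error(dna_index(list(mean = -1), ref_cen, ref, ref_cen),
               class = "nm_invalid_input")
})

test_that("the DNA index is invariant to a common detector-gain rescaling", {
  set.seed(105)
  x_smp <- rnorm(10000, 108, 5)
  x_cen <- rnorm(3000, 35, 1.5)
  x_ref <- rnorm(10000, 100, 5)
  x_refcen <- rnorm(3000, 35, 1.5)
  di <- function(gain) {
    dna_index(
      detect_g0g1_peak(flow_events(x_smp * gain)),
      detect_g0g1_peak(flow_events(x_cen * gain)),
      detect_g0g1_peak(flow_events(x_ref)),
      detect_g0g1_peak(flow_events(x_refcen))
    )$di
  }
  expect_equal(di(1.7), di(1), tolerance = 1e-8)
  expect_equal(di(0.4), di(1), tolerance = 1e-8)
})

test_that("NeuN gating thresholds on the unlabeled control quantile", {
  set.seed(106)
  ctrl <- tibble::tibble(neun_intensity = rnorm(5000, 100, 30))
  below <- tibble::tibble(neun_intensity = rnorm(1000, 50, 10))
  g <- neun_gate(below, ctrl)
  expect_equal(nrow(g$pos), 0L)
  expect_equal(nrow(g$neg), 1000L)

  lab <- tibble::tibble(neun_intensity = c(rnorm(3000, 1000, 100),
                                           rnorm(7000, 100, 30)))
  g2 <- neun_gate(lab, ctrl)
  expect_equal(nrow(g2$pos) / nrow(lab), 0.30, tolerance = 0.02)
})

test_that("group comparison reports ANOVA, Tukey pairs and regressions", {
  base <- c(1, 2, 3, 4, 5)
  same <- tibble::tibble(group = rep(c("A", "B", "C"), each = 5),
                         percent_change = rep(base, 3))
  res <- dcv_compare_groups(same, "percent_change")
  expect_equal(glance(res)$p_value, 1)  # identical value sets: F = 0
  expect_equal(nrow(tidy(res)), 3L)

  set.seed(107)
  shifted <- tibble::tibble(
    group = rep(c("A", "B"), each = 15),
    percent_change = c(rnorm(15, 0, 1), rnorm(15, 3, 1))  # 3 SD apart
  )
  expect_lt(glance(dcv_compare_groups(shifted, "percent_change"))$p_value, 0.05)

  # constant groups with different means: residual variance 0 -> NA p
  flat <- tibble::tibble(group = rep(c("A", "B"), each = 3),
                         percent_change = rep(c(1, 2), each = 3))
  flat_res <- suppressWarnings(dcv_compare_groups(flat, "percent_change"))
  expect_true(is.na(glance(flat_res)$p_value))

  # regression recovers a positive age slope
  set.seed(108)
  aged <- tibble::tibble(group = rep(c("A", "B"), each = 10),
                         age = runif(20, 60, 95))
  aged$percent_change <- 0.2 * aged$age + rnorm(20, 0, 1)
  reg <- dcv_compare_groups(aged, "percent_change", covariates = "age")$regressions
  expect_gt(reg$slope, 0.1)
  expect_lt(reg$p_value, 0.01)
})

test_that("paired t-tests use the pairing column", {
  d <- tibble::tibble(
    group = rep(c("CTX", "CBL"), each = 6),
    brain = rep(sprintf("b%d", 1:6), 2),
    percent_change = c(8, 9, 7, 8.5, 9.5, 8.2, 1, 0.5, 1.2, 0.8, 1.1, 0.9)
  )
  res <- dcv_compare_groups(d, "percent_change", pair_col = "brain")
  expect_false(is.null(res$paired_t))
  expect_lt(res$paired_t$p_value, 0.001)
})

test_that("a whole-chromosome hypersomy predicts a ~3.9% DNA gain", {
  expect_equal(hypersomy_percent_gain(250, 12800), 3.90625)
  expect_equal(hypersomy_percent_gain(250, 12800), 3.9, tolerance = 0.01)
})
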
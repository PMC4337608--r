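#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Fits an ordinary least-squares line of Ct against log10 input copies for a
#' dilution series and derives the amplification efficiency
#' `E = 10^(-1/slope) - 1` (`E = 1` means perfect doubling each cycle). A
#' curve is flagged usable only when its R-squared exceeds `r_squared_min`;
#' curves below that threshold should not be used for quantification.
#'
#' @param points Data frame with numeric columns `log10_copies` and `ct`.
#' @param assay_id Optional assay identifier carried into the result.
#' @param r_squared_min Minimum R-squared for the curve to be usable
#'   (default 0.99).
#' @return An object of class `standard_curve`: a list with `assay_id`,
#'   `slope`, `intercept`, `r_squared`, `efficiency`, `usable`, `n_points`
#'   and the underlying `lm` fit. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @examples
#' pts <- tibble::tibble(log10_copies = 1:5, ct = 38 - 3.32193 * (1:5))
#' glance(fit_standard_curve(pts))
#' @export
fit_standard_curve <- function(points, assay_id = NULL, r_squared_min = 0.99) {
  check_columns(points, c("log10_copies", "ct"), "standard curve points")
  points <- dplyr::filter(points, complete.cases(.data$log10_copies, .data$ct))
  if (dplyr::n_distinct(points$log10_copies) < 3) {
    nm_abort("a standard curve needs at least 3 distinct dilution levels",
             class = "nm_invalid_input")
  }
  fit <- lm(ct ~ log10_copies, data = points)
  slope <- unname(coef(fit)[["log10_copies"]])
  if (!is.finite(slope) || slope >= 0) {
    nm_abort("degenerate standard curve: slope must be negative (Ct falls as input rises)",
             class = "nm_degenerate_curve")
  }
  r2 <- summary(fit)$r.squared
  structure(
    list(
      assay_id = assay_id,
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      usable = r2 > r_squared_min,
      n_points = nrow(points),
      points = as_tibble(points),
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>", if (!is.null(x$assay_id)) x$assay_id else "", "\n")
  cat(sprintf("  slope %.4f, intercept %.2f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  efficiency E = %.3f; usable: %s\n", x$efficiency, x$usable))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve` object.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    assay_id = x$assay_id %||% NA_character_,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    efficiency = x$efficiency,
    usable = x$usable,
    n_points = x$n_points
  )
}

#' Fit standard curves for every assay in a dilution-series table
#'
#' @param data Data frame with columns `assay_id`, `log10_copies`, `ct`
#'   (the `standard_curve.csv` schema).
#' @inheritParams fit_standard_curve
#' @return A tibble with one row per assay: slope, intercept, R-squared,
#'   efficiency and the usability flag.
#' @export
fit_standard_curves <- function(data, r_squared_min = 0.99) {
  check_columns(data, c("assay_id", "log10_copies", "ct"), "standard_curve table")
  data |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::group_map(~ glance(fit_standard_curve(.x, assay_id = .y$assay_id,
                                                 r_squared_min = r_squared_min))) |>
    dplyr::bind_rows()
}

#' Mean Ct of the replicates for one unit/assay pair
#'
#' Replicate Ct values are aggregated by a plain arithmetic mean, with a
#' replicate-count quality gate: a (unit, assay) pair with fewer than
#' `min_reps` retained replicates fails QC and is excluded from analysis.
#' The nominal single-nucleus design is 18 replicates (3 sample loads x 6
#' assay replicates); pairs with 10 or more are analyzable.
#'
#' @param table Ct replicate table (columns `unit_id`, `assay_id`, `ct`).
#' @param unit_id,assay_id The pair to aggregate.
#' @param min_reps Minimum replicates required (default 10).
#' @return One-row tibble with `mean_ct` and `n_reps`.
#' @export
mean_ct <- function(table, unit_id, assay_id, min_reps = 10) {
  check_columns(table, c("unit_id", "assay_id", "ct"), "ct_replicates table")
  cts <- table$ct[table$unit_id == unit_id & table$assay_id == assay_id]
  cts <- cts[is.finite(cts)]
  if (length(cts) == 0) {
    nm_abort(sprintf("no replicates for unit '%s', assay '%s'", unit_id, assay_id),
             class = "nm_invalid_input")
  }
  if (length(cts) < min_reps) {
    nm_abort(
      sprintf("QC failure: unit '%s', assay '%s' has %d replicates (< %d required)",
              unit_id, assay_id, length(cts), min_reps),
      class = "nm_qc_failure"
    )
  }
  tibble(mean_ct = mean(cts), n_reps = length(cts))
}

#' Summarize Ct replicates per unit and assay with replicate-count QC
#'
#' Vectorized companion to [mean_ct()]: aggregates every (unit, assay) pair,
#' flags pairs failing the minimum-replicate rule, and (by default) drops
#' them with a message. An optional MAD-based outlier filter can discard
#' replicates more than `mad_k` scaled median absolute deviations from the
#' pair median before averaging; the default applies no outlier rejection.
#'
#' @param table Ct replicate table (`unit_id`, `brain_id`, `region`, `group`,
#'   `assay_id`, `ct`; extra columns are preserved per unit).
#' @param min_reps Minimum replicates per pair (default 10).
#' @param drop_failed Drop QC-failing pairs (default TRUE); if FALSE they are
#'   kept with `qc_pass = FALSE`.
#' @param mad_filter Apply MAD outlier rejection before averaging
#'   (default FALSE).
#' @param mad_k Rejection threshold in scaled MADs (default 3).
#' @return Tibble with one row per (unit, assay): `mean_ct`, `n_reps`,
#'   `qc_pass`, plus the unit metadata columns.
#' @export
summarize_ct <- function(table, min_reps = 10, drop_failed = TRUE,
                         mad_filter = FALSE, mad_k = 3) {
  check_columns(table, c("unit_id", "assay_id", "ct"), "ct_replicates table")
  meta_cols <- intersect(c("brain_id", "region", "group"), names(table))
  out <- table |>
    dplyr::filter(is.finite(.data$ct)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("unit_id", meta_cols, "assay_id")))) |>
    dplyr::summarise(
      mean_ct = {
        cts <- .data$ct
        if (mad_filter && length(cts) > 2) {
          dev <- abs(cts - median(cts)) / max(stats::mad(cts), .Machine$double.eps)
          cts <- cts[dev <= mad_k]
        }
        mean(cts)
      },
      n_reps = {
        cts <- .data$ct
        if (mad_filter && length(cts) > 2) {
          dev <- abs(cts - median(cts)) / max(stats::mad(cts), .Machine$double.eps)
          cts <- cts[dev <= mad_k]
        }
        length(cts)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(qc_pass = .data$n_reps >= min_reps)
  n_fail <- sum(!out$qc_pass)
  if (n_fail > 0) {
    message(sprintf("summarize_ct: %d unit/assay pair%s failed the >= %d replicate rule%s",
                    n_fail, if (n_fail > 1) "s" else "", min_reps,
                    if (drop_failed) " and were dropped" else ""))
  }
  if (drop_failed) out <- dplyr::filter(out, .data$qc_pass)
  out
}

#' Per-unit delta-Ct between a target and a reference assay
#'
#' Computes `delta_ct = mean Ct(target) - mean Ct(reference)` per unit from a
#' [summarize_ct()] table. Units lacking either assay (e.g. dropped by QC)
#' are omitted.
#'
#' @param ct_summary Output of [summarize_ct()].
#' @param target_assay Target assay id (e.g. `"APP_ex3"`).
#' @param reference_assay Reference assay id (default `"SEMA4A"`).
#' @return Tibble with `unit_id`, metadata, `target_assay`,
#'   `reference_assay`, `delta_ct` and `n_reps` (the smaller of the two
#'   replicate counts).
#' @export
delta_ct <- function(ct_summary, target_assay, reference_assay = "SEMA4A") {
  check_columns(ct_summary, c("unit_id", "assay_id", "mean_ct", "n_reps"),
                "ct summary")
  meta_cols <- intersect(c("brain_id", "region", "group"), names(ct_summary))
  tgt <- dplyr::filter(ct_summary, .data$assay_id == target_assay)
  ref <- dplyr::filter(ct_summary, .data$assay_id == reference_assay)
  if (nrow(tgt) == 0 || nrow(ref) == 0) {
    nm_abort(sprintf("assay '%s' or '%s' absent from Ct summary",
                     target_assay, reference_assay),
             class = "nm_invalid_input")
  }
  dplyr::inner_join(
    dplyr::select(tgt, dplyr::all_of(c("unit_id", meta_cols)),
                  ct_target = "mean_ct", n_target = "n_reps"),
    dplyr::select(ref, "unit_id", ct_reference = "mean_ct", n_reference = "n_reps"),
    by = "unit_id"
  ) |>
    dplyr::mutate(
      target_assay = target_assay,
      reference_assay = reference_assay,
      delta_ct = .data$ct_target - .data$ct_reference,
      n_reps = pmin(.data$n_target, .data$n_reference)
    ) |>
    dplyr::select(dplyr::all_of(c("unit_id", meta_cols)), "target_assay",
                  "reference_assay", "delta_ct", "n_reps",
                  "ct_target", "ct_reference")
}

#' Delta-delta-Ct of a sample against a calibrator set
#'
#' `ddCt = sample delta-Ct - mean(calibrator delta-Cts)`. In single-nucleus
#' mode the calibrator set is the paired cerebellar nuclei of the same brain,
#' whose delta-Ct values are averaged.
#'
#' @param sample One-row data frame (or single row of a [delta_ct()] table).
#' @param calibrator_units [delta_ct()] rows for the calibrator units; must
#'   share the sample's target and reference assays.
#' @return The ddCt value (numeric scalar).
#' @export
delta_delta_ct <- function(sample, calibrator_units) {
  check_columns(sample, c("delta_ct", "target_assay", "reference_assay"), "sample")
  check_columns(calibrator_units, c("delta_ct", "target_assay", "reference_assay"),
                "calibrators")
  if (nrow(calibrator_units) == 0) {
    nm_abort("calibrator set is empty", class = "nm_invalid_input")
  }
  same <- all(calibrator_units$target_assay == sample$target_assay[1]) &&
    all(calibrator_units$reference_assay == sample$reference_assay[1])
  if (!same) {
    nm_abort("sample and calibrators must share target and reference assays",
             class = "nm_invalid_input")
  }
  sample$delta_ct[1] - mean(calibrator_units$delta_ct)
}

# Critical t value for the CI model; "rounded2" reproduces the printed
# bounds table exactly (the published table is consistent with t = 2.000).
t_critical <- function(df = 68, alpha = 0.05, t_mode = c("exact", "rounded2")) {
  t_mode <- match.arg(t_mode)
  if (t_mode == "rounded2") 2 else qt(1 - alpha / 2, df = df)
}

#' Relative copy number with a replicate-based confidence interval
#'
#' The point estimate is `RCN = 2 * (1 + E)^(-ddct)`, so a diploid sample
#' (ddct = 0) is normalized to 2.00. The confidence half-width on the ddCt
#' scale is `CI = t_crit(df) * system_sd / sqrt(n_reps)`; the RCN bounds are
#' the formula evaluated at `ddct -/+ CI`, ordered so `ci_low <= ci_high`.
#' Defaults encode the calibrated measurement system: system SD 0.25 cycles,
#' 68 degrees of freedom, 18 replicates' worth of averaging, alpha 0.05.
#'
#' @param ddct Numeric vector of delta-delta-Ct values.
#' @param efficiency Amplification efficiency E (scalar or vector).
#' @param n_reps Replicate count(s) behind each ddct.
#' @param system_sd Replicate Ct standard deviation (cycles, default 0.25).
#' @param df Degrees of freedom for the critical t value (default 68).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param t_mode `"exact"` (Student-t quantile) or `"rounded2"` (critical
#'   value 2.000, matching the printed modeled-bounds table).
#' @return Tibble with `ddct`, `efficiency`, `rcn`, `ci_low`, `ci_high`,
#'   `ci_halfwidth_log` (half-width on the ddCt scale) and `n_reps`.
#' @examples
#' rcn_point_and_ci(ddct = c(0, -1), efficiency = 1)
#' @export
rcn_point_and_ci <- function(ddct, efficiency = 1, n_reps = 18,
                             system_sd = 0.25, df = 68, alpha = 0.05,
                             t_mode = c("exact", "rounded2")) {
  t_mode <- match.arg(t_mode)
  stopifnot(all(efficiency > -1), all(n_reps >= 1))
  ci_log <- t_critical(df, alpha, t_mode) * system_sd / sqrt(n_reps)
  base <- 1 + efficiency
  rcn <- 2 * base^(-ddct)
  b1 <- 2 * base^(-(ddct - ci_log))
  b2 <- 2 * base^(-(ddct + ci_log))
  tibble(
    ddct = ddct,
    efficiency = efficiency,
    rcn = rcn,
    ci_low = pmin(b1, b2),
    ci_high = pmax(b1, b2),
    ci_halfwidth_log = ci_log,
    n_reps = n_reps
  )
}

#' Single-nucleus relative copy numbers from a Ct replicate table
#'
#' Runs the full quantification chain: replicate QC and averaging, per-unit
#' delta-Ct against the reference assay, calibration against the averaged
#' delta-Ct of the paired calibrator units (by default, all units of the
#' same brain in the calibrator region, i.e. the cerebellum), and RCN with
#' confidence interval.
#'
#' Two quantification formulas are available. `method = "literal"` (default)
#' uses a single efficiency — the target assay's — in
#' `RCN = 2 (1+E)^(-ddCt)`, which assumes reference efficiency is close to
#' target efficiency. `method = "ratio"` uses each assay's own efficiency:
#' `RCN = 2 (1+E_t)^(-dCt_t) * (1+E_r)^(+dCt_r)` with per-assay delta-Cts
#' taken against the calibrator means. The two agree exactly when
#' `E_t == E_r`.
#'
#' @param ct_replicates Ct replicate table (`unit_id`, `brain_id`, `region`,
#'   `group`, `assay_id`, `replicate_index`, `ct`).
#' @param target_assays Character vector of target assay ids.
#' @param reference_assay Reference assay id (default `"SEMA4A"`).
#' @param efficiencies Named numeric vector of per-assay efficiencies;
#'   assays not named get efficiency 1.
#' @param calibrator_region Region whose units calibrate each brain
#'   (default `"CBL"`).
#' @param min_reps Replicate QC threshold (default 10).
#' @param method `"literal"` or `"ratio"` (see Details).
#' @param mad_filter Passed to [summarize_ct()].
#' @inheritParams rcn_point_and_ci
#' @return Tibble with one row per analyzable unit x target assay:
#'   `unit_id`, `brain_id`, `region`, `group`, `target_assay`, `ddct`,
#'   `efficiency`, `rcn`, `ci_low`, `ci_high`, `ci_halfwidth_log`, `n_reps`.
#' @export
rcn_table <- function(ct_replicates, target_assays, reference_assay = "SEMA4A",
                      efficiencies = NULL, calibrator_region = "CBL",
                      min_reps = 10, system_sd = 0.25, df = 68, alpha = 0.05,
                      t_mode = c("exact", "rounded2"),
                      method = c("literal", "ratio"), mad_filter = FALSE) {
  t_mode <- match.arg(t_mode)
  method <- match.arg(method)
  check_columns(ct_replicates,
                c("unit_id", "brain_id", "region", "group", "assay_id", "ct"),
                "ct_replicates table")
  eff_of <- function(assay) {
    if (!is.null(efficiencies) && assay %in% names(efficiencies)) {
      unname(efficiencies[[assay]])
    } else 1
  }
  summ <- summarize_ct(ct_replicates, min_reps = min_reps, mad_filter = mad_filter)
  purrr::map(target_assays, function(assay) {
    d <- delta_ct(summ, target_assay = assay, reference_assay = reference_assay)
    d <- d |>
      dplyr::group_by(.data$brain_id) |>
      dplyr::mutate(
        calib_delta_ct = {
          cal <- .data$region == calibrator_region
          if (!any(cal)) NA_real_ else mean(.data$delta_ct[cal])
        },
        calib_ct_target = {
          cal <- .data$region == calibrator_region
          if (!any(cal)) NA_real_ else mean(.data$ct_target[cal])
        },
        calib_ct_reference = {
          cal <- .data$region == calibrator_region
          if (!any(cal)) NA_real_ else mean(.data$ct_reference[cal])
        }
      ) |>
      dplyr::ungroup()
    no_cal <- is.na(d$calib_delta_ct)
    if (any(no_cal)) {
      warn(sprintf("rcn_table: %d unit(s) have no calibrator units in region '%s' for their brain and were dropped",
                   sum(no_cal), calibrator_region))
      d <- d[!no_cal, ]
    }
    d$ddct <- d$delta_ct - d$calib_delta_ct
    est <- rcn_point_and_ci(d$ddct, efficiency = eff_of(assay), n_reps = d$n_reps,
                            system_sd = system_sd, df = df, alpha = alpha,
                            t_mode = t_mode)
    if (method == "ratio") {
      e_t <- 1 + eff_of(assay)
      e_r <- 1 + eff_of(reference_assay)
      rcn_ratio <- 2 * e_t^(-(d$ct_target - d$calib_ct_target)) *
        e_r^(d$ct_reference - d$calib_ct_reference)
      scale <- rcn_ratio / est$rcn
      est$rcn <- rcn_ratio
      est$ci_low <- est$ci_low * scale
      est$ci_high <- est$ci_high * scale
    }
    dplyr::bind_cols(
      dplyr::select(d, dplyr::any_of(c("unit_id", "brain_id", "region", "group",
                                       "target_assay"))),
      dplyr::select(est, -"n_reps"),
      tibble(n_reps = d$n_reps)
    )
  }) |>
    dplyr::bind_rows()
}

#' Cohort-mode regional comparison of delta-Ct values
#'
#' For small-population (cohort) qPCR runs, compares target-locus dosage
#' between two regions of the same individual with an unpaired two-tailed
#' t-test on replicate-level delta-Ct values (each replicate's Ct minus the
#' unit's mean reference Ct).
#'
#' @inheritParams rcn_table
#' @param target_assay Single target assay id.
#' @param region_a,region_b Regions to compare (defaults `"CTX"`, `"CBL"`).
#' @return Tibble with one row per brain: mean delta-Ct per region, the
#'   difference, t statistic, degrees of freedom and p value.
#' @export
cohort_region_test <- function(ct_replicates, target_assay,
                               reference_assay = "SEMA4A",
                               region_a = "CTX", region_b = "CBL",
                               min_reps = 2) {
  check_columns(ct_replicates,
                c("unit_id", "brain_id", "region", "assay_id", "ct"),
                "ct_replicates table")
  ref_means <- ct_replicates |>
    dplyr::filter(.data$assay_id == reference_assay) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  reps <- ct_replicates |>
    dplyr::filter(.data$assay_id == target_assay) |>
    dplyr::inner_join(ref_means, by = "unit_id") |>
    dplyr::mutate(rep_delta_ct = .data$ct - .data$ref_ct)
  reps |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::group_map(function(df, key) {
      a <- df$rep_delta_ct[df$region == region_a]
      b <- df$rep_delta_ct[df$region == region_b]
      if (length(a) < min_reps || length(b) < min_reps) {
        return(tibble(brain_id = key$brain_id, mean_dct_a = NA_real_,
                      mean_dct_b = NA_real_, diff = NA_real_,
                      statistic = NA_real_, df = NA_real_, p_value = NA_real_))
      }
      tt <- t.test(a, b, alternative = "two.sided", paired = FALSE)
      tibble(brain_id = key$brain_id, mean_dct_a = mean(a), mean_dct_b = mean(b),
             diff = mean(a) - mean(b), statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
    }) |>
    dplyr::bind_rows()
}
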
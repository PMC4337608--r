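#' Modeled per-copy-number RCN acceptance intervals
#'
#' Models the expected relative-copy-number interval for each integer copy
#' number k = 1..`k_max`, assuming the measurement system's replicate SD and
#' averaging depth: with `CI = t_crit(df) * system_sd / sqrt(n_reps)` on the
#' ddCt scale, the interval for copy number k is
#' `k * (1 + E)^(-CI) .. k * (1 + E)^(+CI)` — every row is the k = 1 row
#' scaled by k, so intervals widen linearly with k. Under the defaults
#' (SD 0.25, n 18, df 68, alpha 0.05, E 1) consecutive intervals are
#' disjoint through k = 6 and first overlap at 6 vs 7, which is why calls
#' are binned 1-6 and ">6".
#'
#' @param k_max Largest modeled copy number (default 6).
#' @param efficiency Amplification efficiency E (default 1, perfect doubling).
#' @inheritParams rcn_point_and_ci
#' @return Tibble of class `bounds_table` with columns `k`, `lower`,
#'   `upper`; model parameters are stored in attribute `params`.
#' @examples
#' build_bounds_table(t_mode = "rounded2")
#' @export
build_bounds_table <- function(k_max = 6, system_sd = 0.25, df = 68,
                               n_reps = 18, alpha = 0.05, efficiency = 1,
                               t_mode = c("exact", "rounded2")) {
  t_mode <- match.arg(t_mode)
  stopifnot(k_max >= 1)
  ci_log <- t_critical(df, alpha, t_mode) * system_sd / sqrt(n_reps)
  base <- 1 + efficiency
  k <- seq_len(k_max)
  out <- tibble(k = k, lower = k * base^(-ci_log), upper = k * base^(ci_log))
  structure(
    out,
    params = list(system_sd = system_sd, df = df, n_reps = n_reps,
                  alpha = alpha, efficiency = efficiency, t_mode = t_mode,
                  ci_log = ci_log),
    class = c("bounds_table", class(out))
  )
}

# Single-call decision rule shared by call_copy_number(); returns a list.
# Rule: collect every modeled interval the estimate's CI intersects;
# one hit -> that bin; several -> nearest k on the log2 scale (ambiguous);
# none -> ">6" if beyond the last interval per gt6_rule, else nearest k
# with the gap flag set.
call_one <- function(rcn, ci_low, ci_high, bounds, gt6_rule) {
  k <- bounds$k
  k_max <- max(k)
  hit <- ci_low <= bounds$upper & ci_high >= bounds$lower
  n_hit <- sum(hit)
  nearest <- function(ks) ks[which.min(abs(log2(rcn) - log2(ks)))]
  if (n_hit == 1) {
    list(bin = as.character(k[hit]), bin_numeric = k[hit],
         ambiguous = FALSE, gap_assigned = FALSE)
  } else if (n_hit > 1) {
    kb <- nearest(k[hit])
    list(bin = as.character(kb), bin_numeric = kb,
         ambiguous = TRUE, gap_assigned = FALSE)
  } else {
    beyond <- switch(gt6_rule,
                     ci = ci_low > bounds$upper[k_max],
                     point = rcn > bounds$upper[k_max])
    if (beyond) {
      list(bin = paste0(">", k_max), bin_numeric = k_max + 1,
           ambiguous = FALSE, gap_assigned = FALSE)
    } else {
      kb <- nearest(k)
      list(bin = as.character(kb), bin_numeric = kb,
           ambiguous = FALSE, gap_assigned = TRUE)
    }
  }
}

#' Assign integer copy-number bins by confidence-interval overlap
#'
#' Each estimate's confidence interval is compared with the modeled
#' per-copy-number intervals: a CI overlapping exactly one modeled interval
#' is called that copy number; a CI overlapping several is called the
#' nearest copy number on the log2 scale and flagged `ambiguous`; a CI
#' beyond the last modeled interval is called `">6"` (or `">k_max"`); a CI
#' falling in an inter-bin gap (including below the copy-number-1 interval)
#' is assigned the nearest copy number and flagged `gap_assigned`.
#'
#' @param estimates Tibble with columns `rcn`, `ci_low`, `ci_high` (e.g.
#'   from [rcn_table()] or [rcn_point_and_ci()]).
#' @param bounds A [build_bounds_table()] result.
#' @param gt6_rule How to call beyond-the-table estimates: `"ci"` (default,
#'   CI lower bound exceeds the last modeled upper bound) or `"point"`
#'   (point estimate exceeds it).
#' @return The input with added columns `bin` (character, `"1"`..`"6"`,
#'   `">6"`), `bin_numeric` (`">6"` coded as 7), `ambiguous`,
#'   `gap_assigned`.
#' @export
call_copy_number <- function(estimates, bounds = build_bounds_table(),
                             gt6_rule = c("ci", "point")) {
  gt6_rule <- match.arg(gt6_rule)
  check_columns(estimates, c("rcn", "ci_low", "ci_high"), "RCN estimates")
  ok <- is.finite(estimates$rcn) & is.finite(estimates$ci_low) &
    is.finite(estimates$ci_high) & estimates$rcn > 0
  if (!all(ok)) {
    nm_abort("non-finite or non-positive RCN estimate(s); cannot call copy number",
             class = "nm_invalid_input")
  }
  calls <- purrr::pmap(
    list(estimates$rcn, estimates$ci_low, estimates$ci_high),
    function(r, lo, hi) call_one(r, lo, hi, bounds, gt6_rule)
  )
  estimates |>
    dplyr::mutate(
      bin = purrr::map_chr(calls, "bin"),
      bin_numeric = purrr::map_dbl(calls, "bin_numeric"),
      ambiguous = purrr::map_lgl(calls, "ambiguous"),
      gap_assigned = purrr::map_lgl(calls, "gap_assigned")
    )
}

#' Concordance of copy-number calls between two assays
#'
#' Joins two call sets (e.g. two exons of the same locus) on shared unit
#' ids and counts units whose bins agree to within one copy-number call;
#' among the remaining discordant pairs it counts those where both assays
#' nonetheless call a gain (bin above 2). The `">6"` bin is treated as
#' copy number 7 for the distance.
#'
#' @param calls_a,calls_b [call_copy_number()] outputs with `unit_id` and
#'   `bin_numeric` columns.
#' @return Tibble with `n_within_one`, `n_total`, `n_both_gain`.
#' @export
exon_concordance <- function(calls_a, calls_b) {
  check_columns(calls_a, c("unit_id", "bin_numeric"), "calls_a")
  check_columns(calls_b, c("unit_id", "bin_numeric"), "calls_b")
  j <- dplyr::inner_join(
    dplyr::select(calls_a, "unit_id", bin_a = "bin_numeric"),
    dplyr::select(calls_b, "unit_id", bin_b = "bin_numeric"),
    by = "unit_id"
  )
  if (nrow(j) == 0) {
    nm_abort("no shared unit_ids between the two call sets",
             class = "nm_invalid_input")
  }
  within_one <- abs(j$bin_a - j$bin_b) <= 1
  tibble(
    n_within_one = sum(within_one),
    n_total = nrow(j),
    n_both_gain = sum(!within_one & j$bin_a > 2 & j$bin_b > 2)
  )
}

#' Summarize a cohort of copy-number calls
#'
#' Per-group summary of single-unit calls: mean RCN with a 95% t-based
#' confidence interval, the call-bin histogram, the fractions of units
#' called below / at / above two copies, and the mean RCN among units
#' called above two copies (the amplified subset).
#'
#' @param calls [call_copy_number()] output; should carry `rcn`,
#'   `bin_numeric` and `bin`.
#' @param group,region Optional labels recorded in the output (defaults
#'   taken from the data when single-valued).
#' @param conf_level Confidence level for the mean's CI (default 0.95).
#' @return One-row tibble: `group`, `region`, `n_units`, `mean_rcn`,
#'   `ci_low`, `ci_high`, `frac_lt2`, `frac_eq2`, `frac_gt2`,
#'   `mean_rcn_gt2`, and a `bin_histogram` list-column (named counts).
#' @export
cohort_summary <- function(calls, group = NULL, region = NULL,
                           conf_level = 0.95) {
  check_columns(calls, c("rcn", "bin", "bin_numeric"), "calls")
  if (nrow(calls) < 2) {
    nm_abort("cohort_summary needs at least 2 units", class = "nm_invalid_input")
  }
  pick_label <- function(given, col) {
    if (!is.null(given)) return(given)
    if (col %in% names(calls) && dplyr::n_distinct(calls[[col]]) == 1) {
      as.character(calls[[col]][1])
    } else NA_character_
  }
  n <- nrow(calls)
  m <- mean(calls$rcn)
  se <- sd(calls$rcn) / sqrt(n)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  bins <- table(factor(calls$bin, levels = c(as.character(1:6), ">6")))
  gt2 <- calls$bin_numeric > 2
  tibble(
    group = pick_label(group, "group"),
    region = pick_label(region, "region"),
    n_units = n,
    mean_rcn = m,
    ci_low = m - tcrit * se,
    ci_high = m + tcrit * se,
    frac_lt2 = mean(calls$bin_numeric < 2),
    frac_eq2 = mean(calls$bin_numeric == 2),
    frac_gt2 = mean(gt2),
    mean_rcn_gt2 = if (any(gt2)) mean(calls$rcn[gt2]) else NA_real_,
    bin_histogram = list(setNames(as.integer(bins), names(bins)))
  )
}

#' Cohort summaries for every group x region x assay stratum
#'
#' @param calls [call_copy_number()] output carrying `group`, `region` and
#'   (optionally) `target_assay` columns.
#' @inheritParams cohort_summary
#' @return Tibble with one [cohort_summary()] row per stratum.
#' @export
cohort_summaries <- function(calls, conf_level = 0.95) {
  check_columns(calls, c("group", "region"), "calls")
  strata <- intersect(c("target_assay", "group", "region"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::group_map(function(df, key) {
      out <- cohort_summary(df, group = as.character(key$group),
                            region = as.character(key$region),
                            conf_level = conf_level)
      if ("target_assay" %in% names(key)) {
        out <- dplyr::mutate(out, target_assay = key$target_assay,
                             .before = 1)
      }
      out
    }) |>
    dplyr::bind_rows()
}
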
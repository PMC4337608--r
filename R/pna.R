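#' Linearity of a PNA probe dot-blot dilution series
#'
#' Fits intensity against the number of probe binding sites (or DNA
#' amount) by least squares and checks that fluorescence output rises
#' linearly: the intercept estimates background, and the series passes
#' when R-squared reaches `r_squared_min`.
#'
#' @param data Data frame with columns `copies` (binding sites per
#'   template, e.g. 0/3/6/9) and `intensity`.
#' @param r_squared_min Linearity threshold (default 0.95).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `linear`.
#' @export
dotblot_linearity <- function(data, r_squared_min = 0.95) {
  check_columns(data, c("copies", "intensity"), "dot-blot table")
  if (dplyr::n_distinct(data$copies) < 3) {
    nm_abort("dot-blot linearity needs at least 3 copy levels",
             class = "nm_invalid_input")
  }
  fit <- lm(intensity ~ copies, data = data)
  r2 <- summary(fit)$r.squared
  tibble(slope = unname(coef(fit)[["copies"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = r2, linear = r2 >= r_squared_min)
}

# Apply the nucleus-level exclusion rules to per-punctum records:
# nuclei without telomere signal failed hybridization and are removed
# entirely; lipofuscin puncta (autofluorescent in all channels) are
# removed from quantification but their nuclei are kept.
pna_apply_exclusions <- function(records) {
  if ("telomere_present" %in% names(records)) {
    failed <- unique(records$unit_id[!records$telomere_present])
    records <- dplyr::filter(records, !.data$unit_id %in% failed)
  }
  if ("lipofuscin" %in% names(records)) {
    records <- dplyr::mutate(
      records,
      intensity = ifelse(.data$lipofuscin, NA_real_, .data$intensity)
    )
  }
  records
}

#' Fraction of nuclei with target signal above a detection threshold
#'
#' A nucleus is scored positive when the maximum intensity over its
#' non-excluded puncta reaches the detection threshold, below which target
#' copies are undetectable. Exclusion rules are applied first: nuclei
#' lacking telomere signal (hybridization failure) are dropped; lipofuscin
#' puncta are ignored. With `threshold = "auto"` the threshold is a
#' quantile (default: the maximum) of the intensities among designated
#' negative-control records.
#'
#' @param records Per-punctum table: `unit_id`, `group`, `intensity`,
#'   optional `n_puncta`, `lipofuscin`, `telomere_present`,
#'   `is_negative_control`. Nuclei with zero puncta appear as one row with
#'   `intensity = NA`.
#' @param threshold Numeric detection threshold, or `"auto"`.
#' @param control_quantile Quantile of negative-control intensities used
#'   when `threshold = "auto"` (default 1 = the maximum).
#' @return Tibble with one row per group: `group`, `n_positive`,
#'   `n_total`, `fraction`, `threshold`. Negative-control records are
#'   excluded from the group tallies.
#' @export
positive_fraction <- function(records, threshold = "auto",
                              control_quantile = 1) {
  check_columns(records, c("unit_id", "group", "intensity"), "PNA records")
  records <- pna_apply_exclusions(records)
  if (identical(threshold, "auto")) {
    if (!"is_negative_control" %in% names(records) ||
        !any(records$is_negative_control)) {
      nm_abort("threshold = \"auto\" needs negative-control records",
               class = "nm_invalid_input")
    }
    ctrl <- records$intensity[records$is_negative_control]
    ctrl <- ctrl[is.finite(ctrl)]
    threshold <- unname(stats::quantile(ctrl, probs = control_quantile,
                                        names = FALSE))
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if ("is_negative_control" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_negative_control)
  }
  records |>
    dplyr::group_by(.data$group, .data$unit_id) |>
    dplyr::summarise(
      max_intensity = if (all(is.na(.data$intensity))) -Inf
                      else max(.data$intensity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_positive = sum(.data$max_intensity >= threshold),
      n_total = dplyr::n(),
      fraction = .data$n_positive / .data$n_total,
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold = threshold)
}

#' Pairwise comparison of per-nucleus PNA intensities between groups
#'
#' Unpaired two-tailed t-tests on nucleus-level maximum intensities for
#' every pair of groups, Holm-adjusted.
#'
#' @inheritParams positive_fraction
#' @return Tibble with one row per group pair: `group_a`, `group_b`,
#'   `statistic`, `p_value`, `p_adj`.
#' @export
pna_group_compare <- function(records) {
  check_columns(records, c("unit_id", "group", "intensity"), "PNA records")
  records <- pna_apply_exclusions(records)
  if ("is_negative_control" %in% names(records)) {
    records <- dplyr::filter(records, !.data$is_negative_control)
  }
  per_unit <- records |>
    dplyr::group_by(.data$group, .data$unit_id) |>
    dplyr::summarise(
      max_intensity = if (all(is.na(.data$intensity))) NA_real_
                      else max(.data$intensity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$max_intensity))
  gs <- sort(unique(as.character(per_unit$group)))
  if (length(gs) < 2) {
    nm_abort("need at least two groups to compare", class = "nm_invalid_input")
  }
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  out <- purrr::map(pairs, function(p) {
    a <- per_unit$max_intensity[per_unit$group == p[1]]
    b <- per_unit$max_intensity[per_unit$group == p[2]]
    tt <- t.test(a, b, alternative = "two.sided")
    tibble(group_a = p[1], group_b = p[2],
           statistic = unname(tt$statistic), p_value = tt$p.value)
  }) |>
    dplyr::bind_rows()
  dplyr::mutate(out, p_adj = p.adjust(.data$p_value, method = "holm"))
}
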
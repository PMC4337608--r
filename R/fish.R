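#' Per-brain aneusomy rates from FISH spot-count tables
#'
#' Converts raw dual point-paint FISH class counts (monosomy / disomy /
#' trisomy / tetrasomy per nucleus) into per-brain class fractions. When a
#' brain was scored by several observers, each observer's rates are
#' computed first and then averaged per brain, so every observer weighs
#' equally regardless of how many nuclei they scored.
#'
#' @param table Count table with columns `brain_id`, `group`,
#'   `observer_id`, `monosomy`, `disomy`, `trisomy`, `tetrasomy`,
#'   `n_nuclei`. Class counts must sum to `n_nuclei` in every row.
#' @return Tibble with one row per brain: `brain_id`, `group`, `n_nuclei`
#'   (total scored), `n_observers`, and rate columns
#'   `monosomy`/`disomy`/`trisomy`/`tetrasomy` summing to 1.
#' @export
aneusomy_rates <- function(table) {
  classes <- c("monosomy", "disomy", "trisomy", "tetrasomy")
  check_columns(table, c("brain_id", "group", "observer_id", classes, "n_nuclei"),
                "fish_counts table")
  sums <- rowSums(table[classes])
  if (any(sums != table$n_nuclei)) {
    nm_abort("aneusomy class counts must sum to n_nuclei in every row",
             class = "nm_invalid_input")
  }
  table |>
    dplyr::mutate(dplyr::across(dplyr::all_of(classes), ~ .x / n_nuclei)) |>
    dplyr::group_by(.data$brain_id, .data$group) |>
    dplyr::summarise(
      n_nuclei = sum(.data$n_nuclei),
      n_observers = dplyr::n_distinct(.data$observer_id),
      dplyr::across(dplyr::all_of(classes), mean),
      .groups = "drop"
    )
}

#' Group means and standard errors of aneusomy rates
#'
#' @param rates [aneusomy_rates()] output.
#' @return Tibble with one row per group x class: `group`, `class`,
#'   `mean_rate`, `sem`, `n_brains`.
#' @export
aneusomy_group_summary <- function(rates) {
  classes <- c("monosomy", "disomy", "trisomy", "tetrasomy")
  check_columns(rates, c("group", classes), "aneusomy rates")
  rates |>
    tidyr::pivot_longer(dplyr::all_of(classes), names_to = "class",
                        values_to = "rate") |>
    dplyr::group_by(.data$group, .data$class) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate),
      sem = sd(.data$rate) / sqrt(dplyr::n()),
      n_brains = dplyr::n(),
      .groups = "drop"
    )
}

#' Compare aneusomy rates between two groups
#'
#' Primary test: per aneusomy class, an unpaired two-tailed t-test on
#' per-brain rates, matching brain-level error structure. Secondary: a
#' chi-squared test on counts pooled across brains within each group (more
#' powerful but ignores brain-to-brain variation). Groups with a single
#' brain yield NA for the t-test with a warning.
#'
#' @param table Raw FISH count table (see [aneusomy_rates()]).
#' @param groups Optional length-2 character vector selecting/ordering the
#'   groups; default = the two groups present.
#' @return Tibble with one row per class: group means, t statistic and p
#'   value of the per-brain test, and the pooled chi-squared p value.
#' @export
compare_aneusomy <- function(table, groups = NULL) {
  classes <- c("monosomy", "disomy", "trisomy", "tetrasomy")
  rates <- aneusomy_rates(table)
  if (is.null(groups)) groups <- sort(unique(as.character(rates$group)))
  if (length(groups) != 2) {
    nm_abort("compare_aneusomy needs exactly two groups",
             class = "nm_invalid_input")
  }
  ra <- dplyr::filter(rates, .data$group == groups[1])
  rb <- dplyr::filter(rates, .data$group == groups[2])
  if (nrow(ra) < 2 || nrow(rb) < 2) {
    warn("a group has fewer than 2 brains; per-brain t-tests reported as NA")
  }
  pooled <- table |>
    dplyr::filter(.data$group %in% groups) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(classes), sum),
                     n_nuclei = sum(.data$n_nuclei), .groups = "drop")
  purrr::map(classes, function(cl) {
    a <- ra[[cl]]
    b <- rb[[cl]]
    tres <- if (length(a) >= 2 && length(b) >= 2 &&
                (sd(a) > 0 || sd(b) > 0)) {
      tt <- t.test(a, b, alternative = "two.sided", paired = FALSE)
      c(unname(tt$statistic), tt$p.value)
    } else if (length(a) >= 2 && length(b) >= 2 && mean(a) == mean(b)) {
      c(0, 1)  # identical degenerate groups: no evidence of difference
    } else {
      c(NA_real_, NA_real_)
    }
    ka <- pooled[[cl]][pooled$group == groups[1]]
    kb <- pooled[[cl]][pooled$group == groups[2]]
    na <- pooled$n_nuclei[pooled$group == groups[1]]
    nb <- pooled$n_nuclei[pooled$group == groups[2]]
    chi_p <- tryCatch(
      suppressWarnings(chisq.test(matrix(c(ka, na - ka, kb, nb - kb), nrow = 2))$p.value),
      error = function(e) NA_real_
    )
    tibble(class = cl,
           mean_rate_a = mean(a), mean_rate_b = mean(b),
           statistic = tres[1], p_value = tres[2], chisq_p = chi_p,
           group_a = groups[1], group_b = groups[2])
  }) |>
    dplyr::bind_rows()
}
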
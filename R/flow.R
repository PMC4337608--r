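#' Locate and summarize the G0/G1 (2N) peak of a DNA-content histogram
#'
#' The mode is located on a kernel-density estimate of the intensity
#' distribution (Silverman bandwidth, evaluated on a fixed grid); a
#' symmetric relative gate `[mode*(1-w), mode*(1+w)]` is drawn around it and
#' the gated events summarized. When two density modes are within 10% of
#' each other (e.g. a strong aneuploid or doublet peak) the lower-intensity
#' mode is chosen — the diploid peak sits lowest — with a warning.
#'
#' @param events Flow event table.
#' @param channel Intensity column to analyze (default `"pi_intensity"`).
#' @param gate_halfwidth Relative gate half-width w (default 0.25).
#' @param n_grid Density grid size (default 1024).
#' @param min_events Minimum events required (default 500).
#' @return An object of class `peak_stats`: list with `mean`, `mode`, `sd`,
#'   `cv_percent` (100 sd/mean), `skew` ((mean - mode)/sd), `n_events`,
#'   `gate` (length-2 numeric) and `channel`. Has [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
detect_g0g1_peak <- function(events, channel = "pi_intensity",
                             gate_halfwidth = 0.25, n_grid = 1024,
                             min_events = 500) {
  check_columns(events, channel, "flow events")
  x <- events[[channel]]
  x <- x[is.finite(x) & x >= 0]
  if (length(x) < min_events) {
    nm_abort(sprintf("peak detection needs at least %d events (got %d)",
                     min_events, length(x)),
             class = "nm_invalid_input")
  }
  if (sd(x) == 0) {
    # degenerate but well-defined: a delta spike has cv 0 and undefined skew
    gate <- c(x[1] * (1 - gate_halfwidth), x[1] * (1 + gate_halfwidth))
    return(structure(
      list(mean = x[1], mode = x[1], sd = 0, cv_percent = 0, skew = NA_real_,
           n_events = length(x), gate = gate, channel = channel,
           density = NULL, data = x),
      class = "peak_stats"
    ))
  }
  dens <- density(x, n = n_grid)
  y <- dens$y
  # interior local maxima of the smoothed histogram
  is_max <- c(FALSE, y[2:(n_grid - 1)] > y[1:(n_grid - 2)] &
                y[2:(n_grid - 1)] >= y[3:n_grid], FALSE)
  peaks_x <- dens$x[is_max]
  peaks_y <- y[is_max]
  if (length(peaks_x) == 0) {
    mode_x <- dens$x[which.max(y)]
  } else {
    top <- max(peaks_y)
    contenders <- peaks_x[peaks_y >= 0.9 * top]
    # adjacent KDE wiggle is not multimodality; only well-separated
    # near-equal modes are ambiguous
    if (length(contenders) > 1 &&
        max(contenders) / min(contenders) > 1.15) {
      warn("multiple density modes within 10%; choosing the lower-intensity mode (diploid assumption)")
      mode_x <- min(contenders)
    } else {
      mode_x <- peaks_x[which.max(peaks_y)]
    }
  }
  gate <- c(mode_x * (1 - gate_halfwidth), mode_x * (1 + gate_halfwidth))
  g <- x[x >= gate[1] & x <= gate[2]]
  m <- mean(g)
  s <- sd(g)
  structure(
    list(mean = m, mode = mode_x, sd = s,
         cv_percent = 100 * s / m,
         skew = if (s > 0) (m - mode_x) / s else NA_real_,
         n_events = length(g), gate = gate, channel = channel,
         density = dens, data = x),
    class = "peak_stats"
  )
}

#' @export
print.peak_stats <- function(x, ...) {
  cat("<peak_stats>", x$channel, "\n")
  cat(sprintf("  mode %.3g, mean %.3g, sd %.3g, CV %.2f%%, skew %.3f\n",
              x$mode, x$mean, x$sd, x$cv_percent, x$skew))
  cat(sprintf("  gate [%.3g, %.3g], %d events\n", x$gate[1], x$gate[2], x$n_events))
  invisible(x)
}

#' @rdname detect_g0g1_peak
#' @param x,object A `peak_stats` object.
#' @param ... Unused.
#' @export
glance.peak_stats <- function(x, ...) {
  tibble(mean = x$mean, mode = x$mode, sd = x$sd, cv_percent = x$cv_percent,
         skew = x$skew, n_events = x$n_events,
         gate_low = x$gate[1], gate_high = x$gate[2])
}

#' Skew statistic of a DNA-content peak
#'
#' `(mean - mode) / sd` of the gated diploid peak: positive values indicate
#' a right shoulder of events with elevated DNA content.
#'
#' @param peak A `peak_stats` object (or anything with `mean`, `mode`, `sd`).
#' @return Numeric skew value.
#' @export
peak_skew <- function(peak) {
  if (!is.finite(peak$sd) || peak$sd <= 0) {
    nm_abort("skew undefined: peak sd is zero or non-finite",
             class = "nm_undefined_skew")
  }
  (peak$mean - peak$mode) / peak$sd
}

#' DNA index of a sample against a reference, CEN-normalized
#'
#' `DI = (sample 2N mean / sample CEN mean) / (reference 2N mean /
#' reference CEN mean)`. The chicken-erythrocyte (CEN) spike-in peak in
#' each tube cancels instrument gain, so DI is invariant to any common
#' rescaling of a tube's intensities; the reference is typically a
#' lymphocyte control. `percent_change = (DI - 1) * 100`.
#'
#' @param sample_peak,sample_cen_peak,ref_peak,ref_cen_peak `peak_stats`
#'   objects (or lists with a `mean` element) for the sample 2N peak, the
#'   sample tube's CEN peak, the reference 2N peak and the reference tube's
#'   CEN peak.
#' @param sample_id,reference_id Optional identifiers carried through.
#' @return One-row tibble: `sample_id`, `reference_id`, `di`,
#'   `percent_change`.
#' @export
dna_index <- function(sample_peak, sample_cen_peak, ref_peak, ref_cen_peak,
                      sample_id = NA_character_, reference_id = NA_character_) {
  means <- c(sample_peak$mean, sample_cen_peak$mean,
             ref_peak$mean, ref_cen_peak$mean)
  if (any(!is.finite(means)) || any(means <= 0)) {
    nm_abort("all peak means must be positive and finite",
             class = "nm_invalid_input")
  }
  di <- (sample_peak$mean / sample_cen_peak$mean) /
    (ref_peak$mean / ref_cen_peak$mean)
  tibble(sample_id = sample_id, reference_id = reference_id,
         di = di, percent_change = (di - 1) * 100)
}

# Split a tube's events into sample and CEN calibration events. Uses the
# species_tag column when present; otherwise the CEN peak is taken as the
# lowest-intensity substantial density mode (CEN genomes are much smaller
# than human, so their peak sits below the 2N peak).
split_cen_events <- function(events, channel = "pi_intensity") {
  if ("species_tag" %in% names(events) && !all(is.na(events$species_tag))) {
    list(sample = dplyr::filter(events, .data$species_tag != "CEN" |
                                  is.na(.data$species_tag)),
         cen = dplyr::filter(events, .data$species_tag == "CEN"))
  } else {
    x <- events[[channel]]
    dens <- density(x[is.finite(x) & x >= 0], n = 1024)
    y <- dens$y
    is_max <- c(FALSE, y[2:1023] > y[1:1022] & y[2:1023] >= y[3:1024], FALSE)
    px <- dens$x[is_max][dens$y[is_max] >= 0.1 * max(y)]
    if (length(px) < 2) {
      nm_abort("cannot locate a CEN calibration peak: tag events with species_tag or provide a bimodal histogram",
               class = "nm_invalid_input")
    }
    cut <- mean(sort(px)[1:2])
    list(sample = dplyr::filter(events, .data[[channel]] > cut),
         cen = dplyr::filter(events, .data[[channel]] <= cut))
  }
}

#' Per-sample DNA-content statistics for a multi-sample event table
#'
#' For each `sample_id`, locates the 2N peak of the sample events and of
#' the CEN calibration events, then computes the DNA index against a
#' designated reference sample (a lymphocyte control), plus CV and skew of
#' the 2N peak.
#'
#' @param events Event table: `sample_id`, `pi_intensity`, optional
#'   `species_tag`, `fsc_w`, `neun_intensity`; optional metadata columns
#'   `group`, `region`, `brain_id` (constant within sample).
#' @param reference_id `sample_id` of the reference (control) sample.
#' @param fsc_w_max Optional doublet cut: events with `fsc_w` above this are
#'   dropped before peak detection.
#' @inheritParams detect_g0g1_peak
#' @return Tibble with one row per sample: metadata, `di`,
#'   `percent_change`, `cv_percent`, `skew`, `n_events`.
#' @export
dcv_sample_stats <- function(events, reference_id, channel = "pi_intensity",
                             gate_halfwidth = 0.25, fsc_w_max = NULL,
                             min_events = 500) {
  check_columns(events, c("sample_id", channel), "flow events")
  if (!reference_id %in% events$sample_id) {
    nm_abort(sprintf("reference sample '%s' not present", reference_id),
             class = "nm_invalid_input")
  }
  if (!is.null(fsc_w_max) && "fsc_w" %in% names(events)) {
    events <- dplyr::filter(events, is.na(.data$fsc_w) | .data$fsc_w <= fsc_w_max)
  }
  peaks_for <- function(df) {
    parts <- split_cen_events(df, channel)
    list(sample = detect_g0g1_peak(parts$sample, channel, gate_halfwidth,
                                   min_events = min_events),
         cen = detect_g0g1_peak(parts$cen, channel, gate_halfwidth,
                                min_events = min(min_events, max(50, nrow(parts$cen) %/% 2))))
  }
  ref <- peaks_for(dplyr::filter(events, .data$sample_id == reference_id))
  meta_cols <- intersect(c("group", "region", "brain_id"), names(events))
  events |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      pk <- peaks_for(df)
      di <- dna_index(pk$sample, pk$cen, ref$sample, ref$cen,
                      sample_id = as.character(key$sample_id),
                      reference_id = reference_id)
      meta <- df[1, meta_cols, drop = FALSE]
      dplyr::bind_cols(
        di, as_tibble(meta),
        tibble(cv_percent = pk$sample$cv_percent, skew = pk$sample$skew,
               n_events = pk$sample$n_events)
      )
    }) |>
    dplyr::bind_rows()
}

#' Gate events into NeuN-positive and NeuN-negative fractions
#'
#' The positivity threshold is a high quantile (default 99.9%) of the NeuN
#' channel in an unlabeled control tube, so essentially no control event
#' is called positive.
#'
#' @param events Labeled event table with a `neun_intensity` column.
#' @param unlabeled_control Control event table (no NeuN antibody).
#' @param quantile Control quantile defining the threshold (default 0.999).
#' @return List with tibbles `pos` and `neg` and the numeric `threshold`.
#' @export
neun_gate <- function(events, unlabeled_control, quantile = 0.999) {
  check_columns(events, "neun_intensity", "events")
  check_columns(unlabeled_control, "neun_intensity", "unlabeled control")
  ctrl <- unlabeled_control$neun_intensity
  ctrl <- ctrl[is.finite(ctrl)]
  if (length(ctrl) == 0) {
    nm_abort("unlabeled control has no finite NeuN intensities",
             class = "nm_invalid_input")
  }
  thr <- unname(stats::quantile(ctrl, probs = quantile, names = FALSE))
  list(pos = dplyr::filter(events, .data$neun_intensity > thr),
       neg = dplyr::filter(events, .data$neun_intensity <= thr),
       threshold = thr)
}

#' Group comparison of per-sample DCV statistics
#'
#' One-way ANOVA across groups with Tukey's multiple-comparison test on all
#' pairs; optionally paired t-tests (when `pair_col` identifies matched
#' samples in exactly two groups) and simple linear regressions of the
#' value against covariates such as age, post-mortem interval or Braak
#' score.
#'
#' @param data Per-sample table (e.g. [dcv_sample_stats()] output).
#' @param value Column to compare, as a string (e.g. `"percent_change"` or
#'   `"cv_percent"`).
#' @param group Grouping column name (default `"group"`).
#' @param pair_col Optional column pairing samples across two groups for a
#'   paired t-test.
#' @param covariates Optional character vector of numeric covariate columns
#'   to regress `value` on (one simple regression each).
#' @return Object of class `dcv_test`: list with `anova` (one-row tibble
#'   `statistic`, `df`, `df_residual`, `p_value`), `tukey` (pairwise
#'   tibble), optional `paired_t` and `regressions` tibbles. [tidy()]
#'   returns the Tukey table, [glance()] the ANOVA row.
#' @export
dcv_compare_groups <- function(data, value, group = "group", pair_col = NULL,
                               covariates = NULL) {
  check_columns(data, c(value, group), "DCV statistics")
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  df <- df[is.finite(df$y), ]
  if (nlevels(droplevels(df$g)) < 2 || any(table(droplevels(df$g)) < 2)) {
    nm_abort("group comparison needs >= 2 groups with >= 2 values each",
             class = "nm_invalid_input")
  }
  df$g <- droplevels(df$g)
  degenerate <- all(tapply(df$y, df$g, function(v) sd(v) == 0))
  fit <- aov(y ~ g, data = df)
  an <- anova(fit)
  anova_row <- tibble(
    statistic = an[["F value"]][1], df = an[["Df"]][1],
    df_residual = an[["Df"]][2],
    p_value = if (degenerate) NA_real_ else an[["Pr(>F)"]][1]
  )
  tk <- TukeyHSD(fit)$g
  tukey <- tibble(
    contrast = rownames(tk), diff = tk[, "diff"],
    ci_low = tk[, "lwr"], ci_high = tk[, "upr"], p_adj = tk[, "p adj"]
  )
  paired_t <- NULL
  if (!is.null(pair_col)) {
    check_columns(data, pair_col, "DCV statistics")
    wide <- tibble(y = data[[value]], g = factor(data[[group]]),
                   id = data[[pair_col]]) |>
      tidyr::pivot_wider(names_from = "g", values_from = "y")
    gs <- setdiff(names(wide), "id")
    if (length(gs) == 2) {
      cc <- complete.cases(wide[gs])
      tt <- t.test(wide[[gs[1]]][cc], wide[[gs[2]]][cc], paired = TRUE)
      paired_t <- tibble(contrast = paste(gs[1], "-", gs[2]),
                         estimate = unname(tt$estimate),
                         statistic = unname(tt$statistic),
                         df = unname(tt$parameter), p_value = tt$p.value)
    }
  }
  regressions <- NULL
  if (!is.null(covariates)) {
    regressions <- purrr::map(covariates, function(cv) {
      check_columns(data, cv, "DCV statistics")
      rf <- lm(data[[value]] ~ data[[cv]])
      s <- summary(rf)$coefficients
      tibble(covariate = cv, slope = s[2, "Estimate"],
             std_error = s[2, "Std. Error"], statistic = s[2, "t value"],
             p_value = s[2, "Pr(>|t|)"],
             r_squared = summary(rf)$r.squared)
    }) |> dplyr::bind_rows()
  }
  structure(list(anova = anova_row, tukey = tukey, paired_t = paired_t,
                 regressions = regressions, value = value),
            class = "dcv_test")
}

#' @export
print.dcv_test <- function(x, ...) {
  cat("<dcv_test> one-way ANOVA on", x$value, "\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$anova$df,
              x$anova$df_residual, x$anova$statistic, x$anova$p_value))
  cat("  Tukey pairs:\n")
  print(as.data.frame(x$tukey), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname dcv_compare_groups
#' @param x,object A `dcv_test` object.
#' @param ... Unused.
#' @export
tidy.dcv_test <- function(x, ...) x$tukey

#' @rdname dcv_compare_groups
#' @export
glance.dcv_test <- function(x, ...) x$anova

#' Expected percent DNA gain from a whole-chromosome hypersomy
#'
#' The percent increase in total DNA content produced by one extra copy of
#' a chromosome, relative to the haploid-equivalent content of the genome:
#' `100 * chr_mb / (genome_mb / 2)`. For the largest human chromosome
#' (~250 Mb) against a tetraploid DNA content of 12,800 Mb this is ~3.9%,
#' a yardstick for judging whether an observed DCV gain could be explained
#' by a single aneusomy.
#'
#' @param chr_mb Chromosome size in Mb (default 250).
#' @param genome_mb Total DNA content of the cell in Mb (default 12800,
#'   tetraploid human).
#' @return Percent gain (numeric scalar).
#' @export
hypersomy_percent_gain <- function(chr_mb = 250, genome_mb = 12800) {
  stopifnot(chr_mb > 0, genome_mb > 0)
  100 * chr_mb / (genome_mb / 2)
}
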
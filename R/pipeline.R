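# Required columns per recognized input file.
nm_schemas <- list(
  "standard_curve.csv" = c("assay_id", "log10_copies", "ct"),
  "ct_replicates.csv" = c("unit_id", "brain_id", "region", "group",
                          "assay_id", "replicate_index", "ct"),
  "events.csv" = c("sample_id", "event_id", "pi_intensity"),
  "fish_counts.csv" = c("brain_id", "group", "observer_id", "monosomy",
                        "disomy", "trisomy", "tetrasomy", "n_nuclei"),
  "pna_intensities.csv" = c("unit_id", "group", "intensity")
)

read_stage_input <- function(path) {
  fname <- basename(path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, nm_schemas[[fname]], fname)
  if (nrow(data) == 0) {
    nm_abort(sprintf("%s has no data rows", fname), class = "nm_schema_error")
  }
  data
}

#' Run the full mosaicism analysis pipeline on a directory of inputs
#'
#' Reads whichever recognized inputs are present in `input_dir`
#' (`standard_curve.csv`, `ct_replicates.csv`, `events.csv`,
#' `fish_counts.csv`, `pna_intensities.csv`), validates their schemas,
#' runs the corresponding stages — efficiency calibration, single-nucleus
#' quantification and copy-number calling with cohort summaries, DCV flow
#' statistics with group tests, FISH aneusomy rates, PNA positive
#' fractions — and writes per-stage CSV/JSON outputs plus a run manifest
#' to `out_dir`. Malformed inputs raise a schema error naming the missing
#' column before any computation.
#'
#' @param input_dir Directory containing the input CSVs.
#' @param out_dir Output directory (created if needed).
#' @param config Named list of options overriding the defaults:
#'   `target_assays`, `reference_assay`, `calibrator_region`, `min_reps`,
#'   `system_sd`, `df`, `n_reps_model`, `alpha`, `t_mode`, `k_max`,
#'   `gt6_rule`, `flow_reference`, `gate_halfwidth`, `pna_threshold`.
#' @param seed Integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed is set for completeness).
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(input_dir, out_dir, config = list(), seed = 1) {
  set.seed(seed)
  defaults <- list(
    target_assays = NULL, reference_assay = "SEMA4A",
    calibrator_region = "CBL", min_reps = 10, system_sd = 0.25, df = 68,
    n_reps_model = 18, alpha = 0.05, t_mode = "exact", k_max = 6,
    gt6_rule = "ci", flow_reference = NULL, gate_halfwidth = 0.25,
    pna_threshold = "auto"
  )
  cfg <- modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  present <- intersect(names(nm_schemas), list.files(input_dir))
  if (length(present) == 0) {
    nm_abort(sprintf("no recognized input files in '%s'", input_dir),
             class = "nm_schema_error")
  }
  inputs <- lapply(file.path(input_dir, present), read_stage_input)
  names(inputs) <- present
  outputs <- character(0)
  emit_csv <- function(data, fname) {
    p <- file.path(out_dir, fname)
    readr::write_csv(data, p)
    outputs <<- c(outputs, fname)
  }
  emit_json <- function(x, fname) {
    p <- file.path(out_dir, fname)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    outputs <<- c(outputs, fname)
  }

  efficiencies <- NULL
  if ("standard_curve.csv" %in% present) {
    curves <- fit_standard_curves(inputs[["standard_curve.csv"]])
    emit_csv(curves, "standard_curves.csv")
    usable <- dplyr::filter(curves, .data$usable)
    efficiencies <- setNames(usable$efficiency, usable$assay_id)
  }

  if ("ct_replicates.csv" %in% present) {
    ct <- inputs[["ct_replicates.csv"]]
    targets <- cfg$target_assays %||%
      setdiff(unique(ct$assay_id), cfg$reference_assay)
    est <- rcn_table(ct, target_assays = targets,
                     reference_assay = cfg$reference_assay,
                     efficiencies = efficiencies,
                     calibrator_region = cfg$calibrator_region,
                     min_reps = cfg$min_reps, system_sd = cfg$system_sd,
                     df = cfg$df, alpha = cfg$alpha, t_mode = cfg$t_mode)
    emit_csv(dplyr::select(est, "unit_id", "target_assay", "ddct",
                           "efficiency", "rcn", "ci_low", "ci_high", "n_reps"),
             "rcn_estimates.csv")
    bounds <- build_bounds_table(k_max = cfg$k_max, system_sd = cfg$system_sd,
                                 df = cfg$df, n_reps = cfg$n_reps_model,
                                 alpha = cfg$alpha, t_mode = cfg$t_mode)
    emit_csv(as_tibble(bounds), "bounds_table.csv")
    calls <- call_copy_number(est, bounds, gt6_rule = cfg$gt6_rule)
    emit_csv(dplyr::select(calls, "unit_id", "target_assay", "rcn", "ci_low",
                           "ci_high", "bin", "ambiguous", "gap_assigned"),
             "calls.csv")
    summ <- cohort_summaries(calls)
    emit_csv(dplyr::select(summ, -"bin_histogram"), "cohort_summary.csv")
    summary_json <- purrr::pmap(summ, function(...) {
      row <- list(...)
      row$bin_histogram <- as.list(row$bin_histogram)
      row
    })
    conc <- NULL
    if (length(targets) >= 2) {
      conc <- exon_concordance(
        dplyr::filter(calls, .data$target_assay == targets[1]),
        dplyr::filter(calls, .data$target_assay == targets[2])
      )
    }
    emit_json(list(cohorts = summary_json, concordance = conc),
              "copy_number_summary.json")
  }

  if ("events.csv" %in% present) {
    ev <- inputs[["events.csv"]]
    ref_id <- cfg$flow_reference %||% {
      if ("group" %in% names(ev) && any(ev$group == "LYM")) {
        ev$sample_id[ev$group == "LYM"][1]
      } else unique(ev$sample_id)[1]
    }
    dcv <- dcv_sample_stats(ev, reference_id = ref_id,
                            gate_halfwidth = cfg$gate_halfwidth)
    emit_csv(dcv, "dna_index.csv")
    stats_json <- list(reference_id = ref_id)
    if ("group" %in% names(dcv)) {
      tab <- table(dcv$group)
      if (sum(tab >= 2) >= 2) {
        keep <- dcv$group %in% names(tab)[tab >= 2]
        cmp <- dcv_compare_groups(dcv[keep, ], value = "percent_change")
        stats_json$anova <- as.list(glance(cmp))
        stats_json$tukey <- tidy(cmp)
      }
    }
    emit_json(stats_json, "dcv_stats.json")
  }

  if ("fish_counts.csv" %in% present) {
    fish <- inputs[["fish_counts.csv"]]
    rates <- aneusomy_rates(fish)
    emit_csv(rates, "aneusomy_rates.csv")
    emit_csv(aneusomy_group_summary(rates), "aneusomy_group_summary.csv")
    if (dplyr::n_distinct(fish$group) == 2) {
      emit_json(compare_aneusomy(fish), "fish_stats.json")
    }
  }

  if ("pna_intensities.csv" %in% present) {
    pna <- inputs[["pna_intensities.csv"]]
    fr <- positive_fraction(pna, threshold = cfg$pna_threshold)
    emit_csv(fr, "pna_fractions.csv")
    emit_json(pna_group_compare(pna), "pna_stats.json")
  }

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    package_version = as.character(utils::packageVersion("neuromosaic")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    config_hash = rlang::hash(cfg),
    inputs = lapply(setNames(present, present), function(f) {
      list(file = f, hash = rlang::hash(inputs[[f]]))
    }),
    outputs = lapply(setNames(outputs, outputs), function(f) {
      list(file = f, hash = rlang::hash(readr::read_file(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Aggregate pipeline stage outputs into a single report
#'
#' Collects the per-stage outputs written by [run_pipeline()] in `out_dir`
#' into one structure: the modeled bounds table, per-cohort copy-number
#' summaries and bin histograms, exon concordance, DCV group statistics,
#' FISH aneusomy summaries and PNA fractions. Missing stages produce a
#' partial report with a warning. The report is written as `report.json`
#' and a human-readable `report.txt`.
#'
#' @param out_dir Directory containing [run_pipeline()] outputs.
#' @return The report, invisibly (a named list).
#' @export
make_report <- function(out_dir) {
  grab_csv <- function(fname) {
    p <- file.path(out_dir, fname)
    if (!file.exists(p)) {
      warn(sprintf("make_report: '%s' missing; report will be partial", fname))
      return(NULL)
    }
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  grab_json <- function(fname) {
    p <- file.path(out_dir, fname)
    if (!file.exists(p)) return(NULL)
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  report <- list(
    bounds_table = grab_csv("bounds_table.csv"),
    cohort_summary = grab_csv("cohort_summary.csv"),
    copy_number = grab_json("copy_number_summary.json"),
    dna_index = grab_csv("dna_index.csv"),
    dcv_stats = grab_json("dcv_stats.json"),
    aneusomy = grab_csv("aneusomy_group_summary.csv"),
    fish_stats = grab_json("fish_stats.json"),
    pna_fractions = grab_csv("pna_fractions.csv"),
    pna_stats = grab_json("pna_stats.json")
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  txt <- c("neuromosaic pipeline report", strrep("=", 27), "")
  if (!is.null(report$cohort_summary)) {
    txt <- c(txt, "Copy-number cohort summaries:",
             utils::capture.output(print(as.data.frame(report$cohort_summary),
                                         digits = 4, row.names = FALSE)), "")
  }
  if (!is.null(report$dna_index)) {
    txt <- c(txt, "DNA index per sample:",
             utils::capture.output(print(as.data.frame(report$dna_index),
                                         digits = 4, row.names = FALSE)), "")
  }
  if (!is.null(report$aneusomy)) {
    txt <- c(txt, "Aneusomy group summary:",
             utils::capture.output(print(as.data.frame(report$aneusomy),
                                         digits = 4, row.names = FALSE)), "")
  }
  if (!is.null(report$pna_fractions)) {
    txt <- c(txt, "PNA positive fractions:",
             utils::capture.output(print(as.data.frame(report$pna_fractions),
                                         digits = 4, row.names = FALSE)), "")
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(report)
}
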
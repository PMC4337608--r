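#' Copy-number mixture presets for synthetic cohorts
#'
#' Named probability vectors over integer copy numbers (names = copy
#' number) used as defaults by [simulate_ct_table()]. The disease/control
#' cortex profiles emulate the published single-nucleus distributions —
#' a disease cortex with mean near 3.9, a majority of nuclei above two
#' copies and occasional nuclei up to 12 copies, versus a control cortex
#' with mean near 1.6 and ~10% above two copies. `diploid` is a point mass
#' at two copies, used for calibrator nuclei.
#'
#' @return Named list of probability vectors.
#' @export
cn_mixtures <- function() {
  list(
    AD_CTX = c(`1` = 0.06, `2` = 0.34, `3` = 0.15, `4` = 0.12, `5` = 0.11,
               `6` = 0.08, `7` = 0.05, `8` = 0.04, `9` = 0.02, `10` = 0.02,
               `11` = 0.005, `12` = 0.005),
    ND_CTX = c(`1` = 0.52, `2` = 0.38, `3` = 0.06, `4` = 0.03, `5` = 0.01),
    AD_CBL = c(`1` = 0.15, `2` = 0.62, `3` = 0.15, `4` = 0.05, `5` = 0.03),
    ND_CBL = c(`1` = 0.12, `2` = 0.62, `3` = 0.18, `4` = 0.05, `5` = 0.03),
    diploid = c(`2` = 1)
  )
}

#' Default simulation configuration
#'
#' Returns the full default configuration for the synthetic-data
#' generators, a nested named list; any element can be overridden via
#' `...` (overrides are merged recursively with [utils::modifyList()]).
#' The defaults encode the measurement system the pipeline models:
#' replicate Ct noise SD 0.25 cycles, 18 replicates per assay per nucleus,
#' per-assay efficiencies in the 0.97-1.04 range, diploid cerebellar
#' calibrator nuclei, flow samples with a diploid peak CV of ~5% and a
#' spiked CEN calibration peak, near-null FISH aneusomy class frequencies,
#' and log-normal PNA puncta intensities around a fixed detection
#' threshold.
#'
#' @param ... Named overrides, e.g. `qpcr = list(ct_noise_sd = 0)`.
#' @return Nested configuration list with components `qpcr`, `flow`,
#'   `fish`, `pna`.
#' @export
sim_config <- function(...) {
  mix <- cn_mixtures()
  defaults <- list(
    qpcr = list(
      groups = c("AD", "ND"),
      n_brains = c(AD = 3, ND = 3),
      n_nuclei_ctx = 13,
      n_nuclei_cbl = 8,
      n_replicates = 18,
      ct_noise_sd = 0.25,
      ref_ct = 22,
      reference_assay = "SEMA4A",
      efficiencies = c(APP_ex3 = 1.0, APP_ex14 = 0.973, SEMA4A = 0.997),
      target_assays = c("APP_ex3", "APP_ex14"),
      mixtures_ctx = list(AD = mix$AD_CTX, ND = mix$ND_CTX),
      mixtures_cbl = list(AD = mix$diploid, ND = mix$diploid)
    ),
    flow = list(
      groups = list(
        LYM     = list(n_samples = 2, di_mean = 1.00, di_sd = 0,
                       shoulder_fraction = 0),
        ND_CTX  = list(n_samples = 4, di_mean = 1.02, di_sd = 0.03,
                       shoulder_fraction = 0.05),
        AD_CTX  = list(n_samples = 6, di_mean = 1.08, di_sd = 0.05,
                       shoulder_fraction = 0.15)
      ),
      n_events = 8000,
      n_cen = 2000,
      peak_cv = 0.05,
      diploid_center = 100,
      cen_center = 35,
      cen_cv = 0.04,
      shoulder_shift = 0.20,
      debris_fraction = 0.02,
      neun = NULL  # or list(pos_fraction=, pos_mean=, pos_sd=, neg_mean=, neg_sd=)
    ),
    fish = list(
      n_brains = c(AD = 9, ND = 5),
      n_nuclei = 500,
      n_observers = 2,
      probs = list(
        AD = c(monosomy = 0.02, disomy = 0.955, trisomy = 0.02, tetrasomy = 0.005),
        ND = c(monosomy = 0.02, disomy = 0.955, trisomy = 0.02, tetrasomy = 0.005)
      )
    ),
    pna = list(
      n_nuclei = c(AD = 50, ND = 50, DS = 50),
      positive_fraction = c(AD = 0.56, ND = 0.22, DS = 0.14),
      threshold = 100,
      n_controls = 30,
      lipofuscin_fraction = 0.2,
      telomere_fail_fraction = 0.05
    )
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    stopifnot(!is.null(names(overrides)), all(names(overrides) != ""))
    defaults <- modifyList(defaults, overrides)
  }
  # YAML-sourced overrides arrive as lists; these fields must be named
  # numeric vectors
  defaults$qpcr$n_brains <- unlist(defaults$qpcr$n_brains)
  defaults$qpcr$efficiencies <- unlist(defaults$qpcr$efficiencies)
  defaults$qpcr$mixtures_ctx <- lapply(defaults$qpcr$mixtures_ctx, unlist)
  defaults$qpcr$mixtures_cbl <- lapply(defaults$qpcr$mixtures_cbl, unlist)
  defaults$fish$n_brains <- unlist(defaults$fish$n_brains)
  defaults$fish$probs <- lapply(defaults$fish$probs, unlist)
  defaults$pna$n_nuclei <- unlist(defaults$pna$n_nuclei)
  defaults$pna$positive_fraction <- unlist(defaults$pna$positive_fraction)
  defaults
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML structure mirrors [sim_config()]'s nested list; only the keys
#' present need be given, and they are merged over the defaults.
#'
#' @param path Path to a YAML file.
#' @return A full configuration list (defaults plus overrides).
#' @export
read_sim_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) return(sim_config())
  do.call(sim_config, overrides)
}

# Draw integer copy numbers from a named mixture vector.
draw_cn <- function(n, mixture) {
  p <- as.numeric(mixture)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    nm_abort("copy-number mixture probabilities must be non-negative and sum to 1",
             class = "nm_config_error")
  }
  vals <- as.integer(names(mixture))
  vals[sample.int(length(vals), size = n, replace = TRUE, prob = p)]
}

#' Simulate a single-nucleus Ct replicate table with known truth
#'
#' Forward model of the qPCR measurement: each nucleus draws a true copy
#' number from its group/region mixture; the reference assay's replicate
#' Cts are normal around a fixed base Ct, and each target assay's
#' replicates are normal around
#' `base_ct - log(CN/2) / log(1 + E)` — so a diploid nucleus has ddCt 0
#' and CN doublings shift the target Ct by one cycle at E = 1. All
#' biological signal is placed in the target-gene Ct. Cerebellar
#' calibrator nuclei are generated per brain (diploid by default) so the
#' quantification chain can calibrate exactly as in the paired-cerebellum
#' design.
#'
#' @param config A [sim_config()] list (component `qpcr` is used).
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output.
#' @return List with `ct_replicates` (schema: `unit_id`, `brain_id`,
#'   `region`, `group`, `assay_id`, `replicate_index`, `ct`) and `truth`
#'   (`unit_id`, `brain_id`, `region`, `group`, `true_cn`).
#' @export
simulate_ct_table <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  qc <- config$qpcr
  units <- purrr::map(qc$groups, function(g) {
    mix_ctx <- qc$mixtures_ctx[[g]] %||% cn_mixtures()$diploid
    mix_cbl <- qc$mixtures_cbl[[g]] %||% cn_mixtures()$diploid
    purrr::map(seq_len(qc$n_brains[[g]]), function(b) {
      brain <- sprintf("%s_%d", g, b)
      dplyr::bind_rows(
        tibble(unit_id = sprintf("%s_CTX_n%02d", brain, seq_len(qc$n_nuclei_ctx)),
               brain_id = brain, region = "CTX", group = g,
               true_cn = draw_cn(qc$n_nuclei_ctx, mix_ctx)),
        tibble(unit_id = sprintf("%s_CBL_n%02d", brain, seq_len(qc$n_nuclei_cbl)),
               brain_id = brain, region = "CBL", group = g,
               true_cn = draw_cn(qc$n_nuclei_cbl, mix_cbl))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  assays <- c(qc$reference_assay, qc$target_assays)
  eff <- setNames(rep(1, length(assays)), assays)
  eff[names(qc$efficiencies)[names(qc$efficiencies) %in% assays]] <-
    qc$efficiencies[names(qc$efficiencies) %in% assays]
  qc$efficiencies <- eff
  reps <- tidyr::crossing(units, assay_id = assays,
                          replicate_index = seq_len(qc$n_replicates)) |>
    dplyr::mutate(
      mean_ct = ifelse(
        .data$assay_id == qc$reference_assay,
        qc$ref_ct,
        qc$ref_ct - log(.data$true_cn / 2) /
          log(1 + qc$efficiencies[.data$assay_id])
      ),
      ct = .data$mean_ct + rnorm(dplyr::n(), 0, qc$ct_noise_sd)
    ) |>
    dplyr::select("unit_id", "brain_id", "region", "group", "assay_id",
                  "replicate_index", "ct")
  list(ct_replicates = reps,
       truth = dplyr::select(units, "unit_id", "brain_id", "region",
                             "group", "true_cn"))
}

#' Simulate a qPCR standard-curve dilution series
#'
#' Points follow `ct = intercept - log10_copies / log10(1 + E) + noise`,
#' i.e. slope `-1/log10(1+E)`; with zero noise, [fit_standard_curve()]
#' recovers E exactly.
#'
#' @param efficiency True amplification efficiency E.
#' @param noise_sd Ct noise SD (default 0, noiseless).
#' @param levels log10 copy-number levels (default 2..7).
#' @param intercept Ct at one copy (default 38).
#' @param assay_id Assay label.
#' @param seed RNG seed (only matters when `noise_sd > 0`).
#' @return Tibble with `assay_id`, `log10_copies`, `ct`.
#' @export
simulate_standard_curve <- function(efficiency = 1, noise_sd = 0,
                                    levels = 2:7, intercept = 38,
                                    assay_id = "assay", seed = 1) {
  set.seed(seed)
  stopifnot(efficiency > 0)
  tibble(
    assay_id = assay_id,
    log10_copies = as.numeric(levels),
    ct = intercept - as.numeric(levels) / log10(1 + efficiency) +
      rnorm(length(levels), 0, noise_sd)
  )
}

#' Simulate flow-cytometry DNA-content event tables
#'
#' Each sample's propidium-iodide histogram is a mixture: a main G0/G1
#' peak at `diploid_center * DI` with the configured CV, an optional right
#' shoulder (a fraction of events shifted up by `shoulder_shift`), a small
#' uniform debris fraction, and a tagged CEN calibration peak. NeuN
#' intensities are bimodal when a `neun` component is configured.
#'
#' @param config A [sim_config()] list (component `flow` is used).
#' @param seed Integer RNG seed.
#' @return List with `events` (`sample_id`, `event_id`, `pi_intensity`,
#'   `fsc_w`, `neun_intensity`, `species_tag`, `group`) and `truth`
#'   (`sample_id`, `group`, `true_di`, `shoulder_fraction`).
#' @export
simulate_flow_events <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  fl <- config$flow
  out <- purrr::imap(fl$groups, function(spec, gname) {
    purrr::map(seq_len(spec$n_samples), function(i) {
      sid <- sprintf("%s_%d", gname, i)
      di <- if (spec$di_sd > 0) rnorm(1, spec$di_mean, spec$di_sd) else spec$di_mean
      center <- fl$diploid_center * di
      n <- fl$n_events
      n_debris <- round(fl$debris_fraction * n)
      n_shoulder <- round(spec$shoulder_fraction * (n - n_debris))
      n_main <- n - n_debris - n_shoulder
      pi_main <- rnorm(n_main, center, fl$peak_cv * center)
      pi_shoulder <- rnorm(n_shoulder, center * (1 + fl$shoulder_shift),
                           fl$peak_cv * center)
      pi_debris <- runif(n_debris, 0.1 * center, 2.5 * center)
      pi_cen <- rnorm(fl$n_cen, fl$cen_center, fl$cen_cv * fl$cen_center)
      pi_all <- c(pi_main, pi_shoulder, pi_debris, pi_cen)
      n_tot <- length(pi_all)
      neun <- rep(NA_real_, n_tot)
      if (!is.null(fl$neun)) {
        nn <- fl$neun
        is_pos <- runif(n) < nn$pos_fraction
        neun[seq_len(n)] <- ifelse(is_pos,
                                   rnorm(n, nn$pos_mean, nn$pos_sd),
                                   rnorm(n, nn$neg_mean, nn$neg_sd))
      }
      ev <- tibble(
        sample_id = sid,
        event_id = sprintf("%s_e%05d", sid, seq_len(n_tot)),
        pi_intensity = pmax(pi_all, 0),
        fsc_w = rnorm(n_tot, 100, 10),
        neun_intensity = neun,
        species_tag = c(rep("sample", n), rep("CEN", fl$n_cen)),
        group = gname
      )
      truth <- tibble(sample_id = sid, group = gname, true_di = di,
                      shoulder_fraction = spec$shoulder_fraction)
      list(events = ev, truth = truth)
    })
  })
  flat <- purrr::flatten(out)
  list(events = dplyr::bind_rows(purrr::map(flat, "events")),
       truth = dplyr::bind_rows(purrr::map(flat, "truth")))
}

#' Simulate per-brain, per-observer FISH aneusomy count tables
#'
#' Each brain/observer row is one multinomial draw of `n_nuclei` nuclei
#' over the four aneusomy classes with the group's class probabilities.
#'
#' @param config A [sim_config()] list (component `fish` is used).
#' @return Tibble in the `fish_counts.csv` schema.
#' @param seed Integer RNG seed.
#' @export
simulate_fish_counts <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  fc <- config$fish
  classes <- c("monosomy", "disomy", "trisomy", "tetrasomy")
  purrr::map(names(fc$n_brains), function(g) {
    p <- fc$probs[[g]][classes]
    if (abs(sum(p) - 1) > 1e-8) {
      nm_abort("FISH class probabilities must sum to 1", class = "nm_config_error")
    }
    purrr::map(seq_len(fc$n_brains[[g]]), function(b) {
      counts <- rmultinom(fc$n_observers, size = fc$n_nuclei, prob = p)
      tibble(
        brain_id = sprintf("%s_%d", g, b), group = g,
        observer_id = sprintf("obs%d", seq_len(fc$n_observers)),
        monosomy = counts[1, ], disomy = counts[2, ],
        trisomy = counts[3, ], tetrasomy = counts[4, ],
        n_nuclei = fc$n_nuclei
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Simulate PNA-FISH puncta intensity records
#'
#' Per group, a configured fraction of nuclei carry detectable signal:
#' their brightest punctum's intensity is log-normally distributed at or
#' above the detection threshold, while signal-negative nuclei fall below
#' it (some with zero puncta). Lipofuscin-flagged puncta (bright,
#' autofluorescent) and telomere-negative nuclei are mixed in at the
#' configured rates to exercise the exclusion rules; negative-control
#' records sit just below the threshold so that the `"auto"` threshold
#' reproduces it.
#'
#' @param config A [sim_config()] list (component `pna` is used).
#' @param seed Integer RNG seed.
#' @return List with `records` (the `pna_intensities.csv` schema) and
#'   `truth` (`unit_id`, `group`, `true_positive`).
#' @export
simulate_pna <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  pn <- config$pna
  thr <- pn$threshold
  groups <- names(pn$n_nuclei)
  recs <- purrr::map(groups, function(g) {
    n <- pn$n_nuclei[[g]]
    is_pos <- runif(n) < pn$positive_fraction[[g]]
    telomere_ok <- runif(n) >= pn$telomere_fail_fraction
    purrr::map(seq_len(n), function(i) {
      uid <- sprintf("%s_pna_%03d", g, i)
      if (is_pos[i]) {
        # brightest punctum at/above threshold; optional dimmer second punctum
        top <- thr * exp(abs(rnorm(1, 0, 0.35)))
        n_p <- sample(1:2, 1)
        ints <- c(top, if (n_p == 2) top * exp(-abs(rnorm(1, 0, 0.3)) - 0.05))
      } else {
        n_p <- sample(0:1, 1)
        ints <- if (n_p == 0) NA_real_ else thr * exp(-abs(rnorm(1, 0, 0.4)) - 0.1)
      }
      rows <- tibble(unit_id = uid, group = g, intensity = ints,
                     n_puncta = n_p, lipofuscin = FALSE,
                     telomere_present = telomere_ok[i],
                     is_negative_control = FALSE)
      if (runif(1) < pn$lipofuscin_fraction) {
        rows <- dplyr::bind_rows(rows, tibble(
          unit_id = uid, group = g,
          intensity = thr * exp(abs(rnorm(1, 0.5, 0.3))),
          n_puncta = n_p, lipofuscin = TRUE,
          telomere_present = telomere_ok[i], is_negative_control = FALSE
        ))
      }
      rows
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  controls <- tibble(
    unit_id = sprintf("ctrl_%03d", seq_len(pn$n_controls)),
    group = "control",
    intensity = thr * exp(-abs(rnorm(pn$n_controls, 0, 0.25)) - 0.02),
    n_puncta = 1, lipofuscin = FALSE, telomere_present = TRUE,
    is_negative_control = TRUE
  )
  truth <- recs |>
    dplyr::distinct(.data$unit_id, .data$group) |>
    dplyr::left_join(
      recs |>
        dplyr::filter(!.data$lipofuscin) |>
        dplyr::group_by(.data$unit_id) |>
        dplyr::summarise(true_positive = any(.data$intensity >= thr, na.rm = TRUE),
                         .groups = "drop"),
      by = "unit_id"
    )
  list(records = dplyr::bind_rows(recs, controls), truth = truth)
}

#' Write a complete synthetic input set to a directory
#'
#' Generates every input table the pipeline consumes — standard curves, Ct
#' replicates, flow events, FISH counts, PNA intensities — plus matching
#' `truth_*.csv` files, and writes them as CSV. Byte-identical for
#' identical seed and config.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()] list.
#' @param seed Integer RNG seed; sub-generators use fixed offsets of it.
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(dir, config = sim_config(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc <- config$qpcr
  curves <- purrr::imap(qc$efficiencies,
                        function(e, a) simulate_standard_curve(
                          efficiency = e, noise_sd = 0.05, assay_id = a,
                          seed = seed + 11)) |>
    dplyr::bind_rows()
  ct <- simulate_ct_table(config, seed = seed + 1)
  fl <- simulate_flow_events(config, seed = seed + 2)
  fish <- simulate_fish_counts(config, seed = seed + 3)
  pna <- simulate_pna(config, seed = seed + 4)
  files <- c(
    standard_curve = "standard_curve.csv",
    ct_replicates = "ct_replicates.csv",
    truth_cn = "truth_copy_number.csv",
    events = "events.csv",
    truth_flow = "truth_flow.csv",
    fish_counts = "fish_counts.csv",
    pna_intensities = "pna_intensities.csv",
    truth_pna = "truth_pna.csv"
  )
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  readr::write_csv(curves, paths[["standard_curve"]])
  readr::write_csv(ct$ct_replicates, paths[["ct_replicates"]])
  readr::write_csv(ct$truth, paths[["truth_cn"]])
  readr::write_csv(fl$events, paths[["events"]])
  readr::write_csv(fl$truth, paths[["truth_flow"]])
  readr::write_csv(fish, paths[["fish_counts"]])
  readr::write_csv(pna$records, paths[["pna_intensities"]])
  readr::write_csv(pna$truth, paths[["truth_pna"]])
  invisible(paths)
}
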
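# End-to-end experiment orchestration: synthesis -> localization ->
# acoustic features -> classification, with serialized outputs.

#' Default run configuration
#'
#' All parameters of a full experiment in one serializable list; a run can
#' be replayed bit-identically from its saved config.
#'
#' @param seed Master seed.
#' @param n_nasal,n_oral Population sizes for feature measurement and
#'   classification.
#' @param n_localize Calls per class passed through scene simulation and
#'   map allocation (localization is the expensive stage).
#' @param snr_db SNR of the added background noise for the mono corpus.
#' @param scene_sample_rate Sampling rate for localization scenes in Hz.
#' @param map_nx,map_ny Acoustic-map grid resolution for localization.
#' @param out_dir Output directory.
#' @export
run_config <- function(seed = 1, n_nasal = 60, n_oral = 60, n_localize = 5,
                       snr_db = 20, scene_sample_rate = 16000,
                       map_nx = 24, map_ny = 18, out_dir = tempfile("rumble_run_")) {
  list(seed = seed, n_nasal = n_nasal, n_oral = n_oral,
       n_localize = n_localize, snr_db = snr_db,
       scene_sample_rate = scene_sample_rate,
       map_nx = map_nx, map_ny = map_ny, out_dir = out_dir)
}

#' Per-class summary of measured features
#'
#' Mean and SD per emission class for duration, mean F0, F1, F2 and peak
#' SPL, plus the VTL implied by the class-mean formant spacing
#' (c / (2 * (F2 - F1)), c = 350 m/s).
#'
#' @param features Tibble from [measure_calls()] (needs `emission`,
#'   `duration`, `f0_mean`, `f1`, `f2`, `peak_spl`).
#' @return Tibble with one row per class present.
#' @export
table1_summary <- function(features) {
  out <- features |>
    dplyr::filter(!is.na(.data$emission)) |>
    dplyr::group_by(emission = .data$emission) |>
    dplyr::summarise(
      n = dplyr::n(),
      duration_mean = mean(.data$duration, na.rm = TRUE),
      duration_sd = sd(.data$duration, na.rm = TRUE),
      f0_sd = sd(.data$f0_mean, na.rm = TRUE),
      f0_mean = mean(.data$f0_mean, na.rm = TRUE),
      f1_mean = mean(.data$f1, na.rm = TRUE),
      f1_sd = sd(.data$f1, na.rm = TRUE),
      f2_mean = mean(.data$f2, na.rm = TRUE),
      f2_sd = sd(.data$f2, na.rm = TRUE),
      spl_mean = mean(.data$peak_spl, na.rm = TRUE),
      spl_sd = sd(.data$peak_spl, na.rm = TRUE),
      .groups = "drop"
    )
  out$vtl <- ifelse(out$f2_mean > out$f1_mean,
                    estimate_vtl_safe(out$f1_mean, out$f2_mean), NA_real_)
  out
}

estimate_vtl_safe <- function(f1, f2) {
  vapply(seq_along(f1), function(i) {
    if (is.na(f1[i]) || is.na(f2[i]) || f2[i] <= f1[i]) return(NA_real_)
    estimate_vtl(f1[i], f2[i])
  }, numeric(1))
}

#' Run the full synthetic experiment
#'
#' Stages: (1) draw a call population and synthesize the mono corpus at
#' `snr_db`; (2) simulate single-call scenes for `n_localize` calls per
#' class and allocate each to nasal/oral from its acoustic map; (3)
#' measure per-call features and summarise per class; (4) build LPC
#' descriptors and run the split/CV classification experiment (skipped,
#' with a notice, if a class is absent). Outputs are written under
#' `config$out_dir`, each tagged with the config hash.
#'
#' @param config List from [run_config()].
#' @return Invisibly, a list with `population`, `features`, `summary`,
#'   `allocation`, `experiment`, `out_dir`.
#' @export
run_experiment <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash identifies the scientific configuration, not the output location
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log_line <- function(...) message(sprintf(...))

  # stage 1: population + mono corpus
  pop <- sample_call_population(config$n_nasal, config$n_oral,
                                seed = config$seed)
  calls <- synthesize_calls(pop)
  calls$call <- purrr::map2(calls$call, calls$seed, function(cl, s) {
    add_noise_snr(cl, config$snr_db, seed = (s + 7L) %% .Machine$integer.max)
  })
  log_line("stage synth: %d nasal + %d oral calls", config$n_nasal, config$n_oral)

  # stage 2: localization on a subset
  allocation <- NULL
  if (config$n_localize > 0) {
    sub <- calls |>
      dplyr::group_by(.data$emission) |>
      dplyr::slice_head(n = config$n_localize) |>
      dplyr::ungroup()
    plane <- image_plane(nx = config$map_nx, ny = config$map_ny)
    geom <- build_star_array()
    allocation <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
      one <- place_calls(sub[i, ])
      sc <- scene_spec(one, array = geom, plane = plane,
                       sample_rate = config$scene_sample_rate)
      sim <- simulate_scene(sc, seed = sub$seed[i] %% 100000L)
      allocate_scene(sim, sc)
    }))
    log_line("stage beamform: %d/%d calls allocated correctly",
             sum(allocation$label == allocation$truth), nrow(allocation))
  }

  # stage 3: features
  features <- measure_calls(calls)
  summary_tbl <- table1_summary(features)
  log_line("stage analyze: %d feature rows, %d measurement failures",
           nrow(features), sum(!is.na(features$failure)))

  # stage 4: classification
  experiment <- NULL
  if (config$n_nasal >= 2 && config$n_oral >= 2) {
    desc <- build_descriptors(calls)
    experiment <- classify_experiment(desc, seed = config$seed)
    log_line("stage classify: held-out accuracy %s",
             paste(sprintf("%s %.3f", experiment$accuracies$classifier,
                           experiment$accuracies$accuracy), collapse = ", "))
  } else {
    log_line("stage classify: skipped (need >= 2 calls in each class)")
  }

  # outputs
  out <- function(name) file.path(config$out_dir, name)
  jsonlite::write_json(list(config_hash = cfg_hash, config = config),
                       out("config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config_hash = cfg_hash,
                            population = pop),
                       out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(allocation)) {
    write.csv(cbind(allocation, config_hash = cfg_hash),
              out("allocation.csv"), row.names = FALSE)
  }
  write.csv(cbind(features, config_hash = cfg_hash), out("features.csv"),
            row.names = FALSE)
  if (!is.null(experiment)) {
    jsonlite::write_json(
      list(config_hash = cfg_hash,
           accuracies = experiment$accuracies,
           best = experiment$classifiers$best),
      out("eval.json"), auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(experiment_summary_md(summary_tbl, allocation, experiment, cfg_hash),
             out("summary.md"))
  invisible(list(population = pop, features = features,
                 summary = summary_tbl, allocation = allocation,
                 experiment = experiment, out_dir = config$out_dir))
}

experiment_summary_md <- function(summary_tbl, allocation, experiment, cfg_hash) {
  targets <- population_defaults
  lines <- c(
    sprintf("# Synthetic rumble experiment (config %s)", cfg_hash), "",
    "## Per-class features (measured vs generator population)", "",
    "| class | n | duration (s) | F0 (Hz) | F1 (Hz) | F2 (Hz) | SPL (dB) | VTL (m) |",
    "|---|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(summary_tbl))) {
    s <- summary_tbl[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d | %.2f +/- %.2f | %.1f +/- %.1f | %.1f | %.1f | %.1f | %.2f |",
      s$emission, s$n, s$duration_mean, s$duration_sd, s$f0_mean, s$f0_sd,
      s$f1_mean, s$f2_mean, s$spl_mean, s$vtl))
  }
  pop_line <- sprintf(
    "Population targets: nasal F0 %.1f Hz, duration %.2f s, SPL %.1f dB; oral F0 %.1f Hz, duration %.2f s, SPL %.2f dB.",
    targets$nasal$f0[1], targets$nasal$duration[1], targets$nasal$spl[1],
    targets$oral$f0[1], targets$oral$duration[1], targets$oral$spl[1])
  lines <- c(lines, "", pop_line)
  if (nrow(summary_tbl) == 2) {
    ratio <- summary_tbl$f1_mean[summary_tbl$emission == "oral"] /
      summary_tbl$f1_mean[summary_tbl$emission == "nasal"]
    lines <- c(lines, sprintf("Oral/nasal mean F1 ratio: %.2f", ratio))
  }
  if (!is.null(allocation)) {
    lines <- c(lines, "", sprintf(
      "## Localization: %d/%d calls allocated to the true emission point (%d ambiguous)",
      sum(allocation$label == allocation$truth), nrow(allocation),
      sum(allocation$label == "ambiguous")))
  }
  if (!is.null(experiment)) {
    acc <- experiment$accuracies
    lines <- c(lines, "", "## Classification (held-out accuracy / swap replicate)", "",
               sprintf("- %s: %.3f / %.3f", acc$classifier, acc$accuracy,
                       acc$swap_accuracy))
  }
  lines
}

#' Read a run configuration from JSON or YAML
#'
#' Unknown fields are rejected so a saved config replays exactly.
#'
#' @param path File ending in .json, .yaml or .yml.
#' @return A config list as from [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if ("config" %in% names(vals)) vals <- vals$config   # run_experiment output
  defaults <- run_config()
  extra <- setdiff(names(vals), names(defaults))
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  utils::modifyList(defaults, vals)
}
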
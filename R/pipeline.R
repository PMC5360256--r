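#' Pipeline configuration
#'
#' Bundles the parameters of the end-to-end analysis: either simulate a
#' recording (the default) or load one from disk, then calibrate, parse,
#' detect, quality-filter and summarise.
#'
#' @param seed Integer seed governing all randomness of the run.
#' @param out_dir Output directory for the artifact bundle.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param simulate Generate the recording (`TRUE`) or read it from
#'   `input_prefix` (`FALSE`)?
#' @param input_prefix Path prefix of an existing recording (see
#'   [write_recording()]); required when `simulate = FALSE`.
#' @param threshold Transient detection threshold (noise SDs).
#' @param step_window Step-fit window (s).
#' @param bin_width Lysis-time bin width for proportions (min).
#' @param write_tiff Also simulate and write the TIRF stack?
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("tetherclamp_run_"),
                            sim = sim_config(seed = seed), simulate = TRUE,
                            input_prefix = NULL, threshold = 4,
                            step_window = 0.2, bin_width = 10,
                            write_tiff = FALSE) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 simulate = simulate, input_prefix = input_prefix,
                 threshold = threshold, step_window = step_window,
                 bin_width = bin_width, write_tiff = write_tiff),
            class = "pipeline_config")
}

#' Run the full force-clamp analysis pipeline
#'
#' Executes simulate (or load) -> drift calibration -> phase parsing and
#' force computation -> event detection and classification -> segment
#' quality cascade -> summary statistics, writing the artifact bundle
#' (recording TSV + metadata, ground truth, segments table, events table,
#' QC report, statistics, provenance with seed and config hash) to the
#' configured output directory.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects (`recording`,
#'   `ground_truth`, `phases`, `segments`, `events`, `qc`, `stats`,
#'   `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate) {
    if (is.null(config$input_prefix) ||
        !file.exists(paste0(config$input_prefix, ".tsv")))
      stop("input recording not found: ",
           if (is.null(config$input_prefix)) "(no input_prefix)" else
             config$input_prefix)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # 1. obtain recording
  gt <- NULL
  if (config$simulate) {
    sim <- simulate_recording(config$sim)
    rec <- sim$recording
    gt <- sim$ground_truth
    paths$recording <- write_recording(rec, file.path(config$out_dir,
                                                      "recording"))
    paths$ground_truth <- write_tsv_table(
      gt, file.path(config$out_dir, "ground_truth.tsv"),
      comment = "injected events: times [s], dz [nm], tau [s]")
    if (config$write_tiff) {
      stack <- simulate_tirf_stack(rec, config$sim$tirf, config$sim)
      paths$tirf <- write_tirf_stack(stack,
                                     file.path(config$out_dir, "stack.tiff"))
    }
  } else {
    rec <- read_recording(config$input_prefix)
  }

  # 2. drift calibration from the (free-cantilever) approach phase
  sched <- rec$meta$schedule
  app <- sched[sched$phase == "approach", , drop = FALSE]
  asel <- rec$times >= app$t_start & rec$times < app$t_end
  drift <- estimate_drift(list(data.frame(z = rec$z_servo[asel],
                                          v = rec$v_defl[asel])))
  rec_c <- correct_drift(rec, drift$drift)

  # 3. phases and pull forces
  phases <- parse_phases(rec_c)
  segs <- phases$segments
  noise <- noise_sd_estimate(rec_c$v_defl[asel])
  ff <- lapply(seq_len(nrow(segs)), function(i)
    compute_pull_force(segs$setpoint_v[i], phases$v_contact, NA,
                       rec$meta$spring_constant,
                       rec$meta$deflection_sensitivity, noise_sd = noise))
  segs$F <- vapply(ff, `[[`, numeric(1), "F")
  segs$sigma_F <- vapply(ff, `[[`, numeric(1), "sigma_F")
  segs$t_lysis <- rec$meta$t_lysis

  # 4. events
  events <- detect_events(rec_c, phases, threshold = config$threshold,
                          step_window = config$step_window)

  # 5. segment QC
  segs$is_U <- vapply(seq_len(nrow(segs)), function(i)
    flag_U(segs[i, ], segs, events,
           rises = deflection_rises(rec_c, t_from = segs$t_start[i],
                                    noise_sd = noise)),
    logical(1))
  qc <- filter_segments(segs)
  paths$segments <- write_tsv_table(
    qc$survivors, file.path(config$out_dir, "segments.tsv"),
    comment = "clamp segments after QC cascade; F [pN], sigma_F [pN]")
  paths$events <- write_tsv_table(
    events, file.path(config$out_dir, "events.tsv"),
    comment = "detected tether-extension events; dz [nm], tau [s]")
  jsonlite::write_json(
    list(counts = qc$report$counts, n_input = qc$report$n_input,
         n_survivors = qc$report$n_survivors,
         push_diagnostic = push_force_diagnostic(segs, events)),
    file.path(config$out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA)
  paths$qc <- file.path(config$out_dir, "qc_report.json")

  # 6. summary statistics
  surv_idx <- qc$survivors$index
  durations <- vapply(surv_idx, function(i)
    as.numeric(clamp_duration(segs[segs$index == i, ],
                              events[events$segment_index == i, ])),
    numeric(1))
  fc_short <- events$event_type == "FC" & !is.na(events$dz) &
    events$dz < 50 & events$segment_index %in% surv_idx
  rate <- if (sum(durations) > 0)
    event_rate(sum(fc_short), sum(durations)) else list(rate = NA, se = NA)
  hist <- step_histogram(events$dz[fc_short])
  peak <- if (sum(hist$count > 0) >= 4)
    try(fit_gaussian_peak(hist), silent = TRUE) else NULL
  if (inherits(peak, "try-error")) peak <- NULL
  stats_out <- list(
    n_events = nrow(events),
    n_fc_short = sum(fc_short),
    total_clamp_duration_s = sum(durations),
    short_event_rate_per_s = rate$rate,
    short_event_rate_se = rate$se,
    dz_peak_nm = if (!is.null(peak)) peak$dz_peak else NA,
    dz_peak_se_nm = if (!is.null(peak)) peak$dz_peak_se else NA,
    dz_sd_nm = if (!is.null(peak)) peak$sd_peak else NA)
  jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$stats <- file.path(config$out_dir, "stats.json")

  # 7. provenance
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), "sim")],
    auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, config_hash = config_hash(as.character(cfg_json)),
         package_version = as.character(utils::packageVersion("tetherclamp"))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  paths$provenance <- file.path(config$out_dir, "provenance.json")

  invisible(list(recording = rec_c, ground_truth = gt, phases = phases,
                 segments = segs, events = events, qc = qc,
                 stats = stats_out, paths = paths))
}
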
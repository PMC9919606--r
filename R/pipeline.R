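# End-to-end pipeline and command-line entry points.
#
# simulate -> preprocess -> delineate -> features -> experiments ->
# importance, with every stage's artifact persistable as plain text
# (CSV/JSON) so each stage is independently inspectable and re-runnable.

#' Process one recording into feature-table rows
#'
#' Centers and band-pass filters the signal, detects R peaks, delineates the
#' waves, and extracts the windowed features for all five epochs.
#'
#' @param recording an [ecg_recording()].
#' @param spec filter design; default 0.5-40 Hz degree-4 at the recording's
#'   sampling rate.
#' @param onoff_frac delineation onset/offset threshold, see
#'   [delineate_waves()].
#' @param window_s,overlap window geometry.
#' @return feature-table rows for the recording.
#' @export
process_recording <- function(recording,
                              spec = design_bandpass(0.5, 40, recording$fs, 4),
                              onoff_frac = 0.10, window_s = 20,
                              overlap = 0.75) {
  epochs <- segment_epochs(recording)
  filtered <- apply_zero_phase(spec, ecg_center(recording$signal))
  r <- detect_r_peaks(filtered, recording$fs)
  fid <- delineate_waves(filtered, r, recording$fs, onoff_frac = onoff_frac)
  build_feature_table(fid, filtered, epochs, recording$fs,
                      recording$participant, recording$session,
                      window_s = window_s, overlap = overlap)
}

#' Run the full pipeline over a synthetic cohort
#'
#' Realizes each recording of a lazy cohort in turn (so memory stays flat),
#' processes it, concatenates the window features, normalizes by the
#' baseline means, and assembles the labeled baseline-vs-CPT dataset.
#'
#' @param cohort an `ecg_cohort` from [generate_cohort()].
#' @param ... passed to [process_recording()].
#' @param progress emit a message per recording.
#' @return labeled, normalized feature table (see [assemble_dataset()]).
#' @export
cohort_dataset <- function(cohort, ..., progress = FALSE) {
  parts <- vector("list", length(cohort))
  for (i in seq_len(length(cohort))) {
    rr <- realize_recording(cohort, i)
    parts[[i]] <- process_recording(rr$recording, ...)
    if (progress)
      message(sprintf("processed recording %d/%d", i, length(cohort)))
  }
  table <- do.call(rbind, parts)
  norm <- normalize_by_baseline(table)
  suppressMessages(assemble_dataset(norm$table))
}

#' Simulate a cohort to disk
#'
#' Writes one signal CSV and one trigger/ground-truth JSON per recording,
#' plus a manifest JSON recording the seed and generator parameters from
#' which every file is re-derivable.
#'
#' @param out_dir output directory (created if needed).
#' @param n_participants,n_sessions,seed,fs cohort parameters, see
#'   [generate_cohort()].
#' @param effect,noise generator components.
#' @return invisibly, the manifest path.
#' @export
cmd_simulate <- function(out_dir, n_participants = 36, n_sessions = 2,
                         effect = effect_spec(), noise = noise_spec(),
                         seed = 1L, fs = 1000) {
  cohort <- generate_cohort(n_participants, n_sessions, effect = effect,
                            noise = noise, seed = seed, fs = fs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- cohort_index(cohort)
  for (i in seq_len(length(cohort))) {
    rr <- realize_recording(cohort, i)
    stem <- sprintf("p%02d_s%d", idx$participant[i], idx$session[i])
    write_recording_csv(rr$recording, file.path(out_dir, paste0(stem, ".csv")))
    write_triggers_json(rr$recording, file.path(out_dir, paste0(stem, "_triggers.json")),
                        truth = rr$truth)
  }
  manifest <- list(seed = seed, n_participants = n_participants,
                   n_sessions = n_sessions, fs = fs,
                   effect = unclass(effect), noise = unclass(noise),
                   recordings = sprintf("p%02d_s%d.csv", idx$participant,
                                        idx$session))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Run experiments and importance over a prepared dataset
#'
#' @param table labeled feature table (from [cohort_dataset()] or read back
#'   from a features CSV).
#' @param out_dir output directory for the result CSVs.
#' @param approaches subset of the three approaches.
#' @param roster classifier roster; default all eight families.
#' @param seed experiment seed.
#' @param importance also compute the per-approach importance reports.
#' @return invisibly, a list of `experiment_result` (and importance reports).
#' @export
cmd_run <- function(table, out_dir, approaches = APPROACHES, roster = NULL,
                    seed = 1L, importance = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (ap in approaches) {
    res <- run_experiment(table, ap, roster = roster, seed = seed)
    results[[ap]] <- res
    write.csv(res$detail, file.path(out_dir, sprintf("metrics_detail_%s.csv", ap)),
              row.names = FALSE)
    if (importance) {
      rep <- importance_for_approach(table, ap, roster = roster, seed = seed)
      results[[paste0(ap, "_importance")]] <- rep
      write.csv(rep$importance,
                file.path(out_dir, sprintf("importance_%s.csv", ap)),
                row.names = FALSE)
    }
  }
  summary <- do.call(rbind, lapply(results[approaches], `[[`, "summary"))
  write.csv(summary, file.path(out_dir, "metrics_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(seed = seed, approaches = approaches),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

#' Render per-approach summary tables (and optional heatmaps) from results
#'
#' @param results_dir directory written by [cmd_run()].
#' @param heatmaps if TRUE and pheatmap is installed, write importance
#'   heatmaps as PDFs.
#' @return named list of models-by-metrics matrices, one per approach.
#' @export
cmd_report <- function(results_dir, heatmaps = FALSE) {
  spath <- file.path(results_dir, "metrics_summary.csv")
  if (!file.exists(spath)) stop_input("no metrics_summary.csv in %s", results_dir)
  s <- read.csv(spath)
  if (!all(c("model", "approach", "metric", "value") %in% names(s)))
    stop_input("metrics_summary.csv has an unexpected schema")
  out <- list()
  for (ap in unique(s$approach)) {
    d <- s[s$approach == ap, ]
    models <- sort(unique(d$model))
    m <- sapply(models, function(mod) sapply(metric_names(), function(met)
      d$value[d$model == mod & d$metric == met]))
    out[[ap]] <- round(t(m), 3)
    write.csv(out[[ap]], file.path(results_dir, sprintf("table_%s.csv", ap)))
  }
  if (heatmaps && requireNamespace("pheatmap", quietly = TRUE)) {
    for (f in list.files(results_dir, "^importance_.*\\.csv$", full.names = TRUE)) {
      imp <- read.csv(f)
      m <- stats::xtabs(scaled ~ model + feature, imp)
      pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                         filename = sub("\\.csv$", ".pdf", f))
    }
  }
  out
}

#' Command-line entry point
#'
#' `Rscript -e 'ecgpain::ecgpain_cli()' simulate|run|report ...` with
#' key=value arguments (or `config=<file.yaml>` holding the same keys; needs
#' the yaml package); see the README for examples. Kept deliberately thin:
#' each subcommand forwards to the corresponding `cmd_*` function.
#'
#' @param args character vector; defaults to `commandArgs(trailingOnly=TRUE)`.
#' @export
ecgpain_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1)
    stop_input("usage: simulate|run|report key=value ...")
  cmd <- args[1]
  kv <- strsplit(args[-1], "=", fixed = TRUE)
  opts <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                          vapply(kv, `[[`, character(1), 1))
  if (!is.null(opts[["config"]])) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("config= requires the yaml package")
    conf <- yaml::read_yaml(opts[["config"]])
    conf[names(opts)] <- opts # explicit key=value overrides the file
    opts <- conf
  }
  num <- function(name, default) as.numeric(opts[[name]] %||% default)
  if (cmd == "simulate") {
    cmd_simulate(opts[["out"]] %||% "cohort",
                 n_participants = num("participants", 36),
                 n_sessions = num("sessions", 2), seed = num("seed", 1))
  } else if (cmd == "run") {
    cohort <- generate_cohort(n_participants = num("participants", 36),
                              n_sessions = num("sessions", 2),
                              seed = num("seed", 1))
    table <- cohort_dataset(cohort, progress = TRUE)
    aps <- strsplit(opts[["approaches"]] %||% paste(APPROACHES, collapse = ","),
                    ",")[[1]]
    cmd_run(table, opts[["out"]] %||% "results", approaches = aps,
            seed = num("seed", 1))
  } else if (cmd == "report") {
    print(cmd_report(opts[["dir"]] %||% "results"))
  } else {
    stop_input("unknown subcommand %s", cmd)
  }
  invisible(NULL)
}
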
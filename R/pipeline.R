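# End-to-end pipeline: segmentation -> morphology -> PSI per patient, the
# cohort table feeding the statistics layer, and the seeded runner.

#' Analyze one patient's paired recording
#'
#' Runs onset detection, beat segmentation, pulse classification and
#' windowed PSI for both channels, phase by phase, and computes the mean
#' pressure per phase on the invasive channel.
#'
#' @param icp,b4c [signal_record()]s sharing phase annotations.
#' @param min_bpm,max_bpm Heart-rate bounds.
#' @param window_len_s,min_pulses PSI windowing parameters.
#' @param reducer Within-patient window reducer (`"median"` or `"mean"`).
#' @return List with `windows` (per channel/phase window table), `summary`
#'   (one row per channel/phase: `patient_id`, `channel`, `phase`,
#'   `psi_median`, `psi_iqr`, `n_windows`, `mean_icp`) and `pulses` (the
#'   classified pulse tables).
#' @export
analyze_patient <- function(icp, b4c, min_bpm = 40, max_bpm = 180,
                            window_len_s = 10, min_pulses = 5,
                            reducer = "median") {
  stopifnot(inherits(icp, "signal_record"), inherits(b4c, "signal_record"))
  phases <- icp$phases %||% b4c$phases
  if (is.null(phases)) stopf("phase annotations are required")
  channels <- list(ICP = icp, B4C = b4c)
  windows_all <- list(); summary_all <- list(); pulses_all <- list()
  for (ch in names(channels)) {
    sig <- channels[[ch]]
    onsets <- detect_onsets(sig, min_bpm = min_bpm, max_bpm = max_bpm)
    segs <- segment_pulses(sig, onsets, min_bpm = min_bpm, max_bpm = max_bpm)
    if (!nrow(segs)) next
    cls <- classify_segments(segs, min_bpm = min_bpm, max_bpm = max_bpm)
    cls$patient_id <- sig$patient_id
    cls$channel <- ch
    pulses_all[[ch]] <- cls
    for (i in seq_len(nrow(phases))) {
      ph <- phases$phase[i]
      w <- psi_windows(cls, phases$start_s[i], phases$end_s[i],
                       window_len_s = window_len_s, min_pulses = min_pulses)
      if (nrow(w)) {
        w$patient_id <- sig$patient_id; w$channel <- ch; w$phase <- ph
        windows_all[[paste(ch, ph)]] <- w
      }
      sm <- summarize_patient_psi(w, reducer = reducer)
      mi <- if (ch == "ICP")
        mean_icp(sig, c(phases$start_s[i], phases$end_s[i])) else NA_real_
      if (!is.null(sm)) {
        sm$patient_id <- sig$patient_id; sm$channel <- ch; sm$phase <- ph
        sm$mean_icp <- mi
        summary_all[[paste(ch, ph)]] <- sm
      }
    }
  }
  list(windows = if (length(windows_all)) do.call(rbind, windows_all) else NULL,
       summary = if (length(summary_all)) do.call(rbind, summary_all) else NULL,
       pulses = if (length(pulses_all)) do.call(rbind, pulses_all) else NULL)
}

#' Build the cohort table from simulated or analyzed patients
#'
#' Runs [analyze_patient()] on every patient of a [simulate_cohort()] result
#' and assembles one row per patient per phase with the invasive and
#' noninvasive PSI and the phase mean pressure.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param phases Phases to include (default baseline and compression).
#' @param ... Passed to [analyze_patient()].
#' @return List with `table` (the cohort table), `windows`, `summaries` and
#'   `pulses` (row-bound per-patient results).
#' @export
build_cohort_table <- function(cohort, phases = c("baseline", "compression"),
                               ...) {
  rows <- list(); windows <- list(); summaries <- list(); pulses <- list()
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    res <- analyze_patient(p$icp, p$b4c, ...)
    meta <- cohort$metadata[i, ]
    if (!is.null(res$summary)) {
      summaries[[i]] <- res$summary
      for (ph in phases) {
        icp_row <- res$summary[res$summary$channel == "ICP" &
                                 res$summary$phase == ph, ]
        b4c_row <- res$summary[res$summary$channel == "B4C" &
                                 res$summary$phase == ph, ]
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = meta$patient_id, age = meta$age,
          cranial_group = meta$cranial_group, phase = ph,
          psi_icp = if (nrow(icp_row)) icp_row$psi_median[1] else NA_real_,
          psi_b4c = if (nrow(b4c_row)) b4c_row$psi_median[1] else NA_real_,
          mean_icp = if (nrow(icp_row)) icp_row$mean_icp[1] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    windows[[i]] <- res$windows
    pulses[[i]] <- res$pulses
  }
  list(table = do.call(rbind, rows),
       windows = do.call(rbind, windows),
       summaries = do.call(rbind, summaries),
       pulses = do.call(rbind, pulses))
}

#' Run configuration for the end-to-end runner
#'
#' Collects every tunable of the pipeline with paper-anchored defaults:
#' 200 Hz sampling, 180-sample pulses, 10-s PSI windows, a 60-s compression
#' phase.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_intact,n_craniotomy,n_craniectomy Cohort group sizes.
#' @param protocol A [protocol_spec()].
#' @param min_bpm,max_bpm Segmentation heart-rate bounds.
#' @param window_len_s,min_pulses PSI windowing parameters.
#' @param p_adjust Dunn post hoc adjustment.
#' @param alpha Significance level for the normality gate.
#' @param ... Further arguments passed to [simulate_cohort()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_intact = 17, n_craniotomy = 17,
                       n_craniectomy = 13, protocol = protocol_spec(),
                       min_bpm = 40, max_bpm = 180, window_len_s = 10,
                       min_pulses = 5, p_adjust = "holm", alpha = 0.05, ...) {
  if (n_intact + n_craniotomy + n_craniectomy < 1)
    stopf("cohort must contain at least one patient")
  if (any(c(n_intact, n_craniotomy, n_craniectomy) < 1))
    stopf("all group sizes must be >= 1")
  structure(list(seed = as.integer(seed), n_intact = n_intact,
                 n_craniotomy = n_craniotomy, n_craniectomy = n_craniectomy,
                 protocol = protocol, min_bpm = min_bpm, max_bpm = max_bpm,
                 window_len_s = window_len_s, min_pulses = min_pulses,
                 p_adjust = p_adjust, alpha = alpha,
                 cohort_args = list(...)),
            class = "run_config")
}

#' Run the whole pipeline and write its artifacts
#'
#' Simulates the cohort, writes per-patient signal and phase files, runs
#' segmentation, classification and windowed PSI, builds the cohort table,
#' runs the statistical battery, and writes a JSON report. A log file
#' records every excluded pulse and window with its reason code
#' (`DURATION`, `FLAT`, `OSCILLATORY`, `SHAPE_OUTLIER`, `BASELINE_JUMP`,
#' `SHORT_WINDOW`). Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort table, the report and the
#'   paths written.
#' @export
run_all <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig_dir <- file.path(out_dir, "signals")
  dir.create(sig_dir, showWarnings = FALSE)

  cohort <- do.call(simulate_cohort, c(
    list(n_intact = config$n_intact, n_craniotomy = config$n_craniotomy,
         n_craniectomy = config$n_craniectomy, seed = config$seed,
         protocol = config$protocol), config$cohort_args))

  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    write_signal_csv(p, file.path(sig_dir, paste0(p$icp$patient_id, ".csv")))
  }
  write_phases_csv(protocol_phases(config$protocol),
                   file.path(out_dir, "phases.csv"))
  write_metadata_csv(cohort$metadata, file.path(out_dir, "metadata.csv"))
  write_truth_csv(cohort$truth, file.path(out_dir, "ground_truth.csv"))

  built <- build_cohort_table(cohort, min_bpm = config$min_bpm,
                              max_bpm = config$max_bpm,
                              window_len_s = config$window_len_s,
                              min_pulses = config$min_pulses)
  write_pulses_csv(built$pulses, file.path(out_dir, "pulses.csv"))
  write_windows_csv(built$windows, file.path(out_dir, "windows.csv"))
  write_summaries_csv(built$summaries, file.path(out_dir, "summaries.csv"))
  utils::write.csv(built$table, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)

  # exclusion log: every artifact pulse and undefined window with its reason
  log_lines <- character(0)
  art <- built$pulses[built$pulses$class == "ARTIFACT", ]
  if (nrow(art))
    log_lines <- c(log_lines,
                   sprintf("EXCLUDED_PULSE %s %s onset=%.3fs reason=%s",
                           art$patient_id, art$channel, art$onset_s, art$reason))
  und <- built$windows[is.na(built$windows$psi), ]
  if (!is.null(und) && nrow(und))
    log_lines <- c(log_lines,
                   sprintf("EXCLUDED_WINDOW %s %s %s start=%gs reason=SHORT_WINDOW n_valid=%d",
                           und$patient_id, und$channel, und$phase,
                           und$window_start_s, und$n_valid))
  writeLines(log_lines, file.path(out_dir, "exclusions.log"))

  report <- run_study_analysis(built$table, p_adjust = config$p_adjust,
                               alpha = config$alpha)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(list(cohort_table = built$table, report = report,
                 out_dir = out_dir))
}
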
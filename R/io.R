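# CSV formats for signals, phases, metadata, ground truth, pulses, windows
# and summaries. Everything is plain delimited text so recordings remain
# human-inspectable.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  df
}

#' Write a paired signal recording to CSV
#'
#' Schema: `time_s,icp_mmhg,b4c_au`, one row per sample.
#'
#' @param sim A [simulate_patient()] result, or a list with `icp` and `b4c`
#'   [signal_record()]s on a common time base.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sim, path) {
  icp <- sim$icp; b4c <- sim$b4c
  if (icp$fs != b4c$fs || length(icp$samples) != length(b4c$samples))
    stopf("channels must share sampling rate and length")
  t <- (seq_along(icp$samples) - 1) / icp$fs
  df <- data.frame(time_s = t, icp_mmhg = icp$samples, b4c_au = b4c$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a paired signal recording from CSV
#'
#' Validates the `time_s,icp_mmhg,b4c_au` schema, a monotone time column and
#' a uniform step of `1/fs` (tolerance 1e-6 s). Round trips with
#' [write_signal_csv()] are lossless to well below 1e-9.
#'
#' @param path Input file path.
#' @param patient_id Identifier attached to the records.
#' @param phases Optional phase annotation data frame
#'   (`phase,start_s,end_s`).
#' @return List with `icp` and `b4c` [signal_record()]s.
#' @export
read_signal_csv <- function(path, patient_id = "unknown", phases = NULL) {
  df <- read_csv_checked(path, c("time_s", "icp_mmhg", "b4c_au"))
  if (nrow(df) < 2L) stopf("%s: need at least 2 samples", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stopf("%s: time column not strictly increasing at row %d", path, bad)
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-6)) {
    bad <- which(abs(dt - step) > 1e-6)[1L] + 1L
    stopf("%s: time step inconsistent with fs at row %d", path, bad)
  }
  fs <- 1 / step
  list(icp = signal_record(df$icp_mmhg, fs, patient_id, "ICP", phases),
       b4c = signal_record(df$b4c_au, fs, patient_id, "B4C", phases))
}

#' Read/write phase annotations (`phase,start_s,end_s`)
#' @param phases Data frame with columns `phase`, `start_s`, `end_s`.
#' @param path File path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_phases_csv <- function(phases, path) {
  utils::write.csv(phases[, c("phase", "start_s", "end_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_phases_csv
#' @export
read_phases_csv <- function(path) {
  df <- read_csv_checked(path, c("phase", "start_s", "end_s"))
  if (any(df$end_s <= df$start_s)) stopf("%s: phases must have end_s > start_s", path)
  df
}

#' Read/write cohort metadata (`patient_id,age,cranial_group`)
#' @param metadata Data frame with columns `patient_id`, `age`,
#'   `cranial_group`.
#' @param path File path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata[, c("patient_id", "age", "cranial_group")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "age", "cranial_group"))
  bad <- setdiff(unique(df$cranial_group), CRANIAL_GROUPS)
  if (length(bad)) stopf("%s: unknown cranial group(s): %s", path,
                         paste(bad, collapse = ", "))
  df
}

#' Read/write ground truth (`patient_id,onset_s,class_icp,class_b4c`)
#' @param truth Ground-truth data frame from [simulate_cohort()].
#' @param path File path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth[, c("patient_id", "onset_s", "class_icp", "class_b4c")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "onset_s", "class_icp",
                                 "class_b4c"))
  # class labels are "1"-"4" or "ARTIFACT"; files without artifacts would
  # otherwise come back as integers
  df$class_icp <- as.character(df$class_icp)
  df$class_b4c <- as.character(df$class_b4c)
  df
}

#' Write classified pulses
#' (`patient_id,channel,onset_s,duration_s,class`)
#' @param pulses Data frame from [classify_segments()] plus `patient_id` and
#'   `channel` columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pulses_csv <- function(pulses, path) {
  utils::write.csv(pulses[, c("patient_id", "channel", "onset_s",
                              "duration_s", "class")], path, row.names = FALSE)
  invisible(path)
}

#' Write PSI windows
#' (`patient_id,channel,phase,window_start_s,n_valid,n_artifact,p1..p4,psi`)
#' @param windows Combined window table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  cols <- c("patient_id", "channel", "phase", "window_start_s", "n_valid",
            "n_artifact", "p1", "p2", "p3", "p4", "psi")
  utils::write.csv(windows[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write per-patient PSI summaries
#' (`patient_id,channel,phase,psi_median,psi_iqr,n_windows,mean_icp`)
#' @param summaries Combined summary table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summaries_csv <- function(summaries, path) {
  cols <- c("patient_id", "channel", "phase", "psi_median", "psi_iqr",
            "n_windows", "mean_icp")
  utils::write.csv(summaries[, cols], path, row.names = FALSE)
  invisible(path)
}
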
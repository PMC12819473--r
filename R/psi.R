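# Pulse Shape Index: windowed class fractions and per-patient summaries.
#
# PSI is the weighted sum of class numbers i multiplied by the fraction p_i
# of valid pulses in each class, computed over non-overlapping 10-s windows.
# It ranges from 1 (exclusively normal, class-1 pulses) to 4 (exclusively
# pathological, class-4 pulses).

#' Pulse Shape Index of a class mixture
#'
#' `PSI = sum_{i=1..4} i * p_i`, the average class number.
#'
#' @param fractions Four class fractions summing to 1.
#' @return A number in \[1, 4\].
#' @export
psi_from_fractions <- function(fractions) {
  if (length(fractions) != 4L || any(!is.finite(fractions)) || any(fractions < 0))
    stopf("`fractions` must be four finite non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("`fractions` must sum to 1 (got %.10f)", sum(fractions))
  sum(seq_len(4) * as.numeric(fractions))
}

#' Windowed class fractions and PSI
#'
#' Tiles a phase interval with consecutive non-overlapping windows anchored
#' at the phase start (the trailing partial window is dropped). A pulse
#' belongs to the window containing its onset. Artifact pulses are excluded
#' from the class fractions but counted; windows with fewer than
#' `min_pulses` valid pulses carry no PSI (`NA`).
#'
#' @param pulses Data frame with columns `onset_s` and `class`
#'   (`"1"`-`"4"` or `"ARTIFACT"`), e.g. from [classify_segments()], sorted
#'   by onset.
#' @param phase_start,phase_end Phase interval in seconds.
#' @param window_len_s Window length in seconds (default 10).
#' @param min_pulses Minimum valid pulses for a defined PSI (default 5).
#' @return Data frame with one row per window: `window_start_s`,
#'   `window_len_s`, `n_valid`, `n_artifact`, `p1`-`p4`, `psi`.
#' @export
psi_windows <- function(pulses, phase_start, phase_end, window_len_s = 10,
                        min_pulses = 5) {
  assert_number(window_len_s, "window_len_s", lower = 1e-9)
  assert_number(min_pulses, "min_pulses", lower = 0)
  if (phase_end - phase_start < window_len_s - 1e-9)
    return(data.frame(window_start_s = numeric(0), window_len_s = numeric(0),
                      n_valid = integer(0), n_artifact = integer(0),
                      p1 = numeric(0), p2 = numeric(0), p3 = numeric(0),
                      p4 = numeric(0), psi = numeric(0)))
  if (is.unsorted(pulses$onset_s)) stopf("`pulses` must be sorted by onset")
  starts <- seq(phase_start, phase_end - window_len_s + 1e-12, by = window_len_s)
  starts <- starts[starts + window_len_s <= phase_end + 1e-9]
  rows <- lapply(starts, function(w0) {
    in_w <- pulses$onset_s >= w0 - 1e-12 & pulses$onset_s < w0 + window_len_s - 1e-12
    lab <- pulses$class[in_w]
    n_art <- sum(lab == "ARTIFACT")
    lab <- lab[lab != "ARTIFACT"]
    n_val <- length(lab)
    if (n_val > 0) {
      p <- tabulate(as.integer(lab), nbins = 4L) / n_val
      psi <- if (n_val >= min_pulses) psi_from_fractions(p) else NA_real_
    } else {
      p <- rep(NA_real_, 4L); psi <- NA_real_
    }
    data.frame(window_start_s = w0, window_len_s = window_len_s,
               n_valid = n_val, n_artifact = n_art,
               p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4], psi = psi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a patient's windowed PSI within a phase
#'
#' Median and interquartile range (Q3 - Q1, linear-interpolation quantiles)
#' over the windows with a defined PSI.
#'
#' @param windows Data frame from [psi_windows()].
#' @param reducer `"median"` (default) or `"mean"` for the within-patient
#'   window reducer.
#' @return One-row data frame `psi_median`, `psi_iqr`, `n_windows`, or
#'   `NULL` when no window has a defined PSI.
#' @export
summarize_patient_psi <- function(windows, reducer = c("median", "mean")) {
  reducer <- match.arg(reducer)
  v <- windows$psi[!is.na(windows$psi)]
  if (!length(v)) return(NULL)
  center <- if (reducer == "median") stats::median(v) else mean(v)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  data.frame(psi_median = center, psi_iqr = q[2] - q[1],
             n_windows = length(v))
}

#' Mean pressure over a phase
#'
#' Mean of the pressure samples whose times fall in `[start, end)` of the
#' given phase interval. Only meaningful for the invasive channel: the
#' skull-expansion channel carries no absolute baseline and is rejected.
#'
#' @param signal A [signal_record()] with `channel == "ICP"`.
#' @param phase Either a phase name present in the record's annotations or a
#'   numeric `c(start_s, end_s)` interval.
#' @return Mean pressure in mm Hg.
#' @export
mean_icp <- function(signal, phase) {
  if (!inherits(signal, "signal_record")) stopf("`signal` must be a signal_record")
  if (signal$channel != "ICP")
    stopf("mean pressure is undefined for the %s channel (no absolute baseline)",
          signal$channel)
  if (is.character(phase)) {
    ph <- signal$phases
    if (is.null(ph) || !phase %in% ph$phase)
      stopf("phase '%s' not annotated on this record", phase)
    iv <- c(ph$start_s[ph$phase == phase][1], ph$end_s[ph$phase == phase][1])
  } else {
    if (length(phase) != 2L || phase[2] <= phase[1])
      stopf("`phase` must be a name or a c(start_s, end_s) interval")
    iv <- as.numeric(phase)
  }
  t <- (seq_along(signal$samples) - 1) / signal$fs
  idx <- t >= iv[1] & t < iv[2]
  if (!any(idx)) stopf("phase interval contains no samples")
  mean(signal$samples[idx])
}
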
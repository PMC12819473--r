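# Cardiac-cycle pulse segmentation.
#
# Beat onsets are the diastolic troughs of the waveform. They are located
# with automatic multiscale-based peak detection (AMPD) applied to the
# negated, locally detrended signal, followed by a physiological-spacing
# filter.

#' Detect pulse onsets (diastolic troughs)
#'
#' Runs automatic multiscale-based peak detection on the detrended signal:
#' a local-minima scalogram is built over window scales `k = 1..L`, with `L`
#' capped at half the longest physiologically plausible beat
#' (`fs * 60 / min_bpm / 2`); the scale `lambda` minimizing the row-wise
#' count of non-minima is selected, and samples that are local minima at
#' *every* scale up to `lambda` are marked as onsets. Detrending subtracts a
#' 10-s sliding local mean (equivalent to a centered local linear fit), so
#' plateau waves do not bias the scalogram. Onsets closer together than the
#' fastest plausible beat (`60 / max_bpm` s) are merged, keeping the deeper
#' trough. Detection is invariant to adding a constant and to positive
#' rescaling of the signal.
#'
#' @param x A [signal_record()] or numeric vector.
#' @param fs Sampling frequency in Hz (ignored when `x` is a signal record).
#' @param min_bpm,max_bpm Physiological heart-rate bounds (defaults 40, 180).
#' @param detrend_s Width of the detrending window in seconds.
#' @return Strictly increasing integer vector of 1-based onset sample
#'   indices. A constant (or near-constant) signal yields an empty result
#'   with a warning.
#' @export
detect_onsets <- function(x, fs = NULL, min_bpm = 40, max_bpm = 180,
                          detrend_s = 10) {
  if (inherits(x, "signal_record")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stopf("`fs` is required when `x` is a plain vector")
  assert_number(fs, "fs", lower = 1e-9)
  assert_number(min_bpm, "min_bpm", lower = 1)
  assert_number(max_bpm, "max_bpm", lower = min_bpm)
  if (any(!is.finite(x))) stopf("signal contains non-finite samples")
  n <- length(x)
  if (n < 2 * fs * 60 / min_bpm)
    stopf("signal too short: need at least two beats at %g bpm", min_bpm)
  rng <- diff(range(x))
  if (rng < 1e-9 * max(1, abs(mean(x)))) {
    warnf("signal is (near-)constant; no onsets detected")
    return(integer(0))
  }
  xd <- x - running_mean(x, round(detrend_s * fs))

  L <- min(floor(fs * 60 / min_bpm / 2), (n - 1L) %/% 2L)
  L <- max(L, 1L)
  # scalogram row sums: count of samples that are NOT scale-k local minima
  gamma <- numeric(L)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    is_min <- xd[i] < xd[i - k] & xd[i] < xd[i + k]
    gamma[k] <- n - sum(is_min)
  }
  lambda <- which.min(gamma)

  cand <- (lambda + 1L):(n - lambda)
  for (k in seq_len(lambda)) {
    cand <- cand[xd[cand] < xd[cand - k] & xd[cand] < xd[cand + k]]
    if (!length(cand)) break
  }
  onsets <- cand

  # physiological spacing: merge troughs closer than the fastest beat
  min_gap <- floor(fs * 60 / max_bpm)
  if (length(onsets) > 1L && min_gap > 1L) {
    keep <- onsets
    i <- 1L
    while (i < length(keep)) {
      if (keep[i + 1L] - keep[i] < min_gap) {
        drop <- if (xd[keep[i + 1L]] < xd[keep[i]]) i else i + 1L
        keep <- keep[-drop]
      } else i <- i + 1L
    }
    onsets <- keep
  }
  as.integer(onsets)
}

#' Cut a signal into per-beat segments
#'
#' One segment per consecutive onset pair, using the half-open convention
#' `[onset_i, onset_{i+1})`: consecutive segments tile the span between the
#' first and last onset with no gaps or overlaps. Segments whose duration
#' falls outside the plausible beat range are flagged invalid (candidate
#' artifacts). The trailing partial beat after the last onset is discarded.
#'
#' @param x A [signal_record()] or numeric vector.
#' @param onsets Integer onset indices from [detect_onsets()].
#' @param fs Sampling frequency in Hz (ignored when `x` is a signal record).
#' @param min_bpm,max_bpm Heart-rate bounds defining the valid duration
#'   range `[60 / max_bpm, 60 / min_bpm]` seconds.
#' @return A data frame with one row per segment: `onset` (1-based sample
#'   index), `onset_s`, `duration_s`, `valid`, and a list column `samples`
#'   holding the raw sub-vector.
#' @export
segment_pulses <- function(x, onsets, fs = NULL, min_bpm = 40, max_bpm = 180) {
  if (inherits(x, "signal_record")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stopf("`fs` is required when `x` is a plain vector")
  onsets <- as.integer(onsets)
  if (is.unsorted(onsets, strictly = TRUE))
    stopf("`onsets` must be strictly increasing")
  if (length(onsets) < 2L) {
    return(data.frame(onset = integer(0), onset_s = numeric(0),
                      duration_s = numeric(0), valid = logical(0),
                      samples = I(list())))
  }
  if (onsets[1L] < 1L || onsets[length(onsets)] > length(x))
    stopf("`onsets` out of range for this signal")
  a <- onsets[-length(onsets)]
  b <- onsets[-1L]
  dur <- (b - a) / fs
  segs <- Map(function(i, j) x[i:(j - 1L)], a, b)
  out <- data.frame(onset = a, onset_s = (a - 1L) / fs, duration_s = dur,
                    valid = dur >= 60 / max_bpm & dur <= 60 / min_bpm)
  out$samples <- I(unname(segs))
  out
}
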
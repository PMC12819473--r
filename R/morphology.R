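# Per-pulse morphology: normalization, resampling, P1/P2/P3 peak
# designation, four-class rule classification, and artifact screening.
#
# Pipeline order per pulse: normalization -> resampling -> peak finding ->
# classification, with artifact screens applied along the way.

PULSE_LEN <- 180L

ARTIFACT_REASONS <- c("DURATION", "FLAT", "OSCILLATORY", "SHAPE_OUTLIER",
                      "BASELINE_JUMP")

# latency windows (fractions of the pulse) used to designate P1/P2/P3
default_peak_windows <- function() {
  list(P1 = c(0.02, 0.30), P2 = c(0.30, 0.55), P3 = c(0.55, 0.90))
}

#' Min-max normalize a pulse to the 0-1 range
#'
#' Applies `(x - min) / (max - min)` samplewise, eliminating the influence of
#' pulse amplitude on the downstream shape classification.
#'
#' @param x Numeric vector (one raw pulse segment).
#' @param eps Resolution threshold; a pulse whose range falls below it is
#'   degenerate (flat).
#' @return The normalized vector (min 0, max 1), or `NULL` for a flat pulse,
#'   which callers must treat as an artifact.
#' @export
normalize_pulse <- function(x, eps = 1e-8) {
  if (!is.numeric(x) || !length(x)) stopf("`x` must be a non-empty numeric vector")
  lo <- min(x); hi <- max(x)
  r <- hi - lo
  if (!is.finite(r) || r <= eps * max(1, abs(hi))) return(NULL)
  (x - lo) / r
}

#' Resample a pulse to a uniform length
#'
#' Linear interpolation onto `target_len` equally spaced points over the same
#' support, removing heart-rate-driven length differences. Endpoints are
#' preserved exactly, and linearity means no overshoot can fabricate peaks.
#'
#' @param x Numeric vector of length >= 2.
#' @param target_len Output length (default 180 samples).
#' @return Numeric vector of length `target_len`.
#' @export
resample_pulse <- function(x, target_len = PULSE_LEN) {
  if (!is.numeric(x) || length(x) < 2L)
    stopf("`x` must be a numeric vector of length >= 2")
  target_len <- as.integer(target_len)
  if (target_len < 2L) stopf("`target_len` must be >= 2")
  if (length(x) == target_len) return(as.numeric(x))
  stats::approx(x = seq(0, 1, length.out = length(x)), y = x,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Locate and designate the P1/P2/P3 peaks of a normalized pulse
#'
#' Local maxima with topographic prominence of at least `prominence_min` are
#' found on a lightly smoothed copy of the pulse (moving average of
#' `smooth_width` samples). Maxima are designated P1, P2 or P3 by membership
#' in latency windows (defaults `[0.02, 0.30)`, `[0.30, 0.55)`,
#' `[0.55, 0.90)` of the pulse duration); when a window holds several maxima
#' the highest is kept. Maxima outside every window are ignored for
#' designation but counted.
#'
#' @param pulse Normalized pulse (values in \[0, 1\]).
#' @param prominence_min Minimum prominence on the normalized scale.
#' @param smooth_width Moving-average width in samples.
#' @param windows Named list of `c(lower, upper)` latency windows.
#' @return Data frame with columns `designation`, `position` (fraction of the
#'   pulse), `amplitude` (normalized height) and `index`; the count of all
#'   prominent maxima is attached as attribute `n_raw_maxima`.
#' @export
find_pulse_peaks <- function(pulse, prominence_min = 0.02, smooth_width = 5,
                             windows = default_peak_windows()) {
  if (!is.numeric(pulse) || length(pulse) < 5L)
    stopf("`pulse` must be a numeric vector of length >= 5")
  n <- length(pulse)
  s <- running_mean(pulse, smooth_width)
  cand <- local_maxima(s)
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
    cand <- cand[prom >= prominence_min]
  }
  pos <- (cand - 1) / n
  amp <- pulse[cand]
  out <- data.frame(designation = character(0), position = numeric(0),
                    amplitude = numeric(0), index = integer(0),
                    stringsAsFactors = FALSE)
  for (w in names(windows)) {
    in_w <- which(pos >= windows[[w]][1] & pos < windows[[w]][2])
    if (length(in_w)) {
      best <- in_w[which.max(amp[in_w])]
      out <- rbind(out, data.frame(designation = w, position = pos[best],
                                   amplitude = amp[best],
                                   index = as.integer(cand[best]),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_raw_maxima") <- length(cand)
  out
}

#' Classify a pulse into one of the four morphological classes
#'
#' Deterministic decision rules on the designated peak amplitudes
#' (an absent peak contributes amplitude 0), evaluated in order:
#' fewer than two designated peaks gives class 4 (single rounded/triangular
#' peak); `A1 >= A2 & A1 >= A3` gives class 1 (dominant percussion wave);
#' `A2 >= A1 & A1 > A3` gives class 2 (prominent tidal wave, P1 still above
#' P3); `A2 > A1 & A3 >= A1` gives class 3 (P2 and P3 dominating P1). Any
#' remaining configuration is ambiguous and resolved by rule priority 3 over
#' 2, flagged through the `"ambiguous"` attribute.
#'
#' @param peaks A peak table from [find_pulse_peaks()].
#' @return Integer class label 1-4, with attribute `ambiguous` (logical).
#' @export
classify_pulse <- function(peaks) {
  a <- c(P1 = 0, P2 = 0, P3 = 0)
  if (nrow(peaks)) a[peaks$designation] <- peaks$amplitude
  ambiguous <- FALSE
  label <- if (nrow(peaks) < 2L) {
    4L
  } else if (a[["P1"]] >= a[["P2"]] && a[["P1"]] >= a[["P3"]]) {
    1L
  } else if (a[["P2"]] >= a[["P1"]] && a[["P1"]] > a[["P3"]]) {
    2L
  } else if (a[["P2"]] > a[["P1"]] && a[["P3"]] >= a[["P1"]]) {
    3L
  } else {
    ambiguous <- TRUE
    3L  # residual configurations (e.g. A3 > A1 >= A2): priority 3 over 2
  }
  structure(label, ambiguous = ambiguous)
}

#' Artifact screen for a single pulse
#'
#' Flags a pulse as an artifact when any of the following holds: the raw
#' segment duration lies outside the heart-rate bounds (`DURATION`); the
#' pulse is flat (`FLAT`); more than `max_maxima` prominent maxima indicate
#' oscillatory noise (`OSCILLATORY`); the mean absolute difference to the
#' pointwise median of up to 10 neighboring valid normalized pulses exceeds
#' `outlier_mad` (`SHAPE_OUTLIER`); or the onset-to-end baseline jump of the
#' raw segment exceeds half the pulse amplitude (`BASELINE_JUMP`).
#'
#' @param samples Raw segment samples.
#' @param duration_s Segment duration in seconds.
#' @param pulse The normalized, resampled pulse, or `NULL` if flat.
#' @param neighbors List of neighboring valid normalized pulses (possibly
#'   empty).
#' @param min_bpm,max_bpm Heart-rate bounds.
#' @param max_maxima Maximum allowed count of prominent maxima.
#' @param outlier_mad Shape-outlier threshold on the normalized scale.
#' @param jump_frac Baseline-jump threshold as a fraction of pulse amplitude.
#' @return Logical; when `TRUE` the attribute `reason` holds one of
#'   `"DURATION"`, `"FLAT"`, `"OSCILLATORY"`, `"SHAPE_OUTLIER"`,
#'   `"BASELINE_JUMP"`.
#' @export
detect_artifact <- function(samples, duration_s, pulse, neighbors = list(),
                            min_bpm = 40, max_bpm = 180, max_maxima = 6,
                            outlier_mad = 0.35, jump_frac = 0.5) {
  flag <- function(reason) structure(TRUE, reason = reason)
  if (duration_s < 60 / max_bpm || duration_s > 60 / min_bpm)
    return(flag("DURATION"))
  if (is.null(pulse)) return(flag("FLAT"))
  r <- diff(range(samples))
  if (r > 0 && abs(samples[length(samples)] - samples[1L]) > jump_frac * r)
    return(flag("BASELINE_JUMP"))
  pk <- find_pulse_peaks(pulse)
  if (attr(pk, "n_raw_maxima") > max_maxima) return(flag("OSCILLATORY"))
  if (length(neighbors)) {
    nb <- neighbors[seq_len(min(10L, length(neighbors)))]
    med <- apply(do.call(cbind, nb), 1L, stats::median)
    if (mean(abs(pulse - med)) > outlier_mad) return(flag("SHAPE_OUTLIER"))
  }
  structure(FALSE, reason = NA_character_)
}

#' Classify all segments of a recording
#'
#' Applies the full per-pulse pipeline (normalize, resample to 180 samples,
#' artifact screens, peak designation, rule classification) to a segment
#' table from [segment_pulses()]. The shape-outlier screen compares each
#' pulse to the pointwise median of up to 10 neighboring pulses that passed
#' the other screens.
#'
#' @param segments Data frame from [segment_pulses()].
#' @param min_bpm,max_bpm Heart-rate bounds.
#' @param prominence_min,smooth_width Passed to [find_pulse_peaks()].
#' @param ... Further thresholds passed to [detect_artifact()].
#' @return Data frame with one row per segment: `onset`, `onset_s`,
#'   `duration_s`, `class` (`"1"`-`"4"` or `"ARTIFACT"`), `reason` (artifact
#'   reason code or `NA`) and `ambiguous`. The count of ambiguous rule hits
#'   is attached as attribute `n_ambiguous`.
#' @export
classify_segments <- function(segments, min_bpm = 40, max_bpm = 180,
                              prominence_min = 0.02, smooth_width = 5, ...) {
  n <- nrow(segments)
  normed <- vector("list", n)
  base_artifact <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    np <- normalize_pulse(segments$samples[[i]])
    normed[[i]] <- if (is.null(np)) NULL else resample_pulse(np)
    art <- detect_artifact(segments$samples[[i]], segments$duration_s[i],
                           normed[[i]], neighbors = list(),
                           min_bpm = min_bpm, max_bpm = max_bpm, ...)
    base_artifact[i] <- isTRUE(as.logical(art))
    if (base_artifact[i]) reason[i] <- attr(art, "reason")
  }
  ok <- which(!base_artifact)
  # second pass: shape-outlier screen against neighboring valid pulses
  for (i in ok) {
    nb_idx <- ok[ok != i]
    if (length(nb_idx)) {
      nb_idx <- nb_idx[order(abs(nb_idx - i))][seq_len(min(10L, length(nb_idx)))]
      art <- detect_artifact(segments$samples[[i]], segments$duration_s[i],
                             normed[[i]], neighbors = normed[nb_idx],
                             min_bpm = min_bpm, max_bpm = max_bpm, ...)
      if (isTRUE(as.logical(art))) {
        base_artifact[i] <- TRUE
        reason[i] <- attr(art, "reason")
      }
    }
  }
  cls <- rep(NA_character_, n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    if (base_artifact[i]) { cls[i] <- "ARTIFACT"; next }
    pk <- find_pulse_peaks(normed[[i]], prominence_min = prominence_min,
                           smooth_width = smooth_width)
    lab <- classify_pulse(pk)
    cls[i] <- as.character(as.integer(lab))
    ambiguous[i] <- isTRUE(attr(lab, "ambiguous"))
  }
  out <- data.frame(onset = segments$onset, onset_s = segments$onset_s,
                    duration_s = segments$duration_s, class = cls,
                    reason = reason, ambiguous = ambiguous,
                    stringsAsFactors = FALSE)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

#' Train a surrogate pulse classifier
#'
#' Fits a small multinomial logistic model on down-sampled pulse shapes as a
#' retrainable stand-in for heavier classifiers. It is never required by the
#' main pipeline, which uses the deterministic rules of [classify_pulse()].
#'
#' @param pulses Numeric matrix, one normalized 180-sample pulse per row.
#' @param labels Integer class labels 1-4, one per row; all four classes must
#'   be present.
#' @param n_features Number of equally spaced samples retained as features.
#' @return An object of class `pulse_surrogate` with a [predict] method.
#' @export
train_surrogate_classifier <- function(pulses, labels, n_features = 30) {
  if (!is.matrix(pulses) || ncol(pulses) != PULSE_LEN)
    stopf("`pulses` must be a matrix with %d columns", PULSE_LEN)
  labels <- as.integer(labels)
  if (length(labels) != nrow(pulses)) stopf("one label per pulse required")
  if (!all(sort(unique(labels)) %in% 1:4) || length(unique(labels)) < 4L)
    stopf("all four classes must be present in `labels`")
  keep <- round(seq(1, PULSE_LEN, length.out = n_features))
  feats <- pulses[, keep, drop = FALSE]
  colnames(feats) <- paste0("X", seq_len(ncol(feats)))
  df <- data.frame(y = factor(labels, levels = 1:4), feats)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
  structure(list(fit = fit, keep = keep), class = "pulse_surrogate")
}

#' @export
predict.pulse_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  feats <- as.data.frame(newdata[, object$keep, drop = FALSE])
  names(feats) <- paste0("X", seq_along(object$keep))
  as.integer(as.character(stats::predict(object$fit, newdata = feats)))
}
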
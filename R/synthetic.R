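# Synthetic paired-signal cohort generator.
#
# Builds invasive pressure (mm Hg, absolute baseline) and noninvasive
# skull-expansion (arbitrary units, pulsatile only) recordings with known
# pulse onsets and morphological class labels, so every downstream stage of
# the pipeline can be validated against ground truth.

CRANIAL_GROUPS <- c("INTACT", "CRANIOTOMY_FRACTURE", "CRANIECTOMY")

#' Pulse shape parameters
#'
#' Parametrizes a single cardiac pulse as the sum of three Gaussian bumps
#' (the percussion, tidal and dicrotic waves P1, P2, P3) riding on an
#' exponentially decaying diastolic baseline. Latencies and widths are
#' expressed as fractions of the pulse duration; widths are full widths at
#' half maximum, chosen narrow enough that the three components produce
#' three distinct local maxima.
#'
#' @param amplitudes Relative heights of the P1, P2, P3 components
#'   (non-negative, at least one positive).
#' @param latencies Component centers as strictly increasing fractions of the
#'   pulse duration in (0, 1).
#' @param widths Component full widths at half maximum, as positive fractions
#'   of the pulse duration.
#' @param noise_sd Additive Gaussian noise, as a fraction of the maximum
#'   component amplitude.
#' @param baseline_amp Height of the decaying diastolic baseline relative to
#'   the maximum component amplitude; the baseline declines linearly to zero
#'   across the pulse, so the inter-beat trough sits at the beat boundary.
#' @return An object of class `pulse_shape_params`.
#' @export
pulse_shape_params <- function(amplitudes = c(1.0, 0.7, 0.4),
                               latencies = c(0.15, 0.40, 0.65),
                               widths = c(0.07, 0.10, 0.12),
                               noise_sd = 0.02,
                               baseline_amp = 0.2) {
  if (length(amplitudes) != 3L || any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stopf("`amplitudes` must be three finite non-negative numbers")
  if (all(amplitudes == 0))
    stopf("at least one amplitude must be positive")
  if (length(latencies) != 3L || any(latencies <= 0) || any(latencies >= 1) ||
      any(diff(latencies) <= 0))
    stopf("`latencies` must be strictly increasing fractions in (0, 1)")
  if (length(widths) != 3L || any(widths <= 0))
    stopf("`widths` must be positive")
  assert_number(noise_sd, "noise_sd", lower = 0)
  structure(list(amplitudes = amplitudes, latencies = latencies,
                 widths = widths, noise_sd = noise_sd,
                 baseline_amp = baseline_amp),
            class = "pulse_shape_params")
}

#' Canonical component amplitudes for each morphological class
#'
#' Class 1: dominant P1; class 2: prominent P2 with P1 still above P3;
#' class 3: P2 and P3 both dominating P1; class 4 is realized as a single
#' rounded bump and carries no amplitude triple.
#'
#' @param class_label Integer 1-4.
#' @return Numeric triple of P1, P2, P3 amplitudes (`NA` for class 4).
#' @export
canonical_amplitudes <- function(class_label) {
  switch(as.character(class_label),
         "1" = c(1.0, 0.7, 0.4),
         "2" = c(0.8, 1.0, 0.5),
         "3" = c(0.6, 1.0, 0.8),
         "4" = c(NA_real_, NA_real_, NA_real_),
         stopf("`class_label` must be 1, 2, 3 or 4 (got %s)", class_label))
}

# Do the raw component amplitudes satisfy the class definition?
amplitudes_match_class <- function(a, class_label) {
  switch(as.character(class_label),
         "1" = a[1] >= a[2] && a[1] >= a[3],
         "2" = a[2] >= a[1] && a[1] > a[3],
         "3" = a[2] > a[1] && a[3] >= a[1],
         "4" = TRUE,
         FALSE)
}

#' Generate a single-pulse template
#'
#' Returns one cardiac pulse of `n` samples realizing the requested
#' morphological class. Classes 1-3 are sums of three Gaussian bumps whose
#' amplitude triple must satisfy the class definition; class 4 is a single
#' rounded bump (latency 0.45, width 0.18 of the pulse duration). Noise is
#' drawn from the current RNG stream.
#'
#' @param class_label Integer 1-4.
#' @param n Number of samples (at least 40).
#' @param params A [pulse_shape_params()] object. For classes 1-3 its
#'   `amplitudes` default to the canonical triple of the class when left at
#'   the constructor default.
#' @param amplitudes Optional override of the P1/P2/P3 amplitude triple.
#' @param noise_sd Optional override of the noise level.
#' @return Numeric vector of length `n`.
#' @export
pulse_template <- function(class_label, n,
                           params = pulse_shape_params(),
                           amplitudes = NULL,
                           noise_sd = NULL) {
  if (!class_label %in% 1:4)
    stopf("`class_label` must be 1, 2, 3 or 4 (got %s)", toString(class_label))
  if (!is.numeric(n) || n < 40)
    stopf("`n` must be a sample count >= 40 (got %s)", toString(n))
  n <- as.integer(n)
  noise_sd <- noise_sd %||% params$noise_sd
  t <- (seq_len(n) - 1) / n
  if (class_label == 4L) {
    # rounded/triangular single-peaked pulse: smooth beta-shaped rise to a
    # lone maximum at 0.45 of the pulse, then decay into the next trough
    a <- 1.636; b <- 2; t0 <- a / (a + b)
    y <- (t^a * (1 - t)^b) / (t0^a * (1 - t0)^b)
    if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
    return(y)
  } else {
    amps <- amplitudes %||% {
      if (identical(params$amplitudes, c(1.0, 0.7, 0.4)))
        canonical_amplitudes(class_label) else params$amplitudes
    }
    if (!amplitudes_match_class(amps, class_label))
      stopf("amplitude triple (%s) is inconsistent with class %d",
            toString(amps), class_label)
    lats <- params$latencies
    sds <- params$widths / 2.355   # FWHM -> Gaussian sd
  }
  amax <- max(amps)
  # decaying diastolic baseline; linear decline keeps the pulse minimum
  # pinned at the beat boundary even under slow respiratory modulation
  y <- params$baseline_amp * amax * (1 - t)
  for (j in seq_along(amps))
    y <- y + amps[j] * exp(-(t - lats[j])^2 / (2 * sds[j]^2))
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd * amax)
  y
}

# Artifact pulse shapes: a jagged random walk (oscillatory noise) or a
# clipped half-pulse (detection error). Shapes are deliberately unlike any
# valid class so that the artifact screen can be exercised.
artifact_pulse <- function(n) {
  if (stats::runif(1) < 0.5) {
    w <- cumsum(stats::rnorm(n)) + stats::rnorm(n, 0, 1.5)
    w <- w - min(w)
    r <- max(w)
    if (r > 0) w <- w / r
    0.1 + 0.9 * w
  } else {
    half <- pulse_template(1L, max(40L, n), noise_sd = 0)
    cut <- floor(0.4 * n)
    c(half[seq_len(cut)], rep(half[cut] + 0.6, n - cut))
  }
}

#' Class mixture
#'
#' Fractions of pulses in each of the four morphological classes.
#'
#' @param p Numeric vector of four fractions summing to one (within 1e-9).
#' @return Numeric vector of length 4 with class `"class_mixture"`.
#' @export
class_mixture <- function(p) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
    stopf("a class mixture needs four finite non-negative fractions")
  if (abs(sum(p) - 1) > 1e-9)
    stopf("class mixture fractions must sum to 1 (got %.12f)", sum(p))
  structure(as.numeric(p), class = "class_mixture")
}

#' Expected class number of a mixture
#'
#' The population value of the Pulse Shape Index for pulses drawn from the
#' mixture: `sum(i * p_i)`.
#'
#' @param mixture A [class_mixture()] or plain fraction vector.
#' @return A number in \[1, 4\].
#' @export
mixture_expected_class <- function(mixture) {
  mixture <- class_mixture(unclass(mixture))
  sum(seq_len(4) * mixture)
}

# Shift probability mass between adjacent classes. s > 0 moves a fraction s
# of each class's mass one class up; s < 0 moves it down. Used to encode the
# age-related drift toward more pathological morphology.
shift_mixture <- function(p, s) {
  s <- max(-0.5, min(0.5, s))
  q <- as.numeric(p)
  out <- q
  if (s >= 0) {
    out <- q * (1 - s)
    out[2:4] <- out[2:4] + s * q[1:3]
    out[4] <- out[4] + s * q[4] # class 4 stays
  } else {
    s <- -s
    out <- q * (1 - s)
    out[1:3] <- out[1:3] + s * q[2:4]
    out[1] <- out[1] + s * q[1] # class 1 stays
  }
  out / sum(out)
}

#' Protocol specification
#'
#' Timing of the three recording phases: baseline, jugular-vein compression
#' and recovery, plus the sampling rate.
#'
#' @param fs Sampling frequency in Hz (default 200).
#' @param baseline_s,compression_s,recovery_s Phase durations in seconds
#'   (defaults 60, 60, 60).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(fs = 200, baseline_s = 60, compression_s = 60,
                          recovery_s = 60) {
  assert_number(fs, "fs", lower = 1e-9)
  assert_number(baseline_s, "baseline_s", lower = 1e-9)
  assert_number(compression_s, "compression_s", lower = 0)
  assert_number(recovery_s, "recovery_s", lower = 0)
  structure(list(fs = fs, baseline_s = baseline_s,
                 compression_s = compression_s, recovery_s = recovery_s),
            class = "protocol_spec")
}

#' Phase annotation table of a protocol
#'
#' Expands a [protocol_spec()] into the `phase, start_s, end_s` annotation
#' table used by [signal_record()]; zero-length phases are dropped.
#'
#' @param protocol A [protocol_spec()].
#' @return Data frame with columns `phase`, `start_s`, `end_s`.
#' @export
protocol_phases <- function(protocol) {
  b <- protocol$baseline_s; c_ <- protocol$compression_s; r <- protocol$recovery_s
  ph <- data.frame(phase = c("baseline", "compression", "recovery"),
                   start_s = c(0, b, b + c_),
                   end_s = c(b, b + c_, b + c_ + r),
                   stringsAsFactors = FALSE)
  ph[ph$end_s > ph$start_s, , drop = FALSE]
}

#' Patient specification for the simulator
#'
#' @param patient_id Identifier string.
#' @param age Age in years (>= 18).
#' @param cranial_group One of `"INTACT"`, `"CRANIOTOMY_FRACTURE"`,
#'   `"CRANIECTOMY"`.
#' @param mixture_baseline,mixture_compression Class mixtures in the baseline
#'   and compression phases (the recovery phase reuses the baseline mixture).
#' @param mean_icp_baseline,mean_icp_compression Mean pressure levels in
#'   mm Hg; the compression level must not be below baseline (the provoked
#'   plateau wave raises pressure).
#' @param heart_rate_mean,heart_rate_sd Per-beat heart-rate distribution in
#'   bpm; the mean must lie in \[40, 180\].
#' @param b4c_disagreement_prob Probability that a skull-expansion pulse's
#'   class differs from its pressure twin.
#' @param b4c_shift Direction of that class shift: `"symmetric"` (one class
#'   up or down at random) or `"down"` (one class down, modeling the
#'   noninvasive channel underestimating morphology after craniectomy).
#' @param artifact_rate Probability that a beat is replaced by an artifact
#'   pulse (independently per channel).
#' @param noise_sd Per-pulse additive noise as a fraction of pulse amplitude.
#' @param pulse_amp_mmhg Peak amplitude of the pressure pulse in mm Hg.
#' @return An object of class `patient_spec`.
#' @export
patient_spec <- function(patient_id,
                         age = 43,
                         cranial_group = "INTACT",
                         mixture_baseline = class_mixture(c(0.3, 0.5, 0.1, 0.1)),
                         mixture_compression = mixture_baseline,
                         mean_icp_baseline = 11.8,
                         mean_icp_compression = 17.1,
                         heart_rate_mean = 75,
                         heart_rate_sd = 2,
                         b4c_disagreement_prob = 0.12,
                         b4c_shift = c("symmetric", "down"),
                         artifact_rate = 0.02,
                         noise_sd = 0.02,
                         pulse_amp_mmhg = 4) {
  cranial_group <- match.arg(cranial_group, CRANIAL_GROUPS)
  b4c_shift <- match.arg(b4c_shift)
  assert_number(age, "age", lower = 18)
  assert_number(heart_rate_mean, "heart_rate_mean", lower = 40, upper = 180)
  assert_number(heart_rate_sd, "heart_rate_sd", lower = 0)
  assert_number(b4c_disagreement_prob, "b4c_disagreement_prob", 0, 1)
  assert_number(artifact_rate, "artifact_rate", 0, 1)
  assert_number(mean_icp_baseline, "mean_icp_baseline")
  assert_number(mean_icp_compression, "mean_icp_compression")
  if (mean_icp_compression < mean_icp_baseline)
    stopf("`mean_icp_compression` must be >= `mean_icp_baseline` (plateau wave)")
  structure(list(patient_id = as.character(patient_id), age = age,
                 cranial_group = cranial_group,
                 mixture_baseline = class_mixture(unclass(mixture_baseline)),
                 mixture_compression = class_mixture(unclass(mixture_compression)),
                 mean_icp_baseline = mean_icp_baseline,
                 mean_icp_compression = mean_icp_compression,
                 heart_rate_mean = heart_rate_mean,
                 heart_rate_sd = heart_rate_sd,
                 b4c_disagreement_prob = b4c_disagreement_prob,
                 b4c_shift = b4c_shift,
                 artifact_rate = artifact_rate,
                 noise_sd = noise_sd,
                 pulse_amp_mmhg = pulse_amp_mmhg),
            class = "patient_spec")
}

#' Signal record
#'
#' A single channel of a patient's recording with its phase annotations.
#'
#' @param samples Numeric vector (mm Hg for the pressure channel, arbitrary
#'   units for the expansion channel).
#' @param fs Sampling frequency in Hz.
#' @param patient_id Identifier string.
#' @param channel `"ICP"` or `"B4C"`.
#' @param phases Data frame with columns `phase`, `start_s`, `end_s`;
#'   intervals must be non-overlapping and lie within the recording.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, patient_id = "unknown",
                          channel = c("ICP", "B4C"), phases = NULL) {
  channel <- match.arg(channel)
  assert_number(fs, "fs", lower = 1e-9)
  if (!is.numeric(samples) || !length(samples))
    stopf("`samples` must be a non-empty numeric vector")
  dur <- length(samples) / fs
  if (!is.null(phases)) {
    need <- c("phase", "start_s", "end_s")
    if (!all(need %in% names(phases)))
      stopf("`phases` needs columns phase, start_s, end_s")
    phases <- phases[order(phases$start_s), , drop = FALSE]
    if (any(phases$end_s <= phases$start_s))
      stopf("phase intervals must have positive length")
    if (nrow(phases) > 1L &&
        any(phases$start_s[-1L] < phases$end_s[-nrow(phases)] - 1e-9))
      stopf("phase intervals must not overlap")
    if (any(phases$end_s > dur + 1e-6))
      stopf("phase intervals must lie within the recording (%.1f s)", dur)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 patient_id = as.character(patient_id), channel = channel,
                 phases = phases),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> patient %s, channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

# logistic plateau between the baseline and compression pressure levels,
# with ~5-s ramps centered on the compression on/offset
plateau_level <- function(t, protocol, low, high, ramp_s = 5) {
  t_on <- protocol$baseline_s
  t_off <- protocol$baseline_s + protocol$compression_s
  s <- ramp_s / 6  # +/- 3 scale units span the nominal ramp
  low + (high - low) * (stats::plogis((t - t_on) / s) -
                        stats::plogis((t - t_off) / s))
}

#' Simulate one patient's paired recording
#'
#' Concatenates per-beat pulse templates into an invasive pressure channel
#' (absolute baseline in mm Hg, with a smooth plateau wave during the
#' compression phase and respiratory modulation) and a noninvasive
#' skull-expansion channel (pulsatile only, arbitrary units). Each beat's
#' morphological class is drawn from the phase-appropriate mixture; the
#' expansion channel reuses the beat's class unless a disagreement is drawn.
#' Artifact pulses are injected independently per channel.
#'
#' @param spec A [patient_spec()].
#' @param protocol A [protocol_spec()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A list with elements `icp` and `b4c` ([signal_record()]s) and
#'   `truth`, a data frame with one row per beat: `onset_s`, `duration_s`,
#'   `class_icp`, `class_b4c` (class labels `"1"`-`"4"` or `"ARTIFACT"`).
#' @export
simulate_patient <- function(spec, protocol = protocol_spec(), seed = NULL) {
  if (!inherits(spec, "patient_spec")) stopf("`spec` must be a patient_spec")
  if (!inherits(protocol, "protocol_spec")) stopf("`protocol` must be a protocol_spec")
  if (!is.null(seed)) set.seed(seed)
  fs <- protocol$fs
  total_s <- protocol$baseline_s + protocol$compression_s + protocol$recovery_s
  n_total <- round(total_s * fs)
  phases <- protocol_phases(protocol)

  onset_s <- numeric(0); dur_s <- numeric(0)
  cls_icp <- character(0); cls_b4c <- character(0)
  icp_pulses <- list(); b4c_pulses <- list()
  t_cur <- 0; k <- 0L
  while (t_cur < total_s) {
    hr <- stats::rnorm(1, spec$heart_rate_mean, spec$heart_rate_sd)
    hr <- min(180, max(40, hr))
    dur <- 60 / hr
    n <- max(40L, as.integer(round(dur * fs)))
    phase_mix <- if (t_cur >= protocol$baseline_s &&
                     t_cur < protocol$baseline_s + protocol$compression_s)
      spec$mixture_compression else spec$mixture_baseline
    beat_class <- sample.int(4L, 1L, prob = phase_mix)
    # expansion-channel class, possibly shifted relative to the pressure twin
    b4c_class <- beat_class
    if (stats::runif(1) < spec$b4c_disagreement_prob) {
      step <- if (spec$b4c_shift == "down") -1L else sample(c(-1L, 1L), 1L)
      b4c_class <- min(4L, max(1L, beat_class + step))
    }
    gen_one <- function(cl) {
      amps <- if (cl == 4L) NULL else jitter_amplitudes(cl)
      pulse_template(cl, n, amplitudes = amps, noise_sd = spec$noise_sd)
    }
    if (stats::runif(1) < spec$artifact_rate) {
      icp_pulses[[k + 1L]] <- artifact_pulse(n); icp_lab <- "ARTIFACT"
    } else {
      icp_pulses[[k + 1L]] <- gen_one(beat_class); icp_lab <- as.character(beat_class)
    }
    if (stats::runif(1) < spec$artifact_rate) {
      b4c_pulses[[k + 1L]] <- artifact_pulse(n); b4c_lab <- "ARTIFACT"
    } else {
      b4c_pulses[[k + 1L]] <- gen_one(b4c_class); b4c_lab <- as.character(b4c_class)
    }
    k <- k + 1L
    onset_s[k] <- t_cur; dur_s[k] <- n / fs
    cls_icp[k] <- icp_lab; cls_b4c[k] <- b4c_lab
    t_cur <- t_cur + n / fs
  }

  icp_puls <- unlist(icp_pulses, use.names = FALSE)[seq_len(n_total)]
  b4c_puls <- unlist(b4c_pulses, use.names = FALSE)[seq_len(n_total)]
  t <- (seq_len(n_total) - 1) / fs

  resp_phase <- stats::runif(1, 0, 2 * pi)
  resp <- sin(2 * pi * 0.25 * t + resp_phase)

  icp_pulsatile <- icp_puls * spec$pulse_amp_mmhg + 0.5 * resp
  level <- plateau_level(t, protocol, spec$mean_icp_baseline,
                         spec$mean_icp_compression)
  icp <- level + icp_pulsatile
  # center the pulsatile component within each phase so phase means track the
  # configured pressure levels
  for (i in seq_len(nrow(phases))) {
    idx <- t >= phases$start_s[i] & t < phases$end_s[i]
    icp[idx] <- icp[idx] - mean(icp_pulsatile[idx])
  }

  b4c <- b4c_puls + 0.05 * resp
  b4c <- b4c - mean(b4c)  # pulsatile only, no absolute baseline

  keep <- onset_s < total_s - 1e-9
  truth <- data.frame(onset_s = onset_s[keep], duration_s = dur_s[keep],
                      class_icp = cls_icp[keep], class_b4c = cls_b4c[keep],
                      stringsAsFactors = FALSE)
  list(icp = signal_record(icp, fs, spec$patient_id, "ICP", phases),
       b4c = signal_record(b4c, fs, spec$patient_id, "B4C", phases),
       truth = truth,
       spec = spec, protocol = protocol)
}

# small per-beat jitter of the canonical amplitude triple, resampled until it
# still satisfies the class definition
jitter_amplitudes <- function(class_label, sd = 0.02) {
  base <- canonical_amplitudes(class_label)
  for (i in 1:20) {
    a <- pmax(0, base + stats::rnorm(3, 0, sd))
    if (amplitudes_match_class(a, class_label)) return(a)
  }
  base
}

#' Default per-group class mixtures
#'
#' Baseline mixtures whose expected class numbers match the group medians the
#' generator is calibrated to: 2.0 for intact skulls and
#' craniotomy/fracture patients, 3.5 for craniectomy patients.
#'
#' @return Named list of [class_mixture()] objects.
#' @export
default_group_mixtures <- function() {
  list(INTACT = class_mixture(c(0.3, 0.5, 0.1, 0.1)),
       CRANIOTOMY_FRACTURE = class_mixture(c(0.3, 0.5, 0.1, 0.1)),
       CRANIECTOMY = class_mixture(c(0, 0.1, 0.3, 0.6)))
}

#' Simulate a full cohort
#'
#' Generates a cohort of patients across the three cranial-integrity groups.
#' The default calibration places the expected pressure-channel class number
#' at 2.0 for intact and craniotomy/fracture patients and 3.5 for
#' craniectomy patients, lets the noninvasive channel underestimate
#' craniectomy morphology (expected class 3.0 via a downward class-shift
#' disagreement), drifts morphology upward with age (centered at the
#' 43-year cohort median so group calibration is preserved), and draws
#' per-patient baseline/compression pressure levels around 11.8 and
#' 17.1 mm Hg. All randomness flows from `seed`; per-patient substreams are
#' derived deterministically.
#'
#' @param n_intact,n_craniotomy,n_craniectomy Group sizes (defaults 17, 17,
#'   13).
#' @param seed Integer seed.
#' @param protocol A [protocol_spec()].
#' @param mixtures Named list of per-group baseline [class_mixture()]s.
#' @param icp_baseline_mmhg,icp_baseline_sd Center and between-patient spread
#'   of the baseline pressure level.
#' @param icp_rise_mmhg,icp_rise_sd Center and spread of the pressure rise
#'   during compression.
#' @param age_range Ages are drawn uniformly over this range.
#' @param age_kappa Strength of the age-related upward class drift (mass
#'   shifted per unit of centered, scaled age).
#' @param artifact_rate,noise_sd Passed to [patient_spec()].
#' @param b4c_disagreement_prob Disagreement probability for non-craniectomy
#'   patients; craniectomy patients use `craniectomy_b4c_prob` with a
#'   downward shift.
#' @param craniectomy_b4c_prob Downward-shift probability for craniectomy
#'   patients (0.5 moves the expected noninvasive class from 3.5 to 3.0).
#' @return A list with `patients` (list of [simulate_patient()] results),
#'   `metadata` (data frame `patient_id`, `age`, `cranial_group`) and
#'   `truth` (row-bound ground truth with a `patient_id` column).
#' @export
simulate_cohort <- function(n_intact = 17, n_craniotomy = 17, n_craniectomy = 13,
                            seed = 1,
                            protocol = protocol_spec(),
                            mixtures = default_group_mixtures(),
                            icp_baseline_mmhg = 11.8, icp_baseline_sd = 1.5,
                            icp_rise_mmhg = 5.3, icp_rise_sd = 0.8,
                            age_range = c(18, 78),
                            age_kappa = 0.6,
                            artifact_rate = 0.02,
                            noise_sd = 0.02,
                            b4c_disagreement_prob = 0.12,
                            craniectomy_b4c_prob = 0.5) {
  sizes <- c(INTACT = n_intact, CRANIOTOMY_FRACTURE = n_craniotomy,
             CRANIECTOMY = n_craniectomy)
  if (any(sizes < 1)) stopf("all group sizes must be >= 1")
  for (g in names(sizes))
    mixtures[[g]] <- class_mixture(unclass(mixtures[[g]]))
  set.seed(as.integer(seed))
  n_all <- sum(sizes)
  groups <- rep(names(sizes), sizes)
  ages <- round(stats::runif(n_all, age_range[1], age_range[2]))
  icp_base <- pmax(3, stats::rnorm(n_all, icp_baseline_mmhg, icp_baseline_sd))
  icp_comp <- icp_base + pmax(0.5, stats::rnorm(n_all, icp_rise_mmhg, icp_rise_sd))
  hr_means <- stats::runif(n_all, 60, 100)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_all)

  patients <- vector("list", n_all)
  meta <- data.frame(patient_id = sprintf("P%02d", seq_len(n_all)),
                     age = ages, cranial_group = groups,
                     stringsAsFactors = FALSE)
  truth_list <- vector("list", n_all)
  age_mid <- mean(age_range)  # calibration center; near the 43-y cohort median
  for (i in seq_len(n_all)) {
    g <- groups[i]
    s_age <- age_kappa * (ages[i] - age_mid) / diff(age_range)
    mix <- class_mixture(shift_mixture(mixtures[[g]], s_age))
    is_cect <- g == "CRANIECTOMY"
    spec <- patient_spec(
      patient_id = meta$patient_id[i], age = ages[i], cranial_group = g,
      mixture_baseline = mix, mixture_compression = mix,
      mean_icp_baseline = icp_base[i], mean_icp_compression = icp_comp[i],
      heart_rate_mean = hr_means[i], heart_rate_sd = 2,
      b4c_disagreement_prob = if (is_cect) craniectomy_b4c_prob else b4c_disagreement_prob,
      b4c_shift = if (is_cect) "down" else "symmetric",
      artifact_rate = artifact_rate, noise_sd = noise_sd)
    patients[[i]] <- simulate_patient(spec, protocol, seed = patient_seeds[i])
    tr <- patients[[i]]$truth
    tr$patient_id <- meta$patient_id[i]
    truth_list[[i]] <- tr[, c("patient_id", "onset_s", "duration_s",
                              "class_icp", "class_b4c")]
  }
  list(patients = patients, metadata = meta,
       truth = do.call(rbind, truth_list))
}
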
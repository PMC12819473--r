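# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they stay independent of the package's own
# implementations.

# exhaustive scan for interior local maxima (strict on the left, >= right)
oracle_local_maxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && x[i] > x[i - 1] && x[i] >= x[i + 1]
  }, logical(1)))
}

# exhaustive scan for interior local minima
oracle_local_minima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && x[i] < x[i - 1] && x[i] <= x[i + 1]
  }, logical(1)))
}

# Kruskal-Wallis H by the textbook rank formula (no ties)
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, groups, mean)
  nj <- table(groups)
  12 / (N * (N + 1)) * sum(nj * (rbar - (N + 1) / 2)^2)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mid <- n * (n + 1) / 4
  all_v <- vapply(0:(2^n - 1), function(m) {
    sum(r[as.logical(bitwAnd(m, 2^(0:(n - 1))))])
  }, numeric(1))
  mean(abs(all_v - mid) >= abs(V - mid) - 1e-12)
}

# greedy matching of detected onsets to ground-truth times within `tol` s
match_onsets <- function(detected_s, truth_s, tol = 0.025) {
  used <- rep(FALSE, length(detected_s))
  hits <- 0L
  for (o in truth_s) {
    d <- abs(detected_s - o)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      hits <- hits + 1L
      used[j] <- TRUE
    }
  }
  list(recall = hits / length(truth_s),
       precision = if (length(detected_s)) hits / length(detected_s) else NA)
}

# align classified pulses to ground-truth beats by nearest onset
align_truth <- function(onset_s, truth) {
  idx <- vapply(onset_s, function(o) which.min(abs(truth$onset_s - o)),
                integer(1))
  truth[idx, , drop = FALSE]
}

# cheap single-patient baseline-only pipeline used in several tests
run_baseline_pipeline <- function(mixture, seed, baseline_s = 60, ...) {
  sp <- patient_spec("X", mixture_baseline = class_mixture(mixture), ...)
  proto <- protocol_spec(baseline_s = baseline_s, compression_s = 0,
                         recovery_s = 0)
  sim <- simulate_patient(sp, proto, seed = seed)
  on <- detect_onsets(sim$icp)
  segs <- segment_pulses(sim$icp, on)
  cls <- classify_segments(segs)
  list(sim = sim, classified = cls,
       windows = psi_windows(cls, 0, baseline_s))
}
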
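# synthetic_cohort module: constructors, pulse templates, patient and cohort
# simulation against grid oracles and configured calibration levels.

test_that("pulse_shape_params validates its invariants", {
  expect_s3_class(pulse_shape_params(), "pulse_shape_params")
  expect_error(pulse_shape_params(amplitudes = c(-1, 0.5, 0.5)), "non-negative")
  expect_error(pulse_shape_params(amplitudes = c(0, 0, 0)), "positive")
  expect_error(pulse_shape_params(latencies = c(0.4, 0.2, 0.6)), "increasing")
  expect_error(pulse_shape_params(latencies = c(0.2, 0.4, 1.1)), "increasing")
  expect_error(pulse_shape_params(widths = c(0.1, -0.1, 0.1)), "positive")
  expect_error(pulse_shape_params(noise_sd = -0.1), "noise_sd")
})

test_that("class_mixture enforces normalization and non-negativity", {
  m <- class_mixture(c(0.3, 0.5, 0.1, 0.1))
  expect_s3_class(m, "class_mixture")
  expect_error(class_mixture(c(0.3, 0.5, 0.1)), "four")
  expect_error(class_mixture(c(0.5, 0.5, 0.5, -0.5)), "non-negative")
  expect_error(class_mixture(c(0.3, 0.3, 0.3, 0.3)), "sum to 1")
})

test_that("mixture_expected_class evaluates the weighted class sum", {
  expect_equal(mixture_expected_class(c(0, 0.1, 0.3, 0.6)), 3.5)
  expect_equal(mixture_expected_class(c(0.3, 0.5, 0.1, 0.1)), 2.0)
  expect_equal(mixture_expected_class(c(1, 0, 0, 0)), 1)
  expect_equal(mixture_expected_class(c(0, 0, 0, 1)), 4)
})

test_that("pulse_template rejects invalid classes and inconsistent amplitudes", {
  expect_error(pulse_template(5L, 200), "class_label")
  expect_error(pulse_template(1L, 10), ">= 40")
  # amplitude triple violating the requested class definition
  expect_error(pulse_template(1L, 200, amplitudes = c(0.5, 1.0, 0.4)),
               "inconsistent")
  expect_error(pulse_template(3L, 200, amplitudes = c(1.0, 0.7, 0.4)),
               "inconsistent")
})

test_that("class 4 template has exactly one local maximum at zero noise", {
  for (n in c(120, 180, 250)) {
    y <- pulse_template(4L, n, noise_sd = 0)
    expect_length(oracle_local_maxima(y), 1L)
  }
})

test_that("class 1 and 2 templates satisfy peak-ordering oracles at zero noise", {
  # class 1, amplitudes (1.0, 0.7, 0.4): first peak is the global maximum
  y1 <- pulse_template(1L, 200, noise_sd = 0)
  mx <- oracle_local_maxima(y1)
  expect_gte(length(mx), 3L)
  expect_equal(which.max(y1), mx[1])
  # class 2, amplitudes (0.8, 1.0, 0.5): middle peak is the global maximum
  # and the first peak exceeds the third
  y2 <- pulse_template(2L, 200, noise_sd = 0)
  mx2 <- oracle_local_maxima(y2)
  expect_gte(length(mx2), 3L)
  expect_equal(which.max(y2), mx2[2])
  expect_gt(y2[mx2[1]], y2[mx2[3]])
  # class 3, amplitudes (0.6, 1.0, 0.8): P2 and P3 both above P1
  y3 <- pulse_template(3L, 200, noise_sd = 0)
  mx3 <- oracle_local_maxima(y3)
  expect_gte(length(mx3), 3L)
  expect_gt(y3[mx3[2]], y3[mx3[1]])
  expect_gt(y3[mx3[3]], y3[mx3[1]])
})

test_that("protocol and patient specs validate their invariants", {
  expect_error(protocol_spec(fs = 0), "fs")
  expect_error(protocol_spec(baseline_s = 0), "baseline_s")
  expect_error(patient_spec("P", age = 10), "age")
  expect_error(patient_spec("P", heart_rate_mean = 200), "heart_rate_mean")
  expect_error(patient_spec("P", cranial_group = "NOPE"))
  expect_error(patient_spec("P", mean_icp_baseline = 15,
                            mean_icp_compression = 12), "plateau")
  ph <- protocol_phases(protocol_spec())
  expect_equal(ph$phase, c("baseline", "compression", "recovery"))
  expect_equal(ph$end_s - ph$start_s, c(60, 60, 60))
})

test_that("signal_record rejects malformed phase annotations", {
  x <- sin(seq(0, 10, by = 0.01))
  bad_overlap <- data.frame(phase = c("a", "b"), start_s = c(0, 3),
                            end_s = c(5, 8))
  expect_error(signal_record(x, 100, phases = bad_overlap), "overlap")
  bad_beyond <- data.frame(phase = "a", start_s = 0, end_s = 99)
  expect_error(signal_record(x, 100, phases = bad_beyond), "within")
  expect_error(signal_record(numeric(0), 100), "non-empty")
})

test_that("zero perturbation makes the two channels' classes identical", {
  sp <- patient_spec("P", artifact_rate = 0, noise_sd = 0,
                     b4c_disagreement_prob = 0)
  sim <- simulate_patient(sp, protocol_spec(baseline_s = 30,
                                            compression_s = 0,
                                            recovery_s = 0), seed = 11)
  expect_identical(sim$truth$class_icp, sim$truth$class_b4c)
  expect_false(any(sim$truth$class_icp == "ARTIFACT"))
})

test_that("beat count and inter-onset interval track the heart rate", {
  sp <- patient_spec("P", heart_rate_mean = 72, heart_rate_sd = 2)
  sim <- simulate_patient(sp, protocol_spec(), seed = 12)  # 180-s protocol
  tr <- sim$truth
  expect_true(!is.unsorted(tr$onset_s, strictly = TRUE))
  expect_true(all(tr$onset_s < 180))
  mean_ibi <- mean(tr$duration_s)
  expect_lt(abs(mean_ibi - 60 / 72) / (60 / 72), 0.05)
  expect_lt(abs(nrow(tr) - 180 * 72 / 60) / (180 * 72 / 60), 0.05)
})

test_that("compression-phase mean pressure exceeds the baseline mean", {
  sp <- patient_spec("P", mean_icp_baseline = 11.8, mean_icp_compression = 17.1)
  sim <- simulate_patient(sp, protocol_spec(), seed = 13)
  mb <- mean_icp(sim$icp, "baseline")
  mc <- mean_icp(sim$icp, "compression")
  expect_gt(mc, mb)
})

test_that("pressure phase means recover configured levels within 0.5 mmHg", {
  sp <- patient_spec("P", mean_icp_baseline = 11.8, mean_icp_compression = 17.1)
  sim <- simulate_patient(sp, protocol_spec(), seed = 14)
  expect_lt(abs(mean_icp(sim$icp, "baseline") - 11.8), 0.5)
  expect_lt(abs(mean_icp(sim$icp, "compression") - 17.1), 0.5)
})

test_that("empirical class fractions converge to the configured mixture", {
  mix <- c(0.3, 0.5, 0.1, 0.1)
  sp <- patient_spec("P", mixture_baseline = class_mixture(mix),
                     artifact_rate = 0, noise_sd = 0,
                     heart_rate_mean = 180, heart_rate_sd = 0)
  # > 10,000 beats at 180 bpm (0.335 s per beat at 200 Hz)
  proto <- protocol_spec(baseline_s = 3400, compression_s = 0, recovery_s = 0)
  sim <- simulate_patient(sp, proto, seed = 15)
  expect_gte(nrow(sim$truth), 10000)
  frac <- tabulate(as.integer(sim$truth$class_icp), 4) / nrow(sim$truth)
  expect_true(all(abs(frac - mix) <= 0.02))
})

test_that("the b4c downward shift moves only disagreeing beats one class down", {
  sp <- patient_spec("P", mixture_baseline = class_mixture(c(0, 0.1, 0.3, 0.6)),
                     b4c_disagreement_prob = 0.5, b4c_shift = "down",
                     artifact_rate = 0, noise_sd = 0)
  sim <- simulate_patient(sp, protocol_spec(baseline_s = 120, compression_s = 0,
                                            recovery_s = 0), seed = 16)
  ci <- as.integer(sim$truth$class_icp); cb <- as.integer(sim$truth$class_b4c)
  expect_true(all(cb == ci | cb == pmax(1L, ci - 1L)))
  # roughly half the beats disagree
  expect_gt(mean(cb != ci), 0.35)
  expect_lt(mean(cb != ci), 0.65)
})

test_that("the noninvasive channel is pulsatile-only (zero mean)", {
  sim <- simulate_patient(patient_spec("P"), protocol_spec(), seed = 17)
  expect_lt(abs(mean(sim$b4c$samples)), 1e-9)
  # while the pressure channel carries the absolute baseline
  expect_gt(mean(sim$icp$samples), 5)
})

test_that("simulate_cohort is deterministic given the seed", {
  proto <- protocol_spec(baseline_s = 20, compression_s = 10, recovery_s = 5)
  c1 <- simulate_cohort(2, 2, 2, seed = 42, protocol = proto)
  c2 <- simulate_cohort(2, 2, 2, seed = 42, protocol = proto)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$truth, c2$truth)
  for (i in seq_along(c1$patients)) {
    expect_identical(c1$patients[[i]]$icp$samples, c2$patients[[i]]$icp$samples)
    expect_identical(c1$patients[[i]]$b4c$samples, c2$patients[[i]]$b4c$samples)
  }
  c3 <- simulate_cohort(2, 2, 2, seed = 43, protocol = proto)
  expect_false(identical(c1$patients[[1]]$icp$samples,
                         c3$patients[[1]]$icp$samples))
})

test_that("cohort structure matches group sizes and metadata schema", {
  proto <- protocol_spec(baseline_s = 20, compression_s = 10, recovery_s = 5)
  co <- simulate_cohort(3, 2, 2, seed = 5, protocol = proto)
  expect_length(co$patients, 7)
  expect_equal(as.vector(table(co$metadata$cranial_group)[CRANIAL_GROUPS]),
               c(3, 2, 2))
  expect_true(all(co$metadata$age >= 18 & co$metadata$age <= 78))
  expect_true(all(co$truth$patient_id %in% co$metadata$patient_id))
  expect_error(simulate_cohort(0, 2, 2, seed = 1), "group sizes")
})

test_that("default group mixtures hit the calibrated expected classes", {
  mx <- default_group_mixtures()
  expect_equal(mixture_expected_class(mx$INTACT), 2.0)
  expect_equal(mixture_expected_class(mx$CRANIOTOMY_FRACTURE), 2.0)
  expect_equal(mixture_expected_class(mx$CRANIECTOMY), 3.5)
})
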
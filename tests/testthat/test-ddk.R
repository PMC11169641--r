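# DDK syllable detection, the eight /pa/ features, and voice onset time.

# a hand-built envelope of Gaussian syllable bumps with known amplitudes
bump_envelope <- function(amps, period_s = 0.2, width_s = 0.03) {
  hop <- 0.001
  dur <- period_s * (length(amps) + 1)
  times <- seq(0, dur, by = hop)
  v <- numeric(length(times))
  for (i in seq_along(amps)) {
    centre <- i * period_s
    v <- v + amps[i] * exp(-0.5 * ((times - centre) / width_s)^2)
  }
  frame_track(times, v, rep(NA, length(v)), 0.02, hop)
}

test_that("syllable detection finds every clean syllable and nothing in silence", {
  d <- synth_ddk(rate_hz = 5, duration_s = 7, period_cv = 0,
                 intensity_cv = 0, sample_rate = TEST_SR, seed = 201)
  ev <- detect_syllables(amplitude_envelope(d$recording))
  expect_equal(nrow(ev), 35)
  expect_true(all(ev$onset_s < ev$peak_s & ev$peak_s < ev$offset_s))
  expect_true(all(diff(ev$peak_s) > 0))

  silence <- audio_recording(rep(1e-10, TEST_SR), TEST_SR)
  expect_warning(none <- detect_syllables(amplitude_envelope(silence)),
                 "no syllable")
  expect_equal(nrow(none), 0)
})

test_that("the prominence threshold separates weak syllables", {
  amps <- c(rep(1, 5), 0.3, rep(1, 4))
  env <- bump_envelope(amps)
  lo <- detect_syllables(env, min_prominence = 0.1, min_period_ms = 100)
  hi <- detect_syllables(env, min_prominence = 0.5, min_period_ms = 100)
  expect_equal(nrow(lo), 10)
  expect_equal(nrow(hi), 9)
  expect_error(detect_syllables(env, min_prominence = 1.5), "prominence")
})

test_that("DDK features match hand computations", {
  d <- synth_ddk(rate_hz = 5, duration_s = 7, period_cv = 0,
                 intensity_cv = 0, sample_rate = TEST_SR, seed = 202)
  ev <- detect_syllables(amplitude_envelope(d$recording))
  fx <- ddk_features(ev, rec_duration(d$recording))
  expect_equal(fx$DDKavr, 5, tolerance = 0.011)
  expect_lt(fx$DDKsdp, 2)
  expect_lt(fx$DDKjit, 2)
  expect_lt(fx$DDKcvi, 1)
  expect_equal(fx$DDKcvp, 100 * fx$DDKsdp / fx$DDKavp, tolerance = 1e-12)

  # alternating periods 180/220 ms -> jitter 100*40/200 = 20 %
  n <- 21
  peaks <- cumsum(c(0.5, rep(c(0.18, 0.22), length.out = n - 1)))
  ev2 <- data.frame(onset_s = peaks - 0.03, peak_s = peaks,
                    offset_s = peaks + 0.03,
                    peak_intensity_db = rep(80, n),
                    period_s = c(diff(peaks), NA))
  fx2 <- ddk_features(ev2, max(peaks) + 0.5)
  expect_equal(fx2$DDKjit, 20, tolerance = 0.01)

  # periods {200, 200, 200, 260} ms -> SD of periods = 30 ms
  peaks3 <- cumsum(c(0.5, 0.2, 0.2, 0.2, 0.26))
  ev3 <- data.frame(onset_s = peaks3 - 0.04, peak_s = peaks3,
                    offset_s = peaks3 + 0.04,
                    peak_intensity_db = rep(80, 5),
                    period_s = c(diff(peaks3), NA))
  fx3 <- ddk_features(ev3, 2)
  expect_equal(fx3$DDKsdp, 30, tolerance = 1e-9)
  expect_equal(fx3$DDKcvp, 100 * 30 / fx3$DDKavp, tolerance = 1e-9)

  expect_error(ddk_features(ev3[1:2, ], 2), "insufficient")
})

test_that("injected period and intensity variability are recovered", {
  d <- synth_ddk(rate_hz = 5, duration_s = 8, period_cv = 0.1,
                 intensity_cv = 0.3, sample_rate = TEST_SR, seed = 203)
  ev <- detect_syllables(amplitude_envelope(d$recording))
  expect_equal(nrow(ev), nrow(d$truth$events))
  periods <- ev$period_s[!is.na(ev$period_s)]
  measured_cv <- 100 * sd(periods) / mean(periods)
  truth_cv <- 100 * sd(d$truth$periods_s) / mean(d$truth$periods_s)
  expect_lt(abs(measured_cv - truth_cv), 3)
  fx <- ddk_features(ev, rec_duration(d$recording))
  # amplitude CV 0.3 corresponds to ~8.686*0.3 = 2.6 dB of peak-level SD
  expect_lt(abs(fx$DDKsdi - 2.6), 1)
})

test_that("voice onset time is recovered from burst and voicing landmarks", {
  d <- synth_ddk(rate_hz = 5, duration_s = 7, vot_ms = 33,
                 sample_rate = TEST_SR, seed = 204)
  ev <- detect_syllables(amplitude_envelope(d$recording))
  expect_lt(abs(measure_vot(d$recording, ev) - 33), 5)

  d2 <- synth_ddk(rate_hz = 5, duration_s = 7, vot_ms = c(20, 30, 40),
                  sample_rate = TEST_SR, seed = 205)
  ev2 <- detect_syllables(amplitude_envelope(d2$recording))
  expect_lt(abs(measure_vot(d2$recording, ev2) - 30), 5)

  # an all-voiced signal has no release bursts
  v <- synth_vowel(f0_hz = 150, duration_s = 2, hnr_db = 40,
                   sample_rate = TEST_SR, seed = 206)
  fake <- data.frame(onset_s = 0.5, peak_s = 0.9, offset_s = 1.2,
                     peak_intensity_db = 80, period_s = NA)
  expect_error(measure_vot(v$recording, fake), "not computable")
})

test_that("period features are amplitude-scale invariant", {
  d <- synth_ddk(rate_hz = 4, duration_s = 7, period_cv = 0.05,
                 intensity_cv = 0.2, sample_rate = TEST_SR, seed = 207)
  rec <- d$recording
  half <- audio_recording(rec$samples * 0.5, TEST_SR, task = "ddk_pa")
  f1 <- ddk_features(detect_syllables(amplitude_envelope(rec)),
                     rec_duration(rec))
  f2 <- ddk_features(detect_syllables(amplitude_envelope(half)),
                     rec_duration(half))
  expect_equal(f1$DDKavr, f2$DDKavr)
  expect_lt(abs(f1$DDKavp - f2$DDKavp), 1)
  expect_lt(abs(f1$DDKsdp - f2$DDKsdp), 1)
  expect_lt(abs(f1$DDKsdi - f2$DDKsdi), 0.05)
})
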
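# Shared DSP primitives: WAV I/O, resampling, envelope, pitch, intensity,
# formants, voicing segmentation, HNR.

test_that("WAV round-trips preserve silence, stereo averages, sines", {
  tmp <- tempfile(fileext = ".wav")

  write_wav(audio_recording(rep(1e-9, 48000), 48000), tmp)
  rec <- read_wav(tmp)
  expect_equal(length(rec$samples), 48000)
  expect_true(all(rec$samples == 0))

  t <- (0:15999) / 16000
  x <- 0.4 * sin(2 * pi * 440 * t)
  write_stereo_wav(tmp, x, x, 16000)
  expect_warning(st <- read_wav(tmp), "averaging")
  expect_equal(length(st$samples), 16000)
  expect_lt(max(abs(st$samples - x)), 2^-14)

  write_wav(audio_recording(x, 16000), tmp)
  back <- read_wav(tmp)
  expect_lt(max(abs(back$samples - x)), 2^-14)
})

test_that("read_wav rejects missing and non-WAV files", {
  expect_error(read_wav(tempfile()), "not found")
  junk <- tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), junk)
  expect_error(read_wav(junk), "RIFF")
})

test_that("resampling preserves content, duration, and identity", {
  s <- sine_rec(1000, 1, sr = 48000)
  expect_identical(resample_audio(s, 48000)$samples, s$samples)

  rt <- resample_audio(resample_audio(s, 16000), 48000)
  expect_gt(stats::cor(rt$samples, s$samples), 0.999)

  for (target in c(8000, 22050, 44100)) {
    out <- resample_audio(sine_rec(500, 1, sr = 32000), target)
    expect_lte(abs(length(out$samples) - target), 1)
  }
  expect_error(resample_audio(s, -1), "positive")
})

test_that("amplitude envelope tracks level and modulation", {
  s <- sine_rec(200, 1, amp = 0.5)
  env <- amplitude_envelope(s, smooth_ms = 20)
  inner <- env$values[env$times > 0.05 & env$times < 0.95]
  expect_true(all(abs(inner - 0.5) < 0.05))

  silence <- audio_recording(rep(1e-12, TEST_SR), TEST_SR)
  expect_true(all(amplitude_envelope(silence)$values < 1e-9))

  # 4 Hz AM for 2 s: 8 modulation peaks (edge effects allow one extra)
  t <- (0:(2 * TEST_SR - 1)) / TEST_SR
  am <- audio_recording(0.5 * (1 + 0.8 * sin(2 * pi * 4 * t)) *
                          sin(2 * pi * 300 * t), TEST_SR)
  env_am <- amplitude_envelope(am)
  pk <- detect_syllables(env_am, min_prominence = 0.3, min_period_ms = 150)
  expect_lte(abs(nrow(pk) - 8), 1)

  expect_error(amplitude_envelope(audio_recording(0.1, TEST_SR)), "short")
})

test_that("F0 tracking recovers synthetic pitch and rejects noise", {
  v <- synth_vowel(f0_hz = 160, duration_s = 4, f0_sd_hz = 0, hnr_db = 30,
                   sample_rate = TEST_SR, seed = 101)
  f0 <- track_f0(v$recording)
  m <- mean(f0$values[f0$voiced])
  expect_lt(abs(m - 160) / 160, 0.01)

  set.seed(7)
  noise <- audio_recording(0.3 * stats::rnorm(2 * TEST_SR), TEST_SR)
  fn <- track_f0(noise)
  expect_lt(mean(fn$voiced), 0.2)
  expect_true(all(is.na(fn$values[!fn$voiced])))

  # linear glide 120 -> 180 Hz over 2 s, frame F0 within 3 Hz of target
  t <- (0:(2 * TEST_SR - 1)) / TEST_SR
  phase <- 2 * pi * cumsum(120 + 30 * t) / TEST_SR
  g <- track_f0(audio_recording(0.5 * sin(phase), TEST_SR))
  tgt <- 120 + 30 * g$times
  expect_true(all(abs(g$values[g$voiced] - tgt[g$voiced]) < 3))

  expect_error(track_f0(v$recording, f0_min = 300, f0_max = 100),
               "impossible")
})

test_that("intensity contour is calibrated to dBFS and obeys the gain law", {
  sq <- audio_recording(rep(c(1, -1), each = 8, times = 2000), TEST_SR)
  expect_lt(max(abs(intensity_contour(sq)$values)), 0.1)

  s <- sine_rec(220, 1, amp = 0.1)
  expect_lt(abs(mean(intensity_contour(s)$values) - (-23.01)), 0.5)

  half <- audio_recording(s$samples / 2, TEST_SR)
  delta <- intensity_contour(s)$values - intensity_contour(half)$values
  expect_true(all(abs(delta - 6.02) < 0.1))
})

test_that("LPC formant tracks recover resonator frequencies in order", {
  v <- synth_vowel(f0_hz = 130, duration_s = 2, f0_sd_hz = 0, hnr_db = 30,
                   formants = list(c(300, 80), c(2200, 150)),
                   sample_rate = TEST_SR, seed = 55)
  fm <- lpc_formants(v$recording, 3)
  expect_true(dplyr::between(median(fm[[1]]$values, na.rm = TRUE), 270, 330))
  expect_true(dplyr::between(median(fm[[2]]$values, na.rm = TRUE), 2100, 2300))
  both <- !is.na(fm[[1]]$values) & !is.na(fm[[2]]$values)
  expect_true(all(fm[[1]]$values[both] < fm[[2]]$values[both]))

  v2 <- synth_vowel(f0_hz = 130, duration_s = 2, f0_sd_hz = 0, hnr_db = 30,
                    formants = list(c(800, 90), c(1200, 110)),
                    sample_rate = TEST_SR, seed = 56)
  fm2 <- lpc_formants(v2$recording, 3)
  expect_lt(abs(median(fm2[[1]]$values, na.rm = TRUE) - 800) / 800, 0.1)
  expect_lt(abs(median(fm2[[2]]$values, na.rm = TRUE) - 1200) / 1200, 0.1)

  expect_error(lpc_formants(audio_recording(rep(0.1, 100), TEST_SR), 3),
               "short")
  expect_error(lpc_formants(v$recording, 1), "n_formants")
})

test_that("voicing segments merge short gaps and handle edge cases", {
  n <- 300
  tr_all <- frame_track((0:(n - 1)) * 0.01 + 0.02, rep(150, n),
                        rep(TRUE, n), 0.04, 0.01)
  segs <- voicing_segments(tr_all)
  expect_equal(nrow(segs), 1)
  expect_lt(abs((segs$end_s - segs$start_s) - 3), 0.05)

  tr_none <- frame_track((0:9) * 0.01, rep(NA_real_, 10), rep(FALSE, 10),
                         0.04, 0.01)
  expect_equal(nrow(voicing_segments(tr_none)), 0)

  # voiced 0-1 s and 1.02-2 s: the 20 ms gap is bridged (default 50 ms)
  times <- (0:199) * 0.01 + 0.02
  voiced <- !(times > 1.0 & times < 1.02)
  tr_gap <- frame_track(times, ifelse(voiced, 150, NA), voiced, 0.04, 0.01)
  merged <- voicing_segments(tr_gap)
  expect_equal(nrow(merged), 1)
  expect_lt(abs((merged$end_s - merged$start_s) - 2), 0.05)
})

test_that("HNR reflects the harmonic-to-noise power ratio", {
  clean <- synth_vowel(f0_hz = 150, duration_s = 3, f0_sd_hz = 0,
                       hnr_db = 60, sample_rate = TEST_SR, seed = 61)
  expect_gt(hnr(clean$recording), 25)

  mixed <- synth_vowel(f0_hz = 150, duration_s = 3, f0_sd_hz = 0,
                       hnr_db = 10, sample_rate = TEST_SR, seed = 62)
  expect_lt(abs(hnr(mixed$recording) - 10), 1.5)

  set.seed(9)
  noise <- audio_recording(0.3 * stats::rnorm(2 * TEST_SR), TEST_SR)
  got <- tryCatch(hnr(noise), error = function(e) NA_real_)
  expect_true(is.na(got) || got < 3)
})

test_that("frame operations are shift-equivariant and gain-invariant", {
  # interior events shift exactly with a prepended silence
  d <- synth_ddk(rate_hz = 5, duration_s = 5, sample_rate = TEST_SR,
                 seed = 72)
  rec_d <- d$recording
  shifted_d <- audio_recording(c(numeric(round(0.1 * TEST_SR)),
                                 rec_d$samples), TEST_SR, task = "ddk_pa")
  pk0 <- detect_syllables(amplitude_envelope(rec_d))$peak_s
  pk1 <- detect_syllables(amplitude_envelope(shifted_d))$peak_s
  expect_equal(length(pk0), length(pk1))
  expect_true(all(abs((pk1 - pk0) - 0.1) < 0.011))

  v <- synth_vowel(f0_hz = 150, duration_s = 2, f0_sd_hz = 0, hnr_db = 25,
                   sample_rate = TEST_SR, seed = 71)
  rec <- v$recording
  halved <- audio_recording(rec$samples * 0.5, TEST_SR)
  f0a <- track_f0(rec); f0b <- track_f0(halved)
  expect_lt(abs(mean(f0a$values[f0a$voiced]) -
                  mean(f0b$values[f0b$voiced])), 0.5)
  expect_lt(abs(hnr(rec) - hnr(halved)), 0.5)
})

test_that("FrameTracks export as tidy CSV", {
  tr <- frame_track(c(0.02, 0.03), c(150, NA), c(TRUE, FALSE), 0.04, 0.01)
  tmp <- tempfile(fileext = ".csv")
  write_frame_track(tr, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(names(back), c("time_s", "value", "voiced"))
  expect_equal(back$value[1], 150)
})
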
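# Seeded synthetic speech and cohort generators.
#
# The source model is a Rosenberg-style glottal pulse train passed through
# second-order formant resonators: deliberately simple, so that every
# generated recording carries exact ground truth (per-cycle periods, event
# times, pause intervals). The contract of these generators is measurement
# recovery, not naturalness.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' random stream. All generators and the classifier use this internally;
#' it is exported so analyses built on the package can be made
#' reproducible the same way.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# one second-order digital resonator applied in cascade
.resonate <- function(x, freq, bw, sr) {
  r <- exp(-pi * bw / sr)
  th <- 2 * pi * freq / sr
  b <- 1 - 2 * r * cos(th) + r^2 # unity gain at the resonance, roughly
  as.numeric(signal::filter(signal::Arma(b = b,
                                         a = c(1, -2 * r * cos(th), r^2)), x))
}

# Rosenberg glottal flow derivative evaluated at normalized cycle phase
# u in [0, 1) (open phase 40%, return phase 20% of the cycle)
.rosenberg_d <- function(u) {
  tp <- 0.4; tn <- 0.2
  out <- numeric(length(u))
  a <- u <= tp
  v <- u[a] / tp
  out[a] <- (6 * v - 6 * v^2) / tp
  b <- u > tp & u <= tp + tn
  out[b] <- -2 * (u[b] - tp) / tn^2
  out
}

# glottal source with exact per-cycle periods (s) and amplitudes, built by
# a phase accumulator so periods are not quantized to whole samples.
# Synthesized 4x oversampled and band-limited back down: the closure
# discontinuity of the pulse would otherwise alias when the period is not
# an integer number of samples, putting a ceiling on the achievable HNR.
.pulse_train <- function(periods_s, amps, sr) {
  os <- 4L
  sro <- sr * os
  n <- ceiling(sum(periods_s) * sro)
  # half-sample grid offset keeps samples off the waveform breakpoints
  # when the period divides the sample rate exactly
  t <- (seq_len(n) - 0.5) / sro
  bounds <- cumsum(c(0, periods_s))
  idx <- findInterval(t, bounds, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(periods_s))
  u <- (t - bounds[idx]) / periods_s[idx]
  x <- amps[idx] * .rosenberg_d(pmin(pmax(u, 0), 1))
  bf <- signal::butter(8, 0.9 / os, type = "low")
  .resample_vec(signal::filtfilt(bf, x), sro, sr)
}

# AR(1)-drifting per-cycle F0 values; the marginal SD is inflated so that
# the SD of the F0 contour seen through a 40 ms analysis frame (which
# averages ~f0*0.04 cycles) matches the requested target
.cycle_f0 <- function(n, f0, f0_sd, rho = 0.9) {
  if (f0_sd <= 0) return(rep(f0, n))
  m <- max(1, round(f0 * 0.04))
  k <- seq_len(m - 1)
  shrink <- sqrt((m + 2 * sum((m - k) * rho^k)) / m^2)
  sd_adj <- f0_sd / shrink
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd_adj)
  z <- stats::rnorm(n, 0, sd_adj * sqrt(1 - rho^2))
  for (i in 2:n) e[i] <- rho * e[i - 1] + z[i]
  pmax(f0 + e, f0 / 2)
}

#' Synthesize a sustained vowel with known ground truth
#'
#' Glottal pulse train at `f0_hz` with slowly drifting per-cycle frequency
#' perturbation (marginal SD `f0_sd_hz`), per-cycle amplitude perturbation
#' (`amp_cv`), formant resonators, and additive noise scaled to the
#' requested harmonics-to-noise ratio.
#'
#' @param f0_hz Target mean fundamental frequency (Hz).
#' @param duration_s Duration in seconds.
#' @param f0_sd_hz Target SD of the frame-level F0 contour (Hz).
#' @param amp_cv Coefficient of variation of per-cycle amplitudes.
#' @param hnr_db Target harmonics-to-noise ratio in dB.
#' @param formants List of `c(centre_hz, bandwidth_hz)` resonators.
#' @param task Vowel task label (`"vowel_a"`, `"vowel_i"`, `"vowel_u"`).
#' @param sample_rate Sampling rate in Hz.
#' @param seed RNG seed (mandatory; generation is fully deterministic).
#' @param subject_id,repetition Labels passed to the recording.
#' @return A list with `recording` (an `AudioRecording`) and `truth`
#'   (target parameters plus the exact per-cycle periods).
#' @export
synth_vowel <- function(f0_hz = 160, duration_s = 6, f0_sd_hz = 0,
                        amp_cv = 0, hnr_db = 30,
                        formants = list(c(800, 90), c(1300, 110),
                                        c(2500, 160)),
                        task = "vowel_a", sample_rate = 48000, seed,
                        subject_id = "synthetic", repetition = 1L) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.finite(hnr_db)) stop("hnr_db must be finite")
  with_seed(seed, {
    n_cyc <- ceiling(duration_s * f0_hz * 1.3) + 8L
    f0c <- .cycle_f0(n_cyc, f0_hz, f0_sd_hz)
    periods <- 1 / f0c
    cum <- cumsum(periods)
    keep <- seq_len(min(which(cum >= duration_s)))
    periods <- periods[keep]
    amps <- pmax(1 + amp_cv * stats::rnorm(length(periods)), 0.05)
    x <- .pulse_train(periods, amps, sample_rate)
    for (fm in formants) x <- .resonate(x, fm[1], fm[2], sample_rate)
    x <- x / max(abs(x))
    noise <- stats::rnorm(length(x))
    noise <- noise * sqrt(stats::var(x) / 10^(hnr_db / 10)) /
      stats::sd(noise)
    x <- x + noise
    x <- 0.9 * x / max(abs(x))
    list(
      recording = audio_recording(x, sample_rate, task = task,
                                  subject_id = subject_id,
                                  repetition = repetition),
      truth = list(f0_hz = f0_hz, f0_sd_hz = f0_sd_hz, amp_cv = amp_cv,
                   hnr_db = hnr_db, formants = formants,
                   cycle_periods_s = periods, duration_s = duration_s)
    )
  })
}

#' Synthesize a /pa/ diadochokinesis train
#'
#' Each syllable is a short high-band release burst (the /p/), a silent
#' voice-onset-time gap, then a Hann-shaped voiced vowel. Inter-syllable
#' periods and peak amplitudes are drawn with the requested coefficients of
#' variation; periods are renormalized so that exactly
#' `round(rate_hz * duration_s)` syllables fill the task duration.
#'
#' @param rate_hz Syllable rate (2-9 /s).
#' @param duration_s Task duration in seconds.
#' @param period_cv,intensity_cv CVs of inter-syllable periods and of peak
#'   amplitudes.
#' @param vot_ms Voice onset time(s) in ms; recycled over syllables.
#' @param f0_hz Vowel fundamental (Hz).
#' @inheritParams synth_vowel
#' @return A list with `recording` and `truth` (a data frame of true events
#'   with onset/peak/offset times, plus the schedule parameters).
#' @export
synth_ddk <- function(rate_hz = 5, duration_s = 7, period_cv = 0,
                      intensity_cv = 0, vot_ms = 15, f0_hz = 140,
                      sample_rate = 48000, seed,
                      subject_id = "synthetic", repetition = 1L) {
  if (missing(seed)) stop("seed is mandatory")
  if (rate_hz < 2 || rate_hz > 9) stop("rate_hz must be in [2, 9]")
  n <- round(rate_hz * duration_s)
  if (n < 3) stop("rate * duration must give at least 3 syllables")
  with_seed(seed, {
    periods <- stats::rnorm(n, 1 / rate_hz, period_cv / rate_hz)
    periods <- pmax(periods, 0.4 / rate_hz)
    periods <- periods * duration_s / sum(periods)
    amps <- pmax(1 + intensity_cv * stats::rnorm(n), 0.1)
    vots <- rep(vot_ms, length.out = n) / 1000
    onsets <- cumsum(c(0, periods[-n]))

    ns <- ceiling(duration_s * sample_rate)
    x <- numeric(ns)
    bf <- signal::butter(4, min(0.95, 3500 / (sample_rate / 2)),
                         type = "high")
    truth <- data.frame(onset_s = numeric(n), peak_s = numeric(n),
                        offset_s = numeric(n), amp = amps, vot_s = vots)
    for (i in seq_len(n)) {
      t0 <- onsets[i]
      burst_len <- round(0.006 * sample_rate)
      burst <- as.numeric(signal::filter(bf, stats::rnorm(burst_len)))
      burst <- 0.25 * amps[i] * burst / max(abs(burst))
      s <- round(t0 * sample_rate) + 1L
      e <- min(ns, s + burst_len - 1L)
      x[s:e] <- x[s:e] + burst[seq_len(e - s + 1L)]

      v0 <- t0 + vots[i]
      vdur <- min(0.12, 0.55 * periods[i])
      cyc <- rep(1 / f0_hz, ceiling(vdur * f0_hz) + 1L)
      vow <- .pulse_train(cyc, rep(1, length(cyc)), sample_rate)
      vow <- .resonate(vow, 700, 90, sample_rate)
      vow <- .resonate(vow, 1200, 110, sample_rate)
      nv <- min(length(vow), round(vdur * sample_rate))
      vow <- vow[seq_len(nv)] / max(abs(vow))
      # sharp 8 ms voicing attack (vocal folds reach amplitude quickly
      # after the release), then a cosine decay
      att <- min(nv - 1L, round(0.008 * sample_rate))
      env <- c(seq(0, 1, length.out = att),
               cos(pi / 2 * seq(0, 1, length.out = nv - att))^2)
      s <- round(v0 * sample_rate) + 1L
      e <- min(ns, s + nv - 1L)
      x[s:e] <- x[s:e] + amps[i] * (vow * env)[seq_len(e - s + 1L)]
      truth$onset_s[i] <- t0
      truth$peak_s[i] <- v0 + vdur / 2
      truth$offset_s[i] <- v0 + vdur
    }
    x <- 0.9 * x / max(abs(x)) + 1e-5 * stats::rnorm(ns)
    list(
      recording = audio_recording(x, sample_rate, task = "ddk_pa",
                                  subject_id = subject_id,
                                  repetition = repetition),
      truth = list(events = truth, rate_hz = rate_hz, periods_s = periods,
                   period_cv = period_cv, intensity_cv = intensity_cv,
                   vot_ms = rep(vot_ms, length.out = n),
                   duration_s = duration_s)
    )
  })
}

#' Synthesize a fast /i/-/u/ alternation
#'
#' A voiced carrier whose second-formant resonator sweeps sinusoidally
#' between `f2_high_hz` (/i/) and `f2_low_hz` (/u/) at `alternation_rate_hz`,
#' with per-cycle period perturbation `period_cv`. The first formant is held
#' at 320 Hz.
#'
#' @param alternation_rate_hz Alternation cycles per second.
#' @param f2_high_hz,f2_low_hz F2 targets at /i/ and /u/ (Hz).
#' @param period_cv CV of the per-cycle alternation periods.
#' @inheritParams synth_ddk
#' @return A list with `recording` and `truth` (cycle peak times and
#'   periods).
#' @export
synth_iu <- function(alternation_rate_hz = 5, duration_s = 5,
                     f2_high_hz = 2200, f2_low_hz = 800, period_cv = 0,
                     f0_hz = 130, sample_rate = 48000, seed,
                     subject_id = "synthetic", repetition = 1L) {
  if (missing(seed)) stop("seed is mandatory")
  if (f2_high_hz <= f2_low_hz) stop("f2_high_hz must exceed f2_low_hz")
  if (alternation_rate_hz <= 0) stop("alternation_rate_hz must be positive")
  with_seed(seed, {
    n_cyc <- ceiling(duration_s * alternation_rate_hz) + 1L
    T_c <- stats::rnorm(n_cyc, 1 / alternation_rate_hz,
                        period_cv / alternation_rate_hz)
    T_c <- pmax(T_c, 0.4 / alternation_rate_hz)
    ns <- ceiling(duration_s * sample_rate)
    t <- (seq_len(ns) - 1) / sample_rate
    # the drawn periods are the /i/-peak-to-peak intervals: peaks at
    # p_k = p_1 + sum(T), troughs midway; phase is piecewise linear
    # through those knots (peak k has phase k - 0.5, trough k has phase k)
    peaks_t <- cumsum(c(0.5 * T_c[1], T_c[-1]))
    troughs_t <- c(0, (peaks_t[-length(peaks_t)] + peaks_t[-1]) / 2)
    knots_t <- as.vector(rbind(troughs_t, peaks_t))
    knots_ph <- as.vector(rbind(seq_along(troughs_t) - 1,
                                seq_along(peaks_t) - 0.5))
    phase <- stats::approx(knots_t, knots_ph, xout = t, rule = 2)$y
    mid <- (f2_high_hz + f2_low_hz) / 2
    amp <- (f2_high_hz - f2_low_hz) / 2
    # mildly saturated cosine: the articulators approach and hold each
    # vowel target, so F2 flattens near the targets; phase starts at a
    # trough (/u/) so every /i/ peak is interior
    f2_t <- mid + amp * tanh(2 * cos(2 * pi * (phase - 0.5))) / tanh(2)

    src <- .pulse_train(rep(1 / f0_hz, ceiling(duration_s * f0_hz) + 1L),
                        rep(1, ceiling(duration_s * f0_hz) + 1L),
                        sample_rate)
    src <- src[seq_len(ns)]
    src <- .resonate(src, 320, 80, sample_rate)
    # time-varying second-formant resonator, sample by sample
    r <- exp(-pi * 120 / sample_rate)
    thv <- 2 * pi * f2_t / sample_rate
    a1 <- 2 * r * cos(thv)
    a2 <- -r^2
    b0 <- 1 - a1 + r^2
    y <- numeric(ns)
    y1 <- 0; y2 <- 0
    for (i in seq_len(ns)) {
      yi <- b0[i] * src[i] + a1[i] * y1 + a2 * y2
      y2 <- y1; y1 <- yi
      y[i] <- yi
    }
    y <- 0.9 * y / max(abs(y)) + 1e-4 * stats::rnorm(ns)
    peak_times <- peaks_t[peaks_t < duration_s]
    list(
      recording = audio_recording(y, sample_rate, task = "iu_alternation",
                                  subject_id = subject_id,
                                  repetition = repetition),
      truth = list(peak_times_s = peak_times, periods_s = T_c,
                   rate_hz = alternation_rate_hz, f2_high_hz = f2_high_hz,
                   f2_low_hz = f2_low_hz, period_cv = period_cv)
    )
  })
}

#' Synthesize a passage-reading proxy
#'
#' `n_syllables` contiguous voiced syllables (per-syllable F0 drawn around
#' `f0_hz` with SD `f0_sd_hz`), with the listed silent pauses inserted at
#' evenly spaced points between syllables. Ground truth carries the exact
#' pause intervals and the net speech time.
#'
#' @param n_syllables Number of syllables (Chinese characters) read.
#' @param syllable_s Duration of one syllable in seconds.
#' @param pause_ms Numeric vector of pause durations to insert (ms).
#' @param f0_hz,f0_sd_hz Per-syllable F0 mean and SD (Hz).
#' @inheritParams synth_ddk
#' @return A list with `recording` and `truth` (pause table, net time,
#'   total duration, true net syllable rate).
#' @export
synth_passage <- function(n_syllables = 105, syllable_s = 0.2,
                          pause_ms = c(200, 300, 250, 400, 150, 350),
                          f0_hz = 150, f0_sd_hz = 30,
                          sample_rate = 48000, seed,
                          subject_id = "synthetic", repetition = 1L) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_syllables < 1) stop("n_syllables must be >= 1")
  if (any(pause_ms < 0)) stop("pause durations must be >= 0")
  with_seed(seed, {
    pauses <- pause_ms / 1000
    n_p <- length(pauses)
    # pause k goes after syllable floor(k * n / (P + 1))
    after <- if (n_p > 0) {
      pmax(1, floor(seq_len(n_p) * n_syllables / (n_p + 1)))
    } else integer(0)
    f0s <- pmax(stats::rnorm(n_syllables, f0_hz, f0_sd_hz), 70)
    total <- n_syllables * syllable_s + sum(pauses)
    ns <- ceiling(total * sample_rate) + 1L
    x <- numeric(ns)
    t_cursor <- 0
    pause_tab <- data.frame(start_s = numeric(0), end_s = numeric(0))
    for (i in seq_len(n_syllables)) {
      cyc <- rep(1 / f0s[i], ceiling(syllable_s * f0s[i]) + 1L)
      syl <- .pulse_train(cyc, rep(1, length(cyc)), sample_rate)
      syl <- .resonate(syl, 600, 90, sample_rate)
      syl <- .resonate(syl, 1200, 120, sample_rate)
      nv <- min(length(syl), round(syllable_s * sample_rate))
      syl <- syl[seq_len(nv)] / max(abs(syl))
      env <- 0.25 + 0.75 * sin(pi * seq(0, 1, length.out = nv))^2
      s <- round(t_cursor * sample_rate) + 1L
      e <- min(ns, s + nv - 1L)
      x[s:e] <- x[s:e] + (syl * env)[seq_len(e - s + 1L)]
      t_cursor <- t_cursor + syllable_s
      hit <- which(after == i)
      for (k in hit) {
        pause_tab <- rbind(pause_tab,
                           data.frame(start_s = t_cursor,
                                      end_s = t_cursor + pauses[k]))
        t_cursor <- t_cursor + pauses[k]
      }
    }
    x <- 0.9 * x / max(abs(x)) + 2e-5 * stats::rnorm(ns)
    net <- n_syllables * syllable_s
    list(
      recording = audio_recording(x, sample_rate, task = "passage",
                                  subject_id = subject_id,
                                  repetition = repetition),
      truth = list(pauses = pause_tab, net_speech_s = net,
                   total_s = total, nsr = n_syllables / net,
                   f0_hz = f0_hz, f0_sd_hz = f0_sd_hz,
                   syllable_f0_hz = f0s, n_syllables = n_syllables)
    )
  })
}

#' Reference cohort feature parameters
#'
#' The bundled preset of per-feature group summary statistics (HC and PD
#' means and SDs for all 29 acoustic features) from a published
#' Mandarin-speaking PD/HC cohort, used to parameterize [synth_cohort()].
#'
#' @return A tibble with columns `feature`, `hc_mean`, `hc_sd`, `pd_mean`,
#'   `pd_sd`.
#' @export
cohort_reference_params <- function() {
  path <- system.file("extdata", "cohort_reference_params.csv",
                      package = "pdspeech", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The 29 acoustic feature names
#' @return Character vector of feature column names.
#' @export
acoustic_feature_names <- function() {
  cohort_reference_params()$feature
}

#' The six preset classification features
#'
#' The representative feature subset used for PD/HC classification:
#' diadochokinetic rate, net syllable rate, pause duration, F0 instability,
#' F2 alternation regularity, and vowel space area.
#' @return Character vector of six feature names.
#' @export
selected_feature_preset <- function() {
  c("DDKavr", "NSR", "DPI", "F0std", "F2reg", "VowelArea")
}

# draw from a normal clamped to a range
.rnorm_rng <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Synthesize a tabular PD/HC cohort
#'
#' Independent Gaussian feature draws per group at the given per-feature
#' parameters (default: the bundled reference preset), plus demographic
#' covariates and clinical scores drawn from the reference cohort's
#' reported ranges. Features are independent by construction; real acoustic
#' features are correlated, so classifier performance on these tables is a
#' lower bound, not an equality.
#'
#' @param n_hc,n_pd Group sizes.
#' @param params Per-feature parameter tibble as in
#'   [cohort_reference_params()].
#' @param seed RNG seed (mandatory).
#' @return A `CohortTable` tibble: one row per subject with metadata,
#'   clinical scores (PD only) and the 29 feature columns.
#' @export
synth_cohort <- function(n_hc = 40, n_pd = 80,
                         params = cohort_reference_params(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(c("feature", "hc_mean", "hc_sd", "pd_mean", "pd_sd") %in%
                  names(params)))
  if (n_hc < 2 || n_pd < 2) stop("group sizes must be >= 2")
  if (any(params$hc_sd < 0) || any(params$pd_sd < 0)) {
    stop("feature SDs must be >= 0")
  }
  with_seed(seed, {
    n <- n_hc + n_pd
    grp <- c(rep("HC", n_hc), rep("PD", n_pd))
    sex <- c(sample(rep(c("M", "F"), length.out = n_hc)),
             sample(rep(c("M", "F"), c(round(0.56 * n_pd),
                                       n_pd - round(0.56 * n_pd)))))
    tab <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = grp,
      sex = sex,
      age = round(c(.rnorm_rng(n_hc, 60.7, 8.1, 45, 77),
                    .rnorm_rng(n_pd, 62.3, 8.9, 44, 80)), 1),
      height = round(c(.rnorm_rng(n_hc, 164.2, 7.1, 150, 182),
                       .rnorm_rng(n_pd, 166.3, 7.9, 150, 185)), 1),
      weight = round(c(.rnorm_rng(n_hc, 67.7, 10.0, 48, 88),
                       .rnorm_rng(n_pd, 66.4, 11.7, 45, 96)), 1),
      MoCA = round(c(.rnorm_rng(n_hc, 25.7, 1.3, 24, 29),
                     .rnorm_rng(n_pd, 23.7, 3.7, 16, 30))),
      handedness = sample(c("R", "L"), n, replace = TRUE,
                          prob = c(0.92, 0.08)),
      HY_stage = c(rep(NA_real_, n_hc),
                   sample(c(1.5, 2, 2.5, 3, 4, 5), n_pd, replace = TRUE,
                          prob = c(0.10, 0.20, 0.25, 0.30, 0.10, 0.05))),
      UPDRS_III = c(rep(NA_real_, n_hc),
                    round(.rnorm_rng(n_pd, 45.6, 18.0, 10, 91))),
      UPDRS_speech = c(rep(NA_real_, n_hc),
                       round(.rnorm_rng(n_pd, 1.1, 0.8, 0, 3))),
      UPDRS_bradykinesia = c(rep(NA_real_, n_hc),
                             round(.rnorm_rng(n_pd, 16, 6, 2, 36))),
      UPDRS_tremor = c(rep(NA_real_, n_hc),
                       round(.rnorm_rng(n_pd, 5, 3.5, 0, 20)))
    )
    for (k in seq_len(nrow(params))) {
      f <- params$feature[k]
      tab[[f]] <- c(stats::rnorm(n_hc, params$hc_mean[k], params$hc_sd[k]),
                    stats::rnorm(n_pd, params$pd_mean[k], params$pd_sd[k]))
    }
    tab
  })
}

#' Synthesize block-structured node time series
#'
#' Latent block signals plus independent noise: nodes in the same block are
#' correlated by construction, so [build_fcn()] on the output shows higher
#' within- than between-block connectivity.
#'
#' @param n_nodes,n_timepoints Matrix dimensions.
#' @param n_blocks Number of latent blocks.
#' @param noise_sd Independent noise SD (latent signals have unit SD).
#' @param seed RNG seed (mandatory).
#' @return A list with `ts` (`n_nodes x n_timepoints` matrix) and `blocks`
#'   (block label per node).
#' @export
synth_network <- function(n_nodes = 90, n_timepoints = 200, n_blocks = 4,
                          noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_nodes < 2 || n_timepoints < 10) {
    stop("need n_nodes >= 2 and n_timepoints >= 10")
  }
  with_seed(seed, {
    blocks <- rep(seq_len(n_blocks), length.out = n_nodes)
    latent <- matrix(stats::rnorm(n_blocks * n_timepoints), n_blocks)
    ts <- latent[blocks, , drop = FALSE] +
      noise_sd * matrix(stats::rnorm(n_nodes * n_timepoints), n_nodes)
    rownames(ts) <- sprintf("node%02d", seq_len(n_nodes))
    list(ts = ts, blocks = blocks)
  })
}
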
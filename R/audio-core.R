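#' Construct an AudioRecording
#'
#' The basic container for a mono speech waveform. Samples are amplitude
#' values on `[-1, 1]`; every paradigm analysis in the package starts from
#' one of these.
#'
#' @param samples Numeric vector of finite samples.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param task One of `"vowel_a"`, `"vowel_i"`, `"vowel_u"`, `"ddk_pa"`,
#'   `"iu_alternation"`, `"passage"`.
#' @param subject_id Opaque subject identifier.
#' @param repetition Positive integer repetition index.
#' @return An object of class `AudioRecording`.
#' @export
audio_recording <- function(samples, sample_rate, task = "vowel_a",
                            subject_id = "unknown", repetition = 1L) {
  task <- match.arg(task, c("vowel_a", "vowel_i", "vowel_u", "ddk_pa",
                            "iu_alternation", "passage"))
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("empty audio: length must be >= 1")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, task = task,
         subject_id = as.character(subject_id),
         repetition = as.integer(repetition)),
    class = "AudioRecording"
  )
}

#' @export
print.AudioRecording <- function(x, ...) {
  cat(sprintf("<AudioRecording> %s / %s rep %d: %.2f s @ %d Hz\n",
              x$subject_id, x$task, x$repetition,
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `AudioRecording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Construct a FrameTrack
#'
#' A time-aligned sequence of frame-level measurements (F0 in Hz, intensity
#' in dB, envelope amplitude, formants in Hz) on a uniform hop grid. Frames
#' flagged unvoiced carry `NA` values, never a spurious Hz value.
#'
#' @param times Frame centre times in seconds (strictly increasing).
#' @param values Per-frame measurements (`NA` where undefined/unvoiced).
#' @param voiced Logical per-frame voicing flags.
#' @param frame_length Analysis window length in seconds.
#' @param hop Hop between frame centres in seconds.
#' @return An object of class `FrameTrack`.
#' @export
frame_track <- function(times, values, voiced, frame_length, hop) {
  stopifnot(length(times) == length(values),
            length(times) == length(voiced),
            hop > 0, frame_length > 0)
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         voiced = as.logical(voiced), frame_length = frame_length, hop = hop),
    class = "FrameTrack"
  )
}

#' @export
print.FrameTrack <- function(x, ...) {
  cat(sprintf("<FrameTrack> %d frames, hop %.0f ms, %.0f%% voiced\n",
              length(x$times), 1000 * x$hop,
              100 * mean(x$voiced, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.FrameTrack <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, voiced = x$voiced)
}

#' Write a FrameTrack as tidy CSV
#' @param track A `FrameTrack`.
#' @param path Output CSV path (columns `time_s`, `value`, `voiced`).
#' @return `path`, invisibly.
#' @export
write_frame_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

# frame start indices for an n-sample signal
frame_starts <- function(n, flen, fhop) {
  if (n < flen) return(integer(0))
  seq(1L, n - flen + 1L, by = fhop)
}

#' Resample a recording
#'
#' Band-limited polyphase resampling (via the `signal` package). Duration is
#' preserved to within one sample period.
#'
#' @param rec An `AudioRecording`.
#' @param target_rate Target sampling rate in Hz.
#' @return A resampled `AudioRecording`.
#' @export
resample_audio <- function(rec, target_rate) {
  stopifnot(inherits(rec, "AudioRecording"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive")
  }
  if (target_rate == rec$sample_rate) return(rec)
  y <- .resample_vec(rec$samples, rec$sample_rate, target_rate)
  audio_recording(pmin(1, pmax(-1, y)), target_rate, task = rec$task,
                  subject_id = rec$subject_id, repetition = rec$repetition)
}

# zero-phase band-limited resampling in the frequency domain: copy the
# shared low-frequency bins, drop (or zero-pad) the rest
.resample_vec <- function(x, from_rate, to_rate) {
  n <- length(x)
  n_target <- round(n * to_rate / from_rate)
  np <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(np - n))
  mp <- max(2L, round(np * to_rate / from_rate))
  if (mp %% 2 == 1) mp <- mp + 1L
  X <- stats::fft(xp)
  k <- min(np, mp) %/% 2
  Y <- complex(mp)
  Y[1] <- X[1]
  Y[2:k] <- X[2:k]
  Y[mp - (2:k) + 2] <- X[np - (2:k) + 2]
  y <- Re(stats::fft(Y, inverse = TRUE)) / np
  y <- y[seq_len(min(n_target, length(y)))]
  if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  y
}

# analytic-signal magnitude via the FFT (zero-padded to a highly
# composite length; a prime-length FFT in base R is quadratic)
.hilbert_env <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Amplitude envelope of a recording
#'
#' Analytic-signal magnitude low-pass filtered so that no energy remains at
#' periods shorter than `smooth_ms`, sampled on a 1 ms hop grid. This is the
#' front end of diadochokinesis syllable detection.
#'
#' @param rec An `AudioRecording`.
#' @param smooth_ms Smoothing window in milliseconds (default 20 ms keeps
#'   syllable trains up to ~7 syll/s resolved).
#' @return A `FrameTrack` of non-negative envelope amplitudes.
#' @export
amplitude_envelope <- function(rec, smooth_ms = 20) {
  stopifnot(inherits(rec, "AudioRecording"))
  if (smooth_ms <= 0) stop("smooth_ms must be positive")
  if (length(rec$samples) < 8) stop("empty or too-short input")
  env <- .hilbert_env(rec$samples)
  fc <- 1000 / smooth_ms
  ny <- rec$sample_rate / 2
  if (fc < ny) {
    bf <- signal::butter(4, fc / ny, type = "low")
    env <- signal::filtfilt(bf, env)
  }
  env <- pmax(env, 0)
  hop_n <- max(1L, round(rec$sample_rate / 1000))
  idx <- seq(1L, length(env), by = hop_n)
  frame_track(times = (idx - 1) / rec$sample_rate, values = env[idx],
              voiced = rep(NA, length(idx)),
              frame_length = smooth_ms / 1000, hop = hop_n / rec$sample_rate)
}

# Shared autocorrelation pitch analysis.
# Returns per-frame time, best normalized ACF peak height, F0 candidate,
# RMS, and voicing decision. The peak height doubles as the periodicity
# strength used by hnr().
.pitch_analysis <- function(rec, f0_min = 75, f0_max = 400,
                            frame_length = 0.04, hop = 0.01,
                            voicing_threshold = 0.45) {
  stopifnot(inherits(rec, "AudioRecording"))
  sr <- rec$sample_rate
  if (!(f0_min > 0 && f0_min < f0_max && f0_max < sr / 2)) {
    stop("impossible F0 search range for this sample rate")
  }
  flen <- round(frame_length * sr)
  fhop <- max(1L, round(hop * sr))
  x <- rec$samples
  starts <- frame_starts(length(x), flen, fhop)
  if (length(starts) == 0) {
    return(list(times = numeric(0), f0 = numeric(0), strength = numeric(0),
                rms = numeric(0), voiced = logical(0),
                frame_length = frame_length, hop = fhop / sr))
  }
  frames <- vapply(starts, function(s) x[s:(s + flen - 1L)], numeric(flen))
  frames <- sweep(frames, 2, colMeans(frames))
  rms <- sqrt(colMeans(frames^2))

  nfft <- 2^ceiling(log2(2 * flen))
  padded <- rbind(frames, matrix(0, nfft - flen, ncol(frames)))
  P <- Mod(stats::mvfft(padded))^2
  A <- Re(stats::mvfft(P, inverse = TRUE)) / nfft

  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- min(flen - 2L, ceiling(sr / f0_min))
  rms_gate <- max(max(rms) * 10^(-45 / 20), 1e-7)

  nfr <- ncol(frames)
  f0 <- rep(NA_real_, nfr)
  strength <- numeric(nfr)
  for (j in seq_len(nfr)) {
    r0 <- A[1, j]
    if (r0 <= 0 || rms[j] < rms_gate) next
    lags <- lag_min:lag_max
    # exact normalized cross-correlation: the FFT term holds the raw
    # lagged product; the energies of the two overlapping segments come
    # from cumulative sums
    c2 <- cumsum(frames[, j]^2)
    E <- c2[flen]
    den <- sqrt(c2[flen - lags] * (E - c2[lags]))
    rn <- A[lags + 1L, j] / pmax(den, 1e-12)
    # candidate = local maxima; prefer the shortest lag among near-best
    # peaks to avoid octave-down errors
    nl <- length(rn)
    cand <- which(rn[2:(nl - 1)] > rn[1:(nl - 2)] &
                    rn[2:(nl - 1)] >= rn[3:nl]) + 1L
    if (length(cand) == 0) cand <- which.max(rn)
    best <- max(rn[cand])
    k <- min(cand[rn[cand] >= 0.97 * best])
    pk <- rn[k]
    # parabolic refinement of the peak lag
    lag_hat <- lags[k]
    if (k > 1 && k < length(lags)) {
      y1 <- rn[k - 1]; y2 <- rn[k]; y3 <- rn[k + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) {
        d <- 0.5 * (y1 - y3) / den
        d <- max(-0.5, min(0.5, d))
        lag_hat <- lags[k] + d
        pk <- y2 - 0.25 * (y1 - y3) * d
      }
    }
    strength[j] <- min(pk, 1)
    f0[j] <- sr / lag_hat
  }
  # octave-correction pass: frames whose estimate sits near a sub- or
  # super-harmonic of the voiced median are re-picked near the median lag
  prelim <- !is.na(f0) & strength >= voicing_threshold & rms >= rms_gate
  if (sum(prelim) >= 5) {
    med <- stats::median(f0[prelim])
    ratio <- med / f0
    # only genuine harmonic confusions (x2 or x3 off the median), so
    # legitimately variable pitch is left alone
    flagged <- which(prelim & ((ratio > 1.8 & ratio < 2.2) |
                                 (ratio > 2.7 & ratio < 3.3) |
                                 (1 / ratio > 1.8 & 1 / ratio < 2.2)))
    lo <- max(lag_min, floor(sr / (1.3 * med)))
    hi <- min(lag_max, ceiling(sr / (0.75 * med)))
    for (j in flagged) {
      if (hi - lo < 3) next
      c2 <- cumsum(frames[, j]^2)
      E <- c2[flen]
      lags2 <- lo:hi
      den <- sqrt(c2[flen - lags2] * (E - c2[lags2]))
      rn2 <- A[lags2 + 1L, j] / pmax(den, 1e-12)
      k2 <- which.max(rn2)
      if (rn2[k2] >= 0.85 * strength[j] && k2 > 1 && k2 < length(lags2)) {
        y1 <- rn2[k2 - 1]; y2 <- rn2[k2]; y3 <- rn2[k2 + 1]
        den2 <- y1 - 2 * y2 + y3
        d <- if (abs(den2) > 1e-12) {
          max(-0.5, min(0.5, 0.5 * (y1 - y3) / den2))
        } else 0
        f0[j] <- sr / (lags2[k2] + d)
        strength[j] <- min(max(rn2[k2], strength[j] * 0.999), 1)
      }
    }
  }
  voiced <- !is.na(f0) & strength >= voicing_threshold &
    f0 >= f0_min & f0 <= f0_max & rms >= rms_gate
  f0[!voiced] <- NA_real_
  list(times = (starts - 1) / sr + frame_length / 2, f0 = f0,
       strength = strength, rms = rms, voiced = voiced,
       frame_length = frame_length, hop = fhop / sr)
}

#' Track fundamental frequency
#'
#' Frame-wise normalized-autocorrelation pitch tracking with parabolic peak
#' interpolation. Frames whose periodicity strength falls below
#' `voicing_threshold` (or whose energy is negligible) are flagged unvoiced
#' and carry `NA`.
#'
#' @inheritParams amplitude_envelope
#' @param f0_min,f0_max F0 search range in Hz (defaults 75-400, adult
#'   speech; override per recording when needed).
#' @param frame_length,hop Analysis frame and hop in seconds.
#' @param voicing_threshold Minimum normalized autocorrelation peak height
#'   for a frame to count as voiced.
#' @return A `FrameTrack` of F0 values in Hz.
#' @export
track_f0 <- function(rec, f0_min = 75, f0_max = 400, frame_length = 0.04,
                     hop = 0.01, voicing_threshold = 0.45) {
  pa <- .pitch_analysis(rec, f0_min, f0_max, frame_length, hop,
                        voicing_threshold)
  frame_track(pa$times, pa$f0, pa$voiced, pa$frame_length, pa$hop)
}

#' Frame-wise intensity contour
#'
#' Per-frame RMS level in dB relative to digital full scale (dBFS): a
#' full-scale square wave reads 0 dBFS, and doubling the amplitude adds
#' 6.02 dB.
#'
#' @inheritParams track_f0
#' @return A `FrameTrack` of dBFS values.
#' @export
intensity_contour <- function(rec, frame_length = 0.04, hop = 0.01) {
  stopifnot(inherits(rec, "AudioRecording"))
  sr <- rec$sample_rate
  flen <- round(frame_length * sr)
  fhop <- max(1L, round(hop * sr))
  starts <- frame_starts(length(rec$samples), flen, fhop)
  if (length(starts) == 0) stop("recording shorter than one frame")
  rms <- vapply(starts, function(s) {
    sqrt(mean(rec$samples[s:(s + flen - 1L)]^2))
  }, numeric(1))
  db <- 20 * log10(pmax(rms, 1e-7))
  frame_track((starts - 1) / sr + frame_length / 2, db,
              rep(NA, length(db)), frame_length, fhop / sr)
}

#' LPC formant tracks
#'
#' Estimates formant frequencies from linear-predictive-coding polynomial
#' roots on a signal downsampled to ~11 kHz (LPC order `2 + rate/1000`,
#' the classic rule). Roots with bandwidth above `max_bandwidth_hz` are
#' rejected as spurious; frames with fewer resolvable resonances than
#' requested carry `NA`.
#'
#' @inheritParams track_f0
#' @param n_formants Number of formants to return (2-5).
#' @param max_bandwidth_hz Bandwidth cap for accepting a pole as a formant.
#' @return A list of `FrameTrack`s `F1`, `F2`, ... with ascending
#'   frequencies within each frame.
#' @export
lpc_formants <- function(rec, n_formants = 4, frame_length = 0.03,
                         hop = 0.01, max_bandwidth_hz = 400) {
  stopifnot(inherits(rec, "AudioRecording"))
  if (n_formants < 2 || n_formants > 5) stop("n_formants must be in [2, 5]")
  target <- 11000
  if (rec$sample_rate > target) rec <- resample_audio(rec, target)
  sr <- rec$sample_rate
  # first-order pre-emphasis flattens the glottal spectral tilt
  x <- rec$samples - 0.97 * c(0, rec$samples[-length(rec$samples)])
  flen <- round(frame_length * sr)
  fhop <- max(1L, round(hop * sr))
  starts <- frame_starts(length(x), flen, fhop)
  if (length(starts) < 2) stop("input too short for formant analysis")
  p <- 2 + round(sr / 1000)
  win <- signal::hamming(flen)
  rms_all <- vapply(starts, function(s) sqrt(mean(x[s:(s + flen - 1L)]^2)),
                    numeric(1))
  gate <- max(rms_all) * 10^(-45 / 20)

  out <- matrix(NA_real_, nrow = length(starts), ncol = n_formants)
  for (j in seq_along(starts)) {
    if (rms_all[j] < gate) next
    fr <- x[starts[j]:(starts[j] + flen - 1L)] * win
    ac <- stats::acf(fr, lag.max = p, plot = FALSE, demean = FALSE,
                     type = "covariance")$acf[, 1, 1]
    a <- tryCatch(signal::levinson(ac, p)$a, error = function(e) NULL)
    if (is.null(a) || any(!is.finite(a))) next
    z <- polyroot(rev(a))
    ang <- Arg(z)
    keep <- ang > 0 & ang < pi
    f <- ang[keep] * sr / (2 * pi)
    bw <- -log(pmin(Mod(z[keep]), 0.99999)) * sr / pi
    ok <- f > 90 & f < sr / 2 - 90 & bw < max_bandwidth_hz
    f <- sort(f[ok])
    if (length(f) >= 1) {
      out[j, seq_len(min(length(f), n_formants))] <-
        f[seq_len(min(length(f), n_formants))]
    }
  }
  times <- (starts - 1) / sr + frame_length / 2
  lapply(seq_len(n_formants), function(k) {
    frame_track(times, out[, k], !is.na(out[, k]), frame_length, fhop / sr)
  })
}

#' Voiced segments of an F0 track
#'
#' Maximal runs of voiced frames as half-open time intervals; unvoiced gaps
#' shorter than `bridge_ms` are merged across (tracking dropouts).
#'
#' @param f0 A `FrameTrack` from [track_f0()].
#' @param bridge_ms Maximum gap (ms) to bridge between voiced runs.
#' @return A data frame with columns `start_s`, `end_s`.
#' @export
voicing_segments <- function(f0, bridge_ms = 50) {
  stopifnot(inherits(f0, "FrameTrack"))
  v <- f0$voiced & !is.na(f0$voiced)
  if (!any(v)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  startsI <- ends - r$lengths + 1L
  seg <- data.frame(
    start_s = f0$times[startsI[r$values]] - f0$hop / 2,
    end_s = f0$times[ends[r$values]] + f0$hop / 2
  )
  seg$start_s <- pmax(seg$start_s, 0)
  if (nrow(seg) > 1) {
    merged <- seg[1, ]
    for (i in 2:nrow(seg)) {
      if ((seg$start_s[i] - merged$end_s[nrow(merged)]) * 1000 <= bridge_ms) {
        merged$end_s[nrow(merged)] <- seg$end_s[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  rownames(seg) <- NULL
  seg
}

#' Harmonics-to-noise ratio
#'
#' Mean over voiced frames of `10*log10(r / (1 - r))`, where `r` is the
#' normalized autocorrelation peak at the pitch period — the standard
#' periodic-to-aperiodic energy ratio in dB.
#'
#' @inheritParams track_f0
#' @return HNR in dB (scalar).
#' @export
hnr <- function(rec, f0_min = 75, f0_max = 400, frame_length = 0.04,
                hop = 0.01, voicing_threshold = 0.45) {
  pa <- .pitch_analysis(rec, f0_min, f0_max, frame_length, hop,
                        voicing_threshold)
  if (!any(pa$voiced)) stop("no voiced frames: HNR not computable")
  r <- pmin(pmax(pa$strength[pa$voiced], 1e-6), 1 - 1e-6)
  mean(10 * log10(r / (1 - r)))
}

# Trim leading/trailing silence, returning the sample index range of the
# active region (envelope above threshold_db re its maximum).
.active_range <- function(rec, threshold_db = -40) {
  env <- .hilbert_env(rec$samples)
  # light smoothing (5 ms moving average) to ignore single-sample spikes
  k <- max(1L, round(rec$sample_rate * 0.005))
  env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  thr <- max(env) * 10^(threshold_db / 20)
  idx <- which(env >= thr)
  if (length(idx) == 0) return(c(1L, length(rec$samples)))
  c(idx[1], idx[length(idx)])
}

#' Trim leading and trailing silence
#'
#' @param rec An `AudioRecording`.
#' @param threshold_db Activity threshold in dB relative to the envelope
#'   maximum.
#' @return A trimmed `AudioRecording`.
#' @export
trim_silence <- function(rec, threshold_db = -40) {
  rng <- .active_range(rec, threshold_db)
  audio_recording(rec$samples[rng[1]:rng[2]], rec$sample_rate,
                  task = rec$task, subject_id = rec$subject_id,
                  repetition = rec$repetition)
}
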
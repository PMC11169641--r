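# Sustained-vowel analysis: F0 and amplitude statistics, maximum phonation
# time, HNR, per-vowel formants, and the vowel space area.

#' Sustained-vowel phonation features
#'
#' All statistics are computed over voiced frames only. `F0`/`F0std` are
#' the mean and SD of the tracked F0 contour; `vF0 = 100*F0std/F0`.
#' `Ampstd` is the SD of the frame intensity in dB; `vAmp` is the CV (%)
#' of the linear frame RMS amplitudes (a percentage of dB values would be
#' ill-defined). `MPT` is the duration of the longest voiced segment, so
#' leading/trailing silence cannot inflate it. `F1`/`F2` are median LPC
#' formants over voiced frames, feeding [vowel_space_area()].
#'
#' @inheritParams track_f0
#' @param min_voiced_s Minimum total voiced duration required (s).
#' @return A named list: `F0`, `F0std`, `vF0`, `Ampstd`, `vAmp`, `MPT`,
#'   `HNR`, `F1`, `F2`.
#' @export
phonation_features <- function(rec, f0_min = 75, f0_max = 400,
                               min_voiced_s = 0.5) {
  stopifnot(inherits(rec, "AudioRecording"))
  f0 <- track_f0(rec, f0_min, f0_max)
  v <- f0$voiced
  if (sum(v) * f0$hop < min_voiced_s) {
    stop("insufficient phonation: less than ", min_voiced_s,
         " s of voiced signal")
  }
  f0v <- f0$values[v]
  f0_mean <- mean(f0v)
  f0_sd <- stats::sd(f0v)

  # amplitude via the smoothed envelope (amplitude within the pitch
  # cycles): frame RMS would ripple with the fractional cycle count.
  # Frames straddling a voicing onset/offset are excluded — they mix
  # phonation with silence.
  env <- amplitude_envelope(rec, smooth_ms = 20)
  nv <- length(v)
  v_interior <- v & c(FALSE, v[-nv]) & c(v[-1], FALSE)
  if (!any(v_interior)) v_interior <- v
  env_v <- stats::approx(env$times, env$values,
                         xout = f0$times[v_interior], rule = 2)$y
  env_v <- pmax(env_v, 1e-7)
  lin_v <- env_v
  db_v <- 20 * log10(env_v)

  segs <- voicing_segments(f0)
  mpt <- max(segs$end_s - segs$start_s)

  fm <- lpc_formants(rec, n_formants = 3)
  in_voiced <- function(tr) {
    ok <- rep(FALSE, length(tr$times))
    for (k in seq_len(nrow(segs))) {
      ok <- ok | (tr$times >= segs$start_s[k] & tr$times <= segs$end_s[k])
    }
    stats::median(tr$values[ok & tr$voiced], na.rm = TRUE)
  }
  list(
    F0 = f0_mean,
    F0std = f0_sd,
    vF0 = 100 * f0_sd / f0_mean,
    Ampstd = stats::sd(db_v),
    vAmp = 100 * stats::sd(lin_v) / mean(lin_v),
    MPT = mpt,
    HNR = hnr(rec, f0_min, f0_max),
    F1 = in_voiced(fm[[1]]),
    F2 = in_voiced(fm[[2]])
  )
}

#' Vowel space area from corner-vowel formants
#'
#' Area (Hz^2) of the F1-F2 triangle spanned by /a/, /i/ and /u/, by the
#' shoelace formula. Invariant to vertex ordering and to translation of all
#' vertices by a common offset; shrinks with articulatory undershoot.
#'
#' @param f1_a,f2_a,f1_i,f2_i,f1_u,f2_u First and second formants (Hz) of
#'   the three corner vowels.
#' @return Triangle area in Hz^2.
#' @export
vowel_space_area <- function(f1_a, f2_a, f1_i, f2_i, f1_u, f2_u) {
  vals <- c(f1_a, f2_a, f1_i, f2_i, f1_u, f2_u)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("formant values must be finite and non-negative")
  }
  0.5 * abs(f1_a * (f2_i - f2_u) + f1_i * (f2_u - f2_a) +
              f1_u * (f2_a - f2_i))
}
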
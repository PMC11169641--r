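# /pa/ diadochokinesis analysis: syllable event detection from the
# amplitude envelope and the eight DDK features plus voice onset time.

# amplitude -> dB re 2e-5 (speech-style convention: full scale ~ 94 dB)
.amp_to_db <- function(a) 20 * log10(pmax(a, 1e-7) / 2e-5)

# local maxima with topographic prominence (MATLAB findpeaks convention:
# the reference saddle extends to the signal end on sides without a higher
# peak)
.peaks_with_prominence <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0) {
    return(data.frame(index = integer(0), prominence = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    h <- v[i]
    hl <- which(v[seq_len(i - 1)] > h)
    lo <- if (length(hl)) max(hl) else 1L
    left_min <- min(v[lo:i])
    hr <- which(v[(i + 1):n] > h)
    hi <- if (length(hr)) i + min(hr) else n
    right_min <- min(v[i:hi])
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = cand, prominence = prom)
}

#' Detect syllable events in a DDK envelope
#'
#' Peak picking on the amplitude envelope with a prominence threshold
#' (fraction of the envelope maximum) and a minimum inter-peak period.
#' Onset and offset are placed where the envelope crosses half the peak's
#' prominence on each side (linear interpolation between samples).
#'
#' @param envelope A `FrameTrack` from [amplitude_envelope()] of a DDK
#'   recording.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   envelope maximum, in (0, 1).
#' @param min_period_ms Minimum spacing between retained peaks (ms).
#' @return A data frame of `SyllableEvent`s: `onset_s`, `peak_s`,
#'   `offset_s`, `peak_intensity_db`, `period_s` (`NA` for the last event).
#'   Empty (with a warning) when no peak passes the threshold.
#' @export
detect_syllables <- function(envelope, min_prominence = 0.25,
                             min_period_ms = 100) {
  stopifnot(inherits(envelope, "FrameTrack"))
  if (min_prominence <= 0 || min_prominence >= 1) {
    stop("min_prominence must be in (0, 1)")
  }
  if (min_period_ms <= 0) stop("min_period_ms must be positive")
  v <- envelope$values
  pk <- .peaks_with_prominence(v)
  # absolute floor keeps numerical ripple on digital silence from
  # registering as speech
  pk <- pk[pk$prominence >= min_prominence * max(v) &
             v[pk$index] > 1e-6, , drop = FALSE]
  if (nrow(pk) == 0) {
    warning("no syllable peaks found")
    return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), peak_intensity_db = numeric(0),
                      period_s = numeric(0)))
  }
  # greedy spacing enforcement, highest peaks first
  keep <- logical(nrow(pk))
  t_pk <- envelope$times[pk$index]
  for (o in order(-v[pk$index])) {
    if (!any(keep & abs(t_pk - t_pk[o]) * 1000 < min_period_ms)) {
      keep[o] <- TRUE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$index), , drop = FALSE]

  cross_time <- function(i, ref, dir) {
    # walk from peak i until envelope drops below ref; interpolate
    j <- i
    repeat {
      j2 <- j + dir
      if (j2 < 1 || j2 > length(v)) return(envelope$times[j])
      if (v[j2] < ref) {
        frac <- (v[j] - ref) / (v[j] - v[j2])
        return(envelope$times[j] +
                 frac * (envelope$times[j2] - envelope$times[j]))
      }
      j <- j2
    }
  }
  half <- v[pk$index] - 0.5 * pk$prominence
  ev <- data.frame(
    onset_s = mapply(cross_time, pk$index, half, -1L),
    peak_s = envelope$times[pk$index],
    offset_s = mapply(cross_time, pk$index, half, 1L),
    peak_intensity_db = .amp_to_db(v[pk$index])
  )
  ev$period_s <- c(diff(ev$peak_s), NA_real_)
  ev
}

#' DDK feature set from detected syllable events
#'
#' @param events Syllable event data frame from [detect_syllables()].
#' @param task_duration_s Analyzed (trimmed) task duration in seconds —
#'   the denominator of the DDK rate.
#' @return A named list: `DDKavr` (syll/s), `DDKavp` (ms, mean
#'   half-prominence syllable duration), `DDKsdp` (ms, SD of inter-peak
#'   periods), `DDKcvp` (%, `100*DDKsdp/DDKavp`), `DDKjit` (%, mean
#'   absolute consecutive-period difference over the mean period),
#'   `DDKsdi` (dB, SD of peak intensities), `DDKcvi` (%, CV of peak
#'   intensities).
#' @export
ddk_features <- function(events, task_duration_s) {
  if (nrow(events) < 3) {
    stop("insufficient events (< 3) for DDK dispersion features ",
         "(DDKsdp, DDKcvp, DDKjit, DDKsdi, DDKcvi)")
  }
  if (task_duration_s <= 0) stop("task_duration_s must be positive")
  periods <- events$period_s[!is.na(events$period_s)]
  dur_ms <- (events$offset_s - events$onset_s) * 1000
  avp <- mean(dur_ms)
  sdp <- stats::sd(periods) * 1000
  ints <- events$peak_intensity_db
  list(
    DDKavr = nrow(events) / task_duration_s,
    DDKavp = avp,
    DDKsdp = sdp,
    DDKcvp = 100 * sdp / avp,
    DDKjit = 100 * mean(abs(diff(periods))) / mean(periods),
    DDKsdi = stats::sd(ints),
    DDKcvi = 100 * stats::sd(ints) / mean(ints)
  )
}

#' Mean voice onset time over a DDK recording
#'
#' Per syllable, VOT is the interval from the release-burst onset (first
#' time high-band (> 3 kHz) energy rises 12 dB above the recording's
#' high-band noise floor inside the syllable window) to the voicing onset
#' (low-band energy rise confirmed by a voiced pitch frame in the
#' syllable). Returns the mean over syllables where both landmarks were
#' found.
#'
#' @param rec The DDK `AudioRecording`.
#' @param events Syllable events from [detect_syllables()].
#' @param rise_db Detection threshold above the noise floor (dB).
#' @return Mean VOT in milliseconds.
#' @export
measure_vot <- function(rec, events, rise_db = 12) {
  stopifnot(inherits(rec, "AudioRecording"))
  if (nrow(events) < 1) stop("no syllable events supplied")
  sr <- rec$sample_rate
  ny <- sr / 2
  hb <- signal::filtfilt(signal::butter(4, min(0.95, 3000 / ny), "high"),
                         rec$samples)
  lb <- signal::filtfilt(signal::butter(4, min(0.95, 1500 / ny), "low"),
                         rec$samples)
  flen <- max(2L, round(0.002 * sr))
  fhop <- max(1L, round(0.001 * sr))
  starts <- frame_starts(length(hb), flen, fhop)
  t_fr <- (starts - 1) / sr + flen / sr / 2
  band_db <- function(x) {
    20 * log10(pmax(vapply(starts, function(s) {
      sqrt(mean(x[s:(s + flen - 1L)]^2))
    }, numeric(1)), 1e-9))
  }
  hb_db <- band_db(hb)
  lb_db <- band_db(lb)
  hb_floor <- stats::quantile(hb_db, 0.1, names = FALSE)
  lb_floor <- stats::quantile(lb_db, 0.1, names = FALSE)

  f0 <- track_f0(rec)
  vots <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    w0 <- events$onset_s[i] - 0.06
    w1 <- events$peak_s[i]
    win <- which(t_fr >= w0 & t_fr <= w1)
    if (length(win) < 2) next
    b <- win[which(hb_db[win] > hb_floor + rise_db)]
    if (length(b) == 0) next
    burst_t <- t_fr[b[1]]
    after <- win[t_fr[win] > burst_t]
    # voicing threshold: well above the noise floor AND within 25 dB of
    # the syllable's own low-band peak, so burst leakage cannot trigger it
    lb_thr <- max(lb_floor + rise_db, max(lb_db[win]) - 25)
    vcross <- after[which(lb_db[after] > lb_thr)]
    if (length(vcross) == 0) next
    voice_t <- t_fr[vcross[1]]
    # require genuine voicing somewhere in the syllable
    has_voicing <- any(f0$voiced & f0$times >= w0 &
                         f0$times <= events$offset_s[i] + 0.05)
    if (!has_voicing) next
    vot <- (voice_t - burst_t) * 1000
    if (vot >= 0 && vot <= 150) vots[i] <- vot
  }
  if (all(is.na(vots))) {
    stop("VOT not computable: no syllable had both a burst and voicing")
  }
  mean(vots, na.rm = TRUE)
}
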
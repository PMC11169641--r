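# Passage-reading analysis: pause detection, pause/rate features, and
# running pitch and amplitude statistics.

#' Detect pauses in a passage recording
#'
#' A frame counts as pause when it is both unvoiced (no F0) and
#' non-consonant — broadband energy below `floor_db` relative to the
#' recording's speech level (90th percentile frame level). Consonants carry
#' broadband energy while true pauses (including respiration intervals) do
#' not, hence the energy test. Candidate intervals shorter than
#' `min_pause_ms` are discarded.
#'
#' @param rec A passage `AudioRecording`.
#' @param min_pause_ms Minimum pause duration in ms (default 30).
#' @param floor_db Energy floor relative to the speech level (dB).
#' @return A `PauseSet`: list with `pauses` (data frame `start_s`,
#'   `end_s`), and the configuration echoed for provenance.
#' @export
detect_pauses <- function(rec, min_pause_ms = 30, floor_db = -25) {
  stopifnot(inherits(rec, "AudioRecording"))
  dur <- rec_duration(rec)
  # both tests on a fine 10 ms / 5 ms grid so boundaries stay sharp:
  # broadband energy low (non-consonant) AND low-band (< 1 kHz) energy
  # low (no vocal-fold vibration)
  en <- intensity_contour(rec, frame_length = 0.01, hop = 0.005)
  lb <- signal::filtfilt(signal::butter(4, min(0.95,
                                               1000 / (rec$sample_rate / 2)),
                                        "low"), rec$samples)
  en_lb <- intensity_contour(audio_recording(pmax(pmin(lb, 1), -1),
                                             rec$sample_rate),
                             frame_length = 0.01, hop = 0.005)
  speech_level <- stats::quantile(en$values, 0.9, names = FALSE)
  voiced_level <- stats::quantile(en_lb$values, 0.9, names = FALSE)
  n_fr <- min(length(en$values), length(en_lb$values))
  is_pause <- (en$values[seq_len(n_fr)] < speech_level + floor_db) &
    (en_lb$values[seq_len(n_fr)] < voiced_level + floor_db)

  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(is_pause)) {
    r <- rle(is_pause)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    half <- en$frame_length / 2
    seg <- data.frame(
      start_s = pmax(0, en$times[starts[r$values]] - half),
      end_s = pmin(dur, en$times[ends[r$values]] + half)
    )
    # merge intervals that touch after the half-frame expansion
    if (nrow(seg) > 1) {
      merged <- seg[1, ]
      for (i in 2:nrow(seg)) {
        if (seg$start_s[i] <= merged$end_s[nrow(merged)]) {
          merged$end_s[nrow(merged)] <- seg$end_s[i]
        } else {
          merged <- rbind(merged, seg[i, ])
        }
      }
      seg <- merged
    }
    seg <- seg[(seg$end_s - seg$start_s) * 1000 >= min_pause_ms, ,
               drop = FALSE]
    rownames(seg) <- NULL
    out <- seg
  }
  structure(list(pauses = out, min_pause_ms = min_pause_ms,
                 floor_db = floor_db),
            class = "PauseSet")
}

#' @export
print.PauseSet <- function(x, ...) {
  cat(sprintf("<PauseSet> %d pauses (min %g ms)\n", nrow(x$pauses),
              x$min_pause_ms))
  invisible(x)
}

#' Write a PauseSet as CSV
#' @param pauses A `PauseSet`.
#' @param path Output path (columns `start_s`, `end_s`).
#' @return `path`, invisibly.
#' @export
write_pause_set <- function(pauses, path) {
  utils::write.csv(pauses$pauses, path, row.names = FALSE)
  invisible(path)
}

#' Passage-reading prosody features
#'
#' `TotalDur` is the recording duration after trimming leading/trailing
#' silence (so recorder start lag does not count as reading time). `NSR`
#' is `n_syllables` divided by the net speech time (total minus pauses).
#' `DPI` is the median pause duration in ms (`NA` when no pause). `rF0`,
#' `rSTD` and `rvF0` summarize the voiced F0 contour over the whole
#' passage; `rvAm` is the CV (%) of linear frame amplitudes over speech
#' (non-pause) frames.
#'
#' @param rec A passage `AudioRecording`.
#' @param pauses A `PauseSet` from [detect_pauses()].
#' @param n_syllables Number of syllables read (default 105, the standard
#'   weather-report passage).
#' @return A named list: `TotalDur`, `NSR`, `DPI`, `rF0`, `rSTD`, `rvF0`,
#'   `rvAm`.
#' @export
prosody_features <- function(rec, pauses, n_syllables = 105) {
  stopifnot(inherits(rec, "AudioRecording"), inherits(pauses, "PauseSet"))
  rng <- .active_range(rec)
  t0 <- (rng[1] - 1) / rec$sample_rate
  t1 <- rng[2] / rec$sample_rate
  total <- t1 - t0

  p <- pauses$pauses
  if (nrow(p) > 0) {
    s <- pmax(p$start_s, t0)
    e <- pmin(p$end_s, t1)
    ok <- e > s
    pause_dur <- (e - s)[ok]
  } else {
    pause_dur <- numeric(0)
  }
  net <- total - sum(pause_dur)
  if (net <= 0) stop("inconsistent input: net speech time <= 0")

  f0 <- track_f0(rec)
  f0v <- f0$values[f0$voiced]
  if (length(f0v) < 2) stop("insufficient voiced frames in passage")
  rf0 <- mean(f0v)
  rstd <- stats::sd(f0v)

  ic <- intensity_contour(rec)
  in_pause <- rep(FALSE, length(ic$times))
  if (nrow(p) > 0) {
    for (k in seq_len(nrow(p))) {
      in_pause <- in_pause | (ic$times >= p$start_s[k] &
                                ic$times <= p$end_s[k])
    }
  }
  speech <- !in_pause & ic$times >= t0 & ic$times <= t1
  lin <- 10^(ic$values[speech] / 20)

  list(
    TotalDur = total,
    NSR = n_syllables / net,
    DPI = if (length(pause_dur) > 0) {
      stats::median(pause_dur) * 1000
    } else NA_real_,
    rF0 = rf0,
    rSTD = rstd,
    rvF0 = 100 * rstd / rf0,
    rvAm = 100 * stats::sd(lin) / mean(lin)
  )
}
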
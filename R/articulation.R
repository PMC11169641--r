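# /i/-/u/ alternation analysis: F2 transition cycles and the six
# second-formant features.

#' Detect F2 alternation cycles
#'
#' The voiced F2 track is median-filtered (50 ms default) to suppress LPC
#' glitches, then local maxima (/i/ targets) and minima (/u/ targets) with
#' topographic prominence at least `prominence_hz` are extracted and forced
#' into a strictly alternating peak/trough sequence (of two same-type
#' neighbours, the more extreme wins).
#'
#' @param f2 A `FrameTrack` of second-formant values (Hz), e.g.
#'   `lpc_formants(rec, 3)[[2]]`.
#' @param prominence_hz Minimum peak/trough prominence in Hz.
#' @param median_ms Median smoothing window in ms.
#' @return A data frame of `F2Cycle`s: `peak_time_s`, `trough_time_s`,
#'   `f2_peak`, `f2_trough`, `cycle_period_s` (peak-to-peak, `NA` last).
#' @export
detect_f2_cycles <- function(f2, prominence_hz = 200, median_ms = 50) {
  stopifnot(inherits(f2, "FrameTrack"))
  v_idx <- which(f2$voiced & !is.na(f2$values))
  if (length(v_idx) < 5) stop("insufficient cycles: too few voiced frames")
  t <- f2$times[v_idx]
  x <- f2$values[v_idx]
  k <- max(3L, round(median_ms / 1000 / f2$hop))
  if (k %% 2 == 0) k <- k + 1L
  xs <- as.numeric(stats::runmed(x, k))

  pk <- .peaks_with_prominence(xs)
  tr <- .peaks_with_prominence(-xs)
  pk <- pk[pk$prominence >= prominence_hz, , drop = FALSE]
  tr <- tr[tr$prominence >= prominence_hz, , drop = FALSE]
  if (nrow(pk) < 2 || nrow(tr) < 1) {
    stop("insufficient cycles: fewer than 2 alternation cycles detected")
  }
  ext <- rbind(data.frame(i = pk$index, type = "peak"),
               data.frame(i = tr$index, type = "trough"))
  ext <- ext[order(ext$i), ]
  # collapse runs of the same type, keeping the most extreme
  keep <- integer(0)
  run_start <- 1
  for (j in seq_len(nrow(ext))) {
    last <- j == nrow(ext)
    if (last || ext$type[j + 1] != ext$type[j]) {
      run <- run_start:j
      best <- run[which.max(if (ext$type[j] == "peak") xs[ext$i[run]]
                            else -xs[ext$i[run]])]
      keep <- c(keep, best)
      run_start <- j + 1
    }
  }
  ext <- ext[keep, ]
  peaks <- ext$i[ext$type == "peak"]
  if (length(peaks) < 2) {
    stop("insufficient cycles: fewer than 2 alternation cycles detected")
  }
  cyc <- data.frame(peak_time_s = t[peaks], f2_peak = xs[peaks],
                    trough_time_s = NA_real_, f2_trough = NA_real_)
  troughs <- ext$i[ext$type == "trough"]
  for (j in seq_along(peaks)) {
    nxt <- troughs[troughs > peaks[j]]
    if (length(nxt) > 0) {
      cyc$trough_time_s[j] <- t[nxt[1]]
      cyc$f2_trough[j] <- xs[nxt[1]]
    }
  }
  cyc$cycle_period_s <- c(diff(cyc$peak_time_s), NA_real_)
  cyc
}

#' F2 alternation features
#'
#' `F2magn` is the mean peak-to-trough F2 excursion; `F2rate` the number of
#' cycles per second of voiced task time; `F2reg` the CV (%) of the cycle
#' periods — lower values indicate more regular alternation.
#' `F2aver`/`F2min`/`F2max` summarize the whole voiced F2 track.
#'
#' @param cycles Cycle table from [detect_f2_cycles()].
#' @param f2 The F2 `FrameTrack` the cycles came from.
#' @return A named list: `F2magn`, `F2rate`, `F2reg`, `F2aver`, `F2min`,
#'   `F2max`.
#' @export
articulation_features <- function(cycles, f2) {
  stopifnot(inherits(f2, "FrameTrack"))
  if (nrow(cycles) < 2) stop("insufficient cycles (< 2)")
  # voiced task duration as the span of voicing: isolated tracker
  # dropouts must not shrink the rate denominator
  vt <- f2$times[f2$voiced & !is.na(f2$values)]
  voiced_dur <- max(vt) - min(vt) + f2$hop
  periods <- cycles$cycle_period_s[!is.na(cycles$cycle_period_s)]
  excurs <- cycles$f2_peak - cycles$f2_trough
  vals <- f2$values[f2$voiced & !is.na(f2$values)]
  list(
    F2magn = mean(excurs, na.rm = TRUE),
    F2rate = nrow(cycles) / voiced_dur,
    F2reg = if (length(periods) >= 2) {
      100 * stats::sd(periods) / mean(periods)
    } else NA_real_,
    F2aver = mean(vals),
    F2min = min(vals),
    F2max = max(vals)
  )
}
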
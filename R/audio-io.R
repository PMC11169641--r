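#' Read a RIFF/WAVE PCM file
#'
#' Reads a `.wav` file into an [audio_recording()]. Supported encodings are
#' 16- and 24-bit integer PCM and 32-bit IEEE float, the formats produced by
#' clinical speech recorders and by [write_wav()]. Multi-channel input is
#' averaged to mono with a warning; samples are returned on the `[-1, 1]`
#' scale.
#'
#' @param path Path to an existing WAV file.
#' @param task Task label attached to the recording (see [audio_recording()]).
#' @param subject_id Subject identifier attached to the recording.
#' @param repetition Repetition index (positive integer).
#' @return An `AudioRecording`.
#' @seealso [write_wav()], [audio_recording()]
#' @export
read_wav <- function(path, task = "vowel_a", subject_id = "unknown",
                     repetition = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", 1, size = 2,
                            endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", 1, size = 4,
                            endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, size = 2,
                            endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("corrupt WAV (no fmt chunk): ", path)
  if (is.null(data_raw) || length(data_raw) == 0) {
    stop("empty audio data in ", path)
  }

  x <- switch(as.character(fmt$format),
    "1" = decode_int_pcm(data_raw, fmt$bits),
    "3" = readBin(data_raw, "numeric", length(data_raw) / 4, size = 4,
                  endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$format, ")")
  )

  if (fmt$channels > 1) {
    warning("averaging ", fmt$channels, " channels to mono")
    n <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)],
                         ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0) stop("empty audio data in ", path)

  audio_recording(x, fmt$rate, task = task, subject_id = subject_id,
                  repetition = repetition)
}

decode_int_pcm <- function(raw, bits) {
  if (bits == 16) {
    readBin(raw, "integer", length(raw) / 2, size = 2,
            endian = "little") / 32768
  } else if (bits == 24) {
    n <- length(raw) / 3
    b <- matrix(as.integer(raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else {
    stop("unsupported PCM bit depth: ", bits)
  }
}

#' Write an AudioRecording as 16-bit PCM WAV
#'
#' @param rec An `AudioRecording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "AudioRecording"))
  x <- pmin(1, pmax(-1, rec$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
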
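# Shared fixtures and independent oracles. Audio fixtures are generated at
# 16 kHz: every spectral landmark used by the features sits far below the
# 8 kHz Nyquist, and synthesis/analysis run several times faster than at
# the 48 kHz field-recording rate.

TEST_SR <- 16000

# a plain sine AudioRecording
sine_rec <- function(freq, dur, amp = 0.5, sr = TEST_SR, task = "vowel_a") {
  t <- (seq_len(round(dur * sr)) - 1) / sr
  audio_recording(amp * sin(2 * pi * freq * t), sr, task = task)
}

# write a 16-bit stereo WAV (the package itself only writes mono)
write_stereo_wav <- function(path, left, right, sr) {
  stopifnot(length(left) == length(right))
  inter <- as.integer(round(rbind(left, right) * 32767))
  n_bytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(as.vector(inter), con, size = 2, endian = "little")
  invisible(path)
}

# ---- independent graph oracles (brute force) --------------------------

# all-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

brute_ne <- function(adj) {
  d <- fw_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  }, numeric(1))
}

brute_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- fw_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

brute_nle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    brute_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(adj[nb, nb]) / 2
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# ---- independent statistics oracles -----------------------------------

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
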
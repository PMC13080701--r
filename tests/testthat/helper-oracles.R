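# Brute-force oracles and small fixture builders used across the suite.
# The oracles are deliberately naive (explicit loops, textbook formulas)
# and never share code with the implementation they check.

# Two-loop sample-wise mean over epochs of a (ch x samples x epochs) array.
naive_epoch_average <- function(arr) {
  d <- dim(arr)
  out <- matrix(0, d[1], d[2])
  for (c in seq_len(d[1])) {
    for (s in seq_len(d[2])) {
      acc <- 0
      for (e in seq_len(d[3])) acc <- acc + arr[c, s, e]
      out[c, s] <- acc / d[3]
    }
  }
  out
}

naive_window_mean <- function(x, idx) {
  acc <- 0
  for (i in idx) acc <- acc + x[i]
  acc / length(idx)
}

naive_rmssd <- function(rr) {
  acc <- 0
  for (i in seq_len(length(rr) - 1)) acc <- acc + (rr[i + 1] - rr[i])^2
  sqrt(acc / (length(rr) - 1))
}

naive_mean_hr <- function(rr) 60000 / (sum(rr) / length(rr))

naive_z_exclude <- function(v, k = 3) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  if (s == 0) return(v)
  keep <- logical(length(v))
  for (i in seq_along(v)) keep[i] <- abs((v[i] - m) / s) <= k
  v[keep]
}

# Peak series at given times (seconds), bypassing detection.
peaks_at <- function(times) hepline:::new_rpeak_series(times)

# Minimal epoch set built directly from an array (channels default to the
# ten-electrode montage prefix).
epochs_from_array <- function(arr, fs = 256, w = hep_windows(),
                              channels = NULL, peak_times = NULL) {
  d <- dim(arr)
  if (is.null(channels)) channels <- MIN_MONTAGE[seq_len(d[1])]
  offs <- hepline:::window_offsets(w, fs)$epoch
  stopifnot(d[2] == length(offs))
  if (is.null(peak_times)) peak_times <- as.numeric(seq_len(d[3]))
  peak_times <- as.numeric(peak_times)
  hepline:::new_epoch_set(arr, channels, fs, offs, peak_times,
                          n_total = d[3], n_rejected_rr = 0L,
                          n_dropped_bounds = 0L)
}

# A quiet recording with a known beat grid, for epoching tests.
grid_recording <- function(duration_s = 120, hr = 60, amp = 0, noise = 0,
                           seed = 1, jitter = 0, ...) {
  cfg <- synth_recording_config(duration_s = duration_s, mean_hr_bpm = hr,
                                hr_sd_bpm = 0, rr_jitter_ms = jitter,
                                hep_amplitude_uv = amp, noise_sd_uv = noise,
                                seed = seed, ...)
  generate_recording(cfg)
}
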
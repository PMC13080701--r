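# Band-pass filtering and artifact subspace reconstruction (ASR).

#' Preprocessing configuration
#'
#' @param highpass_hz,lowpass_hz band edges in Hz (defaults 0.53 and 70,
#'   the digital filters of the clinical recordings).
#' @param asr_enabled run ASR after filtering.
#' @param asr_cutoff component rejection threshold in calibration-SD units
#'   (default 20).
#' @param asr_window_s sliding-window length in seconds.
#' @param asr_calibration `"auto_cleanest"` (quietest contiguous 60 s) or
#'   `"explicit_interval"` (use `calibration_interval`).
#' @param calibration_interval numeric `c(t0, t1)` in seconds when explicit.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_hz = 0.53, lowpass_hz = 70,
                              asr_enabled = TRUE, asr_cutoff = 20,
                              asr_window_s = 0.5,
                              asr_calibration = c("auto_cleanest",
                                                  "explicit_interval"),
                              calibration_interval = NULL) {
  asr_calibration <- match.arg(asr_calibration)
  stopifnot(highpass_hz > 0, highpass_hz < lowpass_hz, asr_cutoff > 0,
            asr_window_s > 0)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 asr_enabled = asr_enabled, asr_cutoff = asr_cutoff,
                 asr_window_s = asr_window_s,
                 asr_calibration = asr_calibration,
                 calibration_interval = calibration_interval),
            class = "preprocess_config")
}

# Evaluate |H(e^{-iw})|^2 of a transfer-function filter at the FFT bin
# frequencies w = 2*pi*(0:(np-1))/np (Horner on the complex unit circle).
filter_mag2 <- function(ba, np) {
  z <- exp(complex(imaginary = -2 * pi * seq.int(0L, np - 1L) / np))
  horner <- function(cf) {
    acc <- complex(real = rep(cf[1], np))
    for (k in seq_along(cf)[-1]) acc <- acc * z + cf[k]
    acc
  }
  Mod(horner(ba$b))^2 / Mod(horner(ba$a))^2
}

# Zero-phase band-pass: the squared magnitude of 4th-order digital
# Butterworth high- and low-pass designs (exactly what a forward-backward
# filtfilt pass realizes, without its edge transients) applied in the
# frequency domain, which is exact in phase and O(n log n).  The design
# cutoffs are pre-warped in tan space by 0.414^(1/(2*order)) so the
# *combined* two-pass response is -3 dB at the nominal band edges; signals
# are reflect-padded 4 s at both ends to suppress circular wrap-around.
zero_phase_bandpass <- function(x, fs, highpass_hz, lowpass_hz, order = 4) {
  nyq <- fs / 2
  if (lowpass_hz >= nyq)
    stop("lowpass cutoff (", lowpass_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  warp <- 0.414^(1 / (2 * order))        # two-pass -3 dB correction
  f_lp <- atan(tan(pi * lowpass_hz / fs) / warp) * fs / pi
  f_hp <- atan(tan(pi * highpass_hz / fs) * warp) * fs / pi
  lp <- signal::butter(order, f_lp / nyq, type = "low")
  hp <- signal::butter(order, f_hp / nyq, type = "high")
  x <- as.matrix(x)                       # samples x channels
  n <- nrow(x)
  nc <- ncol(x)
  pad <- min(n - 1L, as.integer(4 * fs))
  xp <- rbind(x[(pad + 1L):2L, , drop = FALSE], x,
              x[(n - 1L):(n - pad), , drop = FALSE])
  np <- stats::nextn(nrow(xp), c(2, 3, 5))
  xp <- rbind(xp, matrix(0, np - nrow(xp), nc))
  gain <- filter_mag2(lp, np) * filter_mag2(hp, np)
  gain[1] <- 0                            # remove DC exactly
  # the gain is real and even, so two real channels can ride one complex FFT
  odd <- seq(1L, nc, by = 2L)
  even <- odd + 1L
  im <- matrix(0, np, length(odd))
  im[, even <= nc] <- xp[, even[even <= nc], drop = FALSE]
  z <- matrix(complex(real = xp[, odd, drop = FALSE], imaginary = im),
              np, length(odd))
  zf <- stats::mvfft(stats::mvfft(z) * gain, inverse = TRUE) / np
  y <- matrix(0, n, nc)
  sel <- (pad + 1L):(pad + n)
  y[, odd] <- Re(zf[sel, , drop = FALSE])
  if (any(even <= nc))
    y[, even[even <= nc]] <- Im(zf[sel, which(even <= nc), drop = FALSE])
  y
}

#' Zero-phase band-pass of the EEG channels
#'
#' Butterworth filters applied forward-backward (so ERP latencies are
#' preserved) to every EEG channel; the ECG lead is left untouched so that
#' R-peak detection and HRV always see the raw ECG.  The DC offset is
#' removed.
#'
#' @param rec a [new_recording()].
#' @param cfg a [preprocess_config()].
#' @return the filtered recording.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  fs <- rec$sampling_rate_hz
  out <- rec
  labs <- eeg_labels(rec)
  out$signal[labs, ] <- t(zero_phase_bandpass(
    t(rec$signal[labs, , drop = FALSE]), fs,
    cfg$highpass_hz, cfg$lowpass_hz))
  out
}

# Quietest contiguous window of the EEG: minimizes total power over 60 s,
# evaluated on a 5 s grid.  `cpow` is c(0, cumsum(per-sample total power)).
find_calibration_interval <- function(cpow, fs, need_s = 60) {
  n <- length(cpow) - 1L
  wlen <- as.integer(need_s * fs)
  if (n < wlen) return(NULL)
  step <- as.integer(5 * fs)
  starts <- seq(1L, n - wlen + 1L, by = step)
  score <- (cpow[starts + wlen] - cpow[starts]) / wlen
  s <- starts[which.min(score)]
  c(s, s + wlen - 1L)
}

#' Artifact subspace reconstruction
#'
#' Sliding-window PCA cleaning referenced to a calibration segment of
#' artifact-free data.  For each (half-overlapping) window the data are
#' decomposed into their principal directions; a component whose RMS
#' amplitude exceeds `asr_cutoff` times the calibration SD along the same
#' direction is an artifact component and is zeroed before the window is
#' reconstructed; each sample takes its cleaned value from the window whose
#' center is nearest.  Windows without flagged components are reconstructed
#' exactly, so artifact-free data pass through unchanged.  The ECG channel
#' is never altered.
#'
#' @param rec a [new_recording()] (normally already band-passed).
#' @param cfg a [preprocess_config()].
#' @return list with `recording` (cleaned) and `report` (class
#'   `asr_report`): `applied`, `frac_windows_altered`, `frac_samples_altered`,
#'   `calibration_interval_s`, `skipped_reason`.
#' @export
asr_clean <- function(rec, cfg = preprocess_config()) {
  fs <- rec$sampling_rate_hz
  labs <- eeg_labels(rec)
  eeg <- rec$signal[labs, , drop = FALSE]
  n <- ncol(eeg)

  skip <- function(reason) {
    warning("ASR skipped: ", reason)
    list(recording = rec,
         report = structure(list(applied = FALSE,
                                 frac_windows_altered = 0,
                                 frac_samples_altered = 0,
                                 calibration_interval_s = NULL,
                                 skipped_reason = reason),
                            class = "asr_report"))
  }
  if (!cfg$asr_enabled) return(skip("disabled in config"))

  cpow <- c(0, cumsum(colSums(eeg^2)))
  if (cfg$asr_calibration == "explicit_interval") {
    ci <- cfg$calibration_interval
    if (is.null(ci) || diff(ci) < 60)
      return(skip("explicit calibration interval missing or shorter than 60 s"))
    cal_idx <- (samp_range(ci[1], ci[2], fs) + 1L)
    cal_idx <- cal_idx[cal_idx >= 1L & cal_idx <= n]
  } else {
    ci_samp <- find_calibration_interval(cpow, fs)
    if (is.null(ci_samp))
      return(skip("recording shorter than the 60 s calibration requirement"))
    cal_idx <- ci_samp[1]:ci_samp[2]
  }
  cal <- eeg[, cal_idx, drop = FALSE]
  cal_cov <- tcrossprod(cal) / ncol(cal)

  wlen <- as.integer(round(cfg$asr_window_s * fs))
  step <- max(1L, wlen %/% 2L)
  centers <- seq(1L + wlen %/% 2L, n, by = step)
  cleaned <- eeg
  altered_w <- 0L
  altered_samples <- 0L
  half_assign <- step %/% 2L
  # Screen: a window can only flag a component if some eigenvalue of its
  # covariance exceeds cutoff^2 x the smallest calibration variance, and
  # every eigenvalue is bounded by the covariance trace = energy / wlen.
  # Windows below that bound are passed through unchanged (exactly what the
  # full decomposition would do), so only suspicious windows pay for a PCA.
  lam_min <- min(eigen(cal_cov, symmetric = TRUE, only.values = TRUE)$values)
  trace_bound <- cfg$asr_cutoff^2 * max(lam_min, 0)
  energy <- cpow
  for (c0 in centers) {
    lo <- max(1L, c0 - wlen %/% 2L)
    hi <- min(n, lo + wlen - 1L)
    if ((energy[hi + 1L] - energy[lo]) / (hi - lo + 1L) <= trace_bound) next
    X <- eeg[, lo:hi, drop = FALSE]
    co <- tcrossprod(X) / ncol(X)
    eg <- eigen(co, symmetric = TRUE)
    rms <- sqrt(pmax(eg$values, 0))
    ref <- sqrt(pmax(colSums(eg$vectors * (cal_cov %*% eg$vectors)), 0))
    bad <- rms > cfg$asr_cutoff * ref
    if (!any(bad)) next
    a_lo <- max(1L, c0 - half_assign)
    a_hi <- min(n, c0 + half_assign - 1L)
    keepV <- eg$vectors[, !bad, drop = FALSE]
    Xc <- keepV %*% crossprod(keepV, X)
    cleaned[, a_lo:a_hi] <- Xc[, (a_lo - lo + 1L):(a_hi - lo + 1L),
                               drop = FALSE]
    altered_w <- altered_w + 1L
    altered_samples <- altered_samples + (a_hi - a_lo + 1L)
  }
  out <- rec
  out$signal[labs, ] <- cleaned
  list(recording = out,
       report = structure(list(applied = TRUE,
                               frac_windows_altered = altered_w / length(centers),
                               frac_samples_altered = altered_samples / n,
                               calibration_interval_s =
                                 c(cal_idx[1] - 1L, cal_idx[length(cal_idx)]) / fs,
                               skipped_reason = NULL),
                          class = "asr_report"))
}

#' Run the full preprocessing stage
#'
#' Band-pass then (optionally) ASR; returns the cleaned recording with the
#' ASR report attached as `$meta$asr_report`.
#'
#' @param rec a [new_recording()].
#' @param cfg a [preprocess_config()].
#' @return the preprocessed recording.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  out <- bandpass(rec, cfg)
  if (cfg$asr_enabled) {
    res <- asr_clean(out, cfg)
    out <- res$recording
    out$meta$asr_report <- res$report
  }
  out
}
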
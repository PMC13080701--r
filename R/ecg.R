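# R-peak detection, R-R housekeeping and heart-rate-variability metrics.

#' Detect R waves in an ECG channel
#'
#' Derivative-plus-adaptive-threshold detector in the Pan-Tompkins family:
#' the central-difference derivative of the ECG (which suppresses baseline
#' drift and T waves) is squared and integrated over a 120 ms moving
#' window; contiguous supra-threshold runs become beat candidates, a 250 ms
#' refractory period is enforced, and each detection is refined to the
#' extremum of the raw signal within +/-50 ms.  Polarity is handled
#' automatically, so an inverted lead yields identical peak times.
#'
#' @param ecg numeric vector, one ECG channel in µV.
#' @param fs sampling rate in Hz.
#' @return list of class `rpeak_series`: `peak_times_s` (strictly
#'   increasing, seconds), `rr_intervals_ms`, and `quality` (fraction of
#'   R-R intervals in the physiologically plausible 300-2000 ms range).
#' @export
detect_r_peaks <- function(ecg, fs) {
  stopifnot(fs > 0)
  n <- length(ecg)
  if (n < 10 * fs)
    stop("need at least 10 s of ECG signal")
  if (max(ecg) - min(ecg) < 1e-9) {
    warning("flat or saturated ECG signal; no beats detected")
    return(new_rpeak_series(numeric(0)))
  }
  d <- c(0, (ecg[-(1:2)] - ecg[-((n - 1):n)]) / 2, 0)
  m <- mean(ecg)
  flip <- abs(min(ecg) - m) > abs(max(ecg) - m)
  raw <- if (flip) -ecg else ecg
  energy <- d^2
  win <- max(3L, round(0.12 * fs))
  ce <- c(0, cumsum(energy))
  lo <- pmax(seq_len(n) - win %/% 2L, 0L)
  hi <- pmin(seq_len(n) + (win - win %/% 2L) - 1L, n)
  integ <- (ce[hi + 1L] - ce[lo + 1L]) / win
  k99 <- max(1L, ceiling(0.99 * n))
  thr <- 0.2 * sort(integ, partial = k99)[k99]
  above <- which(integ > thr)
  if (!length(above)) {
    warning("no QRS energy above threshold; no beats detected")
    return(new_rpeak_series(numeric(0)))
  }
  gap <- which(diff(above) > round(0.25 * fs))
  starts <- above[c(1L, gap + 1L)]
  ends <- above[c(gap, length(above))]
  half <- round(0.05 * fs)
  cand <- vapply(seq_along(starts), function(g) {
    idx <- starts[g]:ends[g]
    centre <- idx[which.max(integ[idx])]
    lo <- max(1L, centre - half); hi <- min(n, centre + half)
    lo + which.max(raw[lo:hi]) - 1L
  }, numeric(1))
  cand <- sort(unique(cand))
  # refractory: drop the weaker of any pair closer than 250 ms
  keep <- rep(TRUE, length(cand))
  last <- 1L
  for (i in seq_along(cand)[-1]) {
    if ((cand[i] - cand[last]) / fs < 0.25) {
      if (raw[cand[i]] > raw[cand[last]]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  new_rpeak_series((cand[keep] - 1) / fs)
}

new_rpeak_series <- function(peak_times_s) {
  peak_times_s <- as.numeric(peak_times_s)
  stopifnot(!is.unsorted(peak_times_s, strictly = TRUE) || length(peak_times_s) < 2)
  rr <- if (length(peak_times_s) >= 2) 1000 * diff(peak_times_s) else numeric(0)
  quality <- if (length(rr)) mean(rr >= 300 & rr <= 2000) else NA_real_
  structure(list(peak_times_s = peak_times_s, rr_intervals_ms = rr,
                 quality = quality),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d beats, mean RR %.0f ms, quality %.2f\n",
              length(x$peak_times_s),
              if (length(x$rr_intervals_ms)) mean(x$rr_intervals_ms) else NA,
              x$quality))
  invisible(x)
}

#' Keepable-beat mask under the short-R-R exclusion
#'
#' A beat anchors a usable epoch only when the interval to the *next* R wave
#' is at least `min_rr_ms` — a briefer interval would place the following
#' QRS complex inside this beat's epoch and inflate the average with cardiac
#' field artifact.  The final beat is keepable only when at least
#' `epoch_end_s` of signal remains after it, so its epoch fits the record.
#'
#' @param peaks an `rpeak_series`.
#' @param min_rr_ms minimum retained R-R interval (ms); intervals strictly
#'   below are removed.
#' @param end_s end of the available signal/segment in seconds.
#' @param epoch_end_s post-R extent of the epoch (s).
#' @return logical vector over peaks.
#' @export
rr_keep_mask <- function(peaks, min_rr_ms = 700, end_s = Inf,
                         epoch_end_s = 0.8) {
  t <- peaks$peak_times_s
  np <- length(t)
  if (!np) return(logical(0))
  mask <- logical(np)
  # 1 ns tolerance so intervals that are exactly the threshold survive the
  # floating-point error of differencing beat times
  if (np > 1) mask[-np] <- peaks$rr_intervals_ms >= min_rr_ms - 1e-6
  mask[np] <- (end_s - t[np]) >= epoch_end_s
  mask
}

#' Heart rate variability metrics from an R-peak series
#'
#' RMSSD (the primary, vagally mediated index) is the root mean square of
#' successive R-R differences.  LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz)
#' powers are integrated from a Welch periodogram of the R-R tachogram
#' resampled at 4 Hz by cubic spline interpolation; they require at least
#' ~2 min of beats and are `NA` otherwise.
#'
#' @param peaks an `rpeak_series`.
#' @return list of class `hrv_metrics`: `rmssd_ms`, `lf_power`, `hf_power`
#'   (ms^2), `mean_hr_bpm`, `n_beats`, `valid`.
#' @export
compute_hrv <- function(peaks) {
  rr <- peaks$rr_intervals_ms
  n_beats <- length(peaks$peak_times_s)
  if (length(rr) < 2)
    return(structure(list(rmssd_ms = NA_real_, lf_power = NA_real_,
                          hf_power = NA_real_, mean_hr_bpm = NA_real_,
                          n_beats = n_beats, valid = FALSE),
                     class = "hrv_metrics"))
  rmssd <- sqrt(mean(diff(rr)^2))
  mean_hr <- 60000 / mean(rr)
  span <- diff(range(peaks$peak_times_s))
  lf <- hf <- NA_real_
  if (span >= 120) {
    t <- peaks$peak_times_s[-1]
    fs_t <- 4
    grid <- seq(t[1], t[length(t)], by = 1 / fs_t)
    tach <- stats::spline(t, rr, xout = grid)$y
    psd <- welch_psd(tach - mean(tach), fs_t)
    lf <- band_power(psd, 0.04, 0.15)
    hf <- band_power(psd, 0.15, 0.40)
  }
  structure(list(rmssd_ms = rmssd, lf_power = lf, hf_power = hf,
                 mean_hr_bpm = mean_hr, n_beats = n_beats, valid = TRUE),
            class = "hrv_metrics")
}

# Welch periodogram: Hann-windowed segments with 50% overlap, one-sided
# density in x-units^2 per Hz.
welch_psd <- function(x, fs, nseg = 256L) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * u * fs)
  nh <- nseg %/% 2L
  psd <- psd[seq_len(nh + 1L)]
  psd[2:(nh + 1L)] <- 2 * psd[2:(nh + 1L)]
  list(freq = (0:nh) * fs / nseg, psd = psd)
}

band_power <- function(psd, f_lo, f_hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= f_lo & psd$freq < f_hi
  sum(psd$psd[sel]) * df
}
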
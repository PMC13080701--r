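# Band-pass response, linearity, and artifact subspace reconstruction.

sine_rec <- function(freq, duration_s = 60, fs = 256) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(sin(2 * pi * freq * t), each = 11), 11, length(t),
                byrow = FALSE)
  sig[11, ] <- 0
  new_recording(sig, c(MIN_MONTAGE, "ECG"), fs)
}

mid_gain <- function(rec_out, rec_in, ch = "C4") {
  sel <- 3000:12000  # away from the edges
  stats::sd(rec_out$signal[ch, sel]) / stats::sd(rec_in$signal[ch, sel])
}

test_that("band-pass passes 50 Hz nearly untouched and kills 0.1 Hz drift", {
  r50 <- sine_rec(50)
  g50 <- mid_gain(bandpass(r50), r50)
  expect_gt(g50, 0.95)
  rdrift <- sine_rec(0.1)
  gdrift <- mid_gain(bandpass(rdrift), rdrift)
  expect_lt(gdrift, 0.10)
  # zero in, zero out, and ECG untouched
  rz <- new_recording(matrix(0, 11, 256 * 30), c(MIN_MONTAGE, "ECG"), 256)
  rz$signal["ECG", ] <- 42
  bz <- bandpass(rz)
  expect_true(all(bz$signal[eeg_labels(bz), ] == 0))
  expect_true(all(bz$signal["ECG", ] == 42))
})

test_that("band-pass magnitude matches a time-domain filtfilt realization", {
  # same Butterworth designs, independently applied forward-backward in the
  # time domain by the signal package
  fs <- 256
  warp <- 0.414^(1 / 8)
  lp <- signal::butter(4, (atan(tan(pi * 70 / fs) / warp) * fs / pi) / (fs / 2),
                       type = "low")
  hp <- signal::butter(4, (atan(tan(pi * 0.53 / fs) * warp) * fs / pi) / (fs / 2),
                       type = "high")
  for (f in c(1, 5, 20, 45, 60, 80, 100)) {
    r <- sine_rec(f)
    ours <- mid_gain(bandpass(r), r)
    t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    x <- sin(2 * pi * f * t)
    y <- signal::filtfilt(hp, signal::filtfilt(lp, x))
    ref <- stats::sd(y[3000:12000]) / stats::sd(x[3000:12000])
    expect_lt(abs(ours - ref), 0.02)
  }
})

test_that("filtering is linear", {
  rec <- grid_recording(duration_s = 30, amp = 4, noise = 8, seed = 13)
  b1 <- bandpass(rec)
  rec3 <- rec
  rec3$signal[eeg_labels(rec), ] <- 3 * rec3$signal[eeg_labels(rec), ]
  b3 <- bandpass(rec3)
  expect_lt(max(abs(b3$signal[eeg_labels(rec), ] -
                      3 * b1$signal[eeg_labels(rec), ])), 1e-8)
})

test_that("ASR leaves artifact-free recordings unchanged", {
  rec <- grid_recording(duration_s = 90, amp = 4, noise = 10, seed = 14)
  res <- asr_clean(rec)
  expect_true(res$report$applied)
  expect_lt(max(abs(res$recording$signal - rec$signal)), 1)
  expect_equal(res$report$frac_windows_altered, 0)
})

test_that("an infinite cutoff makes ASR the identity", {
  cfg <- synth_recording_config(duration_s = 90, noise_sd_uv = 10,
                                artifact_rate_per_min = 4,
                                artifact_amplitude_uv = 400, seed = 15)
  rec <- generate_recording(cfg)
  res <- asr_clean(rec, preprocess_config(asr_cutoff = 1e12))
  expect_identical(res$recording$signal, rec$signal)
})

test_that("ASR suppresses a 500 uV boxcar below 100 uV peak-to-peak in most seeds", {
  hits <- vapply(1:10, function(s) {
    rec <- grid_recording(duration_s = 120, hr = 62, noise = 10, seed = s)
    set.seed(1000 + s)
    t0 <- stats::runif(1, 70, 110)
    idx <- hepline:::samp_range(t0, t0 + 0.2, 256) + 1L
    ch <- sample(MIN_MONTAGE, 1)
    rec$signal[ch, idx] <- rec$signal[ch, idx] + 500
    res <- asr_clean(rec)
    seg <- res$recording$signal[ch, idx]
    diff(range(seg)) < 100
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ASR never alters the ECG channel and reports its calibration", {
  cfg <- synth_recording_config(duration_s = 120, noise_sd_uv = 10,
                                artifact_rate_per_min = 6,
                                artifact_amplitude_uv = 500, seed = 16)
  rec <- generate_recording(cfg)
  res <- asr_clean(rec)
  expect_identical(res$recording$signal["ECG", ], rec$signal["ECG", ])
  expect_length(res$report$calibration_interval_s, 2)
  expect_gte(diff(res$report$calibration_interval_s), 60)
})

test_that("ASR is skipped with a warning when no calibration data exists", {
  rec <- grid_recording(duration_s = 30, noise = 10, seed = 17)
  expect_warning(res <- asr_clean(rec), "60 s")
  expect_false(res$report$applied)
  expect_identical(res$recording$signal, rec$signal)
})

test_that("preprocessing is HEP-neutral on clean data", {
  rec <- grid_recording(duration_s = 150, amp = 5, noise = 10, seed = 18)
  pk <- peaks_at(rec$meta$r_peaks_s)
  hep_raw <- average_and_baseline(reject_by_amplitude(extract_epochs(rec, pk)))
  prec <- preprocess(rec)
  hep_pp <- average_and_baseline(reject_by_amplitude(extract_epochs(prec, pk)))
  expect_lt(abs(hep_pp$compound_amplitude_uv - hep_raw$compound_amplitude_uv),
            0.1)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- grid_recording(duration_s = 20)
  expect_error(bandpass(rec, preprocess_config(lowpass_hz = 128)), "Nyquist")
  expect_error(preprocess_config(highpass_hz = 80, lowpass_hz = 70))
})
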
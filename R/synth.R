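# Synthetic polygraphy generator: EDF+-writable recordings with known
# ground-truth heartbeat-locked cortical components, R-R variability, EEG
# background noise and large-amplitude artifacts.

#' Configuration for one synthetic polygraphy recording
#'
#' @param duration_s record length in seconds (> 0).
#' @param sampling_rate_hz sampling rate (Hz, integer; 256 matches the
#'   clinical recordings this generator emulates).
#' @param channel_labels EEG montage; must be a superset of the
#'   ten-electrode minimum.
#' @param ecg_label label of the synthesized ECG lead.
#' @param mean_hr_bpm mean heart rate (30-180 beats/min exclusive).
#' @param hr_sd_bpm SD of the slow AR(1) heart-rate drift (beats/min).
#' @param rr_jitter_ms SD of white beat-to-beat R-R jitter (ms); intervals
#'   are truncated at 300 ms.
#' @param hep_amplitude_uv target mean voltage of the heartbeat-locked
#'   component over the 0.455-0.595 s post-R measurement window (µV).
#' @param hep_channels channels receiving the component (subset of
#'   `channel_labels`; default C4 and F8, the compound-HEP leads).
#' @param noise_sd_uv SD of the Gaussian EEG background (µV).
#' @param artifact_rate_per_min Poisson rate of large boxcar artifacts.
#' @param artifact_amplitude_uv artifact amplitude (µV; must exceed 100,
#'   the epoch peak-to-peak rejection threshold, when the rate is > 0).
#' @param cardiac_field_uv optional R-locked bleed of the cardiac field into
#'   all EEG channels (µV at the R peak; 0 disables).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return list of class `synth_recording_config`.
#' @export
synth_recording_config <- function(duration_s, sampling_rate_hz = 256,
                                   channel_labels = MIN_MONTAGE,
                                   ecg_label = "ECG",
                                   mean_hr_bpm = 60, hr_sd_bpm = 2,
                                   rr_jitter_ms = 25,
                                   hep_amplitude_uv = 0,
                                   hep_channels = c("C4", "F8"),
                                   noise_sd_uv = 10,
                                   artifact_rate_per_min = 0,
                                   artifact_amplitude_uv = 300,
                                   cardiac_field_uv = 0,
                                   seed = 1L) {
  cfg <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
              channel_labels = channel_labels, ecg_label = ecg_label,
              mean_hr_bpm = mean_hr_bpm, hr_sd_bpm = hr_sd_bpm,
              rr_jitter_ms = rr_jitter_ms, hep_amplitude_uv = hep_amplitude_uv,
              hep_channels = hep_channels, noise_sd_uv = noise_sd_uv,
              artifact_rate_per_min = artifact_rate_per_min,
              artifact_amplitude_uv = artifact_amplitude_uv,
              cardiac_field_uv = cardiac_field_uv, seed = as.integer(seed))
  stopifnot(cfg$duration_s > 0,
            cfg$sampling_rate_hz > 0,
            cfg$sampling_rate_hz == round(cfg$sampling_rate_hz),
            cfg$mean_hr_bpm > 30, cfg$mean_hr_bpm < 180,
            cfg$hr_sd_bpm >= 0, cfg$rr_jitter_ms >= 0, cfg$noise_sd_uv >= 0,
            cfg$artifact_rate_per_min >= 0)
  if (cfg$artifact_rate_per_min > 0 && cfg$artifact_amplitude_uv <= 100)
    stop("artifact_amplitude_uv must exceed 100 µV when artifacts are enabled")
  if (!all(cfg$hep_channels %in% cfg$channel_labels))
    stop("hep_channels must be a subset of channel_labels")
  structure(cfg, class = "synth_recording_config")
}

# Raised-cosine heartbeat-locked component supported on [0.44, 0.62] s
# post-R, scaled so that its mean over the sampled measurement window is
# exactly 1 µV (callers multiply by the per-beat target amplitude).  The
# support is kept clear of the QRS cardiac field and — at resting heart
# rates (R-R >= ~0.97 s) — of the next beat's pre-R baseline window, so the
# injected window mean is recovered without baseline bleed-through; at
# tachycardic rates the periodic component necessarily overlaps the next
# baseline window, a confound real HEPs share.
hep_component_template <- function(fs, w = hep_windows()) {
  offs <- samp_range(0.44, 0.62, fs)
  t <- offs / fs
  shape <- 0.5 * (1 - cos(2 * pi * (t - 0.44) / 0.18))
  meas <- window_offsets(w, fs)$measure
  m <- mean(shape[match(meas, offs)])
  list(offsets = offs, values = shape / m)
}

# Gaussian-deflection QRS plus a small T wave; only the R-peak timing
# matters downstream, the morphology just has to drive a QRS detector.
ecg_beat_template <- function(fs) {
  offs <- samp_range(-0.30, 0.45, fs)
  t <- offs / fs
  v <- 800 * exp(-(t / 0.012)^2) -
       150 * exp(-((t - 0.035) / 0.015)^2) -
       80 * exp(-((t + 0.035) / 0.02)^2) +
       120 * exp(-((t - 0.25) / 0.06)^2)
  list(offsets = offs, values = v)
}

# Draw beat times over [0, duration): slow AR(1) heart-rate drift plus
# white R-R jitter, truncated at a 300 ms minimum interval.  hr_delta_fun
# (time -> bpm offset) lets cohorts impose segment-wise heart-rate changes.
draw_beat_times <- function(cfg, hr_delta_fun = NULL) {
  phi <- 0.95
  t <- 0.5
  hr_dev <- 0
  times <- numeric(0)
  while (t < cfg$duration_s) {
    times <- c(times, t)
    hr_dev <- phi * hr_dev +
      stats::rnorm(1, 0, cfg$hr_sd_bpm * sqrt(1 - phi^2))
    hr <- cfg$mean_hr_bpm + hr_dev +
      if (is.null(hr_delta_fun)) 0 else hr_delta_fun(t)
    rr_ms <- max(300, 60000 / max(hr, 1) + stats::rnorm(1, 0, cfg$rr_jitter_ms))
    t <- t + rr_ms / 1000
  }
  times
}

#' Generate a synthetic polygraphy recording
#'
#' The ECG channel carries synthetic QRS complexes at the configured rate
#' and jitter; every EEG channel carries Gaussian background noise; the
#' designated HEP channels additionally carry a deterministic
#' heartbeat-locked raised-cosine component whose mean over the
#' 0.455-0.595 s post-R measurement window (after baseline correction,
#' which the component does not touch) equals `hep_amplitude_uv`.
#' Large boxcar artifacts are inserted as a Poisson process.  Ground-truth
#' R-peak times, per-beat injected amplitudes and artifact intervals are
#' returned in `$meta`.
#'
#' @param cfg a [synth_recording_config()].
#' @param annotations optional annotation table embedded in the recording.
#' @param hep_schedule optional data.frame `t0,t1,amplitude_uv`: beats whose
#'   R peak falls in `[t0, t1)` get that amplitude instead of the default
#'   (used to impose preictal / pre-symptom shifts).
#' @param hr_delta_fun optional function time -> bpm offset added to the
#'   instantaneous heart rate (used to impose peri-ictal HR changes).
#' @param subject_id subject identifier stored in the recording.
#' @return a [new_recording()] object with ground truth in `$meta`.
#' @export
generate_recording <- function(cfg, annotations = empty_annotations(),
                               hep_schedule = NULL, hr_delta_fun = NULL,
                               subject_id = "synth01") {
  stopifnot(inherits(cfg, "synth_recording_config"))
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate_hz
  nsamp <- as.integer(round(cfg$duration_s * fs))
  labs <- c(cfg$channel_labels, cfg$ecg_label)
  neeg <- length(cfg$channel_labels)

  beat_t <- draw_beat_times(cfg, hr_delta_fun)
  beat_i <- sec_to_samp(beat_t, fs) + 1L
  ok <- beat_i >= 1L & beat_i <= nsamp
  beat_t <- beat_t[ok]; beat_i <- beat_i[ok]

  # noise stream seeded from the config seed through the R RNG, so
  # identical config + seed still gives bit-identical output
  s12 <- floor(stats::runif(2) * 2^31)
  sig <- noise_matrix(length(labs), nsamp, neeg, cfg$noise_sd_uv,
                      s12[1], s12[2])
  rownames(sig) <- labs

  # accumulate a beat-locked template into a length-nsamp vector (handles
  # overlapping templates at short R-R intervals)
  add_template <- function(tpl_offsets, tpl_values, anchors_i,
                           scale = rep(1, length(anchors_i))) {
    accumulate_template(nsamp, as.integer(tpl_offsets), tpl_values,
                        as.integer(anchors_i), scale)
  }

  qrs <- ecg_beat_template(fs)
  ecg_row <- neeg + 1L
  sig[ecg_row, ] <- add_template(qrs$offsets, qrs$values, beat_i)

  amp <- rep(cfg$hep_amplitude_uv, length(beat_t))
  if (!is.null(hep_schedule) && nrow(hep_schedule)) {
    for (r in seq_len(nrow(hep_schedule))) {
      inwin <- beat_t >= hep_schedule$t0[r] & beat_t < hep_schedule$t1[r]
      amp[inwin] <- hep_schedule$amplitude_uv[r]
    }
  }
  hep_tpl <- hep_component_template(fs)
  hep_rows <- match(cfg$hep_channels, labs)
  if (any(amp != 0)) {
    hv <- add_template(hep_tpl$offsets, hep_tpl$values, beat_i, amp)
    for (r in hep_rows) sig[r, ] <- sig[r, ] + hv
  }
  if (cfg$cardiac_field_uv != 0) {
    cf <- samp_range(-0.05, 0.05, fs)
    cfv <- cfg$cardiac_field_uv * exp(-((cf / fs) / 0.015)^2)
    cfa <- add_template(cf, cfv, beat_i)
    sig[seq_len(neeg), ] <- sig[seq_len(neeg), ] +
      rep(cfa, each = neeg)
  }

  artifacts <- data.frame(t0_s = numeric(0), t1_s = numeric(0),
                          channel = character(0), amplitude_uv = numeric(0))
  if (cfg$artifact_rate_per_min > 0) {
    n_art <- stats::rpois(1, cfg$artifact_rate_per_min * cfg$duration_s / 60)
    if (n_art > 0) {
      t0 <- sort(stats::runif(n_art, 0, cfg$duration_s - 0.3))
      ch <- sample(cfg$channel_labels, n_art, replace = TRUE)
      sgn <- sample(c(-1, 1), n_art, replace = TRUE)
      for (k in seq_len(n_art)) {
        idx <- samp_range(t0[k], t0[k] + 0.2, fs) + 1L
        idx <- idx[idx >= 1L & idx <= nsamp]
        row <- match(ch[k], labs)
        sig[row, idx] <- sig[row, idx] + sgn[k] * cfg$artifact_amplitude_uv
      }
      artifacts <- data.frame(t0_s = t0, t1_s = t0 + 0.2, channel = ch,
                              amplitude_uv = sgn * cfg$artifact_amplitude_uv)
    }
  }

  new_recording(sig, labs, fs, ecg_label = cfg$ecg_label,
                subject_id = subject_id, annotations = annotations,
                meta = list(r_peaks_s = beat_t, beat_amplitudes_uv = amp,
                            artifacts = artifacts, config = cfg),
                validate = FALSE)
}
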
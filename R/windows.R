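#' Epoching, rejection and measurement windows for the HEP
#'
#' Bundles every timing constant of the HEP derivation: the R-locked epoch
#' spans 0.4 s before to 0.8 s after the R wave; the baseline is the mean
#' voltage 0.35 to 0.1 s before the R wave; the HEP amplitude is the mean of
#' the baseline-corrected average over 0.455 to 0.595 s after the R wave.
#' Epochs are rejected when the preceding R-R interval is shorter than
#' `min_rr_ms` (guards against contamination by the next QRS complex) or when
#' the within-epoch peak-to-peak range on any analysis channel strictly
#' exceeds `reject_ptp_uv`.  A segment average built from fewer than
#' `min_epochs` usable epochs is flagged invalid and excluded downstream.
#'
#' @param epoch_start_s,epoch_end_s epoch limits relative to the R wave (s).
#' @param baseline_start_s,baseline_end_s baseline window (s, negative = pre-R).
#' @param measure_start_s,measure_end_s measurement window (s post-R).
#' @param reject_ptp_uv peak-to-peak rejection threshold (µV, strict >).
#' @param min_rr_ms minimum R-R interval retained (ms, strict < removed).
#' @param min_epochs minimum usable epochs for a valid average.
#' @param ptp_mode `"peak_to_peak"` (range within epoch) or `"max_abs"`
#'   (maximum absolute voltage); the former is the default reading of
#'   "maximum potential difference".
#' @return an object of class `hep_windows`.
#' @export
hep_windows <- function(epoch_start_s = -0.400, epoch_end_s = 0.800,
                        baseline_start_s = -0.350, baseline_end_s = -0.100,
                        measure_start_s = 0.455, measure_end_s = 0.595,
                        reject_ptp_uv = 100, min_rr_ms = 700,
                        min_epochs = 60, ptp_mode = c("peak_to_peak", "max_abs")) {
  ptp_mode <- match.arg(ptp_mode)
  w <- list(epoch_start_s = epoch_start_s, epoch_end_s = epoch_end_s,
            baseline_start_s = baseline_start_s, baseline_end_s = baseline_end_s,
            measure_start_s = measure_start_s, measure_end_s = measure_end_s,
            reject_ptp_uv = reject_ptp_uv, min_rr_ms = min_rr_ms,
            min_epochs = min_epochs, ptp_mode = ptp_mode)
  stopifnot(w$epoch_start_s < w$baseline_start_s,
            w$baseline_start_s < w$baseline_end_s,
            w$baseline_end_s < 0,
            0 < w$measure_start_s,
            w$measure_start_s < w$measure_end_s,
            w$measure_end_s <= w$epoch_end_s,
            w$reject_ptp_uv > 0, w$min_rr_ms > 0, w$min_epochs >= 1)
  structure(w, class = "hep_windows")
}

# 0-based sample offsets (relative to the R-peak sample) for the three
# windows at a given sampling rate.  The epoch and baseline are half-open
# [round(t0*fs), round(t1*fs)); the measurement window includes both endpoint
# samples after rounding.
window_offsets <- function(w, fs) {
  list(
    epoch    = samp_range(w$epoch_start_s, w$epoch_end_s, fs),
    baseline = samp_range(w$baseline_start_s, w$baseline_end_s, fs),
    measure  = seq.int(sec_to_samp(w$measure_start_s, fs),
                       sec_to_samp(w$measure_end_s, fs))
  )
}
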
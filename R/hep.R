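# R-locked epoching, rejection, back-averaging and HEP amplitudes.

# Internal container: epochs as a channels x samples x epochs array plus
# the epoch accounting accumulated so far.
new_epoch_set <- function(data, channels, fs, offsets, peak_times_s,
                          n_total, n_rejected_rr, n_dropped_bounds,
                          n_rejected_ptp = 0L) {
  structure(list(data = data, channels = channels, fs = fs,
                 offsets = offsets, peak_times_s = peak_times_s,
                 n_total = n_total, n_rejected_rr = n_rejected_rr,
                 n_dropped_bounds = n_dropped_bounds,
                 n_rejected_ptp = n_rejected_ptp),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d ch x %d samples); total %d, RR-rejected %d, bounds-dropped %d, ptp-rejected %d\n",
              n_epochs(x), length(x$channels), length(x$offsets),
              x$n_total, x$n_rejected_rr, x$n_dropped_bounds, x$n_rejected_ptp))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es an `epoch_set`.
#' @return integer count.
#' @export
n_epochs <- function(es) dim(es$data)[3]

#' Extract R-locked epochs from a recording
#'
#' One epoch per keepable R peak: the short-R-R mask ([rr_keep_mask()]) is
#' applied first, then epochs whose window would cross the recording (or
#' segment) bounds are dropped and counted separately.  Samples run from
#' `epoch_start_s` to `epoch_end_s` around each R-peak sample on all
#' analysis channels.
#'
#' @param rec a [new_recording()] (a whole recording or a segment slice).
#' @param peaks an `rpeak_series` with times relative to `rec`'s start.
#' @param w a [hep_windows()].
#' @param channels analysis channels (default: all EEG channels).
#' @return an `epoch_set`; zero epochs is not an error.
#' @export
extract_epochs <- function(rec, peaks, w = hep_windows(),
                           channels = eeg_labels(rec)) {
  fs <- rec$sampling_rate_hz
  offs <- window_offsets(w, fs)$epoch
  nsamp <- n_samples(rec)
  t <- peaks$peak_times_s
  n_total <- length(t)
  mask <- rr_keep_mask(peaks, min_rr_ms = w$min_rr_ms,
                       end_s = nsamp / fs, epoch_end_s = w$epoch_end_s)
  n_rr <- sum(!mask)
  tk <- t[mask]
  p <- sec_to_samp(tk, fs)  # 0-based R-peak samples
  fits <- p + offs[1] >= 0L & p + offs[length(offs)] <= nsamp - 1L
  n_bounds <- sum(!fits)
  tk <- tk[fits]; p <- p[fits]
  nk <- length(p)
  arr <- if (nk > 0) {
    gather_epochs(rec$signal, as.integer(p), as.integer(offs),
                  match(channels, rownames(rec$signal)))
  } else array(0, dim = c(length(channels), length(offs), 0L))
  new_epoch_set(arr, channels, fs, offs, tk, n_total, n_rr, n_bounds)
}

#' Reject epochs by within-epoch amplitude
#'
#' An epoch is removed iff its amplitude criterion on *any* analysis
#' channel strictly exceeds `reject_ptp_uv`: peak-to-peak range over the
#' full epoch window by default, or maximum absolute voltage when the
#' windows were built with `ptp_mode = "max_abs"`.  An epoch measuring
#' exactly at the threshold is kept.
#'
#' @param es an `epoch_set`.
#' @param w a [hep_windows()].
#' @return the filtered `epoch_set` with `n_rejected_ptp` updated.
#' @export
reject_by_amplitude <- function(es, w = hep_windows()) {
  ne <- n_epochs(es)
  if (ne == 0) return(es)
  ext <- epoch_extremes(es$data)
  crit <- if (w$ptp_mode == "max_abs") pmax(abs(ext$hi), abs(ext$lo)) else
    ext$hi - ext$lo
  epoch_crit <- apply(crit, 2, max)   # worst channel per epoch
  bad <- epoch_crit > w$reject_ptp_uv
  out <- es
  if (any(bad)) {
    out$data <- es$data[, , !bad, drop = FALSE]
    out$peak_times_s <- es$peak_times_s[!bad]
    out$n_rejected_ptp <- es$n_rejected_ptp + sum(bad)
  }
  out
}

# Canonical epoch order (by anchor time) so results are invariant to the
# order epochs arrive in; resampled index vectors are sorted for the same
# reason.
canonical_order <- function(es) order(es$peak_times_s)

# Mean waveform over a set of epoch indices, channels x samples.
epoch_mean <- function(es, idx) {
  out <- mean_epochs(es$data, as.integer(idx))
  rownames(out) <- es$channels
  out
}

baseline_correct <- function(wave, es, w) {
  boffs <- window_offsets(w, es$fs)$baseline
  bcols <- match(boffs, es$offsets)
  wave - rowMeans(wave[, bcols, drop = FALSE])
}

window_amplitudes <- function(wave, es, w) {
  moffs <- window_offsets(w, es$fs)$measure
  mcols <- match(moffs, es$offsets)
  rowMeans(wave[, mcols, drop = FALSE])
}

#' Back-average, baseline-correct and measure the HEP
#'
#' Sample-wise mean over the usable epochs, followed by per-channel
#' subtraction of the mean over the pre-R baseline window; the per-channel
#' HEP amplitude is the mean of the corrected average over the post-R
#' measurement window, and the compound HEP is the sum of the C4 and F8
#' amplitudes.  The result is valid only when at least `min_epochs` epochs
#' survived rejection.
#'
#' @param es an `epoch_set` (normally after [reject_by_amplitude()]).
#' @param w a [hep_windows()].
#' @param compound_channels leads summed into the compound HEP.
#' @return list of class `hep_result`: `channel_waveforms` (channels x
#'   samples, µV, baseline-corrected), `channel_amplitudes_uv`,
#'   `compound_amplitude_uv` (`NA` + flag if a compound lead is missing),
#'   epoch accounting counts, and `valid`.
#' @export
average_and_baseline <- function(es, w = hep_windows(),
                                 compound_channels = c("C4", "F8")) {
  ne <- n_epochs(es)
  valid <- ne >= w$min_epochs
  if (ne == 0) {
    wave <- matrix(NA_real_, length(es$channels), length(es$offsets),
                   dimnames = list(es$channels, NULL))
    amps <- stats::setNames(rep(NA_real_, length(es$channels)), es$channels)
    compound <- NA_real_
  } else {
    wave <- epoch_mean(es, canonical_order(es))
    wave <- baseline_correct(wave, es, w)
    amps <- window_amplitudes(wave, es, w)
    missing_cmp <- setdiff(compound_channels, es$channels)
    compound <- if (length(missing_cmp)) NA_real_ else
      sum(amps[compound_channels])
    if (length(missing_cmp))
      warning("compound HEP undefined; missing lead(s): ",
              paste(missing_cmp, collapse = ", "))
  }
  structure(list(channel_waveforms = wave,
                 channel_amplitudes_uv = amps,
                 compound_amplitude_uv = compound,
                 n_epochs_total = es$n_total,
                 n_rejected_rr = es$n_rejected_rr,
                 n_dropped_bounds = es$n_dropped_bounds,
                 n_rejected_ptp = es$n_rejected_ptp,
                 n_used = ne, valid = valid,
                 time_s = es$offsets / es$fs),
            class = "hep_result")
}

#' @export
print.hep_result <- function(x, ...) {
  cat(sprintf("<hep_result> compound %.3f µV; used %d / %d epochs (RR %d, bounds %d, ptp %d); %s\n",
              x$compound_amplitude_uv, x$n_used, x$n_epochs_total,
              x$n_rejected_rr, x$n_dropped_bounds, x$n_rejected_ptp,
              if (x$valid) "valid" else "INVALID (<min epochs)"))
  invisible(x)
}

#' Compound HEP of one epoch subset
#'
#' Average the given epochs, baseline-correct, and return the sum of the
#' C4 and F8 window-mean amplitudes.  Used by the within-subject epoch
#' bootstrap.
#'
#' @param es an `epoch_set`.
#' @param idx epoch indices (with repetitions allowed); epochs are averaged
#'   in the order given.
#' @param w a [hep_windows()].
#' @param compound_channels leads summed into the compound HEP.
#' @return compound amplitude in µV.
#' @export
compound_hep <- function(es, idx = seq_len(n_epochs(es)), w = hep_windows(),
                         compound_channels = c("C4", "F8")) {
  stopifnot(n_epochs(es) >= 1, all(idx >= 1), all(idx <= n_epochs(es)))
  wave <- epoch_mean(es, idx)
  wave <- baseline_correct(wave, es, w)
  amps <- window_amplitudes(wave, es, w)
  sum(amps[compound_channels])
}
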
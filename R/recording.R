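#' The minimum scalp montage required for inclusion
#'
#' Ten 10-20 electrodes; recordings missing any of these are rejected at
#' load time.  Supplementary electrodes are ignored, never an error.
#' @export
MIN_MONTAGE <- c("Fz", "Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "Cz", "C4")

#' Symptom report categories used in the tilt-table arm
#' @export
SYMPTOM_CATEGORIES <- c("cardiac", "respiratory", "abdominal", "cephalic",
                        "peripheral", "psychological")

# Canonical annotation table with zero rows; every Recording carries one.
empty_annotations <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             kind = character(0), label = character(0),
             symptom_category = character(0), semiology = character(0),
             event_type = character(0), event_id = integer(0),
             stringsAsFactors = FALSE)
}

#' Build an annotation table
#'
#' @param onset_s onset times in seconds from record start (>= 0).
#' @param duration_s durations in seconds (>= 0).
#' @param kind one of `seizure_onset`, `seizure_offset`, `interictal_mark`,
#'   `symptom_report`, `other`.
#' @param label free text as stored in the EDF+ annotation stream.
#' @param symptom_category symptom category for `symptom_report` rows,
#'   `"none"` otherwise.
#' @param semiology `motile` / `non_motile` / `none`.
#' @param event_type `FS` / `ES` / `functional_syncope` / `VVS` / `none`.
#' @param event_id integer pairing seizure onset/offset rows.
#' @return a data.frame with one row per annotation, sorted by onset.
#' @export
annotations <- function(onset_s, duration_s = 0, kind = "other", label = "",
                        symptom_category = "none", semiology = "none",
                        event_type = "none", event_id = NA_integer_) {
  n <- length(onset_s)
  df <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = rep_len(as.numeric(duration_s), n),
                   kind = rep_len(as.character(kind), n),
                   label = rep_len(as.character(label), n),
                   symptom_category = rep_len(as.character(symptom_category), n),
                   semiology = rep_len(as.character(semiology), n),
                   event_type = rep_len(as.character(event_type), n),
                   event_id = rep_len(as.integer(event_id), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$onset_s >= 0), all(df$duration_s >= 0),
            all(df$kind %in% c("seizure_onset", "seizure_offset",
                               "interictal_mark", "symptom_report", "other")))
  bad <- xor(df$kind == "symptom_report", df$symptom_category != "none")
  if (any(bad)) stop("symptom_category must be set exactly for symptom_report annotations")
  df[order(df$onset_s), , drop = FALSE]
}

#' Construct a Recording
#'
#' The raw unit every pipeline stage consumes: a channels-by-samples matrix
#' in microvolts together with its montage, sampling rate and annotation
#' stream.
#'
#' @param signal numeric matrix, channels x samples, in µV; rownames are
#'   ignored (labels come from `channel_labels`).
#' @param channel_labels channel names, in matrix row order.
#' @param sampling_rate_hz sampling rate shared by all channels.
#' @param ecg_label label of the ECG lead used for R-peak detection.
#' @param subject_id subject identifier.
#' @param annotations annotation table (see [annotations()]).
#' @param start_time record start, POSIXct or seconds; informational.
#' @param meta free-form list (the synthetic generator stores ground truth
#'   here).
#' @param validate check finiteness and normalize labels (internal callers
#'   that construct signals themselves skip this).
#' @return an object of class `recording`.
#' @export
new_recording <- function(signal, channel_labels, sampling_rate_hz,
                          ecg_label = "ECG", subject_id = "S01",
                          annotations = empty_annotations(),
                          start_time = 0, meta = list(), validate = TRUE) {
  signal <- as.matrix(signal)
  stopifnot(nrow(signal) == length(channel_labels), sampling_rate_hz > 0)
  if (validate) {
    stopifnot(all(is.finite(signal)))
    channel_labels <- normalize_channel_labels(channel_labels)
    ecg_label <- normalize_channel_labels(ecg_label)
  }
  if (!ecg_label %in% channel_labels)
    stop("ECG lead '", ecg_label, "' not present among channels: ",
         paste(channel_labels, collapse = ", "))
  if (!identical(rownames(signal), channel_labels))
    rownames(signal) <- channel_labels
  structure(list(subject_id = subject_id, channel_labels = channel_labels,
                 sampling_rate_hz = sampling_rate_hz, signal = signal,
                 ecg_label = ecg_label, annotations = annotations,
                 start_time = start_time, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$subject_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate_hz, ncol(x$signal) / x$sampling_rate_hz,
              nrow(x$annotations)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signal)

#' Recording duration in seconds
#' @param rec a [new_recording()].
#' @return length of the recording in seconds.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$sampling_rate_hz

#' EEG analysis channels of a recording
#'
#' Every channel except the ECG lead.
#' @param rec a [new_recording()].
#' @return character vector of channel labels.
#' @export
eeg_labels <- function(rec) setdiff(rec$channel_labels, rec$ecg_label)

#' The ECG lead of a recording
#' @param rec a [new_recording()].
#' @return numeric vector, the ECG signal in µV.
#' @export
ecg_signal <- function(rec) rec$signal[rec$ecg_label, ]

#' Normalize channel label dialects
#'
#' Strips case/whitespace and modality prefixes ("EEG Fp1-REF" -> "Fp1") and
#' maps ECG dialects ("EKG", "ECG1-ECG2") onto a canonical label via an
#' alias table.
#'
#' @param labels character vector of raw channel labels.
#' @param aliases named character vector mapping lower-cased raw labels to
#'   canonical ones; merged over the built-in ECG aliases.
#' @return canonical labels, same length.
#' @export
normalize_channel_labels <- function(labels, aliases = NULL) {
  builtin <- c(ekg = "ECG", ecg = "ECG", "ecg1-ecg2" = "ECG", ecg1 = "ECG",
               ecg2 = "ECG2", ekg1 = "ECG")
  if (!is.null(aliases)) {
    names(aliases) <- tolower(names(aliases))
    builtin[names(aliases)] <- aliases
  }
  out <- vapply(labels, function(lb) {
    s <- trimws(lb)
    s <- sub("^(EEG|POL|REF)[ .:]+", "", s, ignore.case = TRUE)
    s <- sub("-(REF|LE|AVG)$", "", s, ignore.case = TRUE)
    s <- trimws(s)
    key <- tolower(s)
    if (key %in% names(builtin)) return(unname(builtin[key]))
    canon <- MIN_MONTAGE[match(key, tolower(MIN_MONTAGE))]
    if (!is.na(canon)) canon else s
  }, character(1))
  unname(out)
}

#' Check a recording against a required montage
#'
#' Report-only: extra channels are flagged as ignored, never an error, so a
#' recording with supplementary electrodes still passes.
#'
#' @param rec a [new_recording()] object.
#' @param required labels that must be present (default: the ten-electrode
#'   minimum montage plus the recording's ECG lead).
#' @return list with `ok`, `present`, `missing`, `ignored`.
#' @export
validate_montage <- function(rec, required = c(MIN_MONTAGE, rec$ecg_label)) {
  required <- normalize_channel_labels(required)
  present <- intersect(required, rec$channel_labels)
  missing <- setdiff(required, rec$channel_labels)
  ignored <- setdiff(rec$channel_labels, required)
  structure(list(ok = length(missing) == 0L, present = present,
                 missing = missing, ignored = ignored),
            class = "montage_report")
}

#' @export
print.montage_report <- function(x, ...) {
  cat(if (x$ok) "montage OK" else
        paste0("montage FAIL, missing: ", paste(x$missing, collapse = ", ")))
  if (length(x$ignored))
    cat("; ignored:", paste(x$ignored, collapse = ", "))
  cat("\n")
  invisible(x)
}

# Extract a half-open time slice [t0, t1) of a recording; annotations are
# re-expressed relative to the slice start and clipped to it.
slice_recording <- function(rec, t0_s, t1_s) {
  fs <- rec$sampling_rate_hz
  idx <- samp_range(t0_s, t1_s, fs) + 1L
  idx <- idx[idx >= 1L & idx <= n_samples(rec)]
  ann <- rec$annotations
  keep <- ann$onset_s + ann$duration_s >= t0_s & ann$onset_s < t1_s
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann)) ann$onset_s <- pmax(ann$onset_s - t0_s, 0)
  new_recording(rec$signal[, idx, drop = FALSE], rec$channel_labels, fs,
                ecg_label = rec$ecg_label, subject_id = rec$subject_id,
                annotations = ann, start_time = rec$start_time,
                meta = rec$meta, validate = FALSE)
}
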
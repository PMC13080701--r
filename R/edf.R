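# Minimal EDF+ (continuous) reader/writer.
#
# EDF stores a 256-byte fixed header, a 256-byte header per signal, then
# data records of interleaved little-endian 16-bit samples.  EDF+ adds an
# "EDF Annotations" signal whose bytes hold time-stamped annotation lists
# (TALs): "+onset\x15duration\x14text\x14\x00", the first TAL of each record
# being a bare timekeeping stamp.  Signals are scaled between the physical
# and digital ranges declared in the header; clinical EEG exports typically
# use digital extrema of +/-32767 and physical units of microvolts.

fmt_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too wide: ", s)
  formatC(s, width = -width)  # left-justified, space padded
}

fmt_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(fmt_field(s, 8))
  }
  stop("cannot format ", x, " in 8 bytes")
}

# Serialize annotations into one TAL byte vector per data record; each
# annotation lands in the record containing its onset.
build_tals <- function(ann, n_records, record_dur_s) {
  payload <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    t0 <- (r - 1) * record_dur_s
    bytes <- c(utf8ToInt(sprintf("+%g\x14\x14", t0)), 0L)  # timekeeping TAL
    if (nrow(ann)) {
      here <- which(ann$onset_s >= t0 & ann$onset_s < t0 + record_dur_s)
      for (i in here) {
        dur <- if (ann$duration_s[i] > 0) sprintf("\x15%g", ann$duration_s[i]) else ""
        bytes <- c(bytes,
                   utf8ToInt(sprintf("+%.4f%s\x14%s\x14",
                                     ann$onset_s[i], dur, ann$label[i])), 0L)
      }
    }
    payload[[r]] <- bytes
  }
  payload
}

#' Write a recording to an EDF+ file
#'
#' Signals are stored as 16-bit integers scaled to a symmetric per-channel
#' physical range in µV with digital extrema ±32767; annotations are stored
#' as EDF+ TAL records.  The record duration is 1 s, so the sampling rate
#' must be a whole number of Hz.
#'
#' @param rec a [new_recording()] object.
#' @param path output file path.
#' @param digital_max digital extremum (default 32767; the digital range is
#'   symmetric, so min = -max).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, digital_max = 32767) {
  fs <- rec$sampling_rate_hz
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  nchan <- nrow(rec$signal)
  record_dur <- 1
  n_records <- ceiling(n_samples(rec) / fs)
  pad <- n_records * fs - n_samples(rec)
  sig <- if (pad > 0) cbind(rec$signal, matrix(0, nchan, pad)) else rec$signal

  phys_max <- pmax(apply(abs(sig), 1, max) * (1 + 1e-6), 1)
  dig <- round(sweep(sig, 1, digital_max / phys_max, `*`))
  storage.mode(dig) <- "integer"

  tals <- build_tals(rec$annotations, n_records, record_dur)
  ann_bytes <- max(32L, max(vapply(tals, length, integer(1))))
  ann_bytes <- ann_bytes + ann_bytes %% 2L  # even -> whole 2-byte samples
  ann_ns <- ann_bytes %/% 2L

  ns <- nchan + 1L
  header_bytes <- 256L * (ns + 1L)
  labels <- c(rec$channel_labels, "EDF Annotations")
  labels[seq_len(nchan)] <- ifelse(labels[seq_len(nchan)] == rec$ecg_label,
                                   labels[seq_len(nchan)],
                                   paste("EEG", labels[seq_len(nchan)]))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(fmt_field("0", 8))
  wr(fmt_field(paste("X X X", rec$subject_id), 80))
  wr(fmt_field("Startdate X X X X", 80))
  wr(fmt_field("01.01.00", 8)); wr(fmt_field("00.00.00", 8))
  wr(fmt_field(header_bytes, 8))
  wr(fmt_field("EDF+C", 44))
  wr(fmt_field(n_records, 8))
  wr(fmt_num8(record_dur))
  wr(fmt_field(ns, 4))
  for (lb in labels) wr(fmt_field(lb, 16))
  for (i in seq_len(ns)) wr(fmt_field("", 80))                      # transducer
  for (i in seq_len(ns)) wr(fmt_field(if (i <= nchan) "uV" else "", 8))
  for (i in seq_len(ns)) wr(if (i <= nchan) fmt_num8(-phys_max[i]) else fmt_num8(-1))
  for (i in seq_len(ns)) wr(if (i <= nchan) fmt_num8(phys_max[i]) else fmt_num8(1))
  for (i in seq_len(ns)) wr(fmt_num8(-digital_max))
  for (i in seq_len(ns)) wr(fmt_num8(digital_max))
  for (i in seq_len(ns)) wr(fmt_field("HP:0.016Hz LP:128Hz", 80))   # acquisition
  for (i in seq_len(ns)) wr(fmt_num8(if (i <= nchan) fs else ann_ns))
  for (i in seq_len(ns)) wr(fmt_field("", 32))

  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
    tal <- tals[[r]]
    writeBin(as.integer(c(tal, rep(0L, ann_bytes - length(tal)))), con,
             size = 1L)
  }
  invisible(path)
}

parse_tal_bytes <- function(bytes) {
  # Split the byte stream on NUL into TALs, each "onset[\x15dur]\x14text\x14".
  out <- list()
  runs <- split(bytes, cumsum(bytes == 0L))
  tals <- vapply(runs, function(b) rawToChar(as.raw(b[b != 0L])), character(1))
  for (tal in tals) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    dur <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else 0
    texts <- parts[-1]
    texts <- texts[nzchar(texts)]
    for (tx in texts)
      out[[length(out) + 1L]] <- list(onset = onset, dur = dur, text = tx)
  }
  out
}

# Default rules translating annotation label text back into typed fields.
# Each rule: pattern (regex on the label), kind, and optional fixed fields;
# named capture-like extraction is handled via key=value tokens in the text.
default_annotation_rules <- function() {
  list(
    list(pattern = "^interictal", kind = "interictal_mark"),
    list(pattern = "^seizure_onset", kind = "seizure_onset"),
    list(pattern = "^seizure_offset", kind = "seizure_offset"),
    list(pattern = "^symptom", kind = "symptom_report")
  )
}

#' Load annotation mapping rules from a YAML file
#'
#' Site-specific annotation dialects are translated into typed events by a
#' list of rules, each with a `pattern` (regular expression on the label
#' text) and a `kind`, plus optional fixed `event_type` / `semiology` /
#' `symptom_category` fields.
#'
#' @param path YAML file containing a list of rules.
#' @return a rule list usable as `read_edf(..., annotation_rules = )`.
#' @export
read_annotation_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  stopifnot(is.list(rules), all(vapply(rules, function(r)
    !is.null(r$pattern) && !is.null(r$kind), logical(1))))
  rules
}

kv_token <- function(text, key, default) {
  m <- regmatches(text, regexec(paste0(key, "=([A-Za-z_0-9]+)"), text))[[1]]
  if (length(m) == 2) m[2] else default
}

apply_annotation_rules <- function(tal_list, rules) {
  if (!length(tal_list)) return(empty_annotations())
  rows <- lapply(tal_list, function(a) {
    rule <- list()
    for (r in rules) if (grepl(r$pattern, a$text)) { rule <- r; break }
    kind <- rule$kind %||% "other"
    data.frame(
      onset_s = a$onset, duration_s = a$dur, kind = kind, label = a$text,
      symptom_category = if (kind == "symptom_report")
        rule$symptom_category %||% kv_token(a$text, "category", "cardiac")
      else "none",
      semiology = rule$semiology %||% kv_token(a$text, "semiology", "none"),
      event_type = rule$event_type %||% kv_token(a$text, "type", "none"),
      event_id = as.integer(kv_token(a$text, "id", NA)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$onset_s >= 0 & is.finite(df$onset_s), , drop = FALSE]
  df[order(df$onset_s), , drop = FALSE]
}

#' Read an EDF/EDF+ file into a recording
#'
#' Samples are converted to physical units using the per-signal header
#' scaling; channel labels are normalized (case, whitespace, "EEG " prefix,
#' ECG dialects); EDF+ TAL annotations are parsed and mapped to typed events
#' through `annotation_rules`.
#'
#' @param path EDF file.
#' @param ecg_label preferred ECG lead after normalization; defaults to the
#'   first ECG-labeled channel.
#' @param annotation_rules rule list (see [read_annotation_rules()]).
#' @param require_montage validate the ten-electrode minimum montage and
#'   raise an error naming any missing lead (default TRUE).
#' @return a [new_recording()] object.
#' @export
read_edf <- function(path, ecg_label = NULL,
                     annotation_rules = default_annotation_rules(),
                     require_montage = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); subj <- rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_ann <- grepl("EDF Annotations", labels, fixed = TRUE)
  sig_idx <- which(!is_ann)
  if (!length(sig_idx)) stop("EDF file contains no signal channels")
  fs <- nsamp[sig_idx] / record_dur
  if (length(unique(fs)) != 1L)
    stop("channels with mismatched sampling rates: ",
         paste(unique(fs), collapse = ", "), " Hz")
  fs <- fs[1]

  sigs <- lapply(seq_len(ns), function(i) {
    if (is_ann[i]) vector("list", n_records) else
      matrix(0L, nsamp[i], n_records)
  })
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        sigs[[i]][[r]] <- readBin(con, "integer", n = 2L * nsamp[i],
                                  size = 1L, signed = FALSE)
      } else {
        sigs[[i]][, r] <- readBin(con, "integer", n = nsamp[i], size = 2L,
                                  signed = TRUE, endian = "little")
      }
    }
  }

  mat <- do.call(rbind, lapply(sig_idx, function(i) {
    scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    as.numeric(sigs[[i]]) * scale + (pmin_[i] - dmin_[i] * scale)
  }))

  tal_list <- list()
  for (i in which(is_ann))
    for (r in seq_len(n_records))
      tal_list <- c(tal_list, parse_tal_bytes(sigs[[i]][[r]]))
  # drop bare timekeeping stamps (no text) already filtered; dedupe by order
  ann <- apply_annotation_rules(tal_list, annotation_rules)

  labs <- normalize_channel_labels(labels[sig_idx])
  ecg <- if (!is.null(ecg_label)) normalize_channel_labels(ecg_label) else {
    hit <- grep("^ECG", labs, value = TRUE)
    if (!length(hit)) stop("no ECG channel found among: ",
                           paste(labs, collapse = ", "))
    hit[1]
  }
  subj_id <- sub("^X X X ?", "", subj)
  rec <- new_recording(mat, labs, fs, ecg_label = ecg,
                       subject_id = if (nzchar(subj_id)) subj_id else "unknown",
                       annotations = ann)
  if (require_montage) {
    rep <- validate_montage(rec)
    if (!rep$ok)
      stop("recording is missing required lead(s): ",
           paste(rep$missing, collapse = ", "))
  }
  rec
}
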
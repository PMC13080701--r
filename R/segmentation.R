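# Annotation-driven segmentation: peri-ictal windows (seizure arm) and
# pre-symptom vs baseline windows (tilt-table arm), plus the within-subject
# epoch bootstrap and the subject-level summary table.

segment_row <- function(subject_id, t0, t1, role, event_type = "none",
                        semiology = "none", symptom_category = "none",
                        event_id = NA_integer_) {
  data.frame(subject_id = subject_id, t0_s = t0, t1_s = t1, role = role,
             event_type = event_type, semiology = semiology,
             symptom_category = symptom_category,
             event_id = as.integer(event_id), stringsAsFactors = FALSE)
}

empty_segments <- function() segment_row(character(0), numeric(0), numeric(0),
                                         character(0))[0, ]

#' Peri-ictal analysis segments from a recording's annotations
#'
#' Pairs seizure onset/offset annotations into events (by `event_id`, else
#' by order), drops events shorter than `min_event_s`, and emits for each
#' remaining event a preictal window `[onset - peri_s, onset)` truncated at
#' the recording start and at the previous event's offset, and a postictal
#' window `[offset, offset + peri_s)` truncated at the recording end and at
#' the next event's onset.  The interictal segment is the longest annotated
#' artifact-free wakeful interval of at least `min_interictal_s`
#' (ties broken by earliest onset); a recording without one yields no
#' interictal row and the returned table carries `attr(, "no_interictal")`.
#' Events with mixed or unclassifiable semiology are dropped with a count
#' in `attr(, "n_dropped_semiology")`.
#'
#' @param rec a [new_recording()].
#' @param min_event_s minimum event duration retained (s).
#' @param peri_s maximum preictal/postictal extent (s).
#' @param min_interictal_s minimum interictal duration (s).
#' @return a segment table (one row per segment).
#' @export
select_event_segments <- function(rec, min_event_s = 5, peri_s = 300,
                                  min_interictal_s = 300) {
  ann <- rec$annotations
  end_s <- duration_s(rec)
  on <- ann[ann$kind == "seizure_onset", , drop = FALSE]
  off <- ann[ann$kind == "seizure_offset", , drop = FALSE]
  if (nrow(on) == 0 && !any(ann$kind == "interictal_mark"))
    stop("recording has neither seizure annotations nor an interictal mark")

  n_dropped_sem <- 0L
  segs <- list()
  if (nrow(on)) {
    ids <- if (!anyNA(on$event_id)) on$event_id else seq_len(nrow(on))
    events <- do.call(rbind, lapply(seq_len(nrow(on)), function(i) {
      id <- ids[i]
      mt <- if (!anyNA(off$event_id)) which(off$event_id == id) else i
      if (!length(mt) || mt > nrow(off)) return(NULL)
      data.frame(onset = on$onset_s[i], offset = off$onset_s[mt[1]],
                 event_type = on$event_type[i], semiology = on$semiology[i],
                 event_id = id, stringsAsFactors = FALSE)
    }))
    events <- events[order(events$onset), , drop = FALSE]
    mixed <- !(events$semiology %in% c("motile", "non_motile", "none"))
    n_dropped_sem <- sum(mixed)
    events <- events[!mixed, , drop = FALSE]
    events <- events[events$offset - events$onset >= min_event_s, ,
                     drop = FALSE]
    if (nrow(events)) {
      prev_off <- c(-Inf, events$offset[-nrow(events)])
      next_on <- c(events$onset[-1], Inf)
      for (i in seq_len(nrow(events))) {
        e <- events[i, ]
        pre0 <- max(e$onset - peri_s, 0, prev_off[i])
        if (e$onset > pre0)
          segs[[length(segs) + 1L]] <-
            segment_row(rec$subject_id, pre0, e$onset, "preictal",
                        e$event_type, e$semiology, event_id = e$event_id)
        post1 <- min(e$offset + peri_s, end_s, next_on[i])
        if (post1 > e$offset)
          segs[[length(segs) + 1L]] <-
            segment_row(rec$subject_id, e$offset, post1, "postictal",
                        e$event_type, e$semiology, event_id = e$event_id)
      }
    }
  }

  ii <- ann[ann$kind == "interictal_mark" &
              ann$duration_s >= min_interictal_s, , drop = FALSE]
  no_interictal <- nrow(ii) == 0
  if (!no_interictal) {
    pick <- ii[order(-ii$duration_s, ii$onset_s), , drop = FALSE][1, ]
    segs[[length(segs) + 1L]] <-
      segment_row(rec$subject_id, pick$onset_s,
                  min(pick$onset_s + pick$duration_s, end_s), "interictal")
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  attr(out, "no_interictal") <- no_interictal
  attr(out, "n_dropped_semiology") <- n_dropped_sem
  out
}

# Merge overlapping/adjacent half-open intervals given as a 2-column matrix.
merge_intervals <- function(t0, t1) {
  o <- order(t0)
  t0 <- t0[o]; t1 <- t1[o]
  m0 <- t0[1]; m1 <- t1[1]
  out <- NULL
  for (i in seq_along(t0)[-1]) {
    if (t0[i] <= m1) m1 <- max(m1, t1[i])
    else { out <- rbind(out, c(m0, m1)); m0 <- t0[i]; m1 <- t1[i] }
  }
  rbind(out, c(m0, m1))
}

#' Pre-symptom and baseline windows from symptom-report annotations
#'
#' For every symptom report, the pre-symptom window is the `window_s`
#' (default 2 min) ending at the report time; overlapping pre-symptom
#' windows of the same category are merged.  The per-category baseline is
#' every interval whose points all lie more than `window_s` before every
#' report of that category, i.e. `[0, min(report times) - window_s)`.  With
#' no reports the whole record is a single baseline (category `"none"`).
#'
#' @param rec a [new_recording()].
#' @param window_s pre-report window length (s).
#' @param per_category when `TRUE` (default) the baseline of a category
#'   excludes only that category's pre-report windows; when `FALSE` the
#'   baseline excludes the windows of every category.
#' @return a segment table with roles `pre_symptom` / `baseline`.
#' @export
select_symptom_windows <- function(rec, window_s = 120, per_category = TRUE) {
  ann <- rec$annotations
  rep_ <- ann[ann$kind == "symptom_report", , drop = FALSE]
  end_s <- duration_s(rec)
  if (nrow(rep_) == 0)
    return(segment_row(rec$subject_id, 0, end_s, "baseline",
                       symptom_category = "none"))
  segs <- list()
  for (cat in unique(rep_$symptom_category)) {
    tr <- rep_$onset_s[rep_$symptom_category == cat]
    m <- merge_intervals(pmax(tr - window_s, 0), tr)
    for (r in seq_len(nrow(m)))
      segs[[length(segs) + 1L]] <-
        segment_row(rec$subject_id, m[r, 1], m[r, 2], "pre_symptom",
                    symptom_category = cat)
    guard <- if (per_category) tr else rep_$onset_s
    b1 <- min(guard) - window_s
    if (b1 > 0)
      segs[[length(segs) + 1L]] <-
        segment_row(rec$subject_id, 0, b1, "baseline",
                    symptom_category = cat)
  }
  do.call(rbind, segs)
}

#' Within-subject bootstrapped compound HEP
#'
#' Resamples the available epochs with replacement `n_boot` times, computes
#' the compound HEP of each resample's average, and returns the mean of the
#' `n_boot` bootstrapped averages — a robust per-subject, per-condition HEP
#' estimate when few epochs are available.  Epochs are put in canonical
#' (anchor-time) order before resampling, so the value depends only on the
#' epoch contents and the seed, not on arrival order.
#'
#' @param es an `epoch_set` with at least one epoch.
#' @param n_boot number of resamples (default 20).
#' @param seed integer seed (derive per subject via [derive_seed()]).
#' @param w a [hep_windows()].
#' @return mean bootstrapped compound HEP in µV.
#' @export
bootstrap_subject_hep <- function(es, n_boot = 20, seed = 1L,
                                  w = hep_windows()) {
  ne <- n_epochs(es)
  if (ne == 0) stop("cannot bootstrap an empty epoch set")
  ord <- canonical_order(es)
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    # draw in canonical rank space and sort there, so both the resample and
    # the float summation order are invariant to epoch arrival order
    compound_hep(es, ord[sort(sample.int(ne, ne, replace = TRUE))], w)
  }, numeric(1))
  mean(vals)
}

# Concatenate epoch sets that share channels/offsets (pooling the epochs of
# several intervals of one role); accounting counts are summed.
combine_epoch_sets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (!length(sets)) return(NULL)
  base <- sets[[1]]
  if (length(sets) > 1) {
    stopifnot(all(vapply(sets, function(s)
      identical(s$offsets, base$offsets) &&
        identical(s$channels, base$channels), logical(1))))
    base$data <- array(unlist(lapply(sets, `[[`, "data")),
                       dim = c(length(base$channels), length(base$offsets),
                               sum(vapply(sets, n_epochs, integer(1)))))
    base$peak_times_s <- unlist(lapply(sets, `[[`, "peak_times_s"))
    for (f in c("n_total", "n_rejected_rr", "n_dropped_bounds",
                "n_rejected_ptp"))
      base[[f]] <- sum(vapply(sets, `[[`, numeric(1), f))
  }
  base
}

# Score one segment of a recording: slice, epoch against the R peaks that
# fall inside it, reject, average, and compute HRV from the same beats.
score_segment <- function(rec, peaks, t0, t1, w = hep_windows(),
                          keep_epochs = FALSE) {
  sub <- slice_recording(rec, t0, t1)
  inwin <- peaks$peak_times_s >= t0 & peaks$peak_times_s < t1
  pk <- new_rpeak_series(peaks$peak_times_s[inwin] - t0)
  es <- extract_epochs(sub, pk, w)
  es <- reject_by_amplitude(es, w)
  hep <- average_and_baseline(es, w)
  hrv <- compute_hrv(pk)
  list(hep = hep, hrv = hrv, epochs = if (keep_epochs) es else NULL)
}

# Per-segment score table for one subject's recording (seizure arm).
score_segments <- function(rec, segments, peaks, w = hep_windows()) {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    sc <- score_segment(rec, peaks, s$t0_s, s$t1_s, w)
    cbind(s, data.frame(
      compound_uv = sc$hep$compound_amplitude_uv,
      hep_valid = sc$hep$valid, n_used = sc$hep$n_used,
      n_total = sc$hep$n_epochs_total,
      n_rejected_rr = sc$hep$n_rejected_rr,
      n_rejected_ptp = sc$hep$n_rejected_ptp,
      n_dropped_bounds = sc$hep$n_dropped_bounds,
      mean_hr_bpm = sc$hrv$mean_hr_bpm, rmssd_ms = sc$hrv$rmssd_ms,
      lf_power = sc$hrv$lf_power, hf_power = sc$hrv$hf_power))
  })
  out <- do.call(rbind, rows)
  attr(out, "no_interictal") <- attr(segments, "no_interictal")
  out
}

#' Subject-level summary for the seizure arm
#'
#' Per-event compound-HEP changes (preictal minus interictal) are averaged
#' within each subject for each event type x semiology combination, so that
#' a subject contributes at most one value per comparison.  Events whose
#' preictal (or the subject's interictal) average is invalid (< minimum
#' epochs) are omitted from the subject mean.  Heart-rate change and HRV
#' change are computed on the same segments.
#'
#' @param scored a per-segment score table from `score_segments` (one
#'   subject) or several row-bound together.
#' @return one row per subject x event_type x semiology: HEP per role, HEP
#'   change, HR change, RMSSD per role.
#' @export
summarize_subject <- function(scored) {
  inter <- scored[scored$role == "interictal" & scored$hep_valid, ,
                  drop = FALSE]
  out <- list()
  for (sid in unique(scored$subject_id)) {
    ii <- inter[inter$subject_id == sid, , drop = FALSE]
    has_inter <- nrow(ii) > 0
    pre <- scored[scored$subject_id == sid & scored$role == "preictal", ,
                  drop = FALSE]
    for (et in unique(pre$event_type)) for (sem in unique(
      pre$semiology[pre$event_type == et])) {
      p <- pre[pre$event_type == et & pre$semiology == sem & pre$hep_valid, ,
               drop = FALSE]
      po <- scored[scored$subject_id == sid & scored$role == "postictal" &
                     scored$event_type == et & scored$semiology == sem &
                     scored$hep_valid, , drop = FALSE]
      hep_pre <- if (nrow(p)) mean(p$compound_uv) else NA_real_
      hep_int <- if (has_inter) mean(ii$compound_uv) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, event_type = et, semiology = sem,
        n_events = nrow(p),
        hep_interictal_uv = hep_int,
        hep_preictal_uv = hep_pre,
        hep_postictal_uv = if (nrow(po)) mean(po$compound_uv) else NA_real_,
        hep_change_uv = if (nrow(p) && has_inter) hep_pre - hep_int
                        else NA_real_,
        hr_change_bpm = if (nrow(p) && has_inter)
          mean(p$mean_hr_bpm) - mean(ii$mean_hr_bpm) else NA_real_,
        rmssd_interictal_ms = if (has_inter) mean(ii$rmssd_ms) else NA_real_,
        rmssd_preictal_ms = if (nrow(p)) mean(p$rmssd_ms) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
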
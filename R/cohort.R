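# Whole-cohort synthesis: one recording per subject with annotations and a
# ground-truth table, for both study arms.

#' Default seizure-arm cohort cells
#'
#' Encodes the directional hypotheses under study: motile functional
#' seizures are preceded by a compound-HEP decrease, non-motile functional
#' seizures by an increase, and epileptic seizures of either semiology by
#' no change.  Heart-rate changes are peri-ictal tachycardia of plausible
#' magnitude, uncorrelated with the HEP shifts.
#'
#' @param fs_motile_shift_uv,fs_nonmotile_shift_uv,es_shift_uv preictal
#'   per-lead HEP shifts per cell (µV; the compound change is twice this).
#' @param hr_change_bpm peri-ictal heart-rate change per cell.  The default
#'   is 0 (matched heart rates): because the heartbeat-locked response is
#'   periodic, a rate change moves the previous beat's response relative to
#'   the pre-R baseline window and thereby couples into the measured HEP
#'   change — a confound real HEPs share and that the ANCOVA's heart-rate
#'   covariate is there to absorb.  Set nonzero values to study exactly
#'   that confound.
#' @return data.frame of cells (group, semiology, shift_uv, hr_change_bpm).
#' @export
seizure_cells <- function(fs_motile_shift_uv = -3, fs_nonmotile_shift_uv = 3,
                          es_shift_uv = 0, hr_change_bpm = c(0, 0, 0, 0)) {
  data.frame(group = c("FS", "FS", "ES", "ES"),
             semiology = c("motile", "non_motile", "motile", "non_motile"),
             shift_uv = c(fs_motile_shift_uv, fs_nonmotile_shift_uv,
                          es_shift_uv, es_shift_uv),
             hr_change_bpm = hr_change_bpm,
             stringsAsFactors = FALSE)
}

#' Default tilt-table-arm cohort cells
#'
#' Functional syncope carries a positive pre-symptom compound-HEP shift,
#' vasovagal syncope a negative one; every subject additionally reports a
#' psychological symptom with no associated shift.
#'
#' @param fsyncope_shift_uv,vvs_shift_uv pre-symptom shifts (µV).
#' @param bodily_category symptom category carrying the shift.
#' @return data.frame of cells.
#' @export
tilt_cells <- function(fsyncope_shift_uv = 2, vvs_shift_uv = -2,
                       bodily_category = "cardiac") {
  data.frame(group = c("functional_syncope", "VVS"),
             semiology = "none",
             shift_uv = c(fsyncope_shift_uv, vvs_shift_uv),
             hr_change_bpm = c(0, 0),
             bodily_category = bodily_category,
             stringsAsFactors = FALSE)
}

#' Cohort configuration
#'
#' @param n_subjects_per_cell subjects per cell (>= 2).
#' @param cells cell table from [seizure_cells()] or [tilt_cells()].
#' @param interictal_hep_uv population-mean compound-per-lead HEP at rest
#'   (µV); each subject's level and shift get independent
#'   `between_subject_sd_uv` Gaussian deviations.
#' @param between_subject_sd_uv between-subject SD of level and shift (µV).
#' @param noise_sd_uv,artifact_rate_per_min,artifact_amplitude_uv,mean_hr_bpm,hr_sd_bpm,rr_jitter_ms
#'   recording-level parameters passed to [synth_recording_config()].
#' @param postictal_s length of recording retained after seizure offset
#'   (s); 300 keeps the full postictal window, smaller values emulate
#'   clips that end shortly after the event (seizure arm only).
#' @param seed master cohort seed; per-subject seeds are derived from it
#'   and the subject id, so adding a subject never perturbs the others.
#' @return list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_subjects_per_cell, cells = seizure_cells(),
                                interictal_hep_uv = 5,
                                between_subject_sd_uv = 1,
                                noise_sd_uv = 10,
                                artifact_rate_per_min = 0.5,
                                artifact_amplitude_uv = 300,
                                mean_hr_bpm = if (is_tilt_cells(cells)) 75 else 60,
                                hr_sd_bpm = 2, rr_jitter_ms = 25,
                                postictal_s = 300,
                                seed = 1L) {
  stopifnot(n_subjects_per_cell >= 2, nrow(cells) >= 1,
            all(is.finite(cells$shift_uv)))
  structure(list(n_subjects_per_cell = as.integer(n_subjects_per_cell),
                 cells = cells, interictal_hep_uv = interictal_hep_uv,
                 between_subject_sd_uv = between_subject_sd_uv,
                 noise_sd_uv = noise_sd_uv,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amplitude_uv = artifact_amplitude_uv,
                 mean_hr_bpm = mean_hr_bpm, hr_sd_bpm = hr_sd_bpm,
                 rr_jitter_ms = rr_jitter_ms, postictal_s = postictal_s,
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

is_tilt_cells <- function(cells)
  any(cells$group %in% c("functional_syncope", "VVS"))

# Fixed event layout of a synthetic seizure-arm recording (seconds): a
# 5-min interictal mark, a full 5-min preictal run-up, a 15 s seizure, and
# a postictal tail whose length is configurable (postictal_s).
seizure_layout <- function(postictal_s = 300) {
  list(duration_s = 625 + postictal_s + 5, interictal = c(5, 305),
       onset_s = 610, offset_s = 625)
}
# Fixed layout of a synthetic tilt recording: a psychological report at
# 240 s (no shift) and a bodily report at 420 s (shifted 2-min run-up).
TILT_LAYOUT <- list(duration_s = 430, psych_report_s = 240,
                    bodily_report_s = 420, window_s = 120)

# Generate one subject's recording plus its ground-truth row.
generate_cohort_subject <- function(cfg, cell, subject_id) {
  child <- derive_seed(cfg$seed, subject_id)
  set.seed(child)
  level <- cfg$interictal_hep_uv + stats::rnorm(1, 0, cfg$between_subject_sd_uv)
  shift <- cell$shift_uv + stats::rnorm(1, 0, cfg$between_subject_sd_uv)
  tilt <- is_tilt_cells(cell)
  lay <- if (tilt) TILT_LAYOUT else seizure_layout(cfg$postictal_s)
  rcfg <- synth_recording_config(
    duration_s = lay$duration_s, mean_hr_bpm = cfg$mean_hr_bpm,
    hr_sd_bpm = cfg$hr_sd_bpm, rr_jitter_ms = cfg$rr_jitter_ms,
    hep_amplitude_uv = level, noise_sd_uv = cfg$noise_sd_uv,
    artifact_rate_per_min = cfg$artifact_rate_per_min,
    artifact_amplitude_uv = cfg$artifact_amplitude_uv,
    seed = derive_seed(child, "recording"))

  if (!tilt) {
    pre0 <- lay$onset_s - 300
    ann <- annotations(
      onset_s = c(lay$interictal[1], lay$onset_s, lay$offset_s),
      duration_s = c(diff(lay$interictal), 0, 0),
      kind = c("interictal_mark", "seizure_onset", "seizure_offset"),
      label = c("interictal",
                sprintf("seizure_onset type=%s semiology=%s id=1",
                        cell$group, cell$semiology),
                "seizure_offset id=1"),
      semiology = c("none", cell$semiology, cell$semiology),
      event_type = c("none", cell$group, cell$group),
      event_id = c(NA, 1L, 1L))
    sched <- data.frame(t0 = pre0, t1 = lay$onset_s,
                        amplitude_uv = level + shift)
    hr_fun <- local({
      t0 <- pre0; t1 <- lay$offset_s; dhr <- cell$hr_change_bpm
      function(t) ifelse(t >= t0 & t < t1, dhr, 0)
    })
  } else {
    cat_b <- cell$bodily_category
    ann <- annotations(
      onset_s = c(lay$psych_report_s, lay$bodily_report_s),
      kind = "symptom_report",
      label = c("symptom category=psychological",
                sprintf("symptom category=%s", cat_b)),
      symptom_category = c("psychological", cat_b))
    sched <- data.frame(t0 = lay$bodily_report_s - lay$window_s,
                        t1 = lay$bodily_report_s,
                        amplitude_uv = level + shift)
    hr_fun <- NULL
  }
  rec <- generate_recording(rcfg, annotations = ann, hep_schedule = sched,
                            hr_delta_fun = hr_fun, subject_id = subject_id)
  truth <- data.frame(subject_id = subject_id, group = cell$group,
                      semiology = cell$semiology,
                      true_interictal_uv = level,
                      true_shifted_uv = level + shift,
                      true_shift_uv = shift,
                      true_compound_interictal_uv = 2 * level,
                      true_compound_shift_uv = 2 * shift,
                      true_hr_change_bpm = cell$hr_change_bpm,
                      stringsAsFactors = FALSE)
  list(recording = rec, truth = truth)
}

#' Generate a cohort in memory
#'
#' @param cfg a [synth_cohort_config()].
#' @return list with `recordings` (named list) and `truth` (one row per
#'   subject; the injected HEP levels are exact pre-noise window means).
#' @export
generate_cohort_recordings <- function(cfg) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  recs <- list(); truth <- list()
  for (ci in seq_len(nrow(cfg$cells))) {
    cell <- cfg$cells[ci, ]
    for (k in seq_len(cfg$n_subjects_per_cell)) {
      sid <- sprintf("%s_%s_%02d", cell$group,
                     substr(cell$semiology, 1, 3), k)
      sub <- generate_cohort_subject(cfg, cell, sid)
      recs[[sid]] <- sub$recording
      truth[[sid]] <- sub$truth
    }
  }
  list(recordings = recs, truth = do.call(rbind, truth))
}

#' Generate a cohort on disk as EDF+ files
#'
#' One annotated EDF+ per subject, a `ground_truth.csv` with the injected
#' per-subject HEP levels and shift, and a `manifest.csv` mapping subject
#' id and cell to file path.  The cohort config is written alongside as
#' YAML.
#'
#' @param cfg a [synth_cohort_config()].
#' @param out_dir writable output directory (created if needed).
#' @return the manifest data.frame, invisibly carrying the truth table as
#'   `attr(, "truth")`.
#' @export
generate_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  coh <- generate_cohort_recordings(cfg)
  rows <- lapply(names(coh$recordings), function(sid) {
    path <- file.path(out_dir, paste0(sid, ".edf"))
    write_edf(coh$recordings[[sid]], path)
    tr <- coh$truth[coh$truth$subject_id == sid, ]
    data.frame(subject_id = sid, group = tr$group, semiology = tr$semiology,
               path = path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(coh$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(n_subjects_per_cell = cfg$n_subjects_per_cell,
                        interictal_hep_uv = cfg$interictal_hep_uv,
                        between_subject_sd_uv = cfg$between_subject_sd_uv,
                        noise_sd_uv = cfg$noise_sd_uv,
                        artifact_rate_per_min = cfg$artifact_rate_per_min,
                        artifact_amplitude_uv = cfg$artifact_amplitude_uv,
                        mean_hr_bpm = cfg$mean_hr_bpm, seed = cfg$seed,
                        cells = cfg$cells),
                   file.path(out_dir, "cohort_config.yaml"))
  attr(manifest, "truth") <- coh$truth
  invisible(manifest)
}
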
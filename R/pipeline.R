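# End-to-end orchestration of the two study arms.

#' Run the full HEP analysis pipeline
#'
#' Sequences preprocessing, R-peak detection, segmentation, HEP derivation
#' and subject-level inference for one study arm, from either in-memory
#' recordings or a manifest of EDF+ files.  Everything stochastic is seeded
#' from `seed` via per-subject / per-test derived seeds, so a re-run with
#' the same inputs reproduces every number bit-identically.
#'
#' For `arm = "seizure"`: per-cell one-sample bootstrapped t-tests on the
#' compound-HEP change (Bonferroni alpha 0.05/4), the four planned
#' between-group contrasts as two-sample bootstrapped t-tests (alpha
#' 0.05/4), and per-aetiology ANCOVAs of HEP change on semiology with
#' heart-rate change as covariate (type-II F; optional bootstrapped F).
#' For `arm = "tilt_table"`: per group x symptom category, within-subject
#' 20x epoch bootstrap HEP estimates for the pre-symptom and baseline
#' conditions, compared by classical paired t-tests at alpha 0.05/6.
#' Subject-level values beyond 3 SD from their comparison group's mean are
#' excluded before testing.
#'
#' @param recordings named list of [new_recording()] objects, or `NULL` to
#'   load from `manifest`.
#' @param manifest data.frame with `subject_id` and `path` columns (EDF+
#'   files), used when `recordings` is `NULL`.
#' @param arm `"seizure"` or `"tilt_table"`.
#' @param windows a [hep_windows()].
#' @param prep a [preprocess_config()].
#' @param seed master seed.
#' @param n_resamples subject-level bootstrap resamples.
#' @param n_ols_boot resamples for the bootstrapped ANCOVA F (0 skips the
#'   F bootstrap and reports the classical type-II p only).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `run_report`: `summaries` (subject-level table),
#'   `scored` (per-segment table, seizure arm), `subject_hep` (tilt arm),
#'   `tests` (named list of `test_result`s), `models` (ANCOVAs), `audit`
#'   (per-subject epoch accounting and exclusions).
#' @export
run_pipeline <- function(recordings = NULL, manifest = NULL,
                         arm = c("seizure", "tilt_table"),
                         windows = hep_windows(), prep = preprocess_config(),
                         seed = 1L, n_resamples = 2000, n_ols_boot = 2000,
                         out_dir = NULL) {
  arm <- match.arg(arm)
  if (is.null(recordings)) {
    if (is.null(manifest) || nrow(manifest) == 0)
      stop("no recordings and an empty manifest: nothing to analyse")
    recordings <- lapply(seq_len(nrow(manifest)), function(i)
      read_edf(manifest$path[i]))
    names(recordings) <- manifest$subject_id
  }
  if (!length(recordings)) stop("no recordings to analyse")

  per_subject <- lapply(names(recordings), function(sid) {
    rec <- recordings[[sid]]
    rec$subject_id <- sid
    process_subject(rec, arm, windows, prep, seed)
  })
  names(per_subject) <- names(recordings)
  assemble_report(per_subject, arm, seed = seed, n_resamples = n_resamples,
                  n_ols_boot = n_ols_boot, out_dir = out_dir)
}

# Signal-level work for one subject: preprocess, detect beats, segment and
# score.  Returns the small per-subject tables; the recording itself is not
# retained, so whole-cohort studies can stream subjects one at a time.
process_subject <- function(rec, arm, windows = hep_windows(),
                            prep = preprocess_config(), seed = 1L) {
  sid <- rec$subject_id
  prec <- if (is.null(prep)) rec else preprocess(rec, prep)
  peaks <- detect_r_peaks(ecg_signal(rec), rec$sampling_rate_hz)
  if (arm == "seizure") {
    segs <- select_event_segments(prec)
    sc <- score_segments(prec, segs, peaks, windows)
    list(arm = arm, scored = sc,
         no_interictal = isTRUE(attr(segs, "no_interictal")),
         audit = list(n_beats = length(peaks$peak_times_s),
                      no_interictal = isTRUE(attr(segs, "no_interictal")),
                      asr = prec$meta$asr_report,
                      segments = sc[, c("role", "event_type", "semiology",
                                        "n_total", "n_used", "n_rejected_rr",
                                        "n_rejected_ptp", "n_dropped_bounds",
                                        "hep_valid")]))
  } else {
    segs <- select_symptom_windows(prec)
    rows <- list()
    for (cat in setdiff(unique(segs$symptom_category), "none")) {
      byrole <- function(role) {
        s <- segs[segs$symptom_category == cat & segs$role == role, ,
                  drop = FALSE]
        sets <- lapply(seq_len(nrow(s)), function(i)
          score_segment(prec, peaks, s$t0_s[i], s$t1_s[i], windows,
                        keep_epochs = TRUE)$epochs)
        combine_epoch_sets(sets)
      }
      es_pre <- byrole("pre_symptom")
      es_base <- byrole("baseline")
      if (is.null(es_pre) || is.null(es_base) ||
          n_epochs(es_pre) < 1 || n_epochs(es_base) < 1) next
      rows[[cat]] <- data.frame(
        subject_id = sid, symptom_category = cat,
        hep_pre_uv = bootstrap_subject_hep(
          es_pre, seed = derive_seed(seed, paste0(sid, "/", cat, "/pre")),
          w = windows),
        hep_base_uv = bootstrap_subject_hep(
          es_base, seed = derive_seed(seed, paste0(sid, "/", cat, "/base")),
          w = windows),
        n_epochs_pre = n_epochs(es_pre),
        n_epochs_base = n_epochs(es_base), stringsAsFactors = FALSE)
    }
    subject_hep <- if (length(rows)) do.call(rbind, rows) else NULL
    list(arm = arm, subject_hep = subject_hep,
         audit = list(n_beats = length(peaks$peak_times_s),
                      categories = names(rows)))
  }
}

# Pool per-subject results and run the arm's inference stage.
assemble_report <- function(per_subject, arm, seed = 1L, n_resamples = 2000,
                            n_ols_boot = 2000, out_dir = NULL) {
  audit <- lapply(per_subject, `[[`, "audit")
  if (arm == "seizure") {
    keep <- !vapply(per_subject, `[[`, logical(1), "no_interictal")
    scored <- do.call(rbind, lapply(per_subject[keep], `[[`, "scored"))
    summaries <- summarize_subject(scored)
    res <- seizure_inference(summaries, seed = seed,
                             n_resamples = n_resamples,
                             n_ols_boot = n_ols_boot)
    report <- structure(list(arm = arm, summaries = summaries,
                             scored = scored, subject_hep = NULL,
                             tests = res$tests, models = res$models,
                             exclusions = res$exclusions, audit = audit,
                             seed = seed),
                        class = "run_report")
  } else {
    subject_hep <- do.call(rbind, lapply(per_subject, `[[`, "subject_hep"))
    res <- tilt_inference(subject_hep, seed = seed)
    report <- structure(list(arm = arm, summaries = NULL, scored = NULL,
                             subject_hep = subject_hep, tests = res$tests,
                             models = NULL, exclusions = res$exclusions,
                             audit = audit, seed = seed),
                        class = "run_report")
  }
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Run a whole synthetic-cohort study end-to-end
#'
#' Streams the cohort: each subject's recording is generated, preprocessed,
#' segmented and scored, then discarded before the next subject is
#' generated, so memory stays flat; inference runs on the pooled
#' subject-level tables.  Numerically identical to generating the cohort
#' with [generate_cohort_recordings()] and calling [run_pipeline()].
#'
#' @param cfg a [synth_cohort_config()].
#' @param arm `"seizure"` or `"tilt_table"` (defaults to the arm implied by
#'   the cohort cells).
#' @param windows a [hep_windows()].
#' @param prep a [preprocess_config()], or `NULL` to skip preprocessing.
#' @param seed master seed for the inference stage (the cohort's own seed
#'   governs generation).
#' @param n_resamples,n_ols_boot see [run_pipeline()].
#' @param out_dir optional output directory.
#' @return a `run_report` (see [run_pipeline()]).
#' @export
run_cohort_study <- function(cfg, arm = NULL, windows = hep_windows(),
                             prep = preprocess_config(), seed = cfg$seed,
                             n_resamples = 2000, n_ols_boot = 0,
                             out_dir = NULL) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  if (is.null(arm))
    arm <- if (is_tilt_cells(cfg$cells)) "tilt_table" else "seizure"
  per_subject <- list()
  for (ci in seq_len(nrow(cfg$cells))) {
    cell <- cfg$cells[ci, ]
    for (k in seq_len(cfg$n_subjects_per_cell)) {
      sid <- sprintf("%s_%s_%02d", cell$group, substr(cell$semiology, 1, 3), k)
      sub <- generate_cohort_subject(cfg, cell, sid)
      per_subject[[sid]] <- process_subject(sub$recording, arm, windows,
                                            prep, seed)
    }
  }
  assemble_report(per_subject, arm, seed = seed, n_resamples = n_resamples,
                  n_ols_boot = n_ols_boot, out_dir = out_dir)
}

# Seizure-arm inference over the subject summary table.
seizure_inference <- function(summaries, seed = 1L, n_resamples = 2000,
                              n_ols_boot = 2000) {
  tests <- list(); models <- list(); exclusions <- list()
  cells <- unique(summaries[, c("event_type", "semiology")])
  vals <- list()
  for (i in seq_len(nrow(cells))) {
    et <- cells$event_type[i]; sem <- cells$semiology[i]
    key <- paste0(et, "_", sem)
    v <- summaries$hep_change_uv[summaries$event_type == et &
                                   summaries$semiology == sem]
    v <- v[is.finite(v)]
    ex <- exclude_outliers(v)
    exclusions[[key]] <- ex$excluded
    vals[[key]] <- ex$values
    if (length(ex$values) >= 2)
      tests[[paste0("one_sample_", key)]] <- bootstrap_test(
        ex$values, kind = "one_sample", n_resamples = n_resamples,
        seed = derive_seed(seed, paste0("one/", key)),
        name = paste0("one_sample_", key))
  }
  tests[grep("^one_sample_", names(tests))] <-
    bonferroni_gate(tests[grep("^one_sample_", names(tests))],
                    family_size = 4)

  contrasts <- list(
    c("FS_motile", "ES_motile"), c("FS_non_motile", "ES_non_motile"),
    c("FS_motile", "FS_non_motile"), c("ES_motile", "ES_non_motile"))
  ct <- list()
  for (cc in contrasts) {
    if (is.null(vals[[cc[1]]]) || is.null(vals[[cc[2]]])) next
    if (length(vals[[cc[1]]]) < 2 || length(vals[[cc[2]]]) < 2) next
    nm <- paste0("contrast_", cc[1], "_vs_", cc[2])
    ct[[nm]] <- bootstrap_test(
      vals[[cc[1]]], vals[[cc[2]]], kind = "two_sample",
      n_resamples = n_resamples, seed = derive_seed(seed, nm), name = nm)
  }
  tests <- c(tests, bonferroni_gate(ct, family_size = 4))

  for (grp in intersect(c("FS", "ES"), summaries$event_type)) {
    sub <- summaries[summaries$event_type == grp &
                       is.finite(summaries$hep_change_uv), , drop = FALSE]
    if (length(unique(sub$semiology)) < 2 || nrow(sub) < 5) next
    ex <- exclude_outliers(sub$hep_change_uv)
    if (length(ex$excluded)) sub <- sub[-ex$excluded, , drop = FALSE]
    m <- try(fit_ols(sub, outcome = "hep_change_uv",
                     fixed_factors = "semiology",
                     covariates = "hr_change_bpm"), silent = TRUE)
    if (inherits(m, "try-error")) next
    models[[paste0("ancova_", grp)]] <- m
    if (n_ols_boot > 0) {
      tests[[paste0("ancova_F_semiology_", grp)]] <- bootstrap_test(
        m, kind = "ols_F", term = "semiology", strata = "semiology",
        n_resamples = n_ols_boot,
        seed = derive_seed(seed, paste0("ancovaF/", grp)),
        name = paste0("ancova_", grp))
    }
  }
  list(tests = tests, models = models, exclusions = exclusions)
}

# Tilt-arm inference: paired tests per group x category.
tilt_inference <- function(subject_hep, seed = 1L) {
  tests <- list(); exclusions <- list()
  if (is.null(subject_hep) || !nrow(subject_hep))
    return(list(tests = tests, exclusions = exclusions))
  grp_of <- function(sid) sub("_(mot|non|[0-9]).*$", "", sid)
  subject_hep$group <- vapply(subject_hep$subject_id, grp_of, character(1))
  for (grp in unique(subject_hep$group)) {
    for (cat in unique(subject_hep$symptom_category)) {
      s <- subject_hep[subject_hep$group == grp &
                         subject_hep$symptom_category == cat, , drop = FALSE]
      if (nrow(s) < 2) next
      d <- s$hep_pre_uv - s$hep_base_uv
      ex <- exclude_outliers(d)
      key <- paste0("paired_", grp, "_", cat)
      exclusions[[key]] <- ex$excluded
      keep <- if (length(ex$excluded)) -ex$excluded else seq_len(nrow(s))
      if (length(keep) < 2 || nrow(s[keep, ]) < 2) next
      tests[[key]] <- paired_symptom_test(s$hep_pre_uv[keep],
                                          s$hep_base_uv[keep], name = key)
    }
  }
  list(tests = tests, exclusions = exclusions)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> arm=%s, %d subjects summarized, %d tests\n",
              x$arm,
              length(unique((x$summaries %||% x$subject_hep)$subject_id)),
              length(x$tests)))
  for (t in x$tests) print(t)
  invisible(x)
}

#' Serialize a run report to CSV/JSON files
#'
#' Writes the subject summaries, the per-segment scores, a one-row-per-test
#' results table and the audit log (epoch accounting per segment) into
#' `out_dir`.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$summaries))
    utils::write.csv(report$summaries,
                     file.path(out_dir, "subject_summaries.csv"),
                     row.names = FALSE)
  if (!is.null(report$scored))
    utils::write.csv(report$scored, file.path(out_dir, "segment_scores.csv"),
                     row.names = FALSE)
  if (!is.null(report$subject_hep))
    utils::write.csv(report$subject_hep,
                     file.path(out_dir, "subject_hep.csv"), row.names = FALSE)
  tt <- tests_table(report$tests)
  if (!is.null(tt))
    utils::write.csv(tt, file.path(out_dir, "test_results.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report$audit, file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Flatten a list of test results into a data.frame
#' @param tests named list of `test_result`s.
#' @return data.frame, or `NULL` when empty.
#' @export
tests_table <- function(tests) {
  if (!length(tests)) return(NULL)
  do.call(rbind, lapply(tests, function(t) data.frame(
    name = t$name, statistic = t$statistic, df = t$df %||% NA_real_,
    p_classical = t$p_classical, p_empirical = t$p_empirical %||% NA_real_,
    n_resamples = t$n_resamples %||% 0, alpha = t$alpha,
    significant = t$significant, stringsAsFactors = FALSE)))
}
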
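# Peri-ictal segments, symptom windows, within-subject bootstrap, and the
# subject summary table.

rec_with_ann <- function(ann, duration_s = 900) {
  new_recording(matrix(0, 11, duration_s * 256), c(MIN_MONTAGE, "ECG"), 256,
                subject_id = "segsub", annotations = ann)
}

test_that("peri-ictal windows follow the 5-minute rule with truncation", {
  ann <- annotations(onset_s = c(10, 400, 430), duration_s = c(320, 0, 0),
                     kind = c("interictal_mark", "seizure_onset",
                              "seizure_offset"),
                     label = c("interictal", "on", "off"),
                     semiology = c("none", "motile", "motile"),
                     event_type = c("none", "FS", "FS"),
                     event_id = c(NA, 1L, 1L))
  rec <- rec_with_ann(ann)
  segs <- select_event_segments(rec)
  pre <- segs[segs$role == "preictal", ]
  post <- segs[segs$role == "postictal", ]
  expect_equal(c(pre$t0_s, pre$t1_s), c(100, 400))
  expect_equal(c(post$t0_s, post$t1_s), c(430, 730))
  inter <- segs[segs$role == "interictal", ]
  expect_equal(c(inter$t0_s, inter$t1_s), c(10, 330))
})

test_that("events shorter than 5 s are excluded", {
  ann <- annotations(onset_s = c(10, 400, 404), duration_s = c(320, 0, 0),
                     kind = c("interictal_mark", "seizure_onset",
                              "seizure_offset"),
                     semiology = c("none", "motile", "motile"),
                     event_type = c("none", "FS", "FS"),
                     event_id = c(NA, 1L, 1L))
  segs <- select_event_segments(rec_with_ann(ann))
  expect_false(any(segs$role %in% c("preictal", "postictal")))
  # exactly 5 s is kept
  ann2 <- ann; ann2$onset_s[3] <- 405
  segs2 <- select_event_segments(rec_with_ann(ann2))
  expect_true(any(segs2$role == "preictal"))
})

test_that("an early onset truncates the preictal window at the record start", {
  ann <- annotations(onset_s = c(120, 140, 400), duration_s = c(0, 0, 350),
                     kind = c("seizure_onset", "seizure_offset",
                              "interictal_mark"),
                     semiology = c("non_motile", "non_motile", "none"),
                     event_type = c("ES", "ES", "none"),
                     event_id = c(1L, 1L, NA))
  segs <- select_event_segments(rec_with_ann(ann))
  pre <- segs[segs$role == "preictal", ]
  expect_equal(c(pre$t0_s, pre$t1_s), c(0, 120))
})

test_that("consecutive events truncate each other's windows", {
  ann <- annotations(onset_s = c(5, 300, 340, 500, 540),
                     duration_s = c(280, 0, 0, 0, 0),
                     kind = c("interictal_mark", "seizure_onset",
                              "seizure_offset", "seizure_onset",
                              "seizure_offset"),
                     semiology = c("none", "motile", "motile", "motile",
                                   "motile"),
                     event_type = c("none", "FS", "FS", "FS", "FS"),
                     event_id = c(NA, 1L, 1L, 2L, 2L))
  segs <- select_event_segments(rec_with_ann(ann))
  pre2 <- segs[segs$role == "preictal" & segs$event_id == 2, ]
  post1 <- segs[segs$role == "postictal" & segs$event_id == 1, ]
  expect_equal(c(pre2$t0_s, pre2$t1_s), c(340, 500))  # starts at event 1 offset
  expect_equal(c(post1$t0_s, post1$t1_s), c(340, 500))  # ends at event 2 onset
  # no interictal mark >= 300 s: flagged
  expect_true(attr(segs, "no_interictal"))
  # preictal and postictal of one event never overlap
  for (id in 1:2) {
    p <- segs[segs$role == "preictal" & segs$event_id == id, ]
    q <- segs[segs$role == "postictal" & segs$event_id == id, ]
    if (nrow(p) && nrow(q))
      expect_lte(p$t1_s, q$t0_s)
  }
})

test_that("the longest qualifying interictal mark wins, ties to earliest", {
  ann <- annotations(onset_s = c(10, 500, 700, 850),
                     duration_s = c(310, 350, 310, 40),
                     kind = "interictal_mark", label = "interictal")
  segs <- select_event_segments(rec_with_ann(ann, duration_s = 900))
  inter <- segs[segs$role == "interictal", ]
  expect_equal(inter$t0_s, 500)  # the 350 s mark
  expect_equal(inter$t1_s, 850)
})

test_that("symptom windows and per-category baselines follow the 2-minute rule", {
  ann <- annotations(onset_s = 500, kind = "symptom_report",
                     label = "symptom category=cardiac",
                     symptom_category = "cardiac")
  segs <- select_symptom_windows(rec_with_ann(ann))
  pre <- segs[segs$role == "pre_symptom", ]
  base <- segs[segs$role == "baseline", ]
  expect_equal(c(pre$t0_s, pre$t1_s), c(380, 500))
  expect_equal(c(base$t0_s, base$t1_s), c(0, 380))
  expect_identical(pre$symptom_category, "cardiac")
})

test_that("overlapping same-category windows merge; no reports means all baseline", {
  ann <- annotations(onset_s = c(300, 350), kind = "symptom_report",
                     symptom_category = "cardiac")
  segs <- select_symptom_windows(rec_with_ann(ann))
  pre <- segs[segs$role == "pre_symptom", ]
  expect_equal(nrow(pre), 1L)
  expect_equal(c(pre$t0_s, pre$t1_s), c(180, 350))
  base <- segs[segs$role == "baseline", ]
  expect_equal(c(base$t0_s, base$t1_s), c(0, 180))

  segs0 <- select_symptom_windows(rec_with_ann(empty_ann <- annotations(numeric(0))))
  expect_identical(segs0$role, "baseline")
  expect_equal(segs0$t1_s, 900)
})

test_that("per-category vs global baseline exclusion is switchable", {
  ann <- annotations(onset_s = c(200, 500), kind = "symptom_report",
                     symptom_category = c("cephalic", "cardiac"))
  segs <- select_symptom_windows(rec_with_ann(ann))
  base_card <- segs[segs$role == "baseline" &
                      segs$symptom_category == "cardiac", ]
  expect_equal(base_card$t1_s, 380)  # only cardiac reports constrain it
  segs_g <- select_symptom_windows(rec_with_ann(ann), per_category = FALSE)
  base_card_g <- segs_g[segs_g$role == "baseline" &
                          segs_g$symptom_category == "cardiac", ]
  expect_equal(base_card_g$t1_s, 80)  # the cephalic report now constrains it
})

test_that("the within-subject epoch bootstrap behaves as specified", {
  w <- hep_windows(min_epochs = 5)
  base <- array(rnorm(10 * 307, sd = 4), dim = c(10, 307, 1))
  arr_same <- array(rep(base, 12), dim = c(10, 307, 12))
  es_same <- epochs_from_array(arr_same)
  plain <- compound_hep(es_same, w = w)
  expect_equal(bootstrap_subject_hep(es_same, seed = 5, w = w), plain,
               tolerance = 1e-12)
  set.seed(26)
  arr <- array(rnorm(10 * 307 * 30, sd = 6), dim = c(10, 307, 30))
  es <- epochs_from_array(arr)
  b1 <- bootstrap_subject_hep(es, seed = 42, w = w)
  expect_identical(b1, bootstrap_subject_hep(es, seed = 42, w = w))
  expect_false(identical(b1, bootstrap_subject_hep(es, seed = 43, w = w)))
  # convergence to the plain average as n_boot grows
  plain2 <- compound_hep(es, w = w)
  b_small <- bootstrap_subject_hep(es, n_boot = 20, seed = 1, w = w)
  b_big <- bootstrap_subject_hep(es, n_boot = 2000, seed = 1, w = w)
  expect_lt(abs(b_big - plain2), abs(b_small - plain2) + 0.05)
  expect_lt(abs(b_big - plain2), 0.1)
  # permutation invariance under canonical-order resampling
  perm <- sample(30)
  es_p <- epochs_from_array(arr[, , perm], peak_times = perm)
  expect_identical(bootstrap_subject_hep(es_p, seed = 42, w = w), b1)
})

test_that("subject summaries average within subject x type x semiology", {
  scored <- rbind(
    data.frame(subject_id = "s1", role = "interictal", event_type = "none",
               semiology = "none", compound_uv = 1, hep_valid = TRUE,
               mean_hr_bpm = 60, rmssd_ms = 30, event_id = NA),
    data.frame(subject_id = "s1", role = "preictal", event_type = "FS",
               semiology = "motile", compound_uv = c(-1, -2, -3),
               hep_valid = TRUE, mean_hr_bpm = 70, rmssd_ms = 25,
               event_id = 1:3),
    data.frame(subject_id = "s1", role = "preictal", event_type = "FS",
               semiology = "non_motile", compound_uv = 4, hep_valid = TRUE,
               mean_hr_bpm = 65, rmssd_ms = 28, event_id = 4),
    data.frame(subject_id = "s1", role = "preictal", event_type = "FS",
               semiology = "motile", compound_uv = 99, hep_valid = FALSE,
               mean_hr_bpm = 70, rmssd_ms = 25, event_id = 5))
  out <- summarize_subject(scored)
  expect_equal(nrow(out), 2L)  # one row per semiology
  mot <- out[out$semiology == "motile", ]
  expect_equal(mot$n_events, 3L)            # invalid event omitted
  expect_equal(mot$hep_change_uv, mean(c(-1, -2, -3)) - 1)
  expect_equal(mot$hr_change_bpm, 10)
  non <- out[out$semiology == "non_motile", ]
  expect_equal(non$hep_change_uv, 4 - 1)
})
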
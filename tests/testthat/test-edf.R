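# EDF+ writer/reader: round trips, header scaling, montage validation,
# annotation mapping, and an independent read oracle (python/mne).

ann_fixture <- function() {
  annotations(onset_s = c(3, 12.5, 18, 25.25),
              duration_s = c(7, 0, 0, 0),
              kind = c("interictal_mark", "seizure_onset", "seizure_offset",
                       "symptom_report"),
              label = c("interictal",
                        "seizure_onset type=FS semiology=non_motile id=1",
                        "seizure_offset id=1", "symptom category=cephalic"),
              symptom_category = c("none", "none", "none", "cephalic"),
              semiology = c("none", "non_motile", "non_motile", "none"),
              event_type = c("none", "FS", "FS", "none"),
              event_id = c(NA, 1L, 1L, NA))
}

test_that("EDF+ round trip preserves signals to quantization and annotations exactly", {
  cfg <- synth_recording_config(duration_s = 30, noise_sd_uv = 12,
                                hep_amplitude_uv = 4, seed = 9,
                                artifact_rate_per_min = 2,
                                artifact_amplitude_uv = 250)
  rec <- generate_recording(cfg, annotations = ann_fixture(),
                            subject_id = "rt01")
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  r2 <- read_edf(p)
  expect_identical(r2$channel_labels, rec$channel_labels)
  expect_equal(r2$sampling_rate_hz, 256)
  # per-channel error below one quantization step
  step <- 2 * pmax(apply(abs(rec$signal), 1, max) * (1 + 1e-6), 1) / (2 * 32767)
  err <- apply(abs(r2$signal - rec$signal), 1, max)
  expect_true(all(err <= step))
  a <- r2$annotations
  expect_equal(a$onset_s, c(3, 12.5, 18, 25.25), tolerance = 1e-4)
  expect_equal(a$duration_s[1], 7)
  expect_identical(a$kind, c("interictal_mark", "seizure_onset",
                             "seizure_offset", "symptom_report"))
  expect_identical(a$event_type[2], "FS")
  expect_identical(a$semiology[2], "non_motile")
  expect_identical(a$symptom_category[4], "cephalic")
  expect_equal(a$event_id[2], 1L)
})

test_that("digital-range scaling is honoured (unit invariance)", {
  rec <- grid_recording(duration_s = 20, amp = 5, noise = 6, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".edf")
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p1, digital_max = 32767)
  write_edf(rec, p2, digital_max = 8191)  # coarser digital range
  r1 <- read_edf(p1); r2 <- read_edf(p2)
  step2 <- 2 * pmax(apply(abs(rec$signal), 1, max) * (1 + 1e-6), 1) / (2 * 8191)
  expect_true(all(abs(r2$signal - rec$signal) <= step2))
  expect_true(all(abs(r1$signal - r2$signal) <= step2 + step2 / 4))
})

test_that("a recording missing a required lead is rejected by name", {
  labs <- setdiff(MIN_MONTAGE, "C4")
  rec <- new_recording(matrix(0, 11, 2560), c(labs, "T7", "ECG"), 256)
  p <- withr::local_tempfile(fileext = ".edf")
  # give the ECG a pulse so the reader can find it
  rec$signal["ECG", ] <- 100
  write_edf(rec, p)
  expect_error(read_edf(p), "C4")
  r <- read_edf(p, require_montage = FALSE)
  expect_false("C4" %in% r$channel_labels)
})

test_that("montage validation reports ignored and missing leads", {
  rec <- grid_recording(duration_s = 15,
                        channel_labels = c(MIN_MONTAGE, "T7"))
  rep <- validate_montage(rec)
  expect_true(rep$ok)
  expect_identical(rep$ignored, "T7")
  rec2 <- new_recording(matrix(0, 10, 2560),
                        c(setdiff(MIN_MONTAGE, "Cz"), "ECG"), 256)
  rep2 <- validate_montage(rec2)
  expect_false(rep2$ok)
  expect_identical(rep2$missing, "Cz")
})

test_that("channel label dialects normalize to canonical names", {
  expect_identical(normalize_channel_labels(c("EEG Fp1-REF", " cz ", "EKG",
                                              "ECG1-ECG2", "F8")),
                   c("Fp1", "Cz", "ECG", "ECG", "F8"))
  expect_identical(normalize_channel_labels("BIP1", aliases = c(bip1 = "ECG")),
                   "ECG")
})

test_that("annotation mapping rules can come from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- pattern: '^SZ START'", "  kind: seizure_onset",
               "  event_type: ES", "  semiology: motile",
               "- pattern: '^SZ END'", "  kind: seizure_offset"), p)
  rules <- read_annotation_rules(p)
  tal <- list(list(onset = 10, dur = 0, text = "SZ START hypermotor"),
              list(onset = 40, dur = 0, text = "SZ END"))
  ann <- hepline:::apply_annotation_rules(tal, rules)
  expect_identical(ann$kind, c("seizure_onset", "seizure_offset"))
  expect_identical(ann$event_type[1], "ES")
  expect_identical(ann$semiology[1], "motile")
})

test_that("an independent EDF reader (python/mne) agrees with ours", {
  rec <- grid_recording(duration_s = 15, amp = 3, noise = 5, seed = 4)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, p)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(sprintf(paste0(
    "import mne, json\n",
    "raw = mne.io.read_raw_edf(%s, preload=True, verbose='error')\n",
    "sig = raw.get_data() * 1e6\n",
    "i = raw.ch_names.index('EEG C4')\n",
    "print(json.dumps({'sfreq': raw.info['sfreq'],",
    " 'c4': sig[i, :2000].tolist()}))"), deparse(p)), script)
  out <- system2("python", script, stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(out[length(out)])
  expect_equal(ref$sfreq, 256)
  expect_lt(max(abs(ref$c4 - rec$signal["C4", 1:2000])), 0.01)
})
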
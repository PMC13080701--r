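# Epoch extraction, rejection rules, back-averaging and compound HEP.

test_that("epoching arithmetic: 300 s at 60 bpm gives ~300 epochs of 307 samples", {
  rec <- grid_recording(duration_s = 300, hr = 60, noise = 0, amp = 2)
  pk <- peaks_at(rec$meta$r_peaks_s)
  es <- extract_epochs(rec, pk)
  expect_equal(length(es$offsets), 307)
  expect_true(abs(n_epochs(es) - 300) <= 2)
  expect_equal(es$n_total, length(pk$peak_times_s))
  expect_equal(es$n_total,
               n_epochs(es) + es$n_rejected_rr + es$n_dropped_bounds)
})

test_that("epochs that would cross the segment bounds are dropped and counted", {
  rec <- grid_recording(duration_s = 20, hr = 60, noise = 0)
  pk <- peaks_at(c(0.2, 1.5, 2.5, 3.5, 19.7))
  es <- extract_epochs(rec, pk)
  # peak at 0.2 s underflows the 0.4 s pre-R window; 19.7 s fails the
  # last-peak rule (0.8 s must remain) and is attributed to the R-R gate
  expect_equal(es$n_dropped_bounds, 1L)
  expect_equal(es$n_rejected_rr, 1L)
  expect_equal(n_epochs(es), 3L)
})

test_that("uniformly short R-R intervals leave zero epochs", {
  rec <- grid_recording(duration_s = 30, hr = 60, noise = 0)
  # a sustained 600 ms rhythm filling the record: every interior beat fails
  # the <700 ms rule and the last beat has under 0.8 s of signal after it
  pk <- peaks_at(seq(1, 29.9, by = 0.6))
  es <- extract_epochs(rec, pk)
  expect_equal(n_epochs(es), 0L)
  hep <- average_and_baseline(es)
  expect_false(hep$valid)
  expect_true(is.na(hep$compound_amplitude_uv))
})

test_that("amplitude rejection uses strict >100 uV on any analysis channel", {
  w <- hep_windows()
  arr <- array(0, dim = c(10, 307, 5))
  arr[8, 150, 2] <- 150            # F8 spike in epoch 2 only
  arr[3, 10, 3] <- 60; arr[3, 40, 3] <- -40  # ptp exactly 100 in epoch 3
  arr[1, 100, 4] <- 100.0001       # just over threshold in epoch 4
  es <- epochs_from_array(arr, channels = MIN_MONTAGE)
  out <- reject_by_amplitude(es, w)
  expect_equal(n_epochs(out), 3L)          # epochs 2 and 4 rejected
  expect_equal(out$n_rejected_ptp, 2L)
  expect_identical(out$peak_times_s, c(1, 3, 5))
  # max-abs convention flags the 60 uV case differently
  w2 <- hep_windows(ptp_mode = "max_abs")
  out2 <- reject_by_amplitude(es, w2)
  expect_equal(n_epochs(out2), 3L)  # 150 and 100.0001 rejected; 60/-40 kept
})

test_that("baseline correction cancels constant offsets", {
  set.seed(21)
  arr <- array(rnorm(10 * 307 * 80, sd = 5), dim = c(10, 307, 80))
  es <- epochs_from_array(arr)
  h1 <- average_and_baseline(es)
  arr2 <- arr
  arr2[which(MIN_MONTAGE == "C4"), , ] <- arr2[which(MIN_MONTAGE == "C4"), , ] + 7
  h2 <- average_and_baseline(epochs_from_array(arr2))
  expect_equal(h2$compound_amplitude_uv, h1$compound_amplitude_uv,
               tolerance = 1e-10)
  expect_equal(h2$channel_amplitudes_uv, h1$channel_amplitudes_uv,
               tolerance = 1e-10)
})

test_that("the minimum-epoch gate flags 59 invalid and 60 valid", {
  set.seed(22)
  arr <- array(rnorm(10 * 307 * 60), dim = c(10, 307, 60))
  es60 <- epochs_from_array(arr)
  es59 <- epochs_from_array(arr[, , 1:59])
  expect_true(average_and_baseline(es60)$valid)
  expect_false(average_and_baseline(es59)$valid)
})

test_that("averaging is linear and order-invariant", {
  set.seed(23)
  a <- array(rnorm(10 * 307 * 40), dim = c(10, 307, 40))
  b <- array(rnorm(10 * 307 * 40), dim = c(10, 307, 40))
  w <- hep_windows(min_epochs = 10)
  h_a <- average_and_baseline(epochs_from_array(a), w)
  h_b <- average_and_baseline(epochs_from_array(b), w)
  h_ab <- average_and_baseline(epochs_from_array(a + b), w)
  expect_equal(h_ab$channel_waveforms,
               h_a$channel_waveforms + h_b$channel_waveforms,
               tolerance = 1e-10)
  expect_equal(h_ab$compound_amplitude_uv,
               h_a$compound_amplitude_uv + h_b$compound_amplitude_uv,
               tolerance = 1e-10)
  # permuting epoch order leaves outputs bit-identical
  perm <- sample(40)
  es_p <- epochs_from_array(a[, , perm], peak_times = perm)
  expect_identical(average_and_baseline(es_p, w)$channel_waveforms,
                   h_a$channel_waveforms)
})

test_that("sum of lead amplitudes equals amplitude of summed waveforms", {
  set.seed(24)
  arr <- array(rnorm(10 * 307 * 70, sd = 8), dim = c(10, 307, 70))
  es <- epochs_from_array(arr)
  h <- average_and_baseline(es)
  w <- hep_windows()
  moffs <- hepline:::window_offsets(w, 256)$measure
  mcols <- match(moffs, es$offsets)
  summed <- h$channel_waveforms["C4", ] + h$channel_waveforms["F8", ]
  expect_equal(mean(summed[mcols]), h$compound_amplitude_uv,
               tolerance = 1e-12)
})

test_that("waveforms match a naive two-loop average on small instances", {
  set.seed(25)
  for (i in 1:5) {
    ne <- sample(3:8, 1)
    arr <- array(rnorm(3 * 307 * ne), dim = c(3, 307, ne))
    es <- epochs_from_array(arr, channels = c("C4", "F8", "Cz"))
    h <- average_and_baseline(es, hep_windows(min_epochs = 2))
    naive <- naive_epoch_average(arr)
    boffs <- hepline:::window_offsets(hep_windows(), 256)$baseline
    bcols <- match(boffs, es$offsets)
    for (c in 1:3)
      naive[c, ] <- naive[c, ] - naive_window_mean(naive[c, ], bcols)
    expect_equal(unname(h$channel_waveforms), naive, tolerance = 1e-12)
  }
})

test_that("a missing compound lead is flagged", {
  arr <- array(0, dim = c(3, 307, 70))
  es <- epochs_from_array(arr, channels = c("Fz", "Cz", "C3"))
  expect_warning(h <- average_and_baseline(es), "F8|C4")
  expect_true(is.na(h$compound_amplitude_uv))
})
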
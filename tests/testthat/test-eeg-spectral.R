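# EEG preprocessing, time-mirror padding and Morlet decomposition.

make_sine_epochs <- function(freqs_hz, fs = 1024, t_range = c(-1.1, 0.5),
                             amp = 1) {
  times <- seq(t_range[1], t_range[2], by = 1 / fs)
  arr <- array(NA_real_, c(length(freqs_hz), 1, length(times)))
  for (i in seq_along(freqs_hz))
    arr[i, 1, ] <- amp * sin(2 * pi * freqs_hz[i] * times)
  epoched_eeg(arr, times, fs)
}

test_that("band-pass gains match the Butterworth specification", {
  ee <- make_sine_epochs(c(50, 100), amp = 100)
  pp <- preprocess_eeg(ee, resample_to = NULL, reject_uv = NULL)
  mid <- abs(pp$times) < 0.4      # avoid filter edges
  g50 <- sd(pp$data[1, 1, mid]) / sd(ee$data[1, 1, mid])
  g100 <- sd(pp$data[2, 1, mid]) / sd(ee$data[2, 1, mid])
  expect_gt(g50, 0.7); expect_lte(g50, 1.0)
  expect_lt(g100, 1 / 10)
  expect_error(preprocess_eeg(make_sine_epochs(10, fs = 100)),
               "twice the band")
})

test_that("amplitude rejection removes exactly the contaminated trials", {
  set.seed(71)
  fs <- 512
  times <- seq(-1.1, 0.5, by = 1 / fs)
  arr <- array(rnorm(5 * 2 * length(times), sd = 10), c(5, 2, length(times)))
  # sustained 250 uV in-band artifact on trial 3 of the central channel
  # (a one-sample spike would be attenuated by the band-pass, as it should)
  arr[3, 1, 350:450] <- arr[3, 1, 350:450] +
    250 * sin(2 * pi * 10 * times[350:450])
  ee <- epoched_eeg(arr, times, fs, ch_names = c("C1", "P1"))
  pp <- preprocess_eeg(ee, resample_to = 150, reject_uv = 175,
                       central_channels = "C1")
  expect_equal(pp$rejected_trials, 3L)
  expect_equal(dim(pp$data)[1], 4L)
  expect_equal(pp$sample_rate_hz, 150)
  # all trials over threshold: hard error
  arr2 <- arr
  for (tr in 1:5) arr2[tr, 1, 200:320] <- arr2[tr, 1, 200:320] +
    300 * sin(2 * pi * 8 * times[200:320])
  expect_error(preprocess_eeg(epoched_eeg(arr2, times, fs,
                                          c("C1", "P1")),
                              central_channels = "C1", resample_to = NULL),
               "all trials rejected")
})

test_that("time mirroring preserves the pre-stimulus segment exactly", {
  set.seed(72)
  fs <- 150
  times <- seq(-1.1, 1.3, by = 1 / fs)
  arr <- array(rnorm(2 * 2 * length(times)), c(2, 2, length(times)))
  ee <- epoched_eeg(arr, times, fs)
  pad <- time_mirror_pad(ee)
  idx <- attr(pad, "orig_pre_idx")
  expect_identical(pad$data[, , idx],
                   ee$data[, , ee$times < 0])
  # mirror of the mirrored segment restores it (involution)
  n <- length(idx)
  expect_identical(pad$data[, , seq_len(n)],
                   pad$data[, , idx][, , n:1])
  # padded axis remains uniform and covers three pre-stimulus spans
  expect_equal(dim(pad$data)[3], 3 * n)
})

test_that("padding decontaminates pre-stimulus estimates from onset signals", {
  fs <- 150
  times <- seq(-1.1, 1.3, by = 1 / fs)
  osc <- cos(2 * pi * 4 * (times + 0.32))
  clean <- epoched_eeg(array(osc, c(1, 1, length(times))), times, fs)
  stepy <- epoched_eeg(array(osc + 40 * (times > 0), c(1, 1, length(times))),
                       times, fs)
  p_clean <- morlet_tf(time_mirror_pad(clean), freqs = 4,
                       keep_times = -0.1)$power[1, 1, 1, 1]
  p_step <- morlet_tf(time_mirror_pad(stepy), freqs = 4,
                      keep_times = -0.1)$power[1, 1, 1, 1]
  expect_lt(abs(p_step - p_clean) / p_clean, 0.05)
  # and the phase at -0.32 s is unchanged by padding
  ph_pad <- morlet_tf(time_mirror_pad(clean), freqs = 4,
                      keep_times = -0.32)$phase[1, 1, 1, 1]
  ph_raw <- morlet_tf(clean, freqs = 4, keep_times = -0.32)$phase[1, 1, 1, 1]
  expect_lt(abs(wrap_angle(ph_pad - ph_raw)), 0.05)
})

test_that("Morlet responses match closed forms on analytic signals", {
  fs <- 150
  times <- seq(-2, 1, by = 1 / fs)
  x <- cos(2 * pi * 5 * times)
  ee <- epoched_eeg(array(x, c(1, 1, length(times))), times, fs)
  tf <- morlet_tf(ee, freqs = 2:13, keep_times = 0)
  expect_equal((2:13)[which.max(tf$power[1, 1, , 1])], 5)
  expect_lt(abs(tf$phase[1, 1, which(2:13 == 5), 1]), 0.05)
  # amplitude doubling quadruples power at every frequency
  tf2 <- morlet_tf(epoched_eeg(array(2 * x, c(1, 1, length(times))),
                               times, fs), freqs = 2:13, keep_times = 0)
  expect_equal(tf2$power[1, 1, , 1] / tf$power[1, 1, , 1], rep(4, 12),
               tolerance = 1e-10)
  # phase is invariant to signal scale (wavelet normalization irrelevant)
  expect_equal(tf2$phase[1, 1, , 1], tf$phase[1, 1, , 1], tolerance = 1e-10)
  # white noise: time-resolved mean power flat within sampling error
  set.seed(73)
  arr <- array(rnorm(60 * 1 * length(times)), c(60, 1, length(times)))
  tfn <- morlet_tf(epoched_eeg(arr, times, fs), freqs = 6,
                   keep_times = seq(-1, 0, by = 0.1))
  mp <- colMeans(tfn$power[, 1, 1, ])
  expect_lt(diff(range(mp)) / mean(mp), 0.5)
  # insufficient epoch length names the offending frequency
  short <- epoched_eeg(arr[, , 1:100, drop = FALSE], times[1:100], fs)
  expect_error(morlet_tf(short, freqs = 2:13), "2")
})

test_that("time-point selection counts significant channels with tie rules", {
  pv <- array(1, c(4, 3, 5))
  times <- seq(-0.9, -0.1, by = 0.2)
  pv[, 2, 3] <- 0.01               # all channels significant at time 3
  sel <- select_timepoint(pv, times)
  expect_equal(sel$time_s, times[3])
  expect_equal(sel$counts[3], 4)
  # flat p-values: earliest (most negative) time wins deterministically
  sel0 <- select_timepoint(array(1, c(4, 3, 5)), times)
  expect_equal(sel0$time_s, times[1])
})

test_that("spectra localize oscillations and preserve preprocessing idempotence", {
  fs <- 150
  times <- seq(-1, 1, by = 1 / fs)
  x <- sin(2 * pi * 10 * times)
  ee <- epoched_eeg(array(rep(x, 3), c(1, 3, length(times))) * 0 +
                      aperm(array(rep(x, 3), c(length(times), 1, 3)),
                            c(2, 3, 1)), times, fs)
  sp <- eeg_spectrum(ee)
  expect_lt(abs(sp$freqs[which.max(sp$amplitude)] - 10), 0.6)
  # filtering already-band-limited data changes little (idempotence)
  pp1 <- preprocess_eeg(ee, resample_to = NULL, reject_uv = NULL,
                        band = c(0.6, 70), order = 3)
  pp2 <- preprocess_eeg(pp1, resample_to = NULL, reject_uv = NULL,
                        band = c(0.6, 70), order = 3)
  mid <- abs(pp1$times) < 0.7
  expect_lt(max(abs(pp1$data[1, 1, mid] - pp2$data[1, 1, mid])) /
              sd(pp1$data[1, 1, mid]), 0.05)
})

test_that("re-referencing removes the common signal exactly", {
  set.seed(74)
  fs <- 150
  times <- seq(-1, 0.5, by = 1 / fs)
  arr <- array(rnorm(3 * 4 * length(times)), c(3, 4, length(times)))
  common <- sin(2 * pi * 3 * times)
  for (ch in 1:4) arr[, ch, ] <- arr[, ch, ] + rep(common, each = 3)
  ee <- epoched_eeg(arr, times, fs)
  rr <- rereference(ee)
  # average reference: channel mean is zero at every sample
  expect_lt(max(abs(apply(rr$data, c(1, 3), mean))), 1e-12)
  # single-channel reference subtracts that channel
  r1 <- rereference(ee, reference = 2)
  expect_equal(r1$data[, 2, ], ee$data[, 2, ] * 0, tolerance = 1e-12)
  expect_error(rereference(ee, reference = "nope"), "not found")
})
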
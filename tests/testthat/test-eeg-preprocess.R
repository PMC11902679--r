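test_that("resampling halves rates anti-aliased and refuses upsampling", {
  set.seed(1)
  seg <- eeg_segment(matrix(rnorm(2 * 512 * 10), 2), fs = 512)
  out <- resample_eeg(seg, 128)
  expect_equal(ncol(out$data), 1280)  # 10 s at 128 Hz
  expect_equal(out$fs, 128)
  expect_identical(resample_eeg(seg, 512), seg)
  expect_error(resample_eeg(seg, 1024), "upsampling")

  t <- seq(0, 4 - 1 / 512, by = 1 / 512)
  sine <- eeg_segment(matrix(sin(2 * pi * 50 * t), 1), fs = 512)
  down <- resample_eeg(sine, 128)
  expect_equal(dominant_frequency(down$data[1, ], 128), 50, tolerance = 0.01)
})

test_that("band-pass keeps in-band sines and rejects out-of-band ones", {
  fs <- 128
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  lowf <- eeg_segment(matrix(sin(2 * pi * 2 * t), 1), fs)
  inband <- eeg_segment(matrix(sin(2 * pi * 20 * t), 1), fs)
  expect_lt(rms(bandpass_eeg(lowf)$data), 0.1 * rms(lowf$data))
  expect_equal(rms(bandpass_eeg(inband)$data), rms(inband$data),
               tolerance = 0.1)
  zero <- eeg_segment(matrix(0, 2, 256), fs)
  expect_equal(bandpass_eeg(zero)$data, zero$data)
  expect_error(bandpass_eeg(inband, lo = 50, hi = 40), "band edges")
  expect_error(bandpass_eeg(inband, lo = 4, hi = 70), "band edges")
})

test_that("common average reference zeroes column means", {
  set.seed(2)
  seg <- eeg_segment(matrix(rnorm(40), 4, 10), fs = 10)
  out <- common_reference(seg)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  same <- eeg_segment(matrix(rep(rnorm(10), each = 3), 3, 10, byrow = FALSE),
                      fs = 10)
  same$data <- matrix(rep(rnorm(10), 3), 3, 10, byrow = TRUE)
  expect_equal(common_reference(same)$data, matrix(0, 3, 10))
  ab <- eeg_segment(rbind(a = 1:5, b = c(2, 1, 4, 3, 6)), fs = 5)
  out2 <- common_reference(ab)
  expect_equal(out2$data[1, ], (ab$data[1, ] - ab$data[2, ]) / 2,
               ignore_attr = TRUE)
  expect_error(common_reference(eeg_segment(matrix(1:5, 1), fs = 5)),
               ">= 2 channels")
})

test_that("CAR commutes with linear band-pass filtering", {
  set.seed(3)
  seg <- eeg_segment(matrix(rnorm(4 * 512), 4), fs = 128)
  a <- common_reference(bandpass_eeg(seg))
  b <- bandpass_eeg(common_reference(seg))
  expect_lt(max(abs(a$data - b$data)), 1e-8)
})

test_that("windowing yields exact non-overlapping covers", {
  cfg <- sim_config(n_channels = 3, trial_seconds = 60, seed = 5)
  trial <- simulate_eeg_trial(list(arousal = 5, valence = 5), cfg, seed = 5)
  wins <- window_segments(trial, 6)
  expect_length(wins, 10)  # one-minute trial, ten 6-s windows
  recon <- do.call(cbind, lapply(wins, function(w) w$data))
  expect_equal(recon, trial$data[, seq_len(ncol(recon))])
  expect_true(all(vapply(wins, function(w) ncol(w$data), numeric(1)) ==
                    6 * cfg$fs_eeg))

  short <- eeg_segment(matrix(0, 2, 5 * 128), fs = 128)
  expect_warning(empty <- window_segments(short, 6), "shorter")
  expect_length(empty, 0)
  expect_error(window_segments(trial, 0), "positive")
})

test_that("paired windowing keeps EEG and roll spans aligned", {
  cfg <- small_cfg()
  lab <- simulate_labels(cfg)[1, ]
  trial <- simulate_eeg_trial(lab, cfg, seed = 6)
  roll <- midi_to_roll(simulate_midi_clip(lab, cfg, seed = 6),
                       cfg$fs_roll, cfg$pitch_lo, cfg$pitch_hi,
                       duration = cfg$trial_seconds)
  pairs <- window_segments(trial, 3, paired_roll = roll)
  expect_length(pairs, 2)
  expect_equal(ncol(pairs[[1]]$roll$mask), 3 * cfg$fs_roll)
  expect_equal(cbind(pairs[[1]]$roll$mask, pairs[[2]]$roll$mask),
               roll$mask[, seq_len(2 * 3 * cfg$fs_roll)])
})

test_that("fade-out exclusion drops quiet endings only", {
  fs_roll <- 4
  uniform <- piano_roll(matrix(1L, 4, 24), fs_roll, 60)
  faded <- piano_roll(cbind(matrix(1L, 4, 20), matrix(0L, 4, 4)),
                      fs_roll, 60)
  pairs <- list(list(eeg = NULL, roll = uniform),
                list(eeg = NULL, roll = faded))
  kept <- exclude_fadeouts(pairs, energy_frac = 0.1)
  expect_length(kept, 1)
  expect_equal(attr(kept, "n_excluded"), 1)
  expect_length(exclude_fadeouts(list(), 0.1), 0)
})

test_that("rating normalization and binarization follow the 1-9 convention", {
  expect_equal(normalize_rating(c(1, 5, 9)), c(0, 0.5, 1))
  expect_error(normalize_rating(0))
  expect_equal(as.character(binarize_rating(c(2, 5, 5.1))),
               c("low", "low", "high"))
  expect_equal(label_quadrant(c(6, 6, 4, 4), c(6, 4, 4, 6)), 1:4)
})
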
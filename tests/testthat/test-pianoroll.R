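test_that("spectrogram frames and content follow the STFT contract", {
  expect_equal(ncol(stft_magnitude(rnorm(2048), 1024, 512)$mag), 3)
  z <- stft_magnitude(numeric(4096) + 0, 1024, 512)
  expect_true(all(z$mag == 0))
  # sine at an exact bin centre dominates that frequency row
  fs <- 1024; n_fft <- 512
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  f0 <- 16 * fs / n_fft  # bin 17
  sp <- stft_magnitude(sin(2 * pi * f0 * t), n_fft, 256, fs = fs)
  expect_equal(unname(which.max(rowMeans(sp$mag))), 17)
  expect_error(stft_magnitude(numeric(0)), "empty")
})

test_that("NMF multiplicative updates never increase the objective", {
  set.seed(2)
  Z <- matrix(runif(20 * 15), 20)
  for (loss in c("frobenius", "kl")) {
    m <- nmf_factorize(Z, 4, n_iter = 80, tol = 0, loss = loss)
    expect_true(all(diff(m$objective_trace) <= 1e-8 * m$objective_trace[1]))
    expect_true(all(m$dictionary >= 0))
    expect_true(all(m$activations >= 0))
  }
})

test_that("NMF recovers rank-matched factorizations", {
  errs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Z <- matrix(runif(30 * 5), 30) %*% matrix(runif(5 * 40), 5)
    m <- nmf_factorize(Z, 5, n_iter = 500, tol = 0, seed = s)
    norm(m$dictionary %*% m$activations - Z, "F") / norm(Z, "F")
  }, numeric(1))
  expect_lte(median(errs), 1e-2)

  set.seed(7)
  Z1 <- outer(runif(20), runif(15))
  m1 <- nmf_factorize(Z1, 1, n_iter = 500, tol = 0)
  expect_lte(norm(m1$dictionary %*% m1$activations - Z1, "F") /
               norm(Z1, "F"), 1e-6)
})

test_that("NMF is seed-reproducible and validates its inputs", {
  set.seed(3); Z <- matrix(runif(50), 10)
  a <- nmf_factorize(Z, 2, n_iter = 20, seed = 9)
  b <- nmf_factorize(Z, 2, n_iter = 20, seed = 9)
  expect_identical(a, b)
  expect_error(nmf_factorize(-Z, 2), "nonnegative")
  expect_error(nmf_factorize(Z, 11), "rank")
})

test_that("activation thresholding follows the per-template-max rule", {
  mk <- function(A) structure(list(dictionary = matrix(1, 2, nrow(A)),
                                   activations = A, rank = nrow(A),
                                   loss = "frobenius",
                                   objective_trace = 0),
                              class = "nmf_model")
  expect_true(all(activations_to_roll(mk(matrix(0, 2, 5)), c(60, 62))$mask
                  == 0))
  one <- activations_to_roll(mk(rbind(rep(2, 5), rep(0, 5))), c(60, 62),
                             threshold = 0.5)
  expect_equal(one$mask[1, ], rep(1L, 5))
  expect_equal(one$mask[3, ], rep(0L, 5))
  peak <- activations_to_roll(mk(rbind(c(1, 3, 2), c(5, 1, 5))), c(60, 61),
                              threshold = 1)
  expect_equal(peak$mask[1, ], c(0L, 1L, 0L))
  expect_equal(peak$mask[2, ], c(1L, 0L, 1L))
  expect_error(activations_to_roll(mk(matrix(1, 2, 3)), c(60)), "pitch_map")
})

test_that("thresholding is monotone: higher threshold gives a sub-mask", {
  set.seed(4)
  A <- matrix(runif(4 * 30), 4)
  mk <- structure(list(dictionary = matrix(1, 3, 4), activations = A,
                       rank = 4, loss = "frobenius", objective_trace = 0),
                  class = "nmf_model")
  lo <- activations_to_roll(mk, 60:63, threshold = 0.3)
  hi <- activations_to_roll(mk, 60:63, threshold = 0.7)
  expect_true(all(hi$mask <= lo$mask))
})

test_that("midi_to_roll places notes on the frame grid", {
  r <- midi_to_roll(note_sequence(60, 0, 1), fs_roll = 10, pitch_lo = 48,
                    pitch_hi = 71, duration = 1)
  expect_equal(sum(r$mask), 10)
  expect_equal(unname(r$mask[60 - 48 + 1, ]), rep(1L, 10))
  expect_true(all(midi_to_roll(note_sequence(), fs_roll = 10,
                               duration = 1)$mask == 0))
  # overlapping same-pitch notes merge into the union of spans
  ov <- midi_to_roll(note_sequence(c(60, 60), c(0, 0.5), c(0.8, 1.2)),
                     fs_roll = 10, pitch_lo = 60, pitch_hi = 60,
                     duration = 2)
  expect_equal(unname(ov$mask[1, ]), c(rep(1L, 12), rep(0L, 8)))
  expect_error(midi_to_roll(note_sequence(90, 0, 1), 10, 48, 72,
                            duration = 1), "outside")
  clipped <- midi_to_roll(note_sequence(90, 0, 1), 10, 48, 72, duration = 1,
                          out_of_range = "clip")
  expect_equal(sum(clipped$mask[72 - 48 + 1, ]), 10)
})

test_that("roll_to_midi recovers runs and honours the minimum note length", {
  ns <- note_sequence(pitch = c(60, 62, 60), onset = c(0, 0.5, 2),
                      offset = c(0.4, 1.9, 2.5))
  roll <- midi_to_roll(ns, fs_roll = 10, pitch_lo = 55, pitch_hi = 65,
                       duration = 3)
  back <- roll_to_midi(roll, min_frames = 1)
  expect_equal(back$pitch, ns$pitch)
  expect_equal(floor(back$onset * 10), floor(ns$onset * 10))

  short <- piano_roll(matrix(c(rep(1L, 10), rep(0L, 14)), 1, 24,
                             byrow = TRUE), 4, 60)
  expect_equal(nrow(roll_to_midi(short, min_frames = 11)), 0)
  long <- piano_roll(matrix(c(rep(1L, 11), rep(0L, 13)), 1, 24,
                            byrow = TRUE), 4, 60)
  expect_equal(nrow(roll_to_midi(long, min_frames = 11)), 1)
  expect_equal(nrow(roll_to_midi(piano_roll(matrix(0L, 3, 10), 4, 60))), 0)
})

test_that("roll segmentation covers the roll in equal windows", {
  roll <- piano_roll(matrix(rbinom(4 * 960, 1, 0.1), 4), fs_roll = 16,
                     pitch_offset = 60)
  segs <- segment_roll(roll, 6)
  expect_length(segs, 10)
  expect_equal(ncol(segs[[1]]$mask), 96)
  expect_equal(do.call(cbind, lapply(segs, `[[`, "mask")),
               roll$mask[, 1:960])
})

test_that("supervised NMF transcription finds the played pitches", {
  fs <- 4096; t <- seq(0, 1.5 - 1 / fs, by = 1 / fs)
  f <- function(p) 440 * 2^((p - 69) / 12)
  audio <- c(sin(2 * pi * f(60) * t), sin(2 * pi * f(67) * t))
  roll <- transcribe_audio(audio, fs, pitch_lo = 55, pitch_hi = 72,
                           n_fft = 1024, hop = 512, threshold = 0.5,
                           n_iter = 60)
  notes <- roll_to_midi(roll, min_frames = 3)
  expect_true(60 %in% notes$pitch)
  expect_true(67 %in% notes$pitch)
})
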
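test_that("bottleneck dimensionality follows the closed form", {
  ae <- build_autoencoder(128, 96)
  expect_equal(ae$code_shape, c(16, 12, 128))
  expect_equal(ae$code_dim, 24576)
  ae2 <- build_autoencoder(16, 24, filters = c(4, 8, 16))
  expect_equal(ae2$code_dim, 2 * 3 * 16)
  expect_error(build_autoencoder(30, 24), "divisible by 8")
})

test_that("forward passes are bounded, finite and batch-invariant", {
  ae <- build_autoencoder(16, 24, filters = c(4, 8, 8), seed = 3)
  x1 <- array(0, c(16, 24, 1, 1))
  fe <- affectmidi:::.forward_layers(ae$encoder, x1, train = FALSE)
  fd <- affectmidi:::.forward_layers(ae$decoder, fe$out, train = FALSE)
  expect_true(all(is.finite(fd$out)))
  expect_true(all(fd$out >= 0 & fd$out <= 1))

  set.seed(4)
  xb <- array(runif(16 * 24 * 3), c(16, 24, 1, 3))
  f3 <- affectmidi:::.forward_layers(ae$encoder, xb, train = FALSE)
  f1 <- affectmidi:::.forward_layers(ae$encoder, xb[, , , 1, drop = FALSE],
                                     train = FALSE)
  expect_equal(dim(f3$out)[1:3], dim(f1$out)[1:3])
  expect_equal(f3$out[, , , 1], f1$out[, , , 1])
})

test_that("encode/decode demand a trained model and preserve shapes", {
  ae <- build_autoencoder(16, 24, filters = c(4, 8, 8))
  roll <- piano_roll(matrix(0L, 16, 24), 4, 48)
  expect_error(encode_rolls(ae, list(roll)), "untrained")
  expect_error(decode_rolls(ae, matrix(0, 1, ae$code_dim)), "untrained")
})

test_that("training overfits a small roll set to high Dice", {
  rs <- small_rollset(n = 20, seed = 2)
  ae <- train_autoencoder(rs$rolls, rs$labels, epochs = 200, batch = 8,
                          lr = 1e-2, seed = 1, cka_weight = 0,
                          filters = c(8, 16, 32), dropout = 0.2)
  expect_null(ae$history$cka)  # no alignment column without the CKA term
  expect_lt(tail(ae$history$rec_loss, 1), head(ae$history$rec_loss, 1))

  codes <- encode_rolls(ae, rs$rolls)
  expect_equal(dim(codes), c(20, ae$code_dim))
  dec <- decode_rolls(ae, codes)
  expect_equal(dim(dec[[1]]), c(16, 24))
  dc <- vapply(seq_along(rs$rolls), function(i)
    dice(binarize_roll(dec[[i]], 0.5, rs$cfg$fs_roll, rs$cfg$pitch_lo),
         rs$rolls[[i]]), numeric(1))
  expect_gte(mean(dc), 0.8)

  # encoding is deterministic at inference (dropout disabled)
  expect_equal(encode_rolls(ae, rs$rolls[1:2]), codes[1:2, , drop = FALSE])
})

test_that("reconstruction loss descends epoch over epoch", {
  parts <- list(small_rollset(n = 20, seed = 8),
                small_rollset(n = 20, seed = 9),
                small_rollset(n = 10, seed = 11))
  rolls50 <- do.call(c, lapply(parts, `[[`, "rolls"))
  labels50 <- do.call(rbind, lapply(parts, `[[`, "labels"))
  ae <- train_autoencoder(rolls50, labels50, epochs = 25, batch = 10,
                          lr = 2e-3, seed = 2, cka_weight = 0,
                          filters = c(4, 8, 8), dropout = 0.2)
  l <- ae$history$rec_loss
  # per-epoch increases stay within a 5% stochastic-batch tolerance
  expect_true(all(diff(l) <= 0.05 * head(l, -1)))
  expect_lt(tail(l, 1), head(l, 1))
})

test_that("the CKA term requires targets and a workable batch size", {
  rs <- small_rollset(n = 10, seed = 3)
  expect_error(train_autoencoder(rs$rolls, NULL, epochs = 1,
                                 cka_weight = 0.5, filters = c(4, 8, 8)),
               "labels")
  expect_error(train_autoencoder(rs$rolls, rs$labels, epochs = 1, batch = 4,
                                 cka_weight = 0.5, filters = c(4, 8, 8)),
               "batch")
  expect_error(train_autoencoder(rs$rolls, rs$labels, epochs = 1,
                                 cka_weight = 0.5,
                                 cka_target = "features",
                                 filters = c(4, 8, 8)),
               "target_features")
})

test_that("binarization thresholds behave at and beyond the boundaries", {
  p <- matrix(0.6, 3, 8)
  expect_true(all(binarize_roll(p, 0.5)$mask == 1))
  expect_true(all(binarize_roll(matrix(0.99, 3, 8), 1)$mask == 0))
  set.seed(5)
  q <- matrix(runif(24), 3, 8)
  lo <- binarize_roll(q, 0.3)$mask
  hi <- binarize_roll(q, 0.8)$mask
  expect_true(all(hi <= lo))
  expect_error(binarize_roll(matrix(1.2, 2, 2)), "\\[0, 1\\]")
})
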
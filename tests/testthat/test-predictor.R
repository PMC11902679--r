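test_that("label distances are Euclidean with exact special cases", {
  train <- matrix(c(0, 0, 1, 1, 0.5, 0.5), 3, 2, byrow = TRUE)
  d <- label_distances(matrix(c(0, 0), 1), train)
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], sqrt(2))
  expect_equal(d[1, 3], sqrt(0.5))
  sym <- label_distances(train, train)
  expect_equal(sym, t(sym))
  expect_error(label_distances(matrix(0.5, 1, 3), train), "dimension")
  expect_error(label_distances(matrix(2, 1, 2), train))
})

test_that("neighbour weights live on the k-sparse probability simplex", {
  set.seed(1)
  D <- matrix(runif(6 * 12), 6, 12)
  w <- neighbor_weights(D, k = 5)
  expect_equal(rowSums(w$matrix), rep(1, 6), tolerance = 1e-8)
  expect_true(all(w$matrix >= 0))
  expect_true(all(rowSums(w$matrix > 0) <= 5))
  expect_true(all(lengths(w$support) == 5))

  eq <- neighbor_weights(matrix(1, 2, 8), k = 5)
  expect_equal(sort(eq$matrix[1, eq$support[[1]]]), rep(0.2, 5))

  nn <- neighbor_weights(matrix(c(0, 5, 7, 9), 1), k = 1)
  expect_equal(nn$matrix[1, ], c(1, 0, 0, 0))
  expect_error(neighbor_weights(D, k = 0), "positive")
  expect_error(neighbor_weights(D, k = 13), "exceeds")
})

test_that("retrieval is monotone: a smaller distance never loses weight", {
  set.seed(2)
  d <- runif(10, 0.2, 1)
  w1 <- neighbor_weights(matrix(d, 1), k = 5)$matrix[1, ]
  j <- which(w1 > 0)[1]
  d2 <- d; d2[j] <- d2[j] / 2
  w2 <- neighbor_weights(matrix(d2, 1), k = 5)$matrix[1, ]
  expect_gte(w2[j], w1[j])
})

test_that("predicted codes are convex combinations of selected neighbours", {
  set.seed(3)
  codes <- matrix(rnorm(12 * 7), 12, 7)
  D <- matrix(runif(4 * 12), 4, 12)
  w <- neighbor_weights(D, k = 5)
  pred <- predict_codes(w, codes)
  expect_equal(dim(pred), c(4, 7))
  for (i in 1:4) {
    sel <- codes[w$support[[i]], , drop = FALSE]
    expect_true(all(pred[i, ] >= apply(sel, 2, min) - 1e-12))
    expect_true(all(pred[i, ] <= apply(sel, 2, max) + 1e-12))
  }
  # vertex and midpoint of the simplex
  one <- matrix(0, 1, 12); one[1, 4] <- 1
  expect_equal(predict_codes(one, codes)[1, ], codes[4, ])
  two <- matrix(0, 1, 12); two[1, c(2, 9)] <- 0.5
  expect_equal(predict_codes(two, codes)[1, ], (codes[2, ] + codes[9, ]) / 2)
  expect_error(predict_codes(w, codes[1:5, ]), "mismatch")
})

test_that("deep-quadrant queries retrieve same-quadrant neighbours", {
  fracs <- vapply(1:3, function(sd) {
    set.seed(sd)
    # >= 10 training clips per quadrant
    quad_centres <- matrix(c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2, 0.2, 0.8),
                           4, 2, byrow = TRUE)
    train <- do.call(rbind, lapply(1:4, function(q)
      matrix(rep(quad_centres[q, ], each = 12), 12, 2) +
        matrix(runif(24, -0.15, 0.15), 12, 2)))
    train_q <- rep(1:4, each = 12)
    queries <- quad_centres + matrix(runif(8, -0.05, 0.05), 4, 2)
    w <- neighbor_weights(label_distances(queries, train), k = 5)
    mean(vapply(1:4, function(i)
      mean(train_q[w$support[[i]]] == i), numeric(1)))
  }, numeric(1))
  expect_gte(median(fracs), 0.8)
})

test_that("an exact-match query with k = 1 returns that sample's roll", {
  fx <- fixture_trained_ae()
  labs <- as.matrix(fx$labels[, c("arousal01", "valence01")])
  codes <- encode_rolls(fx$ae, fx$rolls)
  j <- 4
  out <- predict_pianorolls(labs[j, , drop = FALSE], labs, codes, fx$ae,
                            k = 1)
  recon <- binarize_roll(decode_rolls(fx$ae, codes[j, , drop = FALSE])[[1]],
                         0.5, fx$ae$fs_roll, fx$ae$pitch_offset)
  expect_identical(out[[1]]$mask, recon$mask)
})

test_that("shuffling the training pool leaves predictions unchanged", {
  fx <- fixture_trained_ae()
  labs <- as.matrix(fx$labels[, c("arousal01", "valence01")])
  codes <- encode_rolls(fx$ae, fx$rolls)
  q <- matrix(c(0.7, 0.6), 1)
  out1 <- predict_pianorolls(q, labs, codes, fx$ae, k = 3)
  set.seed(8)
  perm <- sample(nrow(labs))
  out2 <- predict_pianorolls(q, labs[perm, ], codes[perm, ], fx$ae, k = 3)
  expect_equal(out1[[1]]$mask, out2[[1]]$mask)
})

test_that("uniform weights over an all-equal pool decode the mean code", {
  fx <- fixture_trained_ae()
  codes <- encode_rolls(fx$ae, fx$rolls)
  n <- nrow(codes)
  labs <- matrix(0.5, n, 2)  # all training labels equal
  out <- predict_pianorolls(matrix(0.5, 1, 2), labs, codes, fx$ae, k = n)
  mean_dec <- decode_rolls(fx$ae, matrix(colMeans(codes), 1))[[1]]
  expect_equal(out[[1]]$mask,
               binarize_roll(mean_dec, 0.5, fx$ae$fs_roll,
                             fx$ae$pitch_offset)$mask)
})
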
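test_that("architecture shapes match the printed configuration", {
  expect_equal(eegnet_spec(32, 128)$flat_len, 128)
  expect_equal(eegnet_spec(32, 768)$flat_len, 768)  # 6 s at 128 Hz
  expect_error(eegnet_spec(32, 16), "at least 32")

  net <- build_eegnet(eegnet_spec(6, 128), seed = 2)
  x <- array(rnorm(6 * 128 * 3), c(6, 128, 1, 3))
  fw <- affectmidi:::.forward_layers(net$layers, x, train = FALSE)
  expect_equal(dim(fw$out), c(3, 2))
  expect_true(all(fw$out >= 0 & fw$out <= 1))
})

test_that("the parameter count is the deterministic closed form", {
  spec <- eegnet_spec(32, 128)
  net <- build_eegnet(spec)
  expected <- 1 * 4 * 1 * 4 +          # temporal conv
    2 * 4 +                            # batch norm
    32 * 1 * 4 * 2 +                   # depthwise spatial conv
    2 * 8 +                            # batch norm
    (1 * 16 * 8) + (8 * 32) +          # separable conv (depthwise+pointwise)
    2 * 32 +                           # batch norm
    (128 * 2 + 2)                      # dense head
  expect_equal(n_parameters(net), expected)
  expect_equal(n_parameters(net), 1002)
})

test_that("EEGNet separates arousal classes on noiseless coupled data", {
  accs <- vapply(1:3, function(sd) {
    cfg <- sim_config(n_trials = 16, trial_seconds = 12, n_channels = 6,
                      noise_sd = 0, seed = 40 + sd)
    sub <- simulate_subject(cfg, 1)
    segs <- list(); rows <- list()
    for (tr in seq_along(sub$eeg)) {
      for (w in window_segments(common_reference(bandpass_eeg(
             sub$eeg[[tr]])), 6)) {
        segs[[length(segs) + 1]] <- w
        rows[[length(rows) + 1]] <- sub$labels[tr, ]
      }
    }
    labs <- do.call(rbind, rows)
    labs$class <- ifelse(labs$arousal > 5, "high", "low")
    net <- train_eegnet(segs, labs, mode = "classification", epochs = 20,
                        lr = 1e-3, seed = sd)
    post <- predict_emotion(net, segs)
    mean(colnames(post)[max.col(post)] == labs$class)
  }, numeric(1))
  expect_gte(median(accs), 0.9)
})

test_that("permuted labels give chance-level held-out accuracy", {
  cfg <- sim_config(n_trials = 16, trial_seconds = 3, n_channels = 4,
                    noise_sd = 0, seed = 77)
  sub <- simulate_subject(cfg, 1)
  segs <- lapply(sub$eeg, function(e) common_reference(bandpass_eeg(e)))
  labs <- sub$labels
  set.seed(5)
  labs$class <- sample(ifelse(labs$arousal > 5, "high", "low"))
  tr_idx <- 1:12; te_idx <- 13:16
  net <- train_eegnet(segs[tr_idx], labs[tr_idx, ],
                      mode = "classification", epochs = 10, lr = 1e-3,
                      seed = 1)
  post <- predict_emotion(net, segs[te_idx])
  acc <- mean(colnames(post)[max.col(post)] == labs$class[te_idx])
  n <- length(te_idx)
  band <- 1.96 * sqrt(0.25 / n)
  expect_true(acc >= 0.5 - band - 1e-9 && acc <= 0.5 + band + 1e-9)
})

test_that("strong L2 regularization shrinks the weights", {
  cfg <- sim_config(n_trials = 8, trial_seconds = 3, n_channels = 4,
                    noise_sd = 0, seed = 13)
  sub <- simulate_subject(cfg, 1)
  segs <- sub$eeg
  wnorm <- function(l2) {
    net <- train_eegnet(segs, sub$labels, mode = "regression", epochs = 8,
                        lr = 1e-3, seed = 2, l2 = l2)
    dense <- net$layers[[14]]
    sqrt(sum(dense$params$W^2))
  }
  expect_lt(wnorm(10), wnorm(0))
})

test_that("prediction is deterministic, bounded and batch-invariant", {
  cfg <- sim_config(n_trials = 6, trial_seconds = 3, n_channels = 4,
                    seed = 21)
  sub <- simulate_subject(cfg, 1)
  net <- train_eegnet(sub$eeg, sub$labels, mode = "regression", epochs = 3,
                      lr = 1e-3, seed = 3)
  p1 <- predict_emotion(net, sub$eeg)
  p2 <- predict_emotion(net, sub$eeg)
  expect_identical(p1, p2)
  expect_true(all(p1$arousal01 >= 0 & p1$arousal01 <= 1))
  expect_true(all(p1$valence01 >= 0 & p1$valence01 <= 1))
  p_single <- predict_emotion(net, sub$eeg[3])
  expect_equal(p_single$arousal01, p1$arousal01[3])
  expect_error(predict_emotion(build_eegnet(eegnet_spec(4, 384)), sub$eeg),
               "untrained")
})

test_that("accuracy, kappa and AUC agree with hand computations", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                    scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$auc, 1)

  half <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(half$accuracy, 0.5)
  expect_equal(half$kappa, 0)  # p_o = p_e = 0.5

  sep <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                scores = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(sep$auc, 1)
  expect_error(classification_metrics(c(1, 1), c(1, 0), scores = c(1, 0)),
               "single class")
})

test_that("AUC matches pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- runif(40) + 0.5 * y
  ours <- classification_metrics(y, as.integer(s > 0.7), scores = s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  trans <- classification_metrics(y, as.integer(s > 0.7),
                                  scores = exp(3 * s))$auc
  expect_equal(trans, ours)
})

test_that("kappa vanishes on average under label permutation", {
  set.seed(7)
  y <- rep(c(0, 1), 30)
  kaps <- vapply(1:20, function(i)
    classification_metrics(y, sample(y))$kappa, numeric(1))
  expect_lt(abs(mean(kaps)), 0.05)
})
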
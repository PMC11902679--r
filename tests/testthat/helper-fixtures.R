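# Shared fixtures, built in code. Heavier objects (a small trained
# autoencoder) are memoized so several tests can reuse them.

.fixture_env <- new.env(parent = emptyenv())

# desk-scale config: short trials, few channels, 16-pitch/24-frame rolls
small_cfg <- function(seed = 2, ...) {
  sim_config(n_trials = 20, trial_seconds = 6, n_channels = 6,
             fs_roll = 4, pitch_lo = 48, pitch_hi = 63, seed = seed, ...)
}

# a list of rolls plus their labels under small_cfg
small_rollset <- function(n = 20, seed = 2) {
  cfg <- small_cfg(seed = seed)
  labels <- simulate_labels(cfg)[seq_len(n), ]
  rolls <- lapply(seq_len(n), function(i)
    midi_to_roll(simulate_midi_clip(labels[i, ], cfg, seed = 100 + i),
                 fs_roll = cfg$fs_roll, pitch_lo = cfg$pitch_lo,
                 pitch_hi = cfg$pitch_hi, duration = cfg$trial_seconds))
  list(cfg = cfg, labels = labels, rolls = rolls)
}

# small trained autoencoder shared across retrieval tests
fixture_trained_ae <- function() {
  if (is.null(.fixture_env$ae)) {
    rs <- small_rollset(n = 12, seed = 5)
    ae <- train_autoencoder(rs$rolls, rs$labels, epochs = 60, batch = 8,
                            lr = 1e-2, seed = 1, cka_weight = 0,
                            filters = c(4, 8, 16), dropout = 0.2)
    .fixture_env$ae <- list(ae = ae, rolls = rs$rolls, labels = rs$labels)
  }
  .fixture_env$ae
}
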
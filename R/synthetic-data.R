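#' Configuration for the synthetic DEAP-style cohort
#'
#' Defines the study conditions the simulator emulates: per subject, 40
#' one-minute trials of 32-channel EEG sampled at 128 Hz, each paired with a
#' one-minute MIDI clip and a 1--9 arousal/valence self-rating. The emotion to
#' signal couplings are monotone and single-parameter per dimension:
#' \itemize{
#'   \item EEG: a 10 Hz (alpha) component whose amplitude decreases with
#'     arousal, a 30 Hz (high-beta) component whose amplitude increases with
#'     arousal, and a 20 Hz left/right amplitude asymmetry that tracks
#'     valence; all superimposed on 1/f (pink) background noise.
#'   \item MIDI: note rate increases with arousal; register (mean pitch) and
#'     scale flavour (major-like vs minor-like interval set) shift with
#'     valence.
#' }
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials trials per subject (DEAP: 40).
#' @param trial_seconds trial duration in seconds (DEAP: 60).
#' @param n_channels EEG channels (DEAP: 32). Channels \code{1:(n/2)} are
#'   treated as the left hemisphere for the valence asymmetry.
#' @param fs_eeg EEG sampling rate in Hz (DEAP preprocessed release: 128).
#'   Must exceed 90 Hz so the 4--45 Hz analysis band is representable.
#' @param fs_roll piano-roll frame rate in frames/s. Default 16 so a 6-s
#'   window is 96 frames (divisible by 8, matching the autoencoder's three
#'   2x downsamplings).
#' @param pitch_lo,pitch_hi MIDI note-number window of the simulated clips.
#' @param effect_arousal,effect_valence dimensionless effect sizes scaling the
#'   emotion-to-signal couplings; 0 removes the coupling.
#' @param noise_sd standard deviation of the pink-noise background
#'   (signal units; the oscillatory components have amplitude of order 1).
#' @param seed integer seed fixing all randomness of the generated dataset.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_subjects = 1L, n_trials = 40L, trial_seconds = 60,
                       n_channels = 32L, fs_eeg = 128, fs_roll = 16,
                       pitch_lo = 36L, pitch_hi = 83L,
                       effect_arousal = 1, effect_valence = 1,
                       noise_sd = 1, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials),
              trial_seconds = trial_seconds, n_channels = as.integer(n_channels),
              fs_eeg = fs_eeg, fs_roll = fs_roll,
              pitch_lo = as.integer(pitch_lo), pitch_hi = as.integer(pitch_hi),
              effect_arousal = effect_arousal, effect_valence = effect_valence,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(cfg$n_subjects >= 1, cfg$n_trials >= 1, cfg$trial_seconds > 0,
            cfg$n_channels >= 1, cfg$fs_roll > 0,
            cfg$pitch_lo < cfg$pitch_hi,
            cfg$pitch_lo >= 0, cfg$pitch_hi <= 127,
            cfg$effect_arousal >= 0, cfg$effect_valence >= 0,
            cfg$noise_sd >= 0)
  if (cfg$fs_eeg <= 2 * 45)
    stop("fs_eeg must exceed 90 Hz so the 4-45 Hz band is representable")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate per-trial emotion ratings on the DEAP 1--9 scale
#'
#' Trials are assigned to the four arousal/valence quadrants in (near-)equal
#' numbers; within a quadrant, ratings are drawn uniformly from the low
#' (\code{[1, 4.5]}) or high (\code{[5.5, 9]}) half of the scale, so the full
#' 1--9 range is covered and the binarization threshold (raw > 5) is never
#' ambiguous.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return data frame with columns \code{trial}, \code{arousal},
#'   \code{valence} (raw 1--9), \code{arousal01}, \code{valence01}
#'   (normalized, see \code{\link{normalize_rating}}), and \code{quadrant}
#'   (1 = HA/HV, 2 = HA/LV, 3 = LA/LV, 4 = LA/HV).
#' @export
simulate_labels <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed %||% cfg$seed)
  n <- cfg$n_trials
  quadrant <- sample(rep_len(1:4, n))
  hi_a <- quadrant %in% c(1L, 2L)
  hi_v <- quadrant %in% c(1L, 4L)
  draw <- function(high) ifelse(high, runif(n, 5.5, 9), runif(n, 1, 4.5))
  arousal <- draw(hi_a)
  valence <- draw(hi_v)
  data.frame(trial = seq_len(n),
             arousal = arousal, valence = valence,
             arousal01 = normalize_rating(arousal),
             valence01 = normalize_rating(valence),
             quadrant = quadrant)
}

# 1/f-shaped Gaussian noise, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Simulate one EEG trial coupled to an emotion label
#'
#' The trial is pink noise plus three oscillatory components (see
#' \code{\link{sim_config}}): alpha (10 Hz) amplitude \code{(1 - arousal01)},
#' high-beta (30 Hz) amplitude \code{arousal01}, both scaled by
#' \code{effect_arousal}, and a 20 Hz component whose amplitude is
#' \code{valence01} on left-hemisphere channels and \code{1 - valence01} on
#' right-hemisphere channels, scaled by \code{effect_valence}. Channel phases
#' are random but seeded.
#'
#' @param label a one-row data frame (or list) with \code{arousal},
#'   \code{valence} raw ratings in \code{[1, 9]}.
#' @param cfg a \code{\link{sim_config}}.
#' @param effect_scale extra per-subject multiplier on both effect sizes
#'   (used to simulate subjects with degraded label--signal coupling).
#' @param seed optional seed for this trial's randomness.
#' @return an \code{\link{eeg_segment}} of size
#'   \code{n_channels x (fs_eeg * trial_seconds)}.
#' @export
simulate_eeg_trial <- function(label, cfg, effect_scale = 1, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            label$arousal >= 1, label$arousal <= 9,
            label$valence >= 1, label$valence <= 9)
  if (!is.null(seed)) set.seed(seed)
  n <- round(cfg$fs_eeg * cfg$trial_seconds)
  t <- (seq_len(n) - 1) / cfg$fs_eeg
  a01 <- normalize_rating(label$arousal)
  v01 <- normalize_rating(label$valence)
  ea <- cfg$effect_arousal * effect_scale
  ev <- cfg$effect_valence * effect_scale
  amp_alpha <- ea * (1 - a01)
  amp_beta <- ea * a01
  left <- seq_len(cfg$n_channels) <= cfg$n_channels %/% 2
  data <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    phase <- runif(3, 0, 2 * pi)
    amp_val <- ev * if (left[ch]) v01 else 1 - v01
    osc <- amp_alpha * sin(2 * pi * 10 * t + phase[1]) +
      amp_beta * sin(2 * pi * 30 * t + phase[2]) +
      amp_val * sin(2 * pi * 20 * t + phase[3])
    noise <- if (cfg$noise_sd > 0) cfg$noise_sd * pink_noise(n) else 0
    data[ch, ] <- osc + noise
  }
  eeg_segment(data, fs = cfg$fs_eeg)
}

# Major-like and minor-like interval sets (semitones above the local root).
.scale_major <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
.scale_minor <- c(0L, 2L, 3L, 5L, 7L, 8L, 10L)

#' Simulate a one-minute note sequence coupled to an emotion label
#'
#' Note rate rises with arousal (about 0.5--3.5 notes/s over the rating
#' range at unit effect size); the register centre and the interval set
#' (major-like for high valence, minor-like for low) shift with valence.
#' Onsets sit on a jittered regular grid and same-pitch notes never abut,
#' so conversion to a piano-roll and back preserves onset frames.
#'
#' @inheritParams simulate_eeg_trial
#' @return a \code{\link{note_sequence}} no longer than
#'   \code{cfg$trial_seconds}.
#' @export
simulate_midi_clip <- function(label, cfg, effect_scale = 1, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            label$arousal >= 1, label$arousal <= 9,
            label$valence >= 1, label$valence <= 9)
  if (!is.null(seed)) set.seed(seed)
  a01 <- normalize_rating(label$arousal)
  v01 <- normalize_rating(label$valence)
  a_eff <- 0.5 + (a01 - 0.5) * min(cfg$effect_arousal * effect_scale, 1)
  v_eff <- 0.5 + (v01 - 0.5) * min(cfg$effect_valence * effect_scale, 1)
  dur_total <- cfg$trial_seconds
  rate <- 0.5 + 3 * a_eff
  n_notes <- max(1L, as.integer(round(rate * dur_total)))
  dt <- dur_total / n_notes
  onsets <- (seq_len(n_notes) - 1) * dt + runif(n_notes, 0, 0.1 * dt)
  durations <- pmax(0.6 * dt, 1.2 / cfg$fs_roll)
  offsets <- pmin(onsets + durations, dur_total)
  span <- cfg$pitch_hi - cfg$pitch_lo
  centre <- cfg$pitch_lo + span * (0.3 + 0.4 * v_eff)
  scale_set <- if (v_eff > 0.5) .scale_major else .scale_minor
  degree <- sample(scale_set, n_notes, replace = TRUE)
  octave <- sample(c(-12L, 0L, 0L, 12L), n_notes, replace = TRUE)
  pitch <- as.integer(clamp(round(centre) + degree + octave - 6L,
                            cfg$pitch_lo, cfg$pitch_hi))
  # keep same-pitch notes at least one empty roll frame apart so roll round
  # trips are lossless: move colliding pitches to the nearest free semitone.
  # Collision is judged in frame units, mirroring midi_to_roll: runs merge
  # when floor(onset*fs) <= ceil(offset*fs) of an earlier same-pitch note.
  for (i in seq_len(n_notes)[-1]) {
    collides <- function(pp) {
      prev <- which(pitch[seq_len(i - 1)] == pp)
      length(prev) > 0 &&
        any(floor(onsets[i] * cfg$fs_roll + 1e-9) <=
              ceiling(offsets[prev] * cfg$fs_roll - 1e-9))
    }
    if (collides(pitch[i])) {
      for (delta in as.integer(rbind(1:6, -(1:6)))) {
        cand <- pitch[i] + delta
        if (cand >= cfg$pitch_lo && cand <= cfg$pitch_hi &&
            !collides(cand)) {
          pitch[i] <- cand
          break
        }
      }
    }
  }
  velocity <- as.integer(round(40 + 60 * a01))
  note_sequence(pitch = pitch, onset = onsets, offset = offsets,
                velocity = velocity, tempo = 120)
}

#' Simulate one subject's full session
#'
#' @inheritParams simulate_eeg_trial
#' @param subject_id integer subject identifier (used for seeding and
#'   provenance).
#' @return list with \code{labels} (data frame, including a \code{subject}
#'   column), \code{eeg} (list of \code{\link{eeg_segment}}s) and
#'   \code{clips} (list of \code{\link{note_sequence}}s), one per trial.
#' @export
simulate_subject <- function(cfg, subject_id = 1L, effect_scale = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- cfg$seed + 100003L * (as.integer(subject_id) %% 1000L)
  labels <- simulate_labels(cfg, seed = base)
  labels$subject <- as.integer(subject_id)
  eeg <- vector("list", cfg$n_trials)
  clips <- vector("list", cfg$n_trials)
  for (tr in seq_len(cfg$n_trials)) {
    lab <- labels[tr, ]
    eeg[[tr]] <- simulate_eeg_trial(lab, cfg, effect_scale,
                                    seed = base + 7L * tr)
    eeg[[tr]]$subject <- as.integer(subject_id)
    eeg[[tr]]$trial <- tr
    clips[[tr]] <- simulate_midi_clip(lab, cfg, effect_scale,
                                      seed = base + 7L * tr + 3L)
  }
  list(labels = labels, eeg = eeg, clips = clips)
}

#' Simulate a cohort
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param effect_scales optional numeric vector (length \code{n_subjects}) of
#'   per-subject coupling multipliers; defaults to 1 for everyone.
#' @return object of class \code{affect_sim}: list of per-subject datasets
#'   (see \code{\link{simulate_subject}}) plus the config.
#' @export
simulate_dataset <- function(cfg, effect_scales = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  effect_scales <- effect_scales %||% rep(1, cfg$n_subjects)
  stopifnot(length(effect_scales) == cfg$n_subjects)
  subjects <- lapply(seq_len(cfg$n_subjects), function(s)
    simulate_subject(cfg, s, effect_scales[s]))
  structure(list(subjects = subjects, config = cfg,
                 effect_scales = effect_scales),
            class = "affect_sim")
}

#' Write a simulated cohort to disk
#'
#' Emits one Standard MIDI file per trial, one tab-separated EEG matrix per
#' trial (channels x samples), and a single \code{labels.csv} with columns
#' \code{subject, trial, arousal, valence}.
#'
#' @param sim an \code{affect_sim} from \code{\link{simulate_dataset}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "affect_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- do.call(rbind, lapply(sim$subjects, `[[`, "labels"))
  utils::write.csv(labels[, c("subject", "trial", "arousal", "valence")],
                   file.path(dir, "labels.csv"), row.names = FALSE)
  for (sub in sim$subjects) {
    sid <- sub$labels$subject[1]
    for (tr in seq_along(sub$clips)) {
      stem <- sprintf("s%02d_t%02d", sid, tr)
      write_midi(sub$clips[[tr]], file.path(dir, paste0(stem, ".mid")))
      utils::write.table(sub$eeg[[tr]]$data,
                         file.path(dir, paste0(stem, "_eeg.tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
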
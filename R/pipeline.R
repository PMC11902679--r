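#' Stratified train/test split of labelled segments
#'
#' Splits segment indices into disjoint, exhaustive train and test sets,
#' stratified by arousal/valence quadrant. The total training size is
#' \code{floor(train_frac * n)}; per-quadrant counts start from the floor of
#' the proportional share with the remainder distributed by largest
#' fractional part (ties to the lower quadrant id), so quadrant proportions
#' in the training set stay within one item of the global proportions.
#'
#' @param labels data frame with one row per segment; quadrants are taken
#'   from a \code{quadrant} column or computed from \code{arousal}/
#'   \code{valence}.
#' @param train_frac fraction of segments assigned to training, in (0, 1).
#' @param seed seed for the within-stratum sampling.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_dataset <- function(labels, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  n <- nrow(labels)
  quad <- labels$quadrant %||% label_quadrant(labels$arousal, labels$valence)
  set.seed(seed)
  total <- floor(train_frac * n)
  strata <- sort(unique(quad))
  share <- train_frac * vapply(strata, function(q) sum(quad == q), numeric(1))
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(share - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  train <- integer(0)
  for (si in seq_along(strata)) {
    ids <- which(quad == strata[si])
    take <- min(base[si], length(ids))
    train <- c(train, sample(ids, take))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Run the three-stage pipeline for one subject
#'
#' Preprocesses the subject's trials (band-pass, common average reference,
#' aligned EEG/roll windowing, fade-out exclusion), splits segments 80/20
#' stratified by quadrant, trains the EEGNet regressor and the CKA-supervised
#' piano-roll autoencoder on the training portion, predicts the test
#' segments' emotion coordinates and retrieves/decodes piano-rolls for them,
#' and finally compares the generated rolls with the training rolls metric by
#' metric.
#'
#' @param data one subject's dataset from \code{\link{simulate_subject}}
#'   (or any list with \code{labels}, \code{eeg}, \code{clips}).
#' @param cfg the \code{\link{sim_config}} describing the recordings.
#' @param window_s window length in seconds.
#' @param train_frac training fraction of the split.
#' @param eegnet_epochs,ae_epochs,eegnet_lr,ae_lr training schedules.
#' @param ae_filters autoencoder filter counts.
#' @param cka_weight weight of the bottleneck alignment term.
#' @param k,threshold retrieval neighbours and binarization threshold.
#' @param energy_frac fade-out exclusion threshold
#'   (see \code{\link{exclude_fadeouts}}).
#' @param seed seed for split and both trainings.
#' @param stages character subset of \code{c("extract", "predict")}:
#'   dropping \code{"predict"} stops after feature extraction.
#' @return list (per-subject manifest): segment counts, split sizes,
#'   \code{val_accuracy} (mean binarized test accuracy over both heads),
#'   training histories, \code{train_rolls}, \code{generated_rolls}, the
#'   \code{report} comparison, and per-stage provenance.
#' @export
run_subject_pipeline <- function(data, cfg, window_s = 6, train_frac = 0.8,
                                 eegnet_epochs = 30, ae_epochs = 30,
                                 eegnet_lr = 3e-3, ae_lr = 1e-2,
                                 ae_filters = c(32, 64, 128),
                                 ae_dropout = 0.5,
                                 cka_weight = 0.5, k = 5, threshold = 0.5,
                                 energy_frac = 0.05, seed = 1L,
                                 stages = c("extract", "predict")) {
  segments <- list(); rolls <- list(); seg_rows <- list()
  for (tr in seq_along(data$eeg)) {
    eeg <- common_reference(bandpass_eeg(data$eeg[[tr]]))
    roll <- midi_to_roll(data$clips[[tr]], fs_roll = cfg$fs_roll,
                         pitch_lo = cfg$pitch_lo, pitch_hi = cfg$pitch_hi,
                         duration = cfg$trial_seconds)
    pairs <- window_segments(eeg, window_s, paired_roll = roll)
    pairs <- exclude_fadeouts(pairs, energy_frac)
    for (p in pairs) {
      segments[[length(segments) + 1]] <- p$eeg
      rolls[[length(rolls) + 1]] <- p$roll
      seg_rows[[length(seg_rows) + 1]] <- data$labels[tr, ]
    }
  }
  seg_labels <- do.call(rbind, seg_rows)
  n_seg <- length(segments)
  sp <- split_dataset(seg_labels, train_frac, seed = seed)
  out <- list(subject = data$labels$subject[1], n_segments = n_seg,
              n_train = length(sp$train), n_test = length(sp$test),
              window_s = window_s, seed = seed)
  if (!"extract" %in% stages) return(out)

  net <- train_eegnet(segments[sp$train], seg_labels[sp$train, ],
                      mode = "regression", epochs = eegnet_epochs,
                      lr = eegnet_lr, seed = seed)
  pred <- predict_emotion(net, segments[sp$test])
  truth <- seg_labels[sp$test, ]
  acc_a <- mean((pred$arousal01 > 0.5) == (truth$arousal01 > 0.5))
  acc_v <- mean((pred$valence01 > 0.5) == (truth$valence01 > 0.5))
  ae <- train_autoencoder(rolls[sp$train], seg_labels[sp$train, ],
                          epochs = ae_epochs, lr = ae_lr, seed = seed,
                          cka_weight = cka_weight, filters = ae_filters,
                          dropout = ae_dropout)
  out$val_accuracy <- mean(c(acc_a, acc_v))
  out$val_accuracy_arousal <- acc_a
  out$val_accuracy_valence <- acc_v
  out$eegnet_history <- net$history
  out$ae_history <- ae$history
  out$train_rolls <- rolls[sp$train]
  out$test_rolls <- rolls[sp$test]
  if (!"predict" %in% stages) return(out)

  codes <- encode_rolls(ae, rolls[sp$train])
  train_lab <- as.matrix(seg_labels[sp$train, c("arousal01", "valence01")])
  gen <- predict_pianorolls(as.matrix(pred), train_lab, codes, ae,
                            k = min(k, length(sp$train)),
                            threshold = threshold)
  out$generated_rolls <- gen
  out$report <- compare_groups(out$train_rolls, gen)
  out
}

#' Rank subjects and compare training data with generated outputs
#'
#' Ranks subjects by EEGNet validation accuracy and emits the three scenario
#' comparisons: training-vs-training (a group compared with itself -- the
#' baseline identity, KL 0 and overlap 1), training vs the worst-performing
#' subject's generated rolls, and training vs the best-performing subject's
#' generated rolls. Each subject's generated rolls are compared against that
#' subject's own training pool (models are per-subject throughout). Ties in
#' accuracy are broken deterministically by subject id.
#'
#' @param results list of per-subject manifests from
#'   \code{\link{run_subject_pipeline}} (with the \code{"predict"} stage).
#' @return list with \code{ranking} (data frame: subject, val_accuracy,
#'   rank), \code{reports} (named list of \code{comparison_report}s for
#'   \code{t_vs_t}, \code{t_vs_w}, \code{t_vs_b}) and \code{table} (the 4
#'   metrics x 3 scenarios long-format data frame).
#' @export
subject_report <- function(results) {
  if (length(results) < 2) stop("need at least two evaluated subjects")
  acc <- vapply(results, `[[`, numeric(1), "val_accuracy")
  sid <- vapply(results, `[[`, numeric(1), "subject")
  ord <- order(-acc, sid)
  ranking <- data.frame(subject = sid[ord], val_accuracy = acc[ord],
                        rank = seq_along(ord))
  best <- results[[ord[1]]]
  worst <- results[[ord[length(ord)]]]
  reports <- list(
    t_vs_t = compare_groups(best$train_rolls, best$train_rolls),
    t_vs_w = compare_groups(worst$train_rolls, worst$generated_rolls),
    t_vs_b = compare_groups(best$train_rolls, best$generated_rolls))
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- as.data.frame(reports[[nm]])
    r$scenario <- nm
    r
  }))
  list(ranking = ranking, reports = reports,
       table = tab[, c("scenario", "metric", "mean", "std", "kl", "overlap")])
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates the cohort, runs the per-subject three-stage pipeline, and when
#' at least two subjects complete the prediction stage, assembles the ranked
#' subject comparison. The returned manifest carries the configuration, all
#' per-subject results and a content fingerprint, so a rerun with the same
#' configuration and seed reproduces it exactly.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param effect_scales per-subject coupling multipliers (see
#'   \code{\link{simulate_dataset}}).
#' @param ... passed to \code{\link{run_subject_pipeline}}.
#' @return list of class \code{pipeline_manifest}: \code{config},
#'   \code{subjects} (per-subject manifests), \code{report} (from
#'   \code{\link{subject_report}}, multi-subject runs only) and \code{hash}.
#' @export
run_pipeline <- function(cfg, effect_scales = NULL, ...) {
  sim <- simulate_dataset(cfg, effect_scales)
  subjects <- lapply(sim$subjects, run_subject_pipeline, cfg = cfg, ...)
  manifest <- list(config = unclass(cfg), effect_scales = sim$effect_scales,
                   subjects = subjects)
  has_pred <- all(vapply(subjects, function(s) !is.null(s$report),
                         logical(1)))
  if (length(subjects) >= 2 && has_pred)
    manifest$report <- subject_report(subjects)
  summary_obj <- list(cfg = unclass(cfg),
                      acc = lapply(subjects, `[[`, "val_accuracy"),
                      tab = if (!is.null(manifest$report))
                        manifest$report$table)
  manifest$hash <- fnv1a(serialize(summary_obj, NULL))
  class(manifest) <- "pipeline_manifest"
  manifest
}
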
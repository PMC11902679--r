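#' EEG segment container
#'
#' A windowed multichannel EEG recording: a channels x samples matrix with its
#' sampling rate and provenance.
#'
#' @param data numeric matrix, channels x samples (microvolts or simulator
#'   units); must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param subject,trial,window optional integer provenance.
#' @return object of class \code{eeg_segment}.
#' @export
eeg_segment <- function(data, fs, subject = NA_integer_, trial = NA_integer_,
                        window = NA_integer_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("EEG data must be finite (no NaN/Inf)")
  stopifnot(is.numeric(fs), fs > 0)
  structure(list(data = data, fs = fs, subject = subject, trial = trial,
                 window = window),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Normalize a 1--9 rating to the unit interval
#'
#' Maps the DEAP self-assessment scale onto \code{[0, 1]} via
#' \code{(raw - 1) / 8}, the range of the network's sigmoid outputs.
#'
#' @param raw numeric rating(s) in \code{[1, 9]}.
#' @return value(s) in \code{[0, 1]}.
#' @export
normalize_rating <- function(raw) {
  stopifnot(all(raw >= 1 & raw <= 9))
  (raw - 1) / 8
}

#' Binarize a 1--9 rating into low/high
#'
#' @param raw numeric rating(s) in \code{[1, 9]}.
#' @return factor with levels \code{low}, \code{high}; high iff raw > 5.
#' @export
binarize_rating <- function(raw) {
  stopifnot(all(raw >= 1 & raw <= 9))
  factor(ifelse(raw > 5, "high", "low"), levels = c("low", "high"))
}

#' Quadrant of the arousal/valence plane
#'
#' @param arousal,valence raw 1--9 ratings.
#' @return integer in 1--4: 1 = high arousal/high valence, 2 = HA/LV,
#'   3 = LA/LV, 4 = LA/HV.
#' @export
label_quadrant <- function(arousal, valence) {
  hi_a <- arousal > 5
  hi_v <- valence > 5
  ifelse(hi_a & hi_v, 1L, ifelse(hi_a & !hi_v, 2L,
         ifelse(!hi_a & !hi_v, 3L, 4L)))
}

#' Anti-aliased polyphase resampling of an EEG segment
#'
#' Downsamples every channel with \code{signal::resample} at the rational
#' rate \code{target_fs / fs}. Upsampling is refused: the conditioning chain
#' only ever reduces the rate (e.g. 512 Hz recordings to 128 Hz).
#'
#' @param seg an \code{\link{eeg_segment}}.
#' @param target_fs desired rate in Hz, at most \code{seg$fs}.
#' @return resampled \code{eeg_segment} with
#'   \code{round(samples * target_fs / fs)} samples.
#' @export
resample_eeg <- function(seg, target_fs) {
  stopifnot(inherits(seg, "eeg_segment"), target_fs > 0)
  if (target_fs > seg$fs) stop("upsampling refused: target_fs > fs")
  if (target_fs == seg$fs) return(seg)
  frac <- .rational(target_fs / seg$fs)
  out <- t(apply(seg$data, 1, function(x)
    signal::resample(x, p = frac[1], q = frac[2])))
  n_target <- round(ncol(seg$data) * target_fs / seg$fs)
  out <- out[, seq_len(min(ncol(out), n_target)), drop = FALSE]
  eeg_segment(out, fs = target_fs, subject = seg$subject, trial = seg$trial,
              window = seg$window)
}

# small rational approximation p/q of a rate ratio
.rational <- function(x, max_den = 4096) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio as a small rational")
}

#' Zero-phase band-pass filtering
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), the conventional zero-phase EEG conditioning
#' filter. Defaults retain the 4--45 Hz band.
#'
#' @param seg an \code{\link{eeg_segment}}.
#' @param lo,hi band edges in Hz, \code{0 < lo < hi < fs/2}.
#' @param order Butterworth order of the one-pass prototype.
#' @return filtered \code{eeg_segment}.
#' @export
bandpass_eeg <- function(seg, lo = 4, hi = 45, order = 4) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!(lo > 0 && lo < hi && hi < seg$fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / (seg$fs / 2), type = "pass")
  out <- t(apply(seg$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_segment(out, fs = seg$fs, subject = seg$subject, trial = seg$trial,
              window = seg$window)
}

#' Common average reference
#'
#' Subtracts the per-sample mean across channels from every channel
#' (common average referencing, the conventional reading of common-reference
#' spatial filtering), so each output column sums to zero.
#'
#' @param seg an \code{\link{eeg_segment}} with at least two channels.
#' @return re-referenced \code{eeg_segment}.
#' @export
common_reference <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (nrow(seg$data) < 2) stop("common average reference needs >= 2 channels")
  out <- sweep(seg$data, 2, colMeans(seg$data))
  eeg_segment(out, fs = seg$fs, subject = seg$subject, trial = seg$trial,
              window = seg$window)
}

#' Split a trial into non-overlapping windows
#'
#' Divides a trial into \code{floor(duration / window_s)} windows starting at
#' t = 0. When a paired piano-roll is supplied, the roll is windowed over the
#' identical time spans so that EEG and music segments stay aligned.
#'
#' @param trial an \code{\link{eeg_segment}} covering the whole trial.
#' @param window_s window length in seconds (default 6).
#' @param paired_roll optional \code{\link{piano_roll}} covering the same
#'   trial.
#' @return list of windows; each element is either an \code{eeg_segment}
#'   (no roll) or a list \code{(eeg =, roll =)}. Empty (with a warning) if the
#'   trial is shorter than one window.
#' @export
window_segments <- function(trial, window_s = 6, paired_roll = NULL) {
  stopifnot(inherits(trial, "eeg_segment"))
  if (window_s <= 0) stop("window_s must be positive")
  n_eeg <- round(window_s * trial$fs)
  n_win <- floor(ncol(trial$data) / n_eeg)
  if (n_win == 0) {
    warning("trial shorter than one window; returning empty list")
    return(list())
  }
  if (!is.null(paired_roll)) stopifnot(inherits(paired_roll, "piano_roll"))
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    cols <- ((w - 1) * n_eeg + 1):(w * n_eeg)
    seg <- eeg_segment(trial$data[, cols, drop = FALSE], fs = trial$fs,
                       subject = trial$subject, trial = trial$trial,
                       window = w)
    if (is.null(paired_roll)) {
      out[[w]] <- seg
    } else {
      n_roll <- round(window_s * paired_roll$fs_roll)
      fcols <- ((w - 1) * n_roll + 1):(w * n_roll)
      fcols <- fcols[fcols <= ncol(paired_roll$mask)]
      mask <- paired_roll$mask[, fcols, drop = FALSE]
      if (ncol(mask) < n_roll)  # right-pad a short final roll window
        mask <- cbind(mask, matrix(0L, nrow(mask), n_roll - ncol(mask)))
      out[[w]] <- list(eeg = seg,
                       roll = piano_roll(mask, paired_roll$fs_roll,
                                         paired_roll$pitch_offset))
    }
  }
  out
}

#' Exclude windows with fade-out endings
#'
#' Drops paired windows whose note activity in the final second falls below
#' \code{energy_frac} of the window's mean activity -- an energy heuristic for
#' the fade-out exclusion applied to the stimulus set (the published count, 9
#' of 400, is data-dependent; only the rule's shape is reproducible).
#'
#' @param pairs list of \code{(eeg =, roll =)} pairs from
#'   \code{\link{window_segments}}.
#' @param energy_frac fraction of mean activity below which the final second
#'   counts as a fade-out.
#' @return the surviving pairs, with attribute \code{n_excluded}.
#' @export
exclude_fadeouts <- function(pairs, energy_frac = 0.1) {
  if (length(pairs) == 0) return(pairs)
  keep <- vapply(pairs, function(p) {
    stopifnot(!is.null(p$roll))
    mask <- p$roll$mask
    n_last <- min(ncol(mask), round(p$roll$fs_roll))
    final <- mean(mask[, (ncol(mask) - n_last + 1):ncol(mask), drop = FALSE])
    final >= energy_frac * mean(mask)
  }, logical(1))
  out <- pairs[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
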
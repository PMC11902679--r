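#' Piano-roll container
#'
#' A binary pitch x time mask of note activity at a fixed frame rate.
#'
#' @param mask matrix of 0/1 entries, rows = pitches (row 1 is
#'   \code{pitch_offset}), columns = frames.
#' @param fs_roll frame rate in frames per second.
#' @param pitch_offset MIDI note number of row 1.
#' @return object of class \code{piano_roll}.
#' @export
piano_roll <- function(mask, fs_roll, pitch_offset) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("piano-roll mask must be binary")
  stopifnot(fs_roll > 0, pitch_offset >= 0, pitch_offset <= 127)
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, fs_roll = fs_roll,
                 pitch_offset = as.integer(pitch_offset)),
            class = "piano_roll")
}

#' @export
print.piano_roll <- function(x, ...) {
  cat(sprintf(
    "<piano_roll> %d pitches x %d frames @ %g fps (pitches %d-%d, %d on-cells)\n",
    nrow(x$mask), ncol(x$mask), x$fs_roll, x$pitch_offset,
    x$pitch_offset + nrow(x$mask) - 1L, sum(x$mask)))
  invisible(x)
}

#' Magnitude spectrogram of a mono waveform
#'
#' Hann-windowed short-time Fourier transform magnitude with
#' \code{1 + floor((length - n_fft) / hop)} frames and \code{n_fft/2 + 1}
#' frequency bins.
#'
#' @param audio numeric vector (mono waveform), length at least \code{n_fft}.
#' @param n_fft frame length in samples.
#' @param hop hop size in samples.
#' @param fs audio sampling rate in Hz (metadata only).
#' @return object of class \code{spectrogram}: list with \code{mag}
#'   (bins x frames, nonnegative), \code{fs_audio}, \code{hop}, \code{n_fft}.
#' @export
stft_magnitude <- function(audio, n_fft = 1024, hop = 512, fs = NA_real_) {
  if (length(audio) == 0) stop("empty audio")
  if (length(audio) < n_fft) stop("audio shorter than one analysis frame")
  n_frames <- 1 + floor((length(audio) - n_fft) / hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_fft - 1) / n_fft)  # Hann
  bins <- n_fft / 2 + 1
  mag <- matrix(0, bins, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- audio[((f - 1) * hop + 1):((f - 1) * hop + n_fft)] * win
    mag[, f] <- Mod(stats::fft(seg))[seq_len(bins)]
  }
  structure(list(mag = mag, fs_audio = fs, hop = hop, n_fft = n_fft),
            class = "spectrogram")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix \code{Z} (frequency x time) into a spectral
#' dictionary \code{D} (frequency x rank) and activations \code{A}
#' (rank x time) so that \code{D \%*\% A} approximates \code{Z}, by the
#' classical multiplicative update rules. The Euclidean (Frobenius) cost is
#' the default; generalized Kullback--Leibler is available. Both rules keep
#' the factors nonnegative and never increase the objective.
#'
#' @param Z nonnegative matrix, or a \code{\link{stft_magnitude}} spectrogram.
#' @param rank decomposition rank (number of spectral templates),
#'   \code{1 <= rank <= min(dim(Z))}.
#' @param n_iter maximum iterations.
#' @param tol stop when the relative objective improvement falls below this.
#' @param seed seed for the random nonnegative initialization.
#' @param loss \code{"frobenius"} (default) or \code{"kl"}.
#' @param dictionary optional fixed/initial dictionary (frequency x rank),
#'   e.g. harmonic templates from \code{\link{harmonic_dictionary}}.
#' @param update_dictionary if \code{FALSE}, only the activations are updated
#'   (supervised transcription against known templates).
#' @return object of class \code{nmf_model}: \code{dictionary},
#'   \code{activations}, \code{rank}, \code{loss}, \code{objective_trace}
#'   (per-iteration cost, non-increasing).
#' @export
nmf_factorize <- function(Z, rank, n_iter = 200, tol = 1e-7, seed = 1L,
                          loss = c("frobenius", "kl"), dictionary = NULL,
                          update_dictionary = is.null(dictionary)) {
  if (inherits(Z, "spectrogram")) Z <- Z$mag
  Z <- as.matrix(Z)
  loss <- match.arg(loss)
  if (any(Z < 0)) stop("Z must be nonnegative")
  f <- nrow(Z); tt <- ncol(Z)
  if (rank < 1 || rank > min(f, tt))
    stop("rank must be in [1, min(dim(Z))]")
  eps <- 1e-12
  set.seed(seed)
  D <- if (is.null(dictionary)) {
    matrix(runif(f * rank, 0.1, 1), f, rank)
  } else {
    stopifnot(nrow(dictionary) == f, ncol(dictionary) == rank,
              all(dictionary >= 0))
    as.matrix(dictionary)
  }
  A <- matrix(runif(rank * tt, 0.1, 1), rank, tt)
  objective <- function() {
    Y <- D %*% A
    if (loss == "frobenius") sqrt(sum((Z - Y)^2))
    else sum(Z * log((Z + eps) / (Y + eps)) - Z + Y)
  }
  trace <- numeric(n_iter + 1)
  trace[1] <- objective()
  used <- 0
  for (it in seq_len(n_iter)) {
    if (loss == "frobenius") {
      A <- A * (crossprod(D, Z)) / (crossprod(D, D) %*% A + eps)
      if (update_dictionary)
        D <- D * (Z %*% t(A)) / (D %*% tcrossprod(A, A) + eps)
    } else {
      Y <- D %*% A + eps
      A <- A * (crossprod(D, Z / Y)) / (colSums(D) + eps)
      if (update_dictionary) {
        Y <- D %*% A + eps
        D <- D * ((Z / Y) %*% t(A)) / matrix(rowSums(A) + eps, f, rank,
                                             byrow = TRUE)
      }
    }
    used <- it
    trace[it + 1] <- objective()
    if (trace[it] - trace[it + 1] < tol * max(trace[1], eps)) break
  }
  structure(list(dictionary = D, activations = A, rank = rank, loss = loss,
                 objective_trace = trace[seq_len(used + 1)]),
            class = "nmf_model")
}

#' Idealized harmonic spectral templates for a pitch range
#'
#' One template per MIDI pitch: Gaussian bumps at the first few harmonics of
#' the pitch's fundamental, with geometric amplitude decay. Supplying these as
#' a fixed dictionary makes the template-to-pitch mapping of the transcription
#' well-defined.
#'
#' @param pitches integer MIDI note numbers.
#' @param n_fft FFT length used for the spectrogram.
#' @param fs audio sampling rate in Hz.
#' @param n_harmonics number of harmonics per template.
#' @param decay per-harmonic amplitude decay factor.
#' @param width bump width in bins.
#' @return nonnegative matrix \code{(n_fft/2 + 1) x length(pitches)} with unit
#'   column norms, plus attribute \code{pitches}.
#' @export
harmonic_dictionary <- function(pitches, n_fft, fs, n_harmonics = 8,
                                decay = 0.7, width = 1) {
  bins <- n_fft / 2 + 1
  D <- matrix(0, bins, length(pitches))
  bin_freq <- (seq_len(bins) - 1) * fs / n_fft
  for (j in seq_along(pitches)) {
    f0 <- 440 * 2^((pitches[j] - 69) / 12)
    for (h in seq_len(n_harmonics)) {
      fh <- h * f0
      if (fh > fs / 2) break
      D[, j] <- D[, j] + decay^(h - 1) *
        exp(-((bin_freq - fh) / (width * fs / n_fft))^2 / 2)
    }
    nrm <- sqrt(sum(D[, j]^2))
    if (nrm > 0) D[, j] <- D[, j] / nrm
  }
  attr(D, "pitches") <- as.integer(pitches)
  D
}

#' Threshold NMF activations into a binary piano-roll
#'
#' A cell is active iff its template's activation reaches \code{threshold}
#' times that template's maximum activation (rows whose activation is
#' identically zero stay silent). Templates mapping to the same pitch are
#' combined by union.
#'
#' @param model an \code{\link{nmf_factorize}} result.
#' @param pitch_map integer MIDI pitch per template (length = rank); defaults
#'   to the dictionary's \code{pitches} attribute when present.
#' @param threshold fraction of the per-template maximum in \code{(0, 1]}.
#' @param fs_roll frame rate of the resulting roll.
#' @return a \code{\link{piano_roll}} spanning
#'   \code{min(pitch_map)..max(pitch_map)}.
#' @export
activations_to_roll <- function(model, pitch_map = NULL, threshold = 0.5,
                                fs_roll = 16) {
  stopifnot(inherits(model, "nmf_model"))
  pitch_map <- pitch_map %||% attr(model$dictionary, "pitches")
  if (is.null(pitch_map) || length(pitch_map) != model$rank ||
      any(is.na(pitch_map)))
    stop("pitch_map must supply one MIDI pitch per template")
  stopifnot(threshold > 0, threshold <= 1)
  lo <- min(pitch_map); hi <- max(pitch_map)
  mask <- matrix(0L, hi - lo + 1, ncol(model$activations))
  for (j in seq_len(model$rank)) {
    act <- model$activations[j, ]
    mx <- max(act)
    if (mx > 0) {
      row <- pitch_map[j] - lo + 1
      mask[row, ] <- pmax(mask[row, ], as.integer(act >= threshold * mx))
    }
  }
  piano_roll(mask, fs_roll = fs_roll, pitch_offset = lo)
}

#' Transcribe mono audio to a piano-roll via supervised NMF
#'
#' Convenience composition: magnitude spectrogram, NMF against a fixed
#' harmonic dictionary (one template per pitch in the window), and activation
#' thresholding. The roll frame rate is \code{fs / hop}.
#'
#' @param audio mono waveform.
#' @param fs audio sampling rate in Hz.
#' @param pitch_lo,pitch_hi MIDI pitch window.
#' @param n_fft,hop spectrogram parameters.
#' @param threshold activation threshold (fraction of per-template maximum).
#' @param n_iter NMF iterations.
#' @return a \code{\link{piano_roll}}.
#' @export
transcribe_audio <- function(audio, fs, pitch_lo = 36, pitch_hi = 83,
                             n_fft = 2048, hop = 512, threshold = 0.3,
                             n_iter = 100) {
  spec <- stft_magnitude(audio, n_fft = n_fft, hop = hop, fs = fs)
  pitches <- pitch_lo:pitch_hi
  D <- harmonic_dictionary(pitches, n_fft = n_fft, fs = fs)
  model <- nmf_factorize(spec, rank = length(pitches), n_iter = n_iter,
                         dictionary = D, update_dictionary = FALSE)
  activations_to_roll(model, pitches, threshold = threshold,
                      fs_roll = fs / hop)
}

#' Convert a note sequence to a binary piano-roll
#'
#' A note occupies frames \code{floor(onset * fs_roll) <= t <
#' ceil(offset * fs_roll)} (zero-based); velocity is discarded.
#'
#' @param notes a \code{\link{note_sequence}}.
#' @param fs_roll frame rate in frames/s.
#' @param pitch_lo,pitch_hi pitch window (rows of the roll).
#' @param duration roll duration in seconds; defaults to the last offset.
#' @param out_of_range \code{"error"} (default) or \code{"clip"} (clamp
#'   pitches into the window).
#' @return a \code{\link{piano_roll}}.
#' @export
midi_to_roll <- function(notes, fs_roll = 16, pitch_lo = 36, pitch_hi = 83,
                         duration = NULL,
                         out_of_range = c("error", "clip")) {
  stopifnot(inherits(notes, "note_sequence"))
  out_of_range <- match.arg(out_of_range)
  duration <- duration %||% if (nrow(notes)) max(notes$offset) else 1 / fs_roll
  n_frames <- max(1L, as.integer(ceiling(duration * fs_roll - 1e-9)))
  mask <- matrix(0L, pitch_hi - pitch_lo + 1, n_frames)
  for (i in seq_len(nrow(notes))) {
    p <- notes$pitch[i]
    if (p < pitch_lo || p > pitch_hi) {
      if (out_of_range == "error")
        stop("pitch ", p, " outside [", pitch_lo, ", ", pitch_hi, "]")
      p <- clamp(p, pitch_lo, pitch_hi)
    }
    t0 <- floor(notes$onset[i] * fs_roll) + 1
    t1 <- ceiling(notes$offset[i] * fs_roll - 1e-9)
    t1 <- min(t1, n_frames)
    if (t0 <= t1) mask[p - pitch_lo + 1, t0:t1] <- 1L
  }
  piano_roll(mask, fs_roll = fs_roll, pitch_offset = pitch_lo)
}

#' Convert a binary piano-roll back to a note sequence
#'
#' Maximal horizontal runs of ones per pitch row become notes; runs shorter
#' than \code{min_frames} are dropped. Defaults follow the transcription
#' convention of a 120 BPM tempo and an 11-frame minimum note length.
#'
#' @param roll a \code{\link{piano_roll}}.
#' @param tempo tempo in BPM attached to the output.
#' @param min_frames minimum run length kept, in frames.
#' @param velocity constant velocity assigned to every note.
#' @return a \code{\link{note_sequence}}.
#' @export
roll_to_midi <- function(roll, tempo = 120, min_frames = 11, velocity = 80L) {
  stopifnot(inherits(roll, "piano_roll"), min_frames >= 1)
  fs <- roll$fs_roll
  pitches <- integer(); onsets <- numeric(); offsets <- numeric()
  for (r in seq_len(nrow(roll$mask))) {
    rl <- rle(roll$mask[r, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    keep <- rl$values == 1L & rl$lengths >= min_frames
    if (any(keep)) {
      pitches <- c(pitches, rep(roll$pitch_offset + r - 1L, sum(keep)))
      onsets <- c(onsets, (starts[keep] - 1) / fs)
      offsets <- c(offsets, ends[keep] / fs)
    }
  }
  note_sequence(pitch = pitches, onset = onsets, offset = offsets,
                velocity = velocity, tempo = tempo)
}

#' Split a piano-roll into non-overlapping windows
#'
#' Frame-domain analogue of \code{\link{window_segments}}:
#' \code{floor(frames / (window_s * fs_roll))} windows starting at frame 1.
#'
#' @param roll a \code{\link{piano_roll}}.
#' @param window_s window length in seconds.
#' @return list of \code{\link{piano_roll}} windows.
#' @export
segment_roll <- function(roll, window_s = 6) {
  stopifnot(inherits(roll, "piano_roll"))
  if (window_s <= 0) stop("window_s must be positive")
  fpw <- round(window_s * roll$fs_roll)
  n_win <- floor(ncol(roll$mask) / fpw)
  lapply(seq_len(n_win), function(w)
    piano_roll(roll$mask[, ((w - 1) * fpw + 1):(w * fpw), drop = FALSE],
               roll$fs_roll, roll$pitch_offset))
}
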
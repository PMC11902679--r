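#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Band power of a single-channel signal
#'
#' Integrates the periodogram over a frequency band. Used by the synthetic-data
#' diagnostics and tests to verify that simulated oscillatory couplings are
#' present at the intended frequencies.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @return scalar power (signal-units squared).
#' @export
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  stopifnot(n > 1, fs > 0, lo < hi)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  sum(sp[keep]) / n
}

#' Dominant frequency of a signal via FFT peak
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return frequency (Hz) of the largest spectral magnitude below Nyquist.
#' @export
dominant_frequency <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))
  half <- seq_len(floor(n / 2))
  freqs <- (half - 1) * fs / n
  freqs[which.max(sp[half])]
}

#' Mean silhouette width for grouped feature vectors
#'
#' Plain Euclidean silhouette score, used to quantify how well latent codes
#' separate by emotion quadrant.
#'
#' @param x numeric matrix, rows = samples.
#' @param groups group membership vector (length \code{nrow(x)}), at least two
#'   distinct groups each with at least one member.
#' @return mean silhouette width in \code{[-1, 1]}.
#' @export
silhouette_score <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  stopifnot(nrow(x) == length(groups), length(unique(groups)) >= 2)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# polynomial rolling hash over a raw vector; used for manifest fingerprints
fnv1a <- function(raw) {
  h <- 17
  for (byte in as.integer(raw)) h <- (h * 131 + byte) %% 2147483647
  sprintf("%08x", h)
}
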
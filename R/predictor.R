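#' Euclidean distances between predicted and training emotion coordinates
#'
#' @param pred n_query x 2 matrix of predicted (arousal01, valence01) pairs in
#'   \code{[0, 1]}.
#' @param train n_train x 2 matrix of training-pool label pairs in
#'   \code{[0, 1]}.
#' @return n_query x n_train matrix of Euclidean distances.
#' @export
label_distances <- function(pred, train) {
  pred <- as.matrix(pred); train <- as.matrix(train)
  if (ncol(pred) != ncol(train)) stop("label dimension mismatch")
  stopifnot(all(pred >= 0 & pred <= 1), all(train >= 0 & train <= 1))
  pq <- rowSums(pred^2)
  tq <- rowSums(train^2)
  d2 <- outer(pq, tq, "+") - 2 * tcrossprod(pred, train)
  sqrt(pmax(d2, 0))
}

#' Softmax-weighted top-k neighbour weights
#'
#' Per query, weights proportional to \code{exp(-distance)} (so near
#' neighbours dominate), truncated to the k largest, then renormalized to sum
#' to one. Rows therefore live on the k-sparse probability simplex.
#'
#' @param distances n_query x n_train distance matrix.
#' @param k neighbours kept per query (default 5).
#' @return object of class \code{neighbor_weights}: list with \code{matrix}
#'   (row-stochastic, at most k nonzeros per row), \code{k}, \code{support}
#'   (per-row indices of the kept neighbours).
#' @export
neighbor_weights <- function(distances, k = 5) {
  D <- as.matrix(distances)
  if (k <= 0) stop("k must be positive")
  if (k > ncol(D)) stop("k exceeds the training-pool size")
  W <- matrix(0, nrow(D), ncol(D))
  support <- vector("list", nrow(D))
  for (i in seq_len(nrow(D))) {
    w <- exp(-(D[i, ] - min(D[i, ])))   # shift for numerical stability
    keep <- order(w, decreasing = TRUE)[seq_len(k)]
    W[i, keep] <- w[keep] / sum(w[keep])
    support[[i]] <- sort(keep)
  }
  structure(list(matrix = W, k = as.integer(k), support = support),
            class = "neighbor_weights")
}

#' Predict latent codes as convex combinations of training codes
#'
#' @param weights a \code{\link{neighbor_weights}} object (or a plain
#'   row-stochastic matrix).
#' @param train_codes n_train x code_dim matrix of encoder outputs for the
#'   training pool.
#' @return n_query x code_dim matrix; each row lies coordinate-wise within
#'   the range of its selected neighbours' codes.
#' @export
predict_codes <- function(weights, train_codes) {
  W <- if (inherits(weights, "neighbor_weights")) weights$matrix
       else as.matrix(weights)
  train_codes <- as.matrix(train_codes)
  if (ncol(W) != nrow(train_codes))
    stop("weight/code dimension mismatch")
  W %*% train_codes
}

#' Affect-driven piano-roll prediction
#'
#' The full retrieval chain: Euclidean distances from EEG-predicted emotion
#' coordinates to the training-pool labels, softmax top-k weighting, convex
#' combination of the pool's latent codes, decoding and binarization.
#'
#' @param pred_labels n_query x 2 matrix of predicted (arousal01, valence01).
#' @param train_labels n_train x 2 matrix of pool labels.
#' @param train_codes n_train x code_dim matrix of pool codes (encoder
#'   outputs).
#' @param model trained autoencoder (\code{\link{train_autoencoder}}).
#' @param k neighbours kept (default 5).
#' @param threshold binarization threshold on the decoded probabilities.
#' @return list of \code{\link{piano_roll}} predictions, with attribute
#'   \code{trace} (list with \code{distances}, \code{weights}).
#' @export
predict_pianorolls <- function(pred_labels, train_labels, train_codes, model,
                               k = 5, threshold = 0.5) {
  d <- label_distances(pred_labels, train_labels)
  w <- neighbor_weights(d, k = k)
  codes <- predict_codes(w, train_codes)
  probs <- decode_rolls(model, codes)
  rolls <- lapply(probs, binarize_roll, threshold = threshold,
                  fs_roll = model$fs_roll, pitch_offset = model$pitch_offset)
  attr(rolls, "trace") <- list(distances = d, weights = w)
  rolls
}
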
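#' EEGNet architecture specification
#'
#' The compact convolutional EEG decoder: a temporal convolution learns
#' frequency filters, a depthwise spatial convolution over the full montage
#' learns per-filter spatial patterns, and a separable convolution summarizes
#' them over time, with average pooling and dropout between stages. The dense
#' head is either a softmax over K classes or two sigmoid units regressing
#' arousal and valence on \code{[0, 1]}.
#'
#' @param n_channels montage size Nc.
#' @param n_samples window length Nt in samples; at least 32 so both pooling
#'   stages are valid.
#' @param f1 temporal filters (default 4), \code{kernel_t} their length
#'   (default 4).
#' @param depth_mult depth multiplier of the spatial convolution (default 2).
#' @param f2 separable filters (default 32), \code{kernel_sep} their length
#'   (default 16).
#' @param pool1,pool2 average-pooling widths (defaults 4 and 8).
#' @param dropout dropout rate (default 0.6).
#' @param head \code{"regression"} (two sigmoid units) or
#'   \code{"classification"} (softmax over \code{n_classes}).
#' @param n_classes classes for the classification head (default 4, the
#'   arousal x valence quadrants).
#' @return object of class \code{eegnet_spec}. The flattened feature length
#'   is \code{f2 * floor(floor(n_samples / pool1) / pool2)}.
#' @export
eegnet_spec <- function(n_channels, n_samples, f1 = 4, kernel_t = 4,
                        depth_mult = 2, f2 = 32, kernel_sep = 16,
                        pool1 = 4, pool2 = 8, dropout = 0.6,
                        head = c("regression", "classification"),
                        n_classes = 4) {
  head <- match.arg(head)
  if (n_samples < 32) stop("n_samples must be at least 32 (pooling stages)")
  spec <- list(n_channels = as.integer(n_channels),
               n_samples = as.integer(n_samples), f1 = f1,
               kernel_t = kernel_t, depth_mult = depth_mult, f2 = f2,
               kernel_sep = kernel_sep, pool1 = pool1, pool2 = pool2,
               dropout = dropout, head = head,
               n_classes = as.integer(n_classes))
  spec$flat_len <- f2 * ((n_samples %/% pool1) %/% pool2)
  class(spec) <- "eegnet_spec"
  spec
}

#' Build an EEGNet model
#'
#' Layer stack: temporal convolution (1 x kernel_t, F1 filters, no bias),
#' batch norm, depthwise spatial convolution (Nc x 1, depth multiplier D, no
#' bias), batch norm, ELU, average pool (1 x 4), dropout, separable
#' convolution (1 x 16, F2 filters), batch norm, ELU, average pool (1 x 8),
#' dropout, flatten, dense head.
#'
#' @param spec an \code{\link{eegnet_spec}}.
#' @param seed weight-initialization seed.
#' @return object of class \code{eegnet_model} (untrained).
#' @export
build_eegnet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "eegnet_spec"))
  set.seed(seed)
  n_out <- if (spec$head == "regression") 2L else spec$n_classes
  cd <- spec$f1 * spec$depth_mult
  layers <- list(
    layer_conv(1, spec$kernel_t, 1, spec$f1, stride = c(1, 1),
               padding = "same", bias = FALSE),
    layer_batchnorm(spec$f1),
    layer_depthwise(spec$n_channels, 1, spec$f1, spec$depth_mult,
                    stride = c(1, 1), padding = "valid"),
    layer_batchnorm(cd),
    layer_act("elu"),
    layer_avgpool(1, spec$pool1),
    layer_dropout(spec$dropout),
    layer_separable(1, spec$kernel_sep, cd, spec$f2),
    layer_batchnorm(spec$f2),
    layer_act("elu"),
    layer_avgpool(1, spec$pool2),
    layer_dropout(spec$dropout),
    layer_flatten(),
    layer_dense(spec$flat_len, n_out))
  if (spec$head == "regression")
    layers <- c(layers, list(layer_act("sigmoid")))
  structure(list(layers = layers, spec = spec, trained = FALSE,
                 classes = NULL, history = NULL),
            class = "eegnet_model")
}

#' Number of learnable parameters of a model
#' @param model an \code{eegnet_model} or \code{pianoroll_ae}.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "eegnet_model")) .count_params(model$layers)
  else if (inherits(model, "pianoroll_ae"))
    .count_params(model$encoder) + .count_params(model$decoder)
  else stop("unsupported model")
}

.stack_segments <- function(segments) {
  nc <- nrow(segments[[1]]$data); nt <- ncol(segments[[1]]$data)
  ok <- vapply(segments, function(s) all(dim(s$data) == c(nc, nt)),
               logical(1))
  if (!all(ok)) stop("all segments must share one shape")
  x <- array(0, c(nc, nt, 1, length(segments)))
  for (s in seq_along(segments)) x[, , 1, s] <- segments[[s]]$data
  x
}

#' Train EEGNet on labelled EEG windows
#'
#' Regression mode minimizes the summed mean-squared error of the two sigmoid
#' heads against the normalized (arousal01, valence01) targets; classification
#' mode minimizes categorical cross-entropy against one-hot classes. Both use
#' Adam with optional L2 weight decay.
#'
#' @param segments list of equally-shaped \code{\link{eeg_segment}}s.
#' @param labels aligned data frame: columns \code{arousal01, valence01}
#'   (regression) or \code{class} (factor/integer; classification).
#' @param mode \code{"regression"} or \code{"classification"}.
#' @param epochs,batch,lr training schedule.
#' @param seed seed fixing initialization, shuffling and dropout.
#' @param l2 L2 regularization weight on convolution/dense weights.
#' @param spec optional \code{\link{eegnet_spec}} override; by default built
#'   from the segment shape.
#' @return trained \code{eegnet_model} with \code{$history} (per-epoch loss).
#' @export
train_eegnet <- function(segments, labels, mode = c("regression",
                                                    "classification"),
                         epochs = 30, batch = 8, lr = 1e-3, seed = 1L,
                         l2 = 0, spec = NULL) {
  mode <- match.arg(mode)
  x_all <- .stack_segments(segments)
  n <- dim(x_all)[4]
  stopifnot(nrow(labels) == n)
  classes <- NULL
  if (mode == "regression") {
    y <- as.matrix(labels[, c("arousal01", "valence01")])
    stopifnot(all(y >= 0 & y <= 1))
  } else {
    cl <- factor(labels$class)
    classes <- levels(cl)
    y <- diag(length(classes))[as.integer(cl), , drop = FALSE]
  }
  spec <- spec %||% eegnet_spec(dim(x_all)[1], dim(x_all)[2],
                                head = mode,
                                n_classes = if (is.null(classes)) 4L
                                            else length(classes))
  model <- build_eegnet(spec, seed = seed)
  st <- .adam_init(model$layers)
  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    loss_sum <- 0
    for (idx in .stack_batches(n, batch)) {
      ids <- ord[idx]
      xb <- x_all[, , , ids, drop = FALSE]
      fw <- .forward_layers(model$layers, xb, train = TRUE)
      lo <- if (mode == "regression") .loss_mse(fw$out, y[ids, , drop = FALSE])
            else .loss_softmax_xent(fw$out, y[ids, , drop = FALSE])
      loss_sum <- loss_sum + lo$loss * length(ids)
      bw <- .backward_layers(model$layers, fw$caches, lo$grad)
      step <- step + 1
      up <- .adam_step(model$layers, bw$grads, st, lr, step, l2 = l2)
      model$layers <- up$layers; st <- up$state
    }
    hist$loss[ep] <- loss_sum / n
  }
  model$history <- hist
  model$trained <- TRUE
  model$mode <- mode
  model$classes <- classes
  model
}

#' Predict emotion coordinates (or class posteriors) from EEG windows
#'
#' @param model a trained \code{eegnet_model}.
#' @param segments list of \code{\link{eeg_segment}}s.
#' @return regression mode: data frame with \code{arousal01, valence01} in
#'   \code{[0, 1]}; classification mode: matrix of class posteriors (rows sum
#'   to 1). Deterministic at inference.
#' @export
predict_emotion <- function(model, segments) {
  stopifnot(inherits(model, "eegnet_model"))
  if (!model$trained) stop("model is untrained")
  x <- .stack_segments(segments)
  fw <- .forward_layers(model$layers, x, train = FALSE)
  if (model$mode == "regression") {
    out <- as.data.frame(fw$out)
    names(out) <- c("arousal01", "valence01")
    out
  } else {
    z <- fw$out - apply(fw$out, 1, max)
    p <- exp(z) / rowSums(exp(z))
    colnames(p) <- model$classes
    p
  }
}

#' Classification performance: accuracy, Cohen's kappa, AUC
#'
#' Accuracy is the fraction correct; kappa is
#' \code{(p_o - p_e) / (1 - p_e)} with the chance agreement \code{p_e}
#' computed from the confusion-matrix marginals; AUC is the Mann--Whitney
#' rank statistic (macro-averaged one-vs-rest for more than two classes).
#'
#' @param y_true true labels (factor or vector).
#' @param y_pred predicted labels, same length.
#' @param scores optional scores for AUC: a vector of positive-class scores
#'   (binary; the positive class is the last factor level) or an n x K matrix
#'   of per-class scores.
#' @return list with \code{accuracy}, \code{kappa}, \code{auc} (NA when no
#'   scores are supplied).
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  stopifnot(length(y_true) == length(y_pred))
  n <- length(y_true)
  acc <- mean(y_true == y_pred, na.rm = FALSE)
  cm <- table(y_true, y_pred)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kap <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  auc <- NA_real_
  if (!is.null(scores)) {
    if (nlevels(y_true) < 2)
      stop("AUC undefined: y_true contains a single class")
    auc <- if (is.matrix(scores)) {
      mean(vapply(seq_len(nlevels(y_true)), function(k)
        .auc_rank(y_true == levels(y_true)[k], scores[, k]), numeric(1)))
    } else {
      .auc_rank(y_true == levels(y_true)[nlevels(y_true)], scores)
    }
  }
  list(accuracy = acc, kappa = kap, auc = auc)
}

.auc_rank <- function(positive, scores) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
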
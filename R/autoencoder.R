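#' Build the residual convolutional piano-roll autoencoder
#'
#' The encoder compresses an \code{Np x Nt x 1} binary piano-roll through a
#' strided 1x1 convolution followed by two residual blocks, each pairing a
#' main path (two separable 3x3 convolutions with batch normalization and a
#' 3x3/stride-2 max-pool) with a projection shortcut (3x3 convolution,
#' stride 2, dropout, ReLU) joined by addition. Three stride-2 stages take
#' \code{Np x Nt x 1} to \code{(Np/8) x (Nt/8) x F3}; the flattened bottleneck
#' is the segment's latent code. The decoder mirrors the encoder with
#' nearest-neighbour upsampling and separable convolutions, ending in a
#' sigmoid per pixel, and is deliberately free of encoder skip connections so
#' that codes decode standalone.
#'
#' @param np,nt input pitch-bin and frame counts; both divisible by 8.
#' @param filters filter counts \code{c(F1, F2, F3)} of the three stages.
#' @param dropout dropout rate of the residual shortcuts.
#' @param seed seed for weight initialization.
#' @return object of class \code{pianoroll_ae} (untrained): encoder/decoder
#'   layer stacks plus shape metadata (\code{code_dim = (np/8)(nt/8) F3}).
#' @export
build_autoencoder <- function(np, nt, filters = c(32, 64, 128),
                              dropout = 0.5, seed = 1L) {
  if (np %% 8 != 0 || nt %% 8 != 0)
    stop("np and nt must be divisible by 8 (three stride-2 stages)")
  stopifnot(length(filters) == 3)
  f1 <- filters[1]; f2 <- filters[2]; f3 <- filters[3]
  set.seed(seed)
  res_block <- function(cin, cout) {
    layer_residual(
      main = list(layer_separable(3, 3, cin, cout),
                  layer_batchnorm(cout),
                  layer_act("relu"),
                  layer_separable(3, 3, cout, cout),
                  layer_batchnorm(cout),
                  layer_maxpool(3, 3, stride = c(2, 2), padding = "same")),
      shortcut = list(layer_conv(3, 3, cin, cout, stride = c(2, 2),
                                 padding = "same"),
                      layer_dropout(dropout),
                      layer_act("relu")))
  }
  encoder <- list(
    layer_conv(1, 1, 1, f1, stride = c(2, 2), padding = "same"),
    layer_batchnorm(f1),
    layer_act("relu"),
    res_block(f1, f2),
    res_block(f2, f3))
  decoder <- list(
    layer_upsample(2),
    layer_separable(3, 3, f3, f2),
    layer_batchnorm(f2),
    layer_act("relu"),
    layer_upsample(2),
    layer_separable(3, 3, f2, f1),
    layer_batchnorm(f1),
    layer_act("relu"),
    layer_upsample(2),
    layer_separable(3, 3, f1, f1),
    layer_batchnorm(f1),
    layer_act("relu"),
    layer_conv(1, 1, f1, 1, stride = c(1, 1), padding = "valid"),
    layer_act("sigmoid"))
  structure(list(encoder = encoder, decoder = decoder,
                 np = np, nt = nt, filters = filters,
                 code_shape = c(np / 8, nt / 8, f3),
                 code_dim = (np / 8) * (nt / 8) * f3,
                 dropout = dropout, trained = FALSE,
                 fs_roll = NA_real_, pitch_offset = NA_integer_,
                 history = NULL),
            class = "pianoroll_ae")
}

#' @export
print.pianoroll_ae <- function(x, ...) {
  cat(sprintf(
    "<pianoroll_ae> %dx%d input, filters (%s), code_dim %d, %s\n",
    x$np, x$nt, paste(x$filters, collapse = ", "), x$code_dim,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.stack_rolls <- function(rolls) {
  np <- nrow(rolls[[1]]$mask); nt <- ncol(rolls[[1]]$mask)
  ok <- vapply(rolls, function(r)
    all(dim(r$mask) == c(np, nt)), logical(1))
  if (!all(ok)) stop("all rolls must share one shape")
  x <- array(0, c(np, nt, 1, length(rolls)))
  for (s in seq_along(rolls)) x[, , 1, s] <- rolls[[s]]$mask
  x
}

#' Train the piano-roll autoencoder
#'
#' Minimizes per-pixel binary cross-entropy between the input mask and the
#' reconstruction, plus (optionally) a Centered Kernel Alignment term
#' \code{cka_weight * (1 - rho(K_code, K_target))} computed per mini-batch on
#' the flattened bottleneck codes, which pulls the latent geometry toward the
#' affective-label (or supplied feature) geometry. Optimized with Adam.
#'
#' @param rolls list of equally-shaped \code{\link{piano_roll}}s.
#' @param labels data frame aligned with \code{rolls} carrying
#'   \code{arousal01}, \code{valence01} (required when
#'   \code{cka_weight > 0} with the \code{"labels"} target).
#' @param epochs,batch,lr training schedule (Adam). \code{batch >= 8} is
#'   enforced when the alignment term is active, since CKA is estimated per
#'   batch.
#' @param seed seed fixing initialization, shuffling and dropout.
#' @param cka_weight nonnegative weight of the alignment term; 0 recovers
#'   plain reconstruction training.
#' @param cka_target \code{"labels"} (linear kernel on the
#'   (arousal01, valence01) pairs) or \code{"features"} (linear kernel on
#'   \code{target_features}, e.g. EEGNet penultimate features).
#' @param target_features optional n x d matrix for the \code{"features"}
#'   target.
#' @param filters,dropout architecture parameters, see
#'   \code{\link{build_autoencoder}}.
#' @return a trained \code{pianoroll_ae}; \code{$history} is a data frame
#'   with per-epoch \code{rec_loss} and (when active) \code{cka}.
#' @export
train_autoencoder <- function(rolls, labels = NULL, epochs = 30, batch = 8,
                              lr = 1e-3, seed = 1L, cka_weight = 0,
                              cka_target = c("labels", "features"),
                              target_features = NULL,
                              filters = c(32, 64, 128), dropout = 0.5) {
  cka_target <- match.arg(cka_target)
  stopifnot(length(rolls) >= 1, cka_weight >= 0)
  x_all <- .stack_rolls(rolls)
  n <- dim(x_all)[4]
  target <- NULL
  if (cka_weight > 0) {
    if (batch < 8) stop("batch >= 8 required when cka_weight > 0")
    target <- switch(cka_target,
      labels = {
        if (is.null(labels)) stop("cka_weight > 0 needs labels")
        as.matrix(labels[, c("arousal01", "valence01")])
      },
      features = {
        if (is.null(target_features))
          stop("cka_weight > 0 with feature target needs target_features")
        as.matrix(target_features)
      })
    stopifnot(nrow(target) == n)
  }
  model <- build_autoencoder(dim(x_all)[1], dim(x_all)[2], filters, dropout,
                             seed = seed)
  st_enc <- .adam_init(model$encoder)
  st_dec <- .adam_init(model$decoder)
  hist <- data.frame(epoch = seq_len(epochs), rec_loss = NA_real_,
                     cka = NA_real_)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    rec_sum <- 0; cka_sum <- 0; cka_n <- 0
    for (idx in .stack_batches(n, batch)) {
      ids <- ord[idx]
      xb <- x_all[, , , ids, drop = FALSE]
      fe <- .forward_layers(model$encoder, xb, train = TRUE)
      fd <- .forward_layers(model$decoder, fe$out, train = TRUE)
      lb <- .loss_bce(fd$out, xb)
      rec_sum <- rec_sum + lb$loss * length(ids)
      bd <- .backward_layers(model$decoder, fd$caches, lb$grad)
      dcode <- bd$dx
      if (cka_weight > 0 && length(ids) >= 4) {
        codes <- t(matrix(fe$out, prod(model$code_shape), length(ids)))
        ky <- tcrossprod(target[ids, , drop = FALSE])
        cl <- tryCatch(cka_loss_grad(codes, ky), error = function(e) NULL)
        if (!is.null(cl)) {
          dcode <- dcode + cka_weight * array(t(cl$grad), dim(fe$out))
          cka_sum <- cka_sum + cl$cka; cka_n <- cka_n + 1
        }
      }
      be <- .backward_layers(model$encoder, fe$caches, dcode)
      step <- step + 1
      up_d <- .adam_step(model$decoder, bd$grads, st_dec, lr, step)
      model$decoder <- up_d$layers; st_dec <- up_d$state
      up_e <- .adam_step(model$encoder, be$grads, st_enc, lr, step)
      model$encoder <- up_e$layers; st_enc <- up_e$state
    }
    hist$rec_loss[ep] <- rec_sum / n
    if (cka_n > 0) hist$cka[ep] <- cka_sum / cka_n
  }
  if (cka_weight == 0) hist$cka <- NULL
  model$history <- hist
  model$trained <- TRUE
  model$cka_weight <- cka_weight
  model$fs_roll <- rolls[[1]]$fs_roll
  model$pitch_offset <- rolls[[1]]$pitch_offset
  model
}

#' Encode piano-rolls into latent codes
#'
#' @param model a trained \code{pianoroll_ae}.
#' @param rolls list of \code{\link{piano_roll}}s matching the training
#'   shape.
#' @return numeric matrix, one row per roll, \code{code_dim} columns (the
#'   flattened bottleneck feature map). Deterministic: dropout is inactive at
#'   inference.
#' @export
encode_rolls <- function(model, rolls) {
  stopifnot(inherits(model, "pianoroll_ae"))
  if (!model$trained) stop("model is untrained")
  x <- .stack_rolls(rolls)
  fe <- .forward_layers(model$encoder, x, train = FALSE)
  t(matrix(fe$out, model$code_dim, dim(x)[4]))
}

#' Decode latent codes into probability piano-rolls
#'
#' @param model a trained \code{pianoroll_ae}.
#' @param codes matrix of codes (rows = segments), e.g. from
#'   \code{\link{encode_rolls}} or \code{\link{predict_codes}}.
#' @return list of \code{np x nt} matrices with entries in \code{[0, 1]}.
#' @export
decode_rolls <- function(model, codes) {
  stopifnot(inherits(model, "pianoroll_ae"))
  if (!model$trained) stop("model is untrained")
  codes <- as.matrix(codes)
  stopifnot(ncol(codes) == model$code_dim)
  n <- nrow(codes)
  fm <- array(t(codes), c(model$code_shape, n))
  fd <- .forward_layers(model$decoder, fm, train = FALSE)
  lapply(seq_len(n), function(s) fd$out[, , 1, s])
}

#' Binarize a probability roll
#'
#' @param prob matrix with entries in \code{[0, 1]}.
#' @param threshold cells at or above this become 1.
#' @param fs_roll,pitch_offset metadata of the resulting roll.
#' @return a \code{\link{piano_roll}}.
#' @export
binarize_roll <- function(prob, threshold = 0.5, fs_roll = 16,
                          pitch_offset = 36L) {
  prob <- as.matrix(prob)
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  piano_roll((prob >= threshold) * 1L, fs_roll, pitch_offset)
}
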
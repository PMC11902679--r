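# Minimal convolutional neural-network engine.
#
# Tensors are 4-d arrays indexed (height, width, channel, sample). Layers are
# plain lists carrying their parameters; composites ("seq", "residual") nest
# sublayers, which gives the residual wiring of the piano-roll encoder.
# Backward passes are hand-derived and verified by finite differences in the
# test suite. Batch-norm running statistics live in a per-layer environment
# so inference after training is deterministic.

# ---- padding / im2col ------------------------------------------------------

.pad_amounts <- function(h, w, kh, kw, sh, sw, padding) {
  if (padding == "same") {
    oh <- ceiling(h / sh); ow <- ceiling(w / sw)
    ph <- max((oh - 1) * sh + kh - h, 0)
    pw <- max((ow - 1) * sw + kw - w, 0)
    c(ph %/% 2, ph - ph %/% 2, pw %/% 2, pw - pw %/% 2)
  } else c(0L, 0L, 0L, 0L)
}

.out_hw <- function(h, w, kh, kw, sh, sw, pad) {
  c((h + pad[1] + pad[2] - kh) %/% sh + 1,
    (w + pad[3] + pad[4] - kw) %/% sw + 1)
}

# batched im2col: x is (h, w, ch, n); columns ordered (oh, ow, n)
.im2col <- function(x, kh, kw, sh, sw, pad) {
  d <- dim(x)
  hp <- d[1] + pad[1] + pad[2]; wp <- d[2] + pad[3] + pad[4]
  xp <- array(0, c(hp, wp, d[3], d[4]))
  xp[(pad[1] + 1):(pad[1] + d[1]), (pad[3] + 1):(pad[3] + d[2]), , ] <- x
  oh <- (hp - kh) %/% sh + 1; ow <- (wp - kw) %/% sw + 1
  cols <- array(0, c(kh, kw, d[3], oh, ow, d[4]))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    rows <- seq(i, by = sh, length.out = oh)
    cc <- seq(j, by = sw, length.out = ow)
    blk <- xp[rows, cc, , , drop = FALSE]        # oh x ow x ch x n
    cols[i, j, , , , ] <- aperm(blk, c(3, 1, 2, 4))
  }
  dim(cols) <- c(kh * kw * d[3], oh * ow * d[4])
  cols
}

.col2im <- function(cols, d, kh, kw, sh, sw, pad) {
  hp <- d[1] + pad[1] + pad[2]; wp <- d[2] + pad[3] + pad[4]
  oh <- (hp - kh) %/% sh + 1; ow <- (wp - kw) %/% sw + 1
  dim(cols) <- c(kh, kw, d[3], oh, ow, d[4])
  xp <- array(0, c(hp, wp, d[3], d[4]))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    rows <- seq(i, by = sh, length.out = oh)
    cc <- seq(j, by = sw, length.out = ow)
    blk <- cols[i, j, , , , , drop = FALSE]
    dim(blk) <- c(d[3], oh, ow, d[4])
    cur <- xp[rows, cc, , , drop = FALSE]
    xp[rows, cc, , ] <- cur + aperm(blk, c(2, 3, 1, 4))
  }
  xp[(pad[1] + 1):(pad[1] + d[1]), (pad[3] + 1):(pad[3] + d[2]), , ,
     drop = FALSE]
}

# ---- layer constructors ----------------------------------------------------

.init_w <- function(n, fan_in) array(stats::rnorm(n, 0, sqrt(2 / fan_in)))

layer_conv <- function(kh, kw, cin, cout, stride = c(1, 1),
                       padding = "same", bias = TRUE) {
  stride <- rep_len(stride, 2)
  W <- matrix(.init_w(kh * kw * cin * cout, kh * kw * cin),
              kh * kw * cin, cout)
  params <- list(W = W)
  if (bias) params$b <- numeric(cout)
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, padding = padding, bias = bias, params = params)
}

layer_depthwise <- function(kh, kw, cin, mult = 1, stride = c(1, 1),
                            padding = "same") {
  stride <- rep_len(stride, 2)
  W <- array(.init_w(kh * kw * cin * mult, kh * kw), c(kh * kw, cin, mult))
  list(type = "depthwise", kh = kh, kw = kw, cin = cin, mult = mult,
       stride = stride, padding = padding, params = list(W = W))
}

layer_separable <- function(kh, kw, cin, cout, padding = "same") {
  list(type = "seq",
       layers = list(layer_depthwise(kh, kw, cin, 1, c(1, 1), padding),
                     layer_conv(1, 1, cin, cout, c(1, 1), "valid",
                                bias = FALSE)))
}

layer_batchnorm <- function(ch, momentum = 0.9, eps = 1e-3) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(ch); st$var <- rep(1, ch); st$initialized <- FALSE
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       state = st, params = list(gamma = rep(1, ch), beta = numeric(ch)))
}

layer_act <- function(fun = c("elu", "relu", "sigmoid")) {
  list(type = "act", fun = match.arg(fun))
}

layer_avgpool <- function(ph, pw) list(type = "avgpool", ph = ph, pw = pw)

layer_maxpool <- function(ph, pw, stride = c(2, 2), padding = "same") {
  list(type = "maxpool", ph = ph, pw = pw, stride = rep_len(stride, 2),
       padding = padding)
}

layer_upsample <- function(factor = 2) list(type = "upsample", f = factor)

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

layer_flatten <- function() list(type = "flatten")

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(.init_w(n_in * n_out, n_in), n_in, n_out),
                     b = numeric(n_out)))
}

layer_residual <- function(main, shortcut) {
  list(type = "residual", main = main, shortcut = shortcut)
}

# ---- forward ---------------------------------------------------------------

.forward_layer <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      d <- dim(x); n <- d[4]
      if (layer$kh == 1 && layer$kw == 1 && all(layer$stride == 1)) {
        # pointwise fast path: a channel mixing matrix, no im2col needed
        cols <- aperm(x, c(3, 1, 2, 4))
        dim(cols) <- c(d[3], d[1] * d[2] * n)
        om <- crossprod(layer$params$W, cols)
        if (layer$bias) om <- om + layer$params$b
        out <- aperm(array(om, c(layer$cout, d[1], d[2], n)), c(2, 3, 1, 4))
        return(list(out = out,
                    cache = list(cols = cols, dims = d, pointwise = TRUE)))
      }
      pad <- .pad_amounts(d[1], d[2], layer$kh, layer$kw,
                          layer$stride[1], layer$stride[2], layer$padding)
      ohw <- .out_hw(d[1], d[2], layer$kh, layer$kw,
                     layer$stride[1], layer$stride[2], pad)
      cols <- .im2col(x, layer$kh, layer$kw,
                      layer$stride[1], layer$stride[2], pad)
      om <- crossprod(layer$params$W, cols)        # cout x (P*n)
      if (layer$bias) om <- om + layer$params$b
      out <- aperm(array(om, c(layer$cout, ohw[1], ohw[2], n)),
                   c(2, 3, 1, 4))
      list(out = out, cache = list(cols = cols, dims = d, pad = pad))
    },
    depthwise = {
      d <- dim(x); n <- d[4]
      pad <- .pad_amounts(d[1], d[2], layer$kh, layer$kw,
                          layer$stride[1], layer$stride[2], layer$padding)
      ohw <- .out_hw(d[1], d[2], layer$kh, layer$kw,
                     layer$stride[1], layer$stride[2], pad)
      cout <- layer$cin * layer$mult
      out <- array(0, c(ohw[1], ohw[2], cout, n))
      cols <- vector("list", layer$cin)
      for (ci in seq_len(layer$cin)) {
        cols[[ci]] <- .im2col(x[, , ci, , drop = FALSE], layer$kh, layer$kw,
                              layer$stride[1], layer$stride[2], pad)
        for (m in seq_len(layer$mult)) {
          om <- crossprod(layer$params$W[, ci, m, drop = FALSE], cols[[ci]])
          out[, , (ci - 1) * layer$mult + m, ] <-
            array(om, c(ohw[1], ohw[2], n))
        }
      }
      list(out = out, cache = list(cols = cols, dims = d, pad = pad))
    },
    batchnorm = {
      d <- dim(x)
      perm <- aperm(x, c(1, 2, 4, 3))
      dim(perm) <- c(d[1] * d[2] * d[4], d[3])   # rows = positions, cols = ch
      if (train) {
        mu <- colMeans(perm)
        v <- colMeans(sweep(perm, 2, mu)^2)
        st <- layer$state
        if (!st$initialized) {
          st$mean <- mu; st$var <- v; st$initialized <- TRUE
        } else {
          st$mean <- layer$momentum * st$mean + (1 - layer$momentum) * mu
          st$var <- layer$momentum * st$var + (1 - layer$momentum) * v
        }
      } else {
        mu <- layer$state$mean; v <- layer$state$var
      }
      inv_std <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(perm, 2, mu), 2, inv_std, `*`)
      om <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                  layer$params$beta, `+`)
      dim(om) <- c(d[1], d[2], d[4], d[3])
      out <- aperm(om, c(1, 2, 4, 3))
      list(out = out,
           cache = list(xhat = xhat, inv_std = inv_std, dims = d,
                        train = train))
    },
    act = {
      out <- switch(layer$fun,
        elu = {
          o <- x
          neg <- x <= 0
          o[neg] <- exp(pmax(x[neg], -30)) - 1
          o
        },
        relu = pmax(x, 0),
        sigmoid = 1 / (1 + exp(-x)))
      list(out = out, cache = list(out = out, x = x))
    },
    avgpool = {
      d <- dim(x)
      oh <- d[1] %/% layer$ph; ow <- d[2] %/% layer$pw
      out <- array(0, c(oh, ow, d[3], d[4]))
      for (i in seq_len(layer$ph)) for (j in seq_len(layer$pw)) {
        rows <- seq(i, by = layer$ph, length.out = oh)
        cc <- seq(j, by = layer$pw, length.out = ow)
        out <- out + x[rows, cc, , , drop = FALSE]
      }
      list(out = out / (layer$ph * layer$pw), cache = list(dims = d))
    },
    maxpool = {
      d <- dim(x)
      pad <- .pad_amounts(d[1], d[2], layer$ph, layer$pw,
                          layer$stride[1], layer$stride[2], layer$padding)
      hp <- d[1] + pad[1] + pad[2]; wp <- d[2] + pad[3] + pad[4]
      xp <- array(-Inf, c(hp, wp, d[3], d[4]))
      xp[(pad[1] + 1):(pad[1] + d[1]), (pad[3] + 1):(pad[3] + d[2]), , ] <- x
      ohw <- .out_hw(d[1], d[2], layer$ph, layer$pw,
                     layer$stride[1], layer$stride[2], pad)
      out <- array(-Inf, c(ohw[1], ohw[2], d[3], d[4]))
      arg <- array(1L, c(ohw[1], ohw[2], d[3], d[4]))
      k <- 0L
      for (i in seq_len(layer$ph)) for (j in seq_len(layer$pw)) {
        k <- k + 1L
        rows <- seq(i, by = layer$stride[1], length.out = ohw[1])
        cc <- seq(j, by = layer$stride[2], length.out = ohw[2])
        vals <- xp[rows, cc, , , drop = FALSE]
        upd <- vals > out
        out[upd] <- vals[upd]
        arg[upd] <- k
      }
      list(out = out, cache = list(dims = d, pad = pad, arg = arg,
                                   ohw = ohw))
    },
    upsample = {
      d <- dim(x); f <- layer$f
      out <- x[rep(seq_len(d[1]), each = f),
               rep(seq_len(d[2]), each = f), , , drop = FALSE]
      list(out = out, cache = list(dims = d))
    },
    dropout = {
      if (train && layer$rate > 0) {
        mask <- array((stats::runif(length(x)) > layer$rate) /
                        (1 - layer$rate), dim(x))
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = list(mask = NULL))
    },
    flatten = {
      d <- dim(x)
      out <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
      list(out = t(out), cache = list(dims = d))   # samples x features
    },
    dense = {
      out <- x %*% layer$params$W
      out <- sweep(out, 2, layer$params$b, `+`)
      list(out = out, cache = list(x = x))
    },
    seq = {
      fw <- .forward_layers(layer$layers, x, train)
      list(out = fw$out, cache = fw$caches)
    },
    residual = {
      fm <- .forward_layers(layer$main, x, train)
      fs <- .forward_layers(layer$shortcut, x, train)
      list(out = fm$out + fs$out,
           cache = list(main = fm$caches, shortcut = fs$caches))
    },
    stop("unknown layer type ", layer$type))
}

.forward_layers <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- .forward_layer(layers[[i]], x, train)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

# ---- backward --------------------------------------------------------------

.backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d <- cache$dims; n <- d[4]
      od <- dim(dout)
      dm <- aperm(dout, c(3, 1, 2, 4))
      dim(dm) <- c(layer$cout, od[1] * od[2] * n)
      dW <- tcrossprod(cache$cols, dm)
      dcols <- layer$params$W %*% dm
      dx <- if (isTRUE(cache$pointwise)) {
        aperm(array(dcols, c(d[3], d[1], d[2], n)), c(2, 3, 1, 4))
      } else {
        .col2im(dcols, d, layer$kh, layer$kw,
                layer$stride[1], layer$stride[2], cache$pad)
      }
      grads <- list(W = dW)
      if (layer$bias) grads$b <- rowSums(dm)
      list(dx = dx, grads = grads)
    },
    depthwise = {
      d <- cache$dims; n <- d[4]
      od <- dim(dout)
      dW <- array(0, dim(layer$params$W))
      dx <- array(0, d)
      for (ci in seq_len(layer$cin)) {
        dc <- matrix(0, layer$kh * layer$kw, od[1] * od[2] * n)
        for (m in seq_len(layer$mult)) {
          dm <- as.vector(dout[, , (ci - 1) * layer$mult + m, ])
          dW[, ci, m] <- cache$cols[[ci]] %*% dm
          dc <- dc + layer$params$W[, ci, m] %o% dm
        }
        dx[, , ci, ] <- .col2im(dc, c(d[1], d[2], 1L, n), layer$kh,
                                layer$kw, layer$stride[1], layer$stride[2],
                                cache$pad)
      }
      list(dx = dx, grads = list(W = dW))
    },
    batchnorm = {
      d <- cache$dims
      dperm <- aperm(dout, c(1, 2, 4, 3))
      dim(dperm) <- c(d[1] * d[2] * d[4], d[3])
      m <- nrow(dperm)
      dgamma <- colSums(dperm * cache$xhat)
      dbeta <- colSums(dperm)
      dxhat <- sweep(dperm, 2, layer$params$gamma, `*`)
      if (cache$train) {
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
        dp <- sweep(t1 - t2, 2, cache$inv_std, `*`)
      } else {
        dp <- sweep(dxhat, 2, cache$inv_std, `*`)
      }
      dim(dp) <- c(d[1], d[2], d[4], d[3])
      list(dx = aperm(dp, c(1, 2, 4, 3)),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      g <- switch(layer$fun,
        elu = ifelse(cache$x > 0, 1, cache$out + 1),
        relu = (cache$x > 0) * 1,
        sigmoid = cache$out * (1 - cache$out))
      list(dx = dout * g, grads = NULL)
    },
    avgpool = {
      d <- cache$dims
      dx <- array(0, d)
      scale <- 1 / (layer$ph * layer$pw)
      oh <- d[1] %/% layer$ph; ow <- d[2] %/% layer$pw
      for (i in seq_len(layer$ph)) for (j in seq_len(layer$pw)) {
        rows <- seq(i, by = layer$ph, length.out = oh)
        cc <- seq(j, by = layer$pw, length.out = ow)
        dx[rows, cc, , ] <- dx[rows, cc, , , drop = FALSE] + dout * scale
      }
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      d <- cache$dims; pad <- cache$pad
      hp <- d[1] + pad[1] + pad[2]; wp <- d[2] + pad[3] + pad[4]
      dxp <- array(0, c(hp, wp, d[3], d[4]))
      k <- 0L
      for (i in seq_len(layer$ph)) for (j in seq_len(layer$pw)) {
        k <- k + 1L
        rows <- seq(i, by = layer$stride[1], length.out = cache$ohw[1])
        cc <- seq(j, by = layer$stride[2], length.out = cache$ohw[2])
        sel <- dout * (cache$arg == k)
        dxp[rows, cc, , ] <- dxp[rows, cc, , , drop = FALSE] + sel
      }
      list(dx = dxp[(pad[1] + 1):(pad[1] + d[1]),
                    (pad[3] + 1):(pad[3] + d[2]), , , drop = FALSE],
           grads = NULL)
    },
    upsample = {
      d <- cache$dims; f <- layer$f
      dx <- array(0, d)
      for (i in seq_len(f)) for (j in seq_len(f)) {
        rows <- seq(i, by = f, length.out = d[1])
        cc <- seq(j, by = f, length.out = d[2])
        dx <- dx + dout[rows, cc, , , drop = FALSE]
      }
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = {
      list(dx = array(t(dout), cache$dims), grads = NULL)
    },
    dense = {
      list(dx = dout %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    seq = {
      bw <- .backward_layers(layer$layers, cache, dout)
      list(dx = bw$dx, grads = bw$grads)
    },
    residual = {
      bm <- .backward_layers(layer$main, cache$main, dout)
      bs <- .backward_layers(layer$shortcut, cache$shortcut, dout)
      list(dx = bm$dx + bs$dx, grads = list(main = bm$grads,
                                            shortcut = bs$grads))
    },
    stop("unknown layer type ", layer$type))
}

.backward_layers <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- .backward_layer(layers[[i]], caches[[i]], dout)
    dout <- bw$dx
    if (!is.null(bw$grads)) grads[[i]] <- bw$grads  # NULL would drop the slot
  }
  list(dx = dout, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(layer) {
    if (layer$type == "residual") {
      list(main = .adam_init(layer$main), shortcut = .adam_init(layer$shortcut))
    } else if (layer$type == "seq") {
      .adam_init(layer$layers)
    } else if (!is.null(layer$params)) {
      lapply(layer$params, function(p) list(m = p * 0, v = p * 0))
    } else NULL
  })
}

.adam_step <- function(layers, grads, state, lr, t, l2 = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (layer$type == "residual") {
      up_m <- .adam_step(layer$main, grads[[i]]$main, state[[i]]$main,
                         lr, t, l2, beta1, beta2, eps)
      up_s <- .adam_step(layer$shortcut, grads[[i]]$shortcut,
                         state[[i]]$shortcut, lr, t, l2, beta1, beta2, eps)
      layer$main <- up_m$layers; layer$shortcut <- up_s$layers
      state[[i]] <- list(main = up_m$state, shortcut = up_s$state)
      layers[[i]] <- layer
    } else if (layer$type == "seq") {
      up <- .adam_step(layer$layers, grads[[i]], state[[i]],
                       lr, t, l2, beta1, beta2, eps)
      layer$layers <- up$layers
      state[[i]] <- up$state
      layers[[i]] <- layer
    } else if (!is.null(layer$params) && !is.null(grads[[i]])) {
      for (pn in names(layer$params)) {
        g <- grads[[i]][[pn]]
        if (l2 > 0 && pn == "W") g <- g + 2 * l2 * layer$params[[pn]]
        st <- state[[i]][[pn]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        layer$params[[pn]] <- layer$params[[pn]] -
          corr * st$m / (sqrt(st$v) + eps)
        state[[i]][[pn]] <- st
      }
      layers[[i]] <- layer
    }
  }
  list(layers = layers, state = state)
}

.count_params <- function(layers) {
  sum(vapply(layers, function(layer) {
    if (layer$type == "residual")
      .count_params(layer$main) + .count_params(layer$shortcut)
    else if (layer$type == "seq") .count_params(layer$layers)
    else if (!is.null(layer$params))
      sum(vapply(layer$params, length, numeric(1)))
    else 0
  }, numeric(1)))
}

# ---- losses ----------------------------------------------------------------

.loss_bce <- function(p, target) {
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  n <- length(p)
  list(loss = -sum(target * log(pc) + (1 - target) * log(1 - pc)) / n,
       grad = array((pc - target) / (pc * (1 - pc)) / n,
                    dim(p) %||% length(p)))
}

.loss_mse <- function(p, target) {
  n <- length(p)
  list(loss = sum((p - target)^2) / n, grad = 2 * (p - target) / n)
}

.loss_softmax_xent <- function(logits, onehot) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  list(loss = -sum(onehot * log(pmax(p, 1e-12))) / n,
       grad = (p - onehot) / n, probs = p)
}

.stack_batches <- function(n, batch) {
  split(seq_len(n), ceiling(seq_len(n) / batch))
}
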
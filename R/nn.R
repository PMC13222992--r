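## Minimal neural-network engine: dense, 1D/2D convolution, max pooling,
## spatial dropout, GRU, layer normalization and multi-head self-attention
## layers with hand-derived backward passes, Glorot initialization, Adam,
## and a mini-batch training loop with early stopping. Everything operates
## on base-R arrays; sample index is always the first dimension.
##
## Tensor flattening convention: dim(x) <- c(n * spatial, channels) keeps
## the sample index fastest, and every backward pass reshapes with the same
## convention, so layers compose without explicit permutes.

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer constructors (specs only; parameters come from nn_init) ------

layer_dense <- function(units) list(type = "dense", units = units)
layer_relu <- function() list(type = "relu")
layer_flatten <- function() list(type = "flatten")
layer_conv1d <- function(filters, kernel = 3L)
  list(type = "conv1d", filters = filters, kernel = kernel)
layer_maxpool1d <- function(size = 2L) list(type = "maxpool1d", size = size)
layer_conv2d <- function(filters, kernel = 3L)
  list(type = "conv2d", filters = filters, kernel = kernel)
layer_maxpool2d <- function(size = 2L) list(type = "maxpool2d", size = size)
layer_spatial_dropout <- function(rate = 0.2)
  list(type = "spatial_dropout", rate = rate)
layer_gru <- function(units, return_sequences = FALSE)
  list(type = "gru", units = units, return_sequences = return_sequences)
layer_layernorm <- function() list(type = "layernorm")
layer_attention <- function(heads = 4L) list(type = "attention", heads = heads)
layer_ffn_residual <- function(hidden = 128L)
  list(type = "ffn_residual", hidden = hidden)
layer_mean_pool_tokens <- function() list(type = "mean_pool_tokens")

## ---- initialization ------------------------------------------------------

## Walks the layer list once with a dummy input shape to size parameters.
nn_init_layers <- function(layers, input_shape) {
  params <- vector("list", length(layers))
  shape <- input_shape                      # shape excludes the sample dim
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    p <- list()
    if (l$type == "dense") {
      d <- prod(shape)
      p <- list(W = glorot(d, l$units, c(d, l$units)), b = numeric(l$units))
      shape <- l$units
    } else if (l$type == "conv1d") {
      ch <- shape[2]
      fin <- l$kernel * ch
      p <- list(W = glorot(fin, l$filters, c(fin, l$filters)),
                b = numeric(l$filters))
      shape <- c(shape[1], l$filters)
    } else if (l$type == "maxpool1d") {
      shape <- c(max(1L, shape[1] %/% l$size), shape[2])
    } else if (l$type == "conv2d") {
      ch <- shape[3]
      fin <- l$kernel^2 * ch
      p <- list(W = glorot(fin, l$filters, c(fin, l$filters)),
                b = numeric(l$filters))
      shape <- c(shape[1], shape[2], l$filters)
    } else if (l$type == "maxpool2d") {
      if (shape[1] < l$size || shape[2] < l$size)
        stopf("pooling depth exceeds input size (%s left)",
              paste(shape, collapse = "x"))
      shape <- c(shape[1] %/% l$size, shape[2] %/% l$size, shape[3])
    } else if (l$type == "gru") {
      d <- shape[2]; u <- l$units
      p <- list(Wz = glorot(d, u, c(d, u)), Uz = glorot(u, u, c(u, u)),
                bz = numeric(u),
                Wr = glorot(d, u, c(d, u)), Ur = glorot(u, u, c(u, u)),
                br = numeric(u),
                Wh = glorot(d, u, c(d, u)), Uh = glorot(u, u, c(u, u)),
                bh = numeric(u))
      shape <- if (l$return_sequences) c(shape[1], u) else u
    } else if (l$type == "layernorm") {
      d <- shape[length(shape)]
      p <- list(g = rep(1, d), b = numeric(d))
    } else if (l$type == "attention") {
      dm <- shape[2]
      if (dm %% l$heads != 0L) stopf("model width %d not divisible by %d heads",
                                     dm, l$heads)
      p <- list(Wq = glorot(dm, dm, c(dm, dm)), Wk = glorot(dm, dm, c(dm, dm)),
                Wv = glorot(dm, dm, c(dm, dm)), Wo = glorot(dm, dm, c(dm, dm)))
    } else if (l$type == "ffn_residual") {
      dm <- shape[2]
      p <- list(W1 = glorot(dm, l$hidden, c(dm, l$hidden)),
                b1 = numeric(l$hidden),
                W2 = glorot(l$hidden, dm, c(l$hidden, dm)), b2 = numeric(dm))
    } else if (l$type == "mean_pool_tokens") {
      shape <- shape[2]
    } else if (l$type == "flatten") {
      shape <- prod(shape)
    }
    params[[li]] <- p
  }
  list(params = params, output_shape = shape)
}

## ---- forward / backward per layer ---------------------------------------

as_mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1) else x
}

layer_forward <- function(l, p, x, training, dropout_rate) {
  switch(l$type,
    dense = {
      xm <- x
      orig_dim <- dim(x)
      if (length(dim(x)) > 2L) dim(xm) <- c(dim(x)[1], prod(dim(x)[-1]))
      out <- sweep(xm %*% p$W, 2, p$b, "+")
      list(out = out, cache = list(x = xm, orig_dim = orig_dim))
    },
    relu = {
      out <- x; out[out < 0] <- 0
      list(out = out, cache = list(mask = x > 0))
    },
    flatten = {
      out <- x
      dim(out) <- c(dim(x)[1], prod(dim(x)[-1]))
      list(out = out, cache = list(orig_dim = dim(x)))
    },
    conv1d = conv1d_forward(l, p, x),
    maxpool1d = maxpool1d_forward(l, x),
    conv2d = conv2d_forward(l, p, x),
    maxpool2d = maxpool2d_forward(l, x),
    spatial_dropout = {
      if (!training || l$rate <= 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        d <- dim(x)
        ch <- d[length(d)]
        keep <- matrix(stats::runif(d[1] * ch) >= l$rate, d[1], ch) /
          (1 - l$rate)
        full <- array(0, d)
        if (length(d) == 3L) {
          for (c in seq_len(ch)) full[, , c] <- keep[, c]
        } else {
          for (c in seq_len(ch)) full[, , , c] <- keep[, c]
        }
        list(out = x * full, cache = list(mask = full))
      }
    },
    gru = gru_forward(l, p, x),
    layernorm = layernorm_forward(p, x),
    attention = attention_forward(l, p, x),
    ffn_residual = {
      d <- dim(x)                       # (n, T, dm)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
      h1 <- sweep(xm %*% p$W1, 2, p$b1, "+")
      a1 <- h1; a1[a1 < 0] <- 0
      h2 <- sweep(a1 %*% p$W2, 2, p$b2, "+")
      out <- xm + h2
      dim(out) <- d
      list(out = out, cache = list(xm = xm, a1 = a1, mask = h1 > 0, d = d))
    },
    mean_pool_tokens = {
      d <- dim(x)                       # (n, T, dm)
      out <- apply(x, c(1, 3), mean)
      list(out = out, cache = list(d = d))
    },
    stopf("unknown layer type %s", l$type))
}

layer_backward <- function(l, p, cache, dout) {
  switch(l$type,
    dense = {
      dW <- crossprod(cache$x, dout)
      db <- colSums(as_mat(dout))
      dx <- tcrossprod(dout, p$W)
      if (length(cache$orig_dim) > 2L) dim(dx) <- cache$orig_dim
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    flatten = {
      dx <- dout; dim(dx) <- cache$orig_dim
      list(dx = dx, grads = list())
    },
    conv1d = conv1d_backward(l, p, cache, dout),
    maxpool1d = maxpool1d_backward(cache, dout),
    conv2d = conv2d_backward(l, p, cache, dout),
    maxpool2d = maxpool2d_backward(cache, dout),
    spatial_dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    gru = gru_backward(l, p, cache, dout),
    layernorm = layernorm_backward(p, cache, dout),
    attention = attention_backward(l, p, cache, dout),
    ffn_residual = {
      d <- cache$d
      dm <- dout; dim(dm) <- c(d[1] * d[2], d[3])
      dW2 <- crossprod(cache$a1, dm); db2 <- colSums(dm)
      da1 <- tcrossprod(dm, p$W2) * cache$mask
      dW1 <- crossprod(cache$xm, da1); db1 <- colSums(da1)
      dx <- dm + tcrossprod(da1, p$W1)
      dim(dx) <- d
      list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
    },
    mean_pool_tokens = {
      d <- cache$d
      dx <- array(0, d)
      for (t in seq_len(d[2])) dx[, t, ] <- dout / d[2]
      list(dx = dx, grads = list())
    },
    stopf("unknown layer type %s", l$type))
}

## ---- convolution ---------------------------------------------------------

conv1d_forward <- function(l, p, x) {
  d <- dim(x); n <- d[1]; len <- d[2]; ch <- d[3]
  k <- l$kernel; pad <- (k - 1L) %/% 2L
  xp <- array(0, c(n, len + 2L * pad, ch))
  xp[, pad + seq_len(len), ] <- x
  blocks <- vector("list", k)
  for (t in seq_len(k)) {
    blk <- xp[, t:(t + len - 1L), , drop = FALSE]
    dim(blk) <- c(n * len, ch)
    blocks[[t]] <- blk
  }
  Xc <- do.call(cbind, blocks)
  out <- sweep(Xc %*% p$W, 2, p$b, "+")
  dim(out) <- c(n, len, l$filters)
  list(out = out, cache = list(Xc = Xc, n = n, len = len, ch = ch,
                               k = k, pad = pad))
}

conv1d_backward <- function(l, p, cache, dout) {
  n <- cache$n; len <- cache$len; ch <- cache$ch
  k <- cache$k; pad <- cache$pad
  dm <- dout; dim(dm) <- c(n * len, l$filters)
  dW <- crossprod(cache$Xc, dm)
  db <- colSums(dm)
  dXc <- tcrossprod(dm, p$W)
  dxp <- array(0, c(n, len + 2L * pad, ch))
  for (t in seq_len(k)) {
    blk <- dXc[, ((t - 1L) * ch + 1L):(t * ch), drop = FALSE]
    dim(blk) <- c(n, len, ch)
    dxp[, t:(t + len - 1L), ] <- dxp[, t:(t + len - 1L), , drop = FALSE] + blk
  }
  dx <- dxp[, pad + seq_len(len), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

conv2d_forward <- function(l, p, x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; ch <- d[4]
  k <- l$kernel; pad <- (k - 1L) %/% 2L
  xp <- array(0, c(n, h + 2L * pad, w + 2L * pad, ch))
  xp[, pad + seq_len(h), pad + seq_len(w), ] <- x
  blocks <- vector("list", k * k)
  bi <- 1L
  for (tx in seq_len(k)) for (ty in seq_len(k)) {
    blk <- xp[, ty:(ty + h - 1L), tx:(tx + w - 1L), , drop = FALSE]
    dim(blk) <- c(n * h * w, ch)
    blocks[[bi]] <- blk
    bi <- bi + 1L
  }
  Xc <- do.call(cbind, blocks)
  out <- sweep(Xc %*% p$W, 2, p$b, "+")
  dim(out) <- c(n, h, w, l$filters)
  list(out = out, cache = list(Xc = Xc, n = n, h = h, w = w, ch = ch,
                               k = k, pad = pad))
}

conv2d_backward <- function(l, p, cache, dout) {
  n <- cache$n; h <- cache$h; w <- cache$w; ch <- cache$ch
  k <- cache$k; pad <- cache$pad
  dm <- dout; dim(dm) <- c(n * h * w, l$filters)
  dW <- crossprod(cache$Xc, dm)
  db <- colSums(dm)
  dXc <- tcrossprod(dm, p$W)
  dxp <- array(0, c(n, h + 2L * pad, w + 2L * pad, ch))
  bi <- 1L
  for (tx in seq_len(k)) for (ty in seq_len(k)) {
    blk <- dXc[, ((bi - 1L) * ch + 1L):(bi * ch), drop = FALSE]
    dim(blk) <- c(n, h, w, ch)
    dxp[, ty:(ty + h - 1L), tx:(tx + w - 1L), ] <-
      dxp[, ty:(ty + h - 1L), tx:(tx + w - 1L), , drop = FALSE] + blk
    bi <- bi + 1L
  }
  dx <- dxp[, pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- pooling -------------------------------------------------------------

maxpool1d_forward <- function(l, x) {
  d <- dim(x); n <- d[1]; len <- d[2]; ch <- d[3]
  m <- len %/% l$size
  if (m < 1L) return(list(out = x, cache = list(identity = TRUE)))
  a <- x[, seq(1L, 2L * m, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * m, by = 2L), , drop = FALSE]
  out <- pmax(a, b)
  list(out = out, cache = list(mask_a = a >= b, d = d, m = m))
}

maxpool1d_backward <- function(cache, dout) {
  if (isTRUE(cache$identity)) return(list(dx = dout, grads = list()))
  d <- cache$d; m <- cache$m
  dx <- array(0, d)
  dx[, seq(1L, 2L * m, by = 2L), ] <- dout * cache$mask_a
  dx[, seq(2L, 2L * m, by = 2L), ] <- dout * !cache$mask_a
  list(dx = dx, grads = list())
}

maxpool2d_forward <- function(l, x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; ch <- d[4]
  mh <- h %/% l$size; mw <- w %/% l$size
  oy <- seq(1L, 2L * mh, by = 2L); ox <- seq(1L, 2L * mw, by = 2L)
  x11 <- x[, oy, ox, , drop = FALSE];     x21 <- x[, oy + 1L, ox, , drop = FALSE]
  x12 <- x[, oy, ox + 1L, , drop = FALSE]; x22 <- x[, oy + 1L, ox + 1L, , drop = FALSE]
  out <- pmax(x11, x21, x12, x22)
  m1 <- x11 == out
  m2 <- (x21 == out) & !m1
  m3 <- (x12 == out) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(out = out,
       cache = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4, d = d,
                    oy = oy, ox = ox))
}

maxpool2d_backward <- function(cache, dout) {
  d <- cache$d; oy <- cache$oy; ox <- cache$ox
  dx <- array(0, d)
  dx[, oy, ox, ] <- dout * cache$m1
  dx[, oy + 1L, ox, ] <- dout * cache$m2
  dx[, oy, ox + 1L, ] <- dout * cache$m3
  dx[, oy + 1L, ox + 1L, ] <- dout * cache$m4
  list(dx = dx, grads = list())
}

## ---- GRU -----------------------------------------------------------------

gru_forward <- function(l, p, x) {
  d <- dim(x); n <- d[1]; L <- d[2]; u <- l$units
  h <- matrix(0, n, u)
  steps <- vector("list", L)
  seq_out <- array(0, c(n, L, u))
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, ], n)
    z <- sigmoid(sweep(xt %*% p$Wz + h %*% p$Uz, 2, p$bz, "+"))
    r <- sigmoid(sweep(xt %*% p$Wr + h %*% p$Ur, 2, p$br, "+"))
    hh <- tanh(sweep(xt %*% p$Wh + (r * h) %*% p$Uh, 2, p$bh, "+"))
    h_new <- (1 - z) * h + z * hh
    steps[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, hh = hh)
    h <- h_new
    seq_out[, t, ] <- h
  }
  out <- if (l$return_sequences) seq_out else h
  list(out = out, cache = list(steps = steps, n = n, L = L, u = u))
}

gru_backward <- function(l, p, cache, dout) {
  n <- cache$n; L <- cache$L; u <- cache$u
  g <- lapply(p, function(q) array(0, dim(q) %||% length(q)))
  dx <- array(0, c(n, L, ncol(cache$steps[[1]]$xt)))
  dh <- matrix(0, n, u)
  for (t in rev(seq_len(L))) {
    dh_t <- dh
    if (l$return_sequences) dh_t <- dh_t + matrix(dout[, t, ], n)
    else if (t == L) dh_t <- dh_t + dout
    st <- cache$steps[[t]]
    dz <- dh_t * (st$hh - st$h_prev)
    dhh <- dh_t * st$z
    dh_prev <- dh_t * (1 - st$z)
    dhh_pre <- dhh * (1 - st$hh^2)
    g$Wh <- g$Wh + crossprod(st$xt, dhh_pre)
    g$Uh <- g$Uh + crossprod(st$r * st$h_prev, dhh_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    drh <- tcrossprod(dhh_pre, p$Uh)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    g$Wz <- g$Wz + crossprod(st$xt, dz_pre)
    g$Uz <- g$Uz + crossprod(st$h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    dh_prev <- dh_prev + tcrossprod(dz_pre, p$Uz)
    dr_pre <- dr * st$r * (1 - st$r)
    g$Wr <- g$Wr + crossprod(st$xt, dr_pre)
    g$Ur <- g$Ur + crossprod(st$h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    dh_prev <- dh_prev + tcrossprod(dr_pre, p$Ur)
    dx[, t, ] <- tcrossprod(dhh_pre, p$Wh) + tcrossprod(dz_pre, p$Wz) +
      tcrossprod(dr_pre, p$Wr)
    dh <- dh_prev
  }
  list(dx = dx, grads = g)
}

## ---- layer norm ----------------------------------------------------------

layernorm_forward <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[-length(d)]), d[length(d)])
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- xc / s
  out <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, s = s, d = d))
}

layernorm_backward <- function(p, cache, dout) {
  d <- cache$d
  dm <- dout; dim(dm) <- dim(cache$xhat)
  D <- ncol(dm)
  dg <- colSums(dm * cache$xhat)
  db <- colSums(dm)
  dxhat <- sweep(dm, 2, p$g, "*")
  ## dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / s, row-wise
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) / cache$s
  dim(dx) <- d
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- multi-head self-attention ------------------------------------------

attention_forward <- function(l, p, x) {
  d <- dim(x); n <- d[1]; Tn <- d[2]; dm <- d[3]
  nh <- l$heads; dk <- dm %/% nh
  xm <- x; dim(xm) <- c(n * Tn, dm)
  Q <- xm %*% p$Wq; K <- xm %*% p$Wk; V <- xm %*% p$Wv
  dim(Q) <- dim(K) <- dim(V) <- c(n, Tn, dm)
  ctx <- array(0, c(n, Tn, dm))
  att_all <- vector("list", nh)
  for (hh in seq_len(nh)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    Qh <- Q[, , cols, drop = FALSE]; Kh <- K[, , cols, drop = FALSE]
    Vh <- V[, , cols, drop = FALSE]
    sc <- array(0, c(n, Tn, Tn))
    for (a in seq_len(Tn)) for (b in seq_len(Tn))
      sc[, a, b] <- rowSums(matrix(Qh[, a, ], n) * matrix(Kh[, b, ], n)) /
        sqrt(dk)
    ## softmax over b
    att <- sc
    for (a in seq_len(Tn)) {
      m <- apply(matrix(sc[, a, ], n), 1, max)
      e <- exp(matrix(sc[, a, ], n) - m)
      att[, a, ] <- e / rowSums(e)
    }
    for (a in seq_len(Tn)) {
      acc <- matrix(0, n, dk)
      for (b in seq_len(Tn))
        acc <- acc + att[, a, b] * matrix(Vh[, b, ], n)
      ctx[, a, cols] <- acc
    }
    att_all[[hh]] <- att
  }
  ctxm <- ctx; dim(ctxm) <- c(n * Tn, dm)
  om <- ctxm %*% p$Wo
  out <- x + array(om, c(n, Tn, dm))       # residual connection
  list(out = out,
       cache = list(xm = xm, Q = Q, K = K, V = V, ctxm = ctxm,
                    att = att_all, n = n, Tn = Tn, dm = dm, nh = nh, dk = dk))
}

attention_backward <- function(l, p, cache, dout) {
  n <- cache$n; Tn <- cache$Tn; dm <- cache$dm
  nh <- cache$nh; dk <- cache$dk
  dm_out <- dout; dim(dm_out) <- c(n * Tn, dm)
  dWo <- crossprod(cache$ctxm, dm_out)
  dctx <- tcrossprod(dm_out, p$Wo)
  dim(dctx) <- c(n, Tn, dm)
  dQ <- array(0, c(n, Tn, dm)); dK <- array(0, c(n, Tn, dm))
  dV <- array(0, c(n, Tn, dm))
  for (hh in seq_len(nh)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    att <- cache$att[[hh]]
    Qh <- cache$Q[, , cols, drop = FALSE]; Kh <- cache$K[, , cols, drop = FALSE]
    Vh <- cache$V[, , cols, drop = FALSE]
    datt <- array(0, c(n, Tn, Tn))
    for (a in seq_len(Tn)) {
      dca <- matrix(dctx[, a, cols], n)
      for (b in seq_len(Tn)) {
        datt[, a, b] <- rowSums(dca * matrix(Vh[, b, ], n))
        dV[, b, cols] <- dV[, b, cols] + att[, a, b] * dca
      }
    }
    ## softmax backward per (sample, a) row: dsc = att * (datt - sum(datt*att))
    dsc <- array(0, c(n, Tn, Tn))
    for (a in seq_len(Tn)) {
      arow <- matrix(att[, a, ], n); drow <- matrix(datt[, a, ], n)
      dot <- rowSums(arow * drow)
      dsc[, a, ] <- arow * (drow - dot)
    }
    for (a in seq_len(Tn)) for (b in seq_len(Tn)) {
      s <- dsc[, a, b] / sqrt(dk)
      dQ[, a, cols] <- dQ[, a, cols] + s * matrix(Kh[, b, ], n)
      dK[, b, cols] <- dK[, b, cols] + s * matrix(Qh[, a, ], n)
    }
  }
  dQm <- dQ; dim(dQm) <- c(n * Tn, dm)
  dKm <- dK; dim(dKm) <- c(n * Tn, dm)
  dVm <- dV; dim(dVm) <- c(n * Tn, dm)
  dWq <- crossprod(cache$xm, dQm)
  dWk <- crossprod(cache$xm, dKm)
  dWv <- crossprod(cache$xm, dVm)
  dxm <- dm_out * 0 + tcrossprod(dQm, p$Wq) + tcrossprod(dKm, p$Wk) +
    tcrossprod(dVm, p$Wv)
  dx <- array(dxm, c(n, Tn, dm)) + dout    # residual path
  list(dx = dx,
       grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

## ---- network-level forward/backward -------------------------------------

## A network is a list of branches (each: input name + layer list) and a
## head layer list consuming the concatenated branch outputs.
nn_init_network <- function(net, input_shapes, seed) {
  with_seed(seed, {
    params <- list(branches = vector("list", length(net$branches)))
    widths <- integer(length(net$branches))
    for (bi in seq_along(net$branches)) {
      br <- net$branches[[bi]]
      ini <- nn_init_layers(br$layers, input_shapes[[br$input]])
      params$branches[[bi]] <- ini$params
      widths[bi] <- prod(ini$output_shape)
    }
    ini <- nn_init_layers(net$head, sum(widths))
    params$head <- ini$params
    params
  })
}

nn_forward <- function(net, params, inputs, training = FALSE) {
  branch_out <- vector("list", length(net$branches))
  branch_cache <- vector("list", length(net$branches))
  branch_dims <- vector("list", length(net$branches))
  for (bi in seq_along(net$branches)) {
    br <- net$branches[[bi]]
    x <- inputs[[br$input]]
    caches <- vector("list", length(br$layers))
    for (li in seq_along(br$layers)) {
      fr <- layer_forward(br$layers[[li]], params$branches[[bi]][[li]], x,
                          training)
      x <- fr$out
      caches[[li]] <- fr$cache
    }
    branch_dims[[bi]] <- dim(x)         # pre-flatten shape of branch output
    if (length(dim(x)) > 2L) dim(x) <- c(dim(x)[1], prod(dim(x)[-1]))
    branch_out[[bi]] <- as_mat(x)
    branch_cache[[bi]] <- caches
  }
  h <- do.call(cbind, branch_out)
  head_cache <- vector("list", length(net$head))
  for (li in seq_along(net$head)) {
    fr <- layer_forward(net$head[[li]], params$head[[li]], h, training)
    h <- fr$out
    head_cache[[li]] <- fr$cache
  }
  list(out = as.vector(h),
       cache = list(branch = branch_cache, head = head_cache,
                    widths = vapply(branch_out, ncol, integer(1)),
                    branch_dims = branch_dims))
}

nn_backward <- function(net, params, cache, dout, inputs) {
  grads <- list(branches = vector("list", length(net$branches)),
                head = vector("list", length(net$head)))
  d <- matrix(dout, ncol = 1)
  for (li in rev(seq_along(net$head))) {
    bb <- layer_backward(net$head[[li]], params$head[[li]],
                         cache$head[[li]], d)
    grads$head[[li]] <- bb$grads
    d <- bb$dx
  }
  offs <- c(0L, cumsum(cache$widths))
  for (bi in seq_along(net$branches)) {
    br <- net$branches[[bi]]
    dx <- d[, (offs[bi] + 1L):offs[bi + 1L], drop = FALSE]
    bd <- cache$branch_dims[[bi]]       # undo the implicit branch-end flatten
    if (length(bd) > 2L) dim(dx) <- bd
    gl <- vector("list", length(br$layers))
    for (li in rev(seq_along(br$layers))) {
      bb <- layer_backward(br$layers[[li]], params$branches[[bi]][[li]],
                           cache$branch[[bi]][[li]], dx)
      gl[[li]] <- bb$grads
      dx <- bb$dx
    }
    grads$branches[[bi]] <- gl
  }
  grads
}

## ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else array(0, dim(x) %||% length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        if (length(p[[k]]) == 0L) next
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^tt)
      vhat <- v2 / (1 - beta2^tt)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}

## ---- training loop -------------------------------------------------------

## Subset the first (sample) dimension of every input tensor.
subset_inputs <- function(inputs, idx) {
  lapply(inputs, function(x) {
    d <- dim(x)
    if (length(d) == 2L) x[idx, , drop = FALSE]
    else if (length(d) == 3L) x[idx, , , drop = FALSE]
    else x[idx, , , , drop = FALSE]
  })
}

## Mini-batch Adam with MSE loss and early stopping on a validation split
## carved from the training data. Returns best-by-validation parameters and
## the per-epoch loss history.
nn_train <- function(net, inputs, y, seed, lr = 1e-3, batch_size = 32L,
                     max_epochs = 200L, patience = 20L, val_fraction = 0.1,
                     verbose = FALSE) {
  n <- length(y)
  input_shapes <- lapply(inputs, function(x) dim(x)[-1])
  params <- nn_init_network(net, input_shapes, seed)
  state <- adam_state(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  with_seed(child_seed(seed, "trainloop"), {
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) { tr_idx <- val_idx }
    Xtr <- subset_inputs(inputs, tr_idx); ytr <- y[tr_idx]
    Xval <- subset_inputs(inputs, val_idx); yval <- y[val_idx]
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(length(ytr))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (b in batches) {
        Xb <- subset_inputs(Xtr, b); yb <- ytr[b]
        fw <- nn_forward(net, params, Xb, training = TRUE)
        err <- fw$out - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        ep_loss <- ep_loss + loss * length(b)
        dout <- 2 * err / length(b)
        grads <- nn_backward(net, params, fw$cache, dout, Xb)
        r <- adam_update(params, grads, state, lr = lr)
        params <- r$params; state <- r$state
      }
      ep_loss <- ep_loss / length(ytr)
      val_pred <- nn_forward(net, params, Xval, training = FALSE)$out
      val_loss <- mean((val_pred - yval)^2)
      if (!is.finite(val_loss))
        stopf("training diverged (non-finite validation loss) at epoch %d",
              epoch)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss,
                                           val_loss = val_loss))
      if (verbose && epoch %% 10L == 0L)
        message(sprintf("epoch %d train %.4f val %.4f", epoch, ep_loss, val_loss))
      if (val_loss < best$loss - 1e-7) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(params = best$params, history = history, best_epoch = best$epoch)
  })
}
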
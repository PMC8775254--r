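## Minimal trainable network engine.
##
## Layers are mutable environments holding parameters, gradients and SGDM
## velocities; `layer_forward()` / `layer_backward()` dispatch on `$type`.
## Spatial maps travel as (batch, W, H, C) arrays (channel-last); dense
## activations as (batch, D) matrices. Convolutions use im2col + one matrix
## product per layer. Every backward pass is covered by finite-difference
## gradient checks in the test suite.

new_layer <- function(type, name, fields = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type; e$name <- name
  e$params <- list(); e$grads <- list(); e$vel <- list()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "nn_layer"
  e
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

nn_conv2d <- function(k, c_in, filters, stride = 1L, bias = TRUE,
                      name = sprintf("conv_%d_%d", filters, k)) {
  l <- new_layer("conv2d", name,
                 list(k = as.integer(k), c_in = as.integer(c_in),
                      filters = as.integer(filters), stride = as.integer(stride),
                      use_bias = bias))
  l$params$W <- he_init(c(k, k, c_in, filters), k * k * c_in)
  if (bias) l$params$b <- rep(0, filters)
  l
}

nn_batchnorm <- function(channels, momentum = 0.99, eps = 1e-5,
                         name = "batch_norm") {
  l <- new_layer("batchnorm", name,
                 list(channels = as.integer(channels), momentum = momentum,
                      eps = eps, running_mean = rep(0, channels),
                      running_var = rep(1, channels)))
  l$params$gamma <- rep(1, channels)
  l$params$beta <- rep(0, channels)
  l
}

nn_relu <- function(name = "relu") new_layer("relu", name)

nn_maxpool2 <- function(name = "max_pool_2") new_layer("maxpool2", name)

## The trainable CFF layer: max-pool branch in parallel with a 2-stride
## convolution branch (ReLU-activated; batch normalization optional and off
## by default — BN is reserved for the 1-stride convolutions), channels
## concatenated pool-first.
nn_cff <- function(k, c_in, filters, bias = TRUE, branch_bn = FALSE,
                   name = sprintf("cff(max_pool_2 || conv_%d_%d_s2)", filters, k)) {
  l <- new_layer("cff", name, list(k = as.integer(k), c_in = as.integer(c_in),
                                   filters = as.integer(filters),
                                   branch_bn = branch_bn))
  l$conv <- nn_conv2d(k, c_in, filters, stride = 2L, bias = bias,
                      name = sprintf("conv_%d_%d_s2", filters, k))
  if (branch_bn) l$bn <- nn_batchnorm(filters, name = "branch_batch_norm")
  l
}

nn_flatten <- function(name = "flatten") new_layer("flatten", name)

nn_dense <- function(d_in, units, name = sprintf("fc_%d", units)) {
  l <- new_layer("dense", name,
                 list(d_in = as.integer(d_in), units = as.integer(units)))
  l$params$W <- he_init(c(d_in, units), d_in)
  l$params$b <- rep(0, units)
  l
}

nn_dropout <- function(rate = 0.5, name = sprintf("dropout_%g", rate)) {
  new_layer("dropout", name, list(rate = rate))
}

nn_lstm <- function(d_in, units, name = sprintf("lstm_%d", units)) {
  l <- new_layer("lstm", name,
                 list(d_in = as.integer(d_in), units = as.integer(units)))
  s <- sqrt(1 / units)
  l$params$Wx <- array(stats::runif(d_in * 4L * units, -s, s), c(d_in, 4L * units))
  l$params$Wh <- array(stats::runif(units * 4L * units, -s, s), c(units, 4L * units))
  b <- rep(0, 4L * units)
  b[(units + 1L):(2L * units)] <- 1     # forget-gate bias
  l$params$b <- b
  l
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- conv2d internals -------------------------------------------------

conv_pad <- function(x, k, stride) {
  d <- dim(x)
  ow <- as.integer(ceiling(d[2L] / stride)); oh <- as.integer(ceiling(d[3L] / stride))
  pw <- max((ow - 1L) * stride + k - d[2L], 0L)
  ph <- max((oh - 1L) * stride + k - d[3L], 0L)
  xp <- array(0, c(d[1L], d[2L] + pw, d[3L] + ph, d[4L]))
  xp[, pw %/% 2L + seq_len(d[2L]), ph %/% 2L + seq_len(d[3L]), ] <- x
  list(xp = xp, ow = ow, oh = oh, off_w = pw %/% 2L, off_h = ph %/% 2L)
}

im2col <- function(xp, k, stride, ow, oh) {
  d <- dim(xp); B <- d[1L]; C <- d[4L]
  col <- array(NA_real_, c(B, ow, oh, k * k * C))
  rw <- (seq_len(ow) - 1L) * stride
  rh <- (seq_len(oh) - 1L) * stride
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    blk <- ((dj - 1L) * k + di - 1L) * C
    col[, , , blk + seq_len(C)] <- xp[, rw + di, rh + dj, , drop = FALSE]
  }
  dim(col) <- c(B * ow * oh, k * k * C)
  col
}

col2im <- function(dcol, dim_xp, k, stride, ow, oh) {
  B <- dim_xp[1L]; C <- dim_xp[4L]
  dim(dcol) <- c(B, ow, oh, k * k * C)
  dxp <- array(0, dim_xp)
  rw <- (seq_len(ow) - 1L) * stride
  rh <- (seq_len(oh) - 1L) * stride
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    blk <- ((dj - 1L) * k + di - 1L) * C
    dxp[, rw + di, rh + dj, ] <- dxp[, rw + di, rh + dj, , drop = FALSE] +
      dcol[, , , blk + seq_len(C), drop = FALSE]
  }
  dxp
}

## weight array (k,k,C,F) -> matrix with rows ordered (C fastest, di, dj)
conv_wmat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3L, 1L, 2L, 4L)), d[1L] * d[2L] * d[3L], d[4L])
}

conv_wmat_inv <- function(Wmat, k, c_in, f) {
  aperm(array(Wmat, c(c_in, k, k, f)), c(2L, 3L, 1L, 4L))
}

conv2d_forward <- function(l, x) {
  p <- conv_pad(x, l$k, l$stride)
  col <- im2col(p$xp, l$k, l$stride, p$ow, p$oh)
  out <- col %*% conv_wmat(l$params$W)
  if (l$use_bias) out <- sweep(out, 2L, l$params$b, "+")
  l$cache <- list(col = col, dim_xp = dim(p$xp), dim_x = dim(x),
                  ow = p$ow, oh = p$oh, off_w = p$off_w, off_h = p$off_h,
                  B = dim(x)[1L])
  dim(out) <- c(dim(x)[1L], p$ow, p$oh, l$filters)
  out
}

conv2d_backward <- function(l, dy) {
  cc <- l$cache
  dmat <- dy; dim(dmat) <- c(cc$B * cc$ow * cc$oh, l$filters)
  Wmat <- conv_wmat(l$params$W)
  l$grads$W <- conv_wmat_inv(crossprod(cc$col, dmat), l$k, l$c_in, l$filters)
  if (l$use_bias) l$grads$b <- colSums(dmat)
  dcol <- tcrossprod(dmat, Wmat)
  dxp <- col2im(dcol, cc$dim_xp, l$k, l$stride, cc$ow, cc$oh)
  dxp[, cc$off_w + seq_len(cc$dim_x[2L]),
      cc$off_h + seq_len(cc$dim_x[3L]), , drop = FALSE]
}

## ---- other layer internals --------------------------------------------

bn_forward <- function(l, x, training) {
  d <- dim(x)
  xm <- x
  if (!is.null(d) && length(d) == 4L) dim(xm) <- c(prod(d[1:3]), d[4L])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
    l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
  } else {
    mu <- l$running_mean; v <- l$running_var
    xc <- sweep(xm, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + l$eps)
  xhat <- sweep(xc, 2L, inv_std, "*")
  y <- sweep(sweep(xhat, 2L, l$params$gamma, "*"), 2L, l$params$beta, "+")
  l$cache <- list(xhat = xhat, inv_std = inv_std, dim = d, training = training)
  if (!is.null(d) && length(d) == 4L) dim(y) <- d
  y
}

bn_backward <- function(l, dy) {
  cc <- l$cache
  d <- cc$dim
  dym <- dy
  if (!is.null(d) && length(d) == 4L) dim(dym) <- c(prod(d[1:3]), d[4L])
  l$grads$gamma <- colSums(dym * cc$xhat)
  l$grads$beta <- colSums(dym)
  dxhat <- sweep(dym, 2L, l$params$gamma, "*")
  if (cc$training) {
    m <- nrow(dxhat)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(cc$xhat, 2L, colMeans(dxhat * cc$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cc$inv_std, "*")
  } else {
    dx <- sweep(dxhat, 2L, cc$inv_std, "*")
  }
  if (!is.null(d) && length(d) == 4L) dim(dx) <- d
  dx
}

maxpool2_forward <- function(l, x) {
  d <- dim(x)
  ow <- as.integer(ceiling(d[2L] / 2)); oh <- as.integer(ceiling(d[3L] / 2))
  xp <- array(-Inf, c(d[1L], 2L * ow, 2L * oh, d[4L]))
  xp[, seq_len(d[2L]), seq_len(d[3L]), ] <- x
  iw <- 2L * seq_len(ow); ih <- 2L * seq_len(oh)
  s11 <- xp[, iw - 1L, ih - 1L, , drop = FALSE]
  s21 <- xp[, iw,      ih - 1L, , drop = FALSE]
  s12 <- xp[, iw - 1L, ih,      , drop = FALSE]
  s22 <- xp[, iw,      ih,      , drop = FALSE]
  z <- pmax(s11, s21, s12, s22)
  l$cache <- list(slices = list(s11, s21, s12, s22), z = z, dim_x = d,
                  ow = ow, oh = oh)
  z
}

maxpool2_backward <- function(l, dy) {
  cc <- l$cache
  d <- cc$dim_x
  dxp <- array(0, c(d[1L], 2L * cc$ow, 2L * cc$oh, d[4L]))
  claimed <- array(FALSE, dim(cc$z))
  iw <- 2L * seq_len(cc$ow); ih <- 2L * seq_len(cc$oh)
  offs <- list(c(-1L, -1L), c(0L, -1L), c(-1L, 0L), c(0L, 0L))
  for (s in 1:4) {
    mask <- (cc$slices[[s]] == cc$z) & !claimed
    claimed <- claimed | mask
    dxp[, iw + offs[[s]][1L], ih + offs[[s]][2L], ] <-
      dxp[, iw + offs[[s]][1L], ih + offs[[s]][2L], , drop = FALSE] + dy * mask
  }
  dxp[, seq_len(d[2L]), seq_len(d[3L]), , drop = FALSE]
}

cff_forward <- function(l, x, training) {
  pool_l <- new_layer("maxpool2", "pool_branch")
  zp <- maxpool2_forward(pool_l, x)
  zc <- conv2d_forward(l$conv, x)
  if (isTRUE(l$branch_bn)) zc <- bn_forward(l$bn, zc, training)
  l$relu_mask <- zc > 0
  zc <- zc * l$relu_mask
  if (!all(dim(zp)[2:3] == dim(zc)[2:3]))
    stop("cff branch shape mismatch: pool ", paste(dim(zp)[2:3], collapse = "x"),
         ", conv ", paste(dim(zc)[2:3], collapse = "x"))
  l$pool_layer <- pool_l
  l$c_pool <- dim(zp)[4L]
  out <- array(NA_real_, c(dim(zp)[1:3], dim(zp)[4L] + dim(zc)[4L]))
  out[, , , seq_len(dim(zp)[4L])] <- zp
  out[, , , dim(zp)[4L] + seq_len(dim(zc)[4L])] <- zc
  out
}

cff_backward <- function(l, dy) {
  cp <- l$c_pool
  dzp <- dy[, , , seq_len(cp), drop = FALSE]
  dzc <- dy[, , , cp + seq_len(dim(dy)[4L] - cp), drop = FALSE]
  dzc <- dzc * l$relu_mask
  if (isTRUE(l$branch_bn)) dzc <- bn_backward(l$bn, dzc)
  maxpool2_backward(l$pool_layer, dzp) + conv2d_backward(l$conv, dzc)
}

lstm_forward <- function(l, x) {
  ## x: (B, T, D); returns final hidden state (B, U)
  d <- dim(x); B <- d[1L]; Tn <- d[2L]; U <- l$units
  h <- matrix(0, B, U); cs <- matrix(0, B, U)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- x[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B, l$d_in)
    z <- xt %*% l$params$Wx + h %*% l$params$Wh +
      matrix(l$params$b, B, 4L * U, byrow = TRUE)
    i <- sigmoid(z[, seq_len(U), drop = FALSE])
    f <- sigmoid(z[, U + seq_len(U), drop = FALSE])
    g <- tanh(z[, 2L * U + seq_len(U), drop = FALSE])
    o <- sigmoid(z[, 3L * U + seq_len(U), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, cs = cs, tc = tc, h_prev = h_prev)
  }
  l$cache <- list(steps = steps, B = B, Tn = Tn)
  h
}

lstm_backward <- function(l, dh_out) {
  cc <- l$cache; U <- l$units
  dWx <- array(0, dim(l$params$Wx)); dWh <- array(0, dim(l$params$Wh))
  db <- rep(0, 4L * U)
  dx <- array(0, c(cc$B, cc$Tn, l$d_in))
  dh <- dh_out; dc <- matrix(0, cc$B, U)
  for (t in rev(seq_len(cc$Tn))) {
    st <- cc$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dzi <- di * st$i * (1 - st$i)
    dzf <- df * st$f * (1 - st$f)
    dzg <- dg * (1 - st$g^2)
    dzo <- do * st$o * (1 - st$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(l$params$Wx)
    dh <- dz %*% t(l$params$Wh)
    dc <- dc * st$f
  }
  l$grads$Wx <- dWx; l$grads$Wh <- dWh; l$grads$b <- db
  dx
}

## ---- dispatch ---------------------------------------------------------

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv2d = conv2d_forward(l, x),
    batchnorm = bn_forward(l, x, training),
    relu = { l$cache <- x > 0; x * l$cache },
    maxpool2 = maxpool2_forward(l, x),
    cff = cff_forward(l, x, training),
    flatten = { l$cache <- dim(x); y <- x; dim(y) <- c(dim(x)[1L], prod(dim(x)[-1L])); y },
    dense = { l$cache <- x; sweep(x %*% l$params$W, 2L, l$params$b, "+") },
    dropout = {
      if (training && l$rate > 0) {
        l$cache <- (array(stats::runif(length(x)), dim(x)) >= l$rate) / (1 - l$rate)
        x * l$cache
      } else { l$cache <- NULL; x }
    },
    lstm = lstm_forward(l, x),
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv2d = conv2d_backward(l, dy),
    batchnorm = bn_backward(l, dy),
    relu = dy * l$cache,
    maxpool2 = maxpool2_backward(l, dy),
    cff = cff_backward(l, dy),
    flatten = { dx <- dy; dim(dx) <- l$cache; dx },
    dense = {
      l$grads$W <- crossprod(l$cache, dy)
      l$grads$b <- colSums(dy)
      tcrossprod(dy, l$params$W)
    },
    dropout = if (is.null(l$cache)) dy else dy * l$cache,
    lstm = lstm_backward(l, dy),
    stop("unknown layer type: ", l$type))
}

## all parameter-carrying layer environments, including cff sub-layers
param_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "cff") {
      out <- c(out, list(l$conv))
      if (!is.null(l$bn)) out <- c(out, list(l$bn))
    } else if (length(l$params) > 0L) out <- c(out, list(l))
  }
  out
}

layer_param_count <- function(l) {
  if (l$type == "cff") {
    n <- sum(vapply(l$conv$params, length, integer(1)))
    if (!is.null(l$bn)) n <- n + sum(vapply(l$bn$params, length, integer(1)))
    return(as.integer(n))
  }
  sum(vapply(l$params, length, integer(1)))
}

## one SGDM update: v <- mom * v - lr * (grad + wd * p); p <- p + v
sgdm_step <- function(layers, lr, momentum, weight_decay) {
  for (l in param_layers(layers)) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      g <- g + weight_decay * l$params[[nm]]
      v <- if (is.null(l$vel[[nm]])) -lr * g else momentum * l$vel[[nm]] - lr * g
      l$vel[[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] + v
    }
  }
  invisible(NULL)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## cross-entropy of the form -[y log p + (1-y) log(1-p)], averaged over
## batch and classes, evaluated on softmax probabilities; returns the loss
## and the gradient w.r.t. the pre-softmax logits
softmax_xent <- function(logits, y_onehot) {
  p <- softmax_rows(logits)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- -mean(y_onehot * log(pc) + (1 - y_onehot) * log(1 - pc))
  gp <- (-y_onehot / pc + (1 - y_onehot) / (1 - pc)) / length(y_onehot)
  ## backprop through softmax: dz = p * (gp - rowSums(gp * p))
  dz <- p * (gp - rowSums(gp * p))
  list(loss = loss, probs = p, dlogits = dz)
}
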
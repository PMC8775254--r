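#' Featurewise max-pooling
#'
#' Applies the parameter-free max operator over sliding windows of the spatial
#' axis. Pooling is *featurewise*: each channel is reduced independently, so the
#' output records the dominant amplitude in every window but discards the
#' position (and hence the temporal order) of the values inside it. With pool
#' size \eqn{s_p} and stride \eqn{s_s} the output element is
#' \deqn{z_t = \max\{y_t, \dots, y_{t+s_p-1}\}.}
#'
#' @param x A numeric vector (single sequence), an `L x C` matrix (length-`L`
#'   feature map with `C` channels), or a `W x H x C` array (2-D map).
#' @param size Pooling window size \eqn{s_p} (applied per spatial axis).
#' @param stride Pooling stride \eqn{s_s}; defaults to `size`.
#' @param ceil If `TRUE`, keep a final truncated window at the spatial edge so
#'   the output extent is `ceiling(L / stride)`; if `FALSE` (default), only
#'   full windows are taken and the extent is `floor((L - size) / stride) + 1`.
#' @return An object of the same kind as `x` with the spatial extent reduced;
#'   channels are preserved.
#' @examples
#' max_pool(c(1, 3, 2, 0), size = 2) # (3, 2)
#' max_pool(c(3, 1, 0, 2), size = 2) # also (3, 2): order inside a window is lost
#' @export
max_pool <- function(x, size = 2L, stride = size, ceil = FALSE) {
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1L || stride < 1L) stop("pool size and stride must be >= 1")
  if (is.vector(x) && is.numeric(x)) {
    drop(pool_axis(matrix(x, ncol = 1L), size, stride, ceil))
  } else if (is.matrix(x)) {
    pool_axis(x, size, stride, ceil)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    ## pool axis 1, then axis 2, channelwise
    w_out <- pooled_len(d[1L], size, stride, ceil)
    h_out <- pooled_len(d[2L], size, stride, ceil)
    out <- array(NA_real_, c(w_out, h_out, d[3L]))
    for (c in seq_len(d[3L])) {
      tmp <- pool_axis(x[, , c, drop = TRUE], size, stride, ceil)      # w_out x H
      out[, , c] <- t(pool_axis(t(tmp), size, stride, ceil))           # w_out x h_out
    }
    out
  } else {
    stop("x must be a numeric vector, matrix, or 3-D array")
  }
}

pooled_len <- function(L, size, stride, ceil) {
  if (ceil) as.integer(ceiling(L / stride))
  else {
    if (L < size) stop("input extent ", L, " shorter than pool window ", size)
    as.integer(floor((L - size) / stride) + 1L)
  }
}

## pool along rows of an L x C matrix
pool_axis <- function(x, size, stride, ceil) {
  L <- nrow(x)
  n_out <- pooled_len(L, size, stride, ceil)
  starts <- (seq_len(n_out) - 1L) * stride + 1L
  out <- matrix(NA_real_, n_out, ncol(x))
  for (i in seq_len(n_out)) {
    idx <- starts[i]:min(starts[i] + size - 1L, L)
    out[i, ] <- apply(x[idx, , drop = FALSE], 2L, max)
  }
  out
}

#' Strided convolution of a single sequence
#'
#' The single-step feature-mixing operation
#' \deqn{y_t = \sum_{j=1}^{k} c_j \, x_{s(t-1)+j},}
#' evaluated pre-activation and (by default) without bias. Unlike pooling, the
#' weighted sum mixes neighbouring samples, so it carries contextual
#' information — but distinct inputs can produce identical outputs (see
#' [find_collision()]).
#'
#' @param x Numeric input sequence.
#' @param kernel Numeric kernel \eqn{c} of length `k`.
#' @param stride Integer stride `s >= 1`.
#' @param padding `"valid"` (no padding; output length
#'   `floor((L - k)/s) + 1`) or `"same"` (zero-padded so the output length is
#'   `ceiling(L / s)`).
#' @param bias Scalar added to every output element (default 0).
#' @return Numeric vector of convolved outputs.
#' @examples
#' strided_conv(c(1, 1, 1), kernel = c(-1, 1, 2)) # 2
#' strided_conv(c(3, 1, 2), kernel = c(-1, 1, 2)) # also 2: a collision
#' @export
strided_conv <- function(x, kernel, stride = 1L, padding = c("valid", "same"),
                         bias = 0) {
  padding <- match.arg(padding)
  stride <- as.integer(stride)
  k <- length(kernel)
  if (k < 1L || stride < 1L) stop("kernel size and stride must be >= 1")
  L <- length(x)
  if (padding == "same") {
    n_out <- as.integer(ceiling(L / stride))
    pad_total <- max((n_out - 1L) * stride + k - L, 0L)
    pad_l <- pad_total %/% 2L
    x <- c(rep(0, pad_l), x, rep(0, pad_total - pad_l))
  } else {
    if (L < k) stop("input length ", L, " shorter than kernel ", k)
    n_out <- as.integer(floor((L - k) / stride) + 1L)
  }
  vapply(seq_len(n_out), function(t) {
    sum(kernel * x[(stride * (t - 1L) + 1L):(stride * (t - 1L) + k)]) + bias
  }, numeric(1))
}

#' Construct a colliding input for a convolution step
#'
#' For a kernel \eqn{c} and input segment \eqn{x} of length `k`, finds a
#' different segment \eqn{x'} with exactly the same weighted sum
#' \eqn{\sum_j c_j x'_j = \sum_j c_j x_j}. The construction transfers mass
#' between coordinates: if some kernel weight is zero the corresponding input
#' coordinate is free; otherwise an increment on one nonzero-weight coordinate
#' is balanced by a compensating decrement on another. The existence of such
#' collisions is what makes a lone strided convolution an ambiguous
#' dimensionality reducer.
#'
#' @param kernel Numeric kernel of length `k >= 1`.
#' @param x Numeric input segment, same length as `kernel`.
#' @param delta Size of the transferred increment (default 2, which reproduces
#'   the canonical \eqn{(-1, 1, 2)} example: `x = (1,1,1)` collides with
#'   `(3,1,2)`).
#' @return A list with `x_prime` (the colliding input), `y` (the shared
#'   output value), and `possible`. When `k == 1` with a nonzero kernel the
#'   map is injective, no nontrivial collision exists, and `possible` is
#'   `FALSE` with `x_prime = NULL`.
#' @export
find_collision <- function(kernel, x, delta = 2) {
  if (length(kernel) != length(x)) stop("kernel and x must have equal length")
  nz <- which(kernel != 0)
  if (length(nz) == 0L)
    stop("degenerate all-zero kernel: every input collides trivially")
  y <- sum(kernel * x)
  if (length(kernel) == 1L)
    return(list(x_prime = NULL, y = y, possible = FALSE))
  x_prime <- x
  z <- which(kernel == 0)
  if (length(z) > 0L) {
    x_prime[z[1L]] <- x[z[1L]] + delta
  } else {
    i <- nz[1L]; j <- nz[length(nz)]
    x_prime[i] <- x[i] + delta
    x_prime[j] <- x[j] - delta * kernel[i] / kernel[j]
  }
  stopifnot(any(x_prime != x))
  list(x_prime = x_prime, y = y, possible = TRUE)
}

#' Receptive field of stacked 1-stride convolutions
#'
#' `n` stacked valid convolutions with kernel size `k` and stride 1 make one
#' output element depend on exactly `n * (k - 1) + 1` input elements.
#'
#' @param n Number of stacked layers (`>= 1`).
#' @param k Kernel size (`>= 1`).
#' @return Integer receptive-field size.
#' @examples
#' receptive_field(2, 3) # 5
#' @export
receptive_field <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 1L) stop("n and k must be >= 1")
  n * (k - 1L) + 1L
}

## multichannel 1-D convolution: x is L x C_in, w is k x C_in x F
conv_map_1d <- function(x, w, stride = 1L, padding = c("same", "valid"),
                        bias = NULL) {
  padding <- match.arg(padding)
  k <- dim(w)[1L]; c_in <- dim(w)[2L]; f <- dim(w)[3L]
  if (ncol(x) != c_in) stop("input has ", ncol(x), " channels, weights expect ", c_in)
  L <- nrow(x)
  if (padding == "same") {
    n_out <- as.integer(ceiling(L / stride))
    pad_total <- max((n_out - 1L) * stride + k - L, 0L)
    pad_l <- pad_total %/% 2L
    x <- rbind(matrix(0, pad_l, c_in), x, matrix(0, pad_total - pad_l, c_in))
  } else {
    if (L < k) stop("input extent ", L, " shorter than kernel ", k)
    n_out <- as.integer(floor((L - k) / stride) + 1L)
  }
  if (is.null(bias)) bias <- rep(0, f)
  wmat <- matrix(w, nrow = k * c_in, ncol = f)   # (k*C_in) x F, kernel-major
  out <- matrix(NA_real_, n_out, f)
  for (t in seq_len(n_out)) {
    seg <- x[(stride * (t - 1L) + 1L):(stride * (t - 1L) + k), , drop = FALSE]
    out[t, ] <- as.vector(matrix(seg, nrow = 1L) %*% wmat) + bias
  }
  out
}

#' Concatenate-feature-fusion block
#'
#' The CFF dimensionality-reduction step: the input map is sent in parallel
#' through a size-2, stride-2 max-pooling branch (parameter-free, amplitude
#' preserving) and a stride-2 convolution branch (trainable, context mixing),
#' and the two outputs are concatenated along the channel axis with the
#' pooling channels first. Inputs that pooling alone cannot distinguish
#' (within-window reorderings) differ in the convolution channels, and inputs
#' that the convolution alone maps to the same value differ in the pooling
#' channels, so the fused map discriminates both.
#'
#' Both branches emit a spatial extent of `ceiling(L / 2)`: the convolution
#' uses same-padding and the pooling keeps a truncated edge window when `L`
#' is odd.
#'
#' @param x Input map: an `L x C_in` matrix (1-D spatial) or a
#'   `W x H x C_in` array (2-D spatial).
#' @param weights Convolution-branch weights: `k x C_in x F` for 1-D input or
#'   `k x k x C_in x F` for 2-D input.
#' @param bias Optional numeric vector of length `F` for the convolution
#'   branch; `NULL` (default) disables bias.
#' @return Fused map with `C_in + F` channels and halved (rounded up) spatial
#'   extent; the first `C_in` channels are the pooling branch.
#' @examples
#' x <- matrix(rnorm(10 * 64), 10, 64)
#' w <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
#' dim(cff_block(x, w)) # 5 128
#' @export
cff_block <- function(x, weights, bias = NULL) {
  if (is.matrix(x)) {
    if (length(dim(weights)) != 3L)
      stop("1-D input requires k x C_in x F weights")
    pooled <- max_pool(x, size = 2L, stride = 2L, ceil = TRUE)
    conved <- conv_map_1d(x, weights, stride = 2L, padding = "same", bias = bias)
    if (nrow(pooled) != nrow(conved))
      stop("branch shape mismatch: pool ", nrow(pooled), ", conv ", nrow(conved))
    cbind(pooled, conved)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (length(dim(weights)) != 4L)
      stop("2-D input requires k x k x C_in x F weights")
    pooled <- max_pool(x, size = 2L, stride = 2L, ceil = TRUE)
    conved <- conv_map_2d(x, weights, stride = 2L, bias = bias)
    if (!all(dim(pooled)[1:2] == dim(conved)[1:2]))
      stop("branch shape mismatch: pool ", paste(dim(pooled)[1:2], collapse = "x"),
           ", conv ", paste(dim(conved)[1:2], collapse = "x"))
    out <- array(NA_real_, c(dim(pooled)[1:2], dim(pooled)[3L] + dim(conved)[3L]))
    out[, , seq_len(dim(pooled)[3L])] <- pooled
    out[, , dim(pooled)[3L] + seq_len(dim(conved)[3L])] <- conved
    out
  } else {
    stop("x must be an L x C matrix or a W x H x C array")
  }
}

## 2-D same-padded strided convolution on a single W x H x C_in map
conv_map_2d <- function(x, w, stride = 2L, bias = NULL) {
  d <- dim(x); k <- dim(w)[1L]; c_in <- dim(w)[3L]; f <- dim(w)[4L]
  if (d[3L] != c_in) stop("input has ", d[3L], " channels, weights expect ", c_in)
  w_out <- as.integer(ceiling(d[1L] / stride))
  h_out <- as.integer(ceiling(d[2L] / stride))
  pad_w <- max((w_out - 1L) * stride + k - d[1L], 0L)
  pad_h <- max((h_out - 1L) * stride + k - d[2L], 0L)
  xp <- array(0, c(d[1L] + pad_w, d[2L] + pad_h, c_in))
  xp[pad_w %/% 2L + seq_len(d[1L]), pad_h %/% 2L + seq_len(d[2L]), ] <- x
  if (is.null(bias)) bias <- rep(0, f)
  wmat <- matrix(w, nrow = k * k * c_in, ncol = f)
  out <- array(NA_real_, c(w_out, h_out, f))
  for (i in seq_len(w_out)) for (j in seq_len(h_out)) {
    seg <- xp[(stride * (i - 1L) + 1L):(stride * (i - 1L) + k),
              (stride * (j - 1L) + 1L):(stride * (j - 1L) + k), , drop = FALSE]
    out[i, j, ] <- as.vector(matrix(as.vector(seg), nrow = 1L) %*% wmat) + bias
  }
  out
}

#' Trainable-parameter count of a CFF block
#'
#' Only the convolution branch carries parameters; pooling and concatenation
#' contribute none.
#'
#' @param k Kernel size (per spatial axis).
#' @param c_in Input channels.
#' @param filters Convolution-branch filter count.
#' @param ndim Spatial dimensionality of the block (1 or 2).
#' @param bias Whether the convolution branch has a bias term.
#' @return Integer parameter count.
#' @export
cff_block_params <- function(k, c_in, filters, ndim = 1L, bias = TRUE) {
  as.integer(k^ndim * c_in * filters + if (bias) filters else 0L)
}
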
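#' Labeled multichannel sEMG recording
#'
#' Container for a sample-by-channel signal with per-sample gesture labels and
#' repetition numbers, the layout used by the NinaPro benchmark databases
#' (`emg` / `stimulus` / `repetition`). Label 0 is rest; labels `1..G` are
#' gesture classes.
#'
#' @param signal Numeric `T x C` matrix of amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz (`> 0`).
#' @param labels Integer vector of length `T`, values in `0..G`.
#' @param repetition Integer vector of length `T`; repetition number of the
#'   movement each sample belongs to (0 during rest).
#' @param subject Subject identifier (scalar).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, labels,
                          repetition = rep(0L, nrow(signal)), subject = 1L) {
  signal <- as.matrix(signal)
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (fs <= 0) stop("fs must be > 0")
  if (length(labels) != nrow(signal))
    stop("labels length ", length(labels), " != ", nrow(signal), " samples")
  if (length(repetition) != nrow(signal))
    stop("repetition length ", length(repetition), " != ", nrow(signal), " samples")
  if (any(labels < 0)) stop("labels must be >= 0 (0 = rest)")
  structure(list(signal = signal, fs = fs, labels = as.integer(labels),
                 repetition = as.integer(repetition), subject = subject),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d samples x %d channels @ %g Hz, %d gesture classes\n",
              format(x$subject), nrow(x$signal), ncol(x$signal), x$fs,
              length(setdiff(unique(x$labels), 0L))))
  invisible(x)
}

#' Sliding-window segmentation configuration
#'
#' @param window_ms Window duration in milliseconds (default 250).
#' @param overlap_ms Overlap between consecutive windows in milliseconds
#'   (default 200, i.e. a 50 ms hop at the defaults).
#' @param W,H Frame width and height for [reshape_frame()]; `NULL` keeps the
#'   raw `N x C` window. `W * H` must divide `N * C`.
#' @param purity Minimum fraction of samples that must carry the majority
#'   label for a window to be kept (default 0.5).
#' @param drop_rest Drop windows whose majority label is rest (default
#'   `FALSE`; rest is a class of its own).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_ms = 250, overlap_ms = 200,
                          W = NULL, H = NULL, purity = 0.5, drop_rest = FALSE) {
  if (overlap_ms < 0 || overlap_ms >= window_ms)
    stop("need 0 <= overlap_ms < window_ms")
  structure(list(window_ms = window_ms, overlap_ms = overlap_ms,
                 W = W, H = H, purity = purity, drop_rest = drop_rest),
            class = "window_config")
}

#' Window length and hop in samples
#'
#' `N = round(window_ms * fs / 1000)` and
#' `hop = N - round(overlap_ms * fs / 1000)`; all arithmetic is done in whole
#' samples so successive windows never drift. At 2 kHz the default 250/200 ms
#' settings give `N = 500`, `hop = 100`; at 100 Hz they give `N = 25`,
#' `hop = 5`.
#'
#' @param cfg A [window_config()].
#' @param fs Sampling rate in Hz.
#' @return List with integer elements `N` and `hop`.
#' @export
window_samples <- function(cfg, fs) {
  N <- as.integer(round(cfg$window_ms * fs / 1000))
  hop <- N - as.integer(round(cfg$overlap_ms * fs / 1000))
  if (N < 1L) stop("window shorter than one sample at fs = ", fs)
  if (hop < 1L) stop("non-positive hop: overlap too close to window length")
  list(N = N, hop = hop)
}

#' Segment a recording into overlapping labeled windows
#'
#' Slides an `N`-sample window with a fixed hop across the recording. Windows
#' start at samples `1, 1 + hop, 1 + 2 hop, ...`; over a span of `T` samples
#' there are `floor((T - N) / hop) + 1` of them. Each window is assigned its
#' majority per-sample label; windows whose majority fraction falls below
#' `cfg$purity` are dropped, as are rest-majority windows when
#' `cfg$drop_rest` is set.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [window_config()].
#' @return A list of class `window_set` with elements `windows` (list of
#'   `N x C` matrices), `labels`, `starts` (1-based start sample),
#'   `repetition` (majority repetition id), `purity` (majority-label
#'   fraction), plus `N`, `hop`, `fs`, `subject`.
#' @export
sliding_windows <- function(rec, cfg) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "window_config"))
  ws <- window_samples(cfg, rec$fs)
  T_n <- nrow(rec$signal)
  if (T_n < ws$N)
    stop("recording too short: ", T_n, " samples < one ", ws$N, "-sample window")
  n_win <- as.integer(floor((T_n - ws$N) / ws$hop) + 1L)
  starts <- (seq_len(n_win) - 1L) * ws$hop + 1L
  windows <- vector("list", n_win)
  labels <- integer(n_win); reps <- integer(n_win); purity <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- starts[i]:(starts[i] + ws$N - 1L)
    windows[[i]] <- rec$signal[idx, , drop = FALSE]
    lab <- rec$labels[idx]
    tab <- sort(table(lab), decreasing = TRUE)
    labels[i] <- as.integer(names(tab)[1L])
    purity[i] <- tab[[1L]] / ws$N
    rtab <- sort(table(rec$repetition[idx]), decreasing = TRUE)
    reps[i] <- as.integer(names(rtab)[1L])
  }
  keep <- purity >= cfg$purity
  if (cfg$drop_rest) keep <- keep & labels != 0L
  structure(list(windows = windows[keep], labels = labels[keep],
                 starts = starts[keep], repetition = reps[keep],
                 purity = purity[keep], N = ws$N, hop = ws$hop,
                 fs = rec$fs, subject = rec$subject),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples (hop %d) from subject %s\n",
              length(x$windows), x$N, x$hop, format(x$subject)))
  invisible(x)
}

#' Reshape an N x C window into a W x H x C_out frame
#'
#' The flattening is a fixed, documented bijection so that [unshape_frame()]
#' recovers the window exactly. The window is read time-major (all `N`
#' samples of channel 1, then channel 2, ...) into a buffer of length
#' `N * C`, and the buffer is written into the frame with the height axis
#' fastest, then width, then output channel:
#' `frame[w, h, c] = buffer[((c-1) * W + (w-1)) * H + h]`.
#'
#' When `C_out = C` (the 2 kHz 12-channel layout, e.g. `500 x 12` into
#' `5 x 100 x 12`) each output channel is an input channel reshaped row-major
#' over `(W, H)`. When `C_out != C` (the 100 Hz layout, `25 x 10` into
#' `5 x 25 x 2`) input channels are folded into the spatial axes by the same
#' buffer rule.
#'
#' @param window Numeric `N x C` matrix.
#' @param W,H Frame width and height.
#' @param C_out Output channel count; defaults to `N * C / (W * H)`, which
#'   must be a whole number.
#' @return Numeric `W x H x C_out` array.
#' @examples
#' f <- reshape_frame(matrix(rnorm(500 * 12), 500, 12), W = 5, H = 100)
#' dim(f) # 5 100 12
#' @export
reshape_frame <- function(window, W, H, C_out = NULL) {
  N <- nrow(window); C <- ncol(window)
  if (is.null(C_out)) {
    if ((N * C) %% (W * H) != 0L)
      stop("shape mismatch: W*H = ", W * H, " does not divide N*C = ", N * C)
    C_out <- (N * C) %/% (W * H)
  }
  if (W * H * C_out != N * C)
    stop("shape mismatch: W*H*C_out = ", W * H * C_out, " but N*C = ", N * C)
  buf <- as.vector(window)                       # time-major: column-major N x C
  frame <- array(NA_real_, c(W, H, C_out))
  ## height fastest, then width, then channel
  frame[] <- as.vector(aperm(array(buf, c(H, W, C_out)), c(2L, 1L, 3L)))
  frame
}

#' Invert [reshape_frame()]
#'
#' @param frame A `W x H x C_out` array produced by [reshape_frame()].
#' @param N,C Dimensions of the original window.
#' @return The original `N x C` window, bit-exact.
#' @export
unshape_frame <- function(frame, N, C) {
  d <- dim(frame)
  if (prod(d) != N * C)
    stop("shape mismatch: frame has ", prod(d), " elements but N*C = ", N * C)
  buf <- as.vector(aperm(frame, c(2L, 1L, 3L)))
  matrix(buf, nrow = N, ncol = C)
}

#' Stack a window set into a frame array
#'
#' @param ws A `window_set`.
#' @param W,H,C_out Frame geometry passed to [reshape_frame()].
#' @return List with `frames` (`n x W x H x C_out` array), `labels`,
#'   `starts`, `repetition`, `subject`.
#' @export
frame_stack <- function(ws, W, H, C_out = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (length(ws$windows) == 0L) stop("empty window set")
  f1 <- reshape_frame(ws$windows[[1L]], W, H, C_out)
  frames <- array(NA_real_, c(length(ws$windows), dim(f1)))
  frames[1L, , , ] <- f1
  for (i in seq_along(ws$windows)[-1L])
    frames[i, , , ] <- reshape_frame(ws$windows[[i]], W, H, C_out)
  list(frames = frames, labels = ws$labels, starts = ws$starts,
       repetition = ws$repetition, subject = rep(ws$subject, length(ws$labels)))
}

#' Fit per-channel standardization statistics on training frames
#'
#' Computes the per-channel mean and standard deviation over all training
#' frames (channel = last array axis). Statistics are estimated on training
#' data only and then applied unchanged to validation and test sets, so no
#' test information leaks into the normalization. An optional min--max step
#' rescales the standardized values to `[0, 1]` using training-set extremes.
#'
#' @param frames Numeric `n x W x H x C` array of training frames.
#' @param minmax Add a second min--max rescaling step fitted on the
#'   standardized training data (default `FALSE`).
#' @return An object of class `frame_scaler` with fields `mean`, `sd` (and
#'   `min`, `max` when `minmax`), serializable with [scaler_to_json()].
#' @export
fit_scaler <- function(frames, minmax = FALSE) {
  d <- dim(frames)
  C <- d[length(d)]
  mu <- numeric(C); sdv <- numeric(C)
  for (c in seq_len(C)) {
    v <- channel_slice(frames, c)
    mu[c] <- mean(v); sdv[c] <- stats::sd(v)
  }
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warning("zero-variance channel(s) ", paste(which(zero), collapse = ", "),
            ": substituting unit scale")
    sdv[zero] <- 1
  }
  sc <- list(mean = mu, sd = sdv, minmax = minmax)
  if (minmax) {
    z <- apply_scaler_z(frames, mu, sdv)
    lo <- numeric(C); hi <- numeric(C)
    for (c in seq_len(C)) {
      v <- channel_slice(z, c); lo[c] <- min(v); hi[c] <- max(v)
    }
    rng <- hi - lo
    rng[rng == 0] <- 1
    sc$min <- lo; sc$range <- rng
  }
  structure(sc, class = "frame_scaler")
}

channel_slice <- function(frames, c) {
  nd <- length(dim(frames))
  if (nd == 4L) frames[, , , c] else frames[, , c]
}

apply_scaler_z <- function(frames, mu, sdv) {
  out <- frames
  C <- dim(frames)[length(dim(frames))]
  for (c in seq_len(C)) {
    if (length(dim(frames)) == 4L) out[, , , c] <- (frames[, , , c] - mu[c]) / sdv[c]
    else out[, , c] <- (frames[, , c] - mu[c]) / sdv[c]
  }
  out
}

#' Apply (or invert) fitted standardization statistics
#'
#' @param scaler A `frame_scaler` from [fit_scaler()].
#' @param frames Frame array to transform.
#' @param inverse Undo the transform instead (default `FALSE`).
#' @return Transformed frame array of the same shape.
#' @export
apply_scaler <- function(scaler, frames, inverse = FALSE) {
  stopifnot(inherits(scaler, "frame_scaler"))
  C <- dim(frames)[length(dim(frames))]
  nd <- length(dim(frames))
  out <- frames
  for (c in seq_len(C)) {
    tr <- if (!inverse) {
      function(v) {
        z <- (v - scaler$mean[c]) / scaler$sd[c]
        if (scaler$minmax) (z - scaler$min[c]) / scaler$range[c] else z
      }
    } else {
      function(v) {
        z <- if (scaler$minmax) v * scaler$range[c] + scaler$min[c] else v
        z * scaler$sd[c] + scaler$mean[c]
      }
    }
    if (nd == 4L) out[, , , c] <- tr(frames[, , , c])
    else out[, , c] <- tr(frames[, , c])
  }
  out
}

#' Serialize / restore scaler statistics as JSON
#'
#' @param scaler A `frame_scaler`.
#' @return `scaler_to_json()` returns a JSON string; `scaler_from_json()`
#'   rebuilds the `frame_scaler`.
#' @export
scaler_to_json <- function(scaler) {
  jsonlite::toJSON(unclass(scaler), digits = NA, auto_unbox = TRUE)
}

#' @rdname scaler_to_json
#' @param json JSON string produced by `scaler_to_json()`.
#' @export
scaler_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(x, class = "frame_scaler")
}

#' One-hot encode integer class labels
#'
#' @param labels Integer vector with values in `0 .. G-1`.
#' @param G Number of classes.
#' @return Binary `length(labels) x G` matrix; each row sums to 1 and
#'   `max.col` inverts the encoding.
#' @export
one_hot <- function(labels, G) {
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= G))
    stop("labels must lie in [0, G); got range ",
         min(labels), "..", max(labels), " with G = ", G)
  out <- matrix(0L, length(labels), G)
  out[cbind(seq_along(labels), labels + 1L)] <- 1L
  out
}

#' Decode a one-hot (or probability) matrix back to integer labels
#'
#' @param mat Numeric `n x G` matrix.
#' @return Integer vector in `0 .. G-1` (argmax per row).
#' @export
one_hot_decode <- function(mat) {
  max.col(mat, ties.method = "first") - 1L
}

#' Save / load a frame container
#'
#' Writes the frame array and its metadata to a single `.rds` file plus a
#' JSON sidecar (`<path>.json`) that records the window configuration and any
#' normalization statistics, so a stored set is self-describing.
#'
#' @param fstack A list as returned by [frame_stack()].
#' @param path Output `.rds` path.
#' @param cfg Optional [window_config()] stored in the sidecar.
#' @param scaler Optional `frame_scaler` stored in the sidecar.
#' @return `save_frames()` returns `path` invisibly; `load_frames()` returns
#'   the frame container with attributes `config` and `scaler` when present.
#' @export
save_frames <- function(fstack, path, cfg = NULL, scaler = NULL) {
  saveRDS(fstack, path)
  side <- list(
    n_frames = dim(fstack$frames)[1L],
    frame_shape = dim(fstack$frames)[-1L],
    config = if (!is.null(cfg)) unclass(cfg),
    scaler = if (!is.null(scaler)) unclass(scaler)
  )
  writeLines(jsonlite::toJSON(side, digits = NA, auto_unbox = TRUE, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_frames
#' @export
load_frames <- function(path) {
  fstack <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(paste(readLines(sidecar), collapse = ""))
    if (!is.null(side$config)) attr(fstack, "config") <- side$config
    if (!is.null(side$scaler))
      attr(fstack, "scaler") <- structure(side$scaler, class = "frame_scaler")
  }
  fstack
}
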
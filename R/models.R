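#' Specification of an RCNN or CFF-RCNN classifier
#'
#' Describes the layer stack of the two compared architectures. Both share a
#' time-distributed convolutional feature extractor (two 3-kernel, 1-stride,
#' batch-normalized, ReLU-activated convolutions with a dimensionality
#' reduction after each) followed by three fully connected layers, an LSTM
#' sequence recognizer with dropout, and a softmax classifier. The only
#' difference is the first reduction: the RCNN uses a plain size-2
#' max-pooling, while the CFF-RCNN applies max-pooling and a 2-stride
#' convolution in parallel and concatenates the channels, doubling the
#' channel count entering the second convolution (64 to 128 at the default
#' width).
#'
#' @param variant `"rcnn"` or `"cff_rcnn"`.
#' @param input_shape Integer vector `c(W, H, C)` of the input frame.
#' @param num_classes Number of output classes `G`.
#' @param conv_filters Filters per convolution (default 64).
#' @param kernel Convolution kernel size (default 3).
#' @param fc_sizes Widths of the three fully connected layers
#'   (default `c(512, 512, 128)`).
#' @param lstm_units LSTM state size (default 512).
#' @param lstm_dropout Dropout rate applied to the LSTM output (default 0.5).
#' @param seq_len Frames per LSTM input sequence `T` (default 1; consecutive
#'   frames of one repetition are grouped when larger).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(variant = c("cff_rcnn", "rcnn"), input_shape,
                       num_classes, conv_filters = 64L, kernel = 3L,
                       fc_sizes = c(512L, 512L, 128L), lstm_units = 512L,
                       lstm_dropout = 0.5, seq_len = 1L) {
  variant <- match.arg(variant)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("input_shape must be a positive c(W, H, C)")
  if (num_classes < 2L) stop("need num_classes >= 2")
  if (length(fc_sizes) != 3L) stop("fc_sizes must have length 3")
  structure(list(variant = variant, input_shape = as.integer(input_shape),
                 num_classes = as.integer(num_classes),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), fc_sizes = as.integer(fc_sizes),
                 lstm_units = as.integer(lstm_units),
                 lstm_dropout = lstm_dropout, seq_len = as.integer(seq_len)),
            class = "model_spec")
}

#' Build a trainable classifier from a spec
#'
#' Instantiates the layer stack with seeded fan-based weight initialization.
#' Spatial extents are reduced with ceiling arithmetic (a truncated edge
#' window is kept when an extent is odd), so two reductions on a `W x H`
#' frame give `ceiling(W/4) x ceiling(H/4)`.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `gesture_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  W <- spec$input_shape[1L]; H <- spec$input_shape[2L]; C <- spec$input_shape[3L]
  f <- spec$conv_filters; k <- spec$kernel
  cnn <- list(
    nn_conv2d(k, C, f),
    nn_batchnorm(f),
    nn_relu()
  )
  if (spec$variant == "cff_rcnn") {
    cnn <- c(cnn, list(nn_cff(k, f, f)))
    c2_in <- 2L * f
  } else {
    cnn <- c(cnn, list(nn_maxpool2()))
    c2_in <- f
  }
  w1 <- as.integer(ceiling(W / 2)); h1 <- as.integer(ceiling(H / 2))
  cnn <- c(cnn, list(
    nn_conv2d(k, c2_in, f),
    nn_batchnorm(f),
    nn_relu(),
    nn_maxpool2()
  ))
  w2 <- as.integer(ceiling(w1 / 2)); h2 <- as.integer(ceiling(h1 / 2))
  if (w2 < 1L || h2 < 1L)
    stop("spatial extent collapsed to zero before flatten (second max-pooling)")
  flat <- w2 * h2 * f
  cnn <- c(cnn, list(nn_flatten(),
                     nn_dense(flat, spec$fc_sizes[1L]), nn_relu(),
                     nn_dense(spec$fc_sizes[1L], spec$fc_sizes[2L]), nn_relu(),
                     nn_dense(spec$fc_sizes[2L], spec$fc_sizes[3L]), nn_relu()))
  rnn <- list(nn_lstm(spec$fc_sizes[3L], spec$lstm_units),
              nn_dropout(spec$lstm_dropout),
              nn_dense(spec$lstm_units, spec$num_classes, name = "fc_out"))
  structure(list(spec = spec, cnn = cnn, rnn = rnn), class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  pr <- count_parameters(x)
  cat(sprintf("<gesture_model> %s: input %s, %d classes, %s trainable parameters\n",
              x$spec$variant, paste(x$spec$input_shape, collapse = "x"),
              x$spec$num_classes, format(pr$total, big.mark = ",")))
  invisible(x)
}

## forward pass; x is (B, W, H, C) for seq_len 1 or (B, T, W, H, C)
model_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) == 4L) {
    B <- d[1L]; Tn <- 1L
  } else if (length(d) == 5L) {
    B <- d[1L]; Tn <- d[2L]
    dim(x) <- c(B * Tn, d[3L], d[4L], d[5L])
  } else stop("input must be a 4-D or 5-D array")
  exp_shape <- model$spec$input_shape
  if (!all(dim(x)[2:4] == exp_shape))
    stop("frame shape ", paste(dim(x)[2:4], collapse = "x"),
         " does not match model input ", paste(exp_shape, collapse = "x"))
  h <- x
  for (l in model$cnn) h <- layer_forward(l, h, training)
  dim(h) <- c(B, Tn, ncol(h))
  for (l in model$rnn) h <- layer_forward(l, h, training)
  h   # logits (B, num_classes)
}

model_backward <- function(model, dlogits) {
  g <- dlogits
  for (l in rev(model$rnn)) g <- layer_backward(l, g)
  d <- dim(g)                       # (B, T, D)
  dim(g) <- c(d[1L] * d[2L], d[3L])
  for (l in rev(model$cnn)) g <- layer_backward(l, g)
  invisible(g)
}

all_layers <- function(model) c(model$cnn, model$rnn)

#' Class probabilities and labels for a batch of frames
#'
#' Inference mode: dropout disabled and batch-normalization statistics
#' frozen, so repeated calls on the same input are identical.
#'
#' @param model A `gesture_model`.
#' @param x Frame array `(n, W, H, C)`, or `(n, T, W, H, C)` for sequences.
#' @return List with `probs` (`n x G`, rows summing to 1) and `labels`
#'   (integer argmax, `0 .. G-1`).
#' @export
predict_gestures <- function(model, x) {
  logits <- model_forward(model, x, training = FALSE)
  probs <- softmax_rows(logits)
  list(probs = probs, labels = one_hot_decode(probs))
}

#' Per-layer trainable-parameter report
#'
#' Pooling, flatten, concatenation, ReLU and dropout layers carry no
#' parameters; the pooling branch of the CFF block contributes zero, so the
#' whole block counts only its convolution branch.
#'
#' @param model A `gesture_model`.
#' @return List with `layers` (data frame of `name`, `params`) and `total`.
#' @export
count_parameters <- function(model) {
  ls <- all_layers(model)
  df <- data.frame(name = vapply(ls, function(l) l$name, character(1)),
                   params = vapply(ls, layer_param_count, integer(1)))
  list(layers = df, total = sum(df$params))
}

#' Ordered layer names of the instantiated stack
#'
#' @param model A `gesture_model`.
#' @param include_aux Include activation/dropout layers (default `TRUE`);
#'   when `FALSE` the list matches the coarse published stack description.
#' @return Character vector of layer names, input to output.
#' @export
model_layer_names <- function(model, include_aux = TRUE) {
  nm <- vapply(all_layers(model), function(l) l$name, character(1))
  nm <- c(nm, "softmax")
  if (!include_aux) nm <- nm[!grepl("^(relu|dropout)", nm)]
  nm
}

#' Save / load a trained model
#'
#' Stores the spec, all parameters and batch-normalization running statistics
#' in a single `.rds` file.
#'
#' @param model A `gesture_model`.
#' @param path Output path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   rebuilt model.
#' @export
save_model <- function(model, path) {
  state <- list(spec = unclass(model$spec),
                params = lapply(param_layers(all_layers(model)), function(l) l$params),
                bn = lapply(Filter(function(l) l$type == "batchnorm",
                                   all_layers(model)),
                            function(l) list(mean = l$running_mean,
                                             var = l$running_var)))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  spec <- do.call(model_spec, state$spec)
  model <- build_model(spec)
  pl <- param_layers(all_layers(model))
  stopifnot(length(pl) == length(state$params))
  for (i in seq_along(pl)) pl[[i]]$params <- state$params[[i]]
  bns <- Filter(function(l) l$type == "batchnorm", all_layers(model))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$mean
    bns[[i]]$running_var <- state$bn[[i]]$var
  }
  model
}

#' Round-trip a model spec through YAML
#'
#' @param spec A [model_spec()].
#' @param path File to write to / read from.
#' @return `spec_to_yaml()` returns `path` invisibly; `spec_from_yaml()` the
#'   restored `model_spec`.
#' @export
spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  do.call(model_spec, yaml::read_yaml(path))
}
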
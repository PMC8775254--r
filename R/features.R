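#' Classic time-domain sEMG features of one window
#'
#' Computes the four canonical Hudgins-style features per channel:
#' mean absolute value `MAV = mean(|x|)`, zero crossings `ZC` (sign changes
#' between consecutive samples whose jump exceeds `zc_threshold`), slope sign
#' changes `SSC` (interior samples that are a local extremum against both
#' neighbours, with the larger neighbour difference exceeding
#' `ssc_threshold`), and waveform length `WL = sum(|diff(x)|)`.
#'
#' @param window Numeric `N x C` matrix, `N >= 3`.
#' @param zc_threshold,ssc_threshold Amplitude thresholds suppressing
#'   noise-induced counts (default 0).
#' @return Named numeric vector of length `4 C`, ordered
#'   `mav_1..mav_C, zc_1..zc_C, ssc_1..ssc_C, wl_1..wl_C`.
#' @examples
#' extract_features(matrix(c(1, -1, 1, -1), 4, 1)) # MAV 1, ZC 3, SSC 2, WL 6
#' @export
extract_features <- function(window, zc_threshold = 0, ssc_threshold = 0) {
  window <- as.matrix(window)
  N <- nrow(window); C <- ncol(window)
  if (N < 3L) stop("need N >= 3 samples (SSC requires interior points); got ", N)
  mav <- colMeans(abs(window))
  wl <- numeric(C); zc <- numeric(C); ssc <- numeric(C)
  for (c in seq_len(C)) {
    x <- window[, c]
    dx <- diff(x)
    wl[c] <- sum(abs(dx))
    zc[c] <- sum(x[-N] * x[-1L] < 0 & abs(dx) >= zc_threshold)
    xm <- x[2:(N - 1L)]
    d1 <- xm - x[1:(N - 2L)]; d2 <- xm - x[3:N]
    ssc[c] <- sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= ssc_threshold)
  }
  stats::setNames(c(mav, zc, ssc, wl),
                  c(paste0("mav_", seq_len(C)), paste0("zc_", seq_len(C)),
                    paste0("ssc_", seq_len(C)), paste0("wl_", seq_len(C))))
}

#' Feature table of a window set
#'
#' @param ws A `window_set` from [sliding_windows()].
#' @param zc_threshold,ssc_threshold Passed to [extract_features()].
#' @return A data frame with one row per window: the `4 C` feature columns
#'   plus `label`, `start`, `repetition`.
#' @export
feature_table <- function(ws, zc_threshold = 0, ssc_threshold = 0) {
  stopifnot(inherits(ws, "window_set"))
  feats <- t(vapply(ws$windows,
                    extract_features,
                    numeric(4L * ncol(ws$windows[[1L]])),
                    zc_threshold = zc_threshold, ssc_threshold = ssc_threshold))
  out <- as.data.frame(feats)
  out$label <- ws$labels
  out$start <- ws$starts
  out$repetition <- ws$repetition
  out
}

#' Shallow baseline classifiers on feature vectors
#'
#' The three classic comparison pipelines: PCA or LDA dimensionality
#' reduction followed by a k-nearest-neighbour vote, or a three-layer dense
#' network (100, 200, 160 units, ReLU, dropout 0.5, softmax) trained with
#' SGD-with-momentum. All projections and network weights are fitted on the
#' training split only.
#'
#' @param train_x,test_x Numeric feature matrices (rows = windows).
#' @param train_y,test_y Integer class labels.
#' @param method `"pca_knn"`, `"lda_knn"`, or `"ann"`.
#' @param k Neighbours for the KNN vote (default 5, Euclidean distance).
#' @param n_components Projection dimensionality; defaults to
#'   `min(ncol(train_x), 20)` for PCA and `G - 1` for LDA.
#' @param epochs,batch_size,lr,momentum,weight_decay Dense-network training
#'   hyperparameters (defaults: 100 epochs, batch 32, and the same SGDM
#'   settings as the deep models).
#' @param seed Seed for the dense-network initialization and batching.
#' @return List with `accuracy` (held-out), `predictions`, and `method`.
#' @export
baseline_classify <- function(train_x, train_y, test_x, test_y,
                              method = c("pca_knn", "lda_knn", "ann"),
                              k = 5L, n_components = NULL,
                              epochs = 100L, batch_size = 32L, lr = 0.002,
                              momentum = 0.95, weight_decay = 5e-4, seed = 1L) {
  method <- match.arg(method)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  classes <- sort(unique(train_y))
  if (length(classes) < 2L) stop("training data must contain >= 2 classes")
  pred <- switch(method,
    pca_knn = {
      nc <- if (is.null(n_components)) min(ncol(train_x), 20L) else n_components
      pca <- stats::prcomp(train_x, center = TRUE, scale. = FALSE)
      nc <- min(nc, ncol(pca$rotation))
      tr <- stats::predict(pca, train_x)[, seq_len(nc), drop = FALSE]
      te <- stats::predict(pca, test_x)[, seq_len(nc), drop = FALSE]
      as.integer(as.character(class::knn(tr, te, factor(train_y), k = k)))
    },
    lda_knn = {
      nc <- if (is.null(n_components)) length(classes) - 1L else n_components
      fit <- MASS::lda(train_x, grouping = factor(train_y))
      nc <- min(nc, ncol(fit$scaling))
      ctr <- colMeans(train_x)
      tr <- scale(train_x, center = ctr, scale = FALSE) %*%
        fit$scaling[, seq_len(nc), drop = FALSE]
      te <- scale(test_x, center = ctr, scale = FALSE) %*%
        fit$scaling[, seq_len(nc), drop = FALSE]
      as.integer(as.character(class::knn(tr, te, factor(train_y), k = k)))
    },
    ann = {
      ## condition the inputs: per-feature z-scoring fitted on training data
      mu <- colMeans(train_x)
      sdv <- apply(train_x, 2L, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      train_x <- scale(train_x, center = mu, scale = sdv)
      test_x <- scale(test_x, center = mu, scale = sdv)
      y_idx <- match(train_y, classes) - 1L
      set.seed(seed)
      net <- list(nn_dense(ncol(train_x), 100L), nn_relu(),
                  nn_dense(100L, 200L), nn_relu(),
                  nn_dense(200L, 160L), nn_relu(),
                  nn_dropout(0.5),
                  nn_dense(160L, length(classes), name = "fc_out"))
      yh <- one_hot(y_idx, length(classes))
      n <- nrow(train_x)
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
          h <- train_x[b, , drop = FALSE]
          for (l in net) h <- layer_forward(l, h, training = TRUE)
          sx <- softmax_xent(h, yh[b, , drop = FALSE])
          g <- sx$dlogits
          for (l in rev(net)) g <- layer_backward(l, g)
          sgdm_step(net, lr, momentum, weight_decay)
        }
      }
      h <- test_x
      for (l in net) h <- layer_forward(l, h, training = FALSE)
      classes[one_hot_decode(softmax_rows(h)) + 1L]
    })
  list(accuracy = mean(pred == test_y), predictions = pred, method = method)
}
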
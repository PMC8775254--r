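#' Training hyperparameter configuration
#'
#' Defaults follow the published training recipe: SGD with momentum 0.95,
#' initial learning rate 0.002, weight decay 0.0005, minibatch size 20,
#' cross-entropy loss on softmax outputs.
#'
#' @param epochs Training epochs (`>= 1`).
#' @param lr Learning rate.
#' @param momentum SGDM momentum.
#' @param weight_decay L2 weight decay added to every gradient.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling batching and dropout.
#' @param split `"random_window"` (windows shuffled into fractions, the
#'   protocol behind the published accuracies) or `"by_repetition"`
#'   (repetition-disjoint, leakage-free; recommended for honest evaluation).
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param k_folds Folds for [kfold_cv()] (default 5).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, lr = 0.002, momentum = 0.95,
                         weight_decay = 5e-4, batch_size = 20L, seed = 1L,
                         split = c("random_window", "by_repetition"),
                         fractions = c(0.8, 0.1, 0.1), k_folds = 5L) {
  split <- match.arg(split)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), split = split, fractions = fractions,
                 k_folds = as.integer(k_folds)),
            class = "train_config")
}

#' Evaluate a model on labeled frames
#'
#' @param model A `gesture_model`.
#' @param x Frame array.
#' @param y Integer labels `0 .. G-1`.
#' @param batch_size Evaluation batch size.
#' @return List with `loss` and `accuracy`.
#' @export
evaluate_model <- function(model, x, y, batch_size = 100L) {
  n <- dim(x)[1L]
  yh <- one_hot(y, model$spec$num_classes)
  loss <- 0; correct <- 0L
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- index_frames(x, b)
    logits <- model_forward(model, xb, training = FALSE)
    sx <- softmax_xent(logits, yh[b, , drop = FALSE])
    loss <- loss + sx$loss * length(b)
    correct <- correct + sum(one_hot_decode(sx$probs) == y[b])
  }
  list(loss = loss / n, accuracy = correct / n)
}

index_frames <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 4L) x[idx, , , , drop = FALSE]
  else x[idx, , , , , drop = FALSE]
}

#' Train a classifier with SGD-with-momentum
#'
#' Runs minibatch gradient descent and records one history row per epoch:
#' training loss/accuracy over the seen batches, validation loss/accuracy
#' (when a validation set is given), and wall-clock seconds (informational
#' only; hardware-dependent). A fixed `cfg$seed` makes batching, dropout and
#' therefore the whole history reproducible on one device.
#'
#' @param model A `gesture_model` (modified in place; also returned).
#' @param x Training frame array `(n, W, H, C)` or `(n, T, W, H, C)`.
#' @param y Integer training labels `0 .. G-1`.
#' @param cfg A [train_config()].
#' @param val_x,val_y Optional validation set.
#' @param verbose Print a line per epoch.
#' @return List with `model` and `history` (data frame, one row per epoch).
#' @export
train_model <- function(model, x, y, cfg, val_x = NULL, val_y = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "gesture_model"), inherits(cfg, "train_config"))
  n <- dim(x)[1L]
  if (n == 0L) stop("empty training split")
  yh <- one_hot(y, model$spec$num_classes)
  set.seed(cfg$seed)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- index_frames(x, b)
      logits <- model_forward(model, xb, training = TRUE)
      sx <- softmax_xent(logits, yh[b, , drop = FALSE])
      if (!is.finite(sx$loss))
        stop("non-finite loss at epoch ", ep,
             "; consider lowering the learning rate")
      ep_loss <- ep_loss + sx$loss * length(b)
      ep_correct <- ep_correct + sum(one_hot_decode(sx$probs) == y[b])
      model_backward(model, sx$dlogits)
      sgdm_step(all_layers(model), cfg$lr, cfg$momentum, cfg$weight_decay)
    }
    val <- if (!is.null(val_x)) evaluate_model(model, val_x, val_y)
           else list(loss = NA_real_, accuracy = NA_real_)
    hist[[ep]] <- data.frame(
      epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val$loss, val_acc = val$accuracy,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f val_acc %.3f",
                      ep, ep_loss / n, ep_correct / n, val$accuracy))
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Split window indices into train / validation / test
#'
#' `random_window` shuffles all windows and cuts at the configured fractions
#' (stratified per class). `by_repetition` assigns whole repetitions to one
#' side only, so overlapping windows of the same movement execution never
#' straddle the split.
#'
#' @param labels Integer window labels.
#' @param cfg A [train_config()] (supplies `split`, `fractions`, `seed`).
#' @param repetition Integer repetition ids (required for `by_repetition`).
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_windows <- function(labels, cfg, repetition = NULL) {
  set.seed(cfg$seed + 1L)
  n <- length(labels)
  fr <- cfg$fractions
  if (cfg$split == "random_window") {
    tr <- integer(0); va <- integer(0); te <- integer(0)
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      n_g <- length(idx)
      n_tr <- round(fr[1L] * n_g); n_va <- round(fr[2L] * n_g)
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[n_tr + seq_len(min(n_va, n_g - n_tr))])
      te <- c(te, idx[setdiff(seq_len(n_g), seq_len(n_tr + n_va))])
    }
    list(train = sort(tr), val = sort(va), test = sort(te))
  } else {
    if (is.null(repetition)) stop("by_repetition split needs repetition ids")
    ids <- sample(sort(unique(repetition)))
    if (length(ids) < 3L) stop("by_repetition split needs >= 3 repetition ids")
    n_tr <- min(max(1L, floor(fr[1L] * length(ids))), length(ids) - 2L)
    n_va <- min(max(1L, floor(fr[2L] * length(ids))), length(ids) - n_tr - 1L)
    rtr <- ids[seq_len(n_tr)]
    rva <- ids[n_tr + seq_len(n_va)]
    rte <- setdiff(ids, c(rtr, rva))
    list(train = which(repetition %in% rtr),
         val = which(repetition %in% rva),
         test = which(repetition %in% rte))
  }
}

#' Stratified k-fold cross-validation of a model builder
#'
#' Windows are dealt round-robin per class into `k` disjoint folds; each
#' fold serves once as the held-out set. Standardization statistics are
#' fitted on each training fold only and applied unchanged to its held-out
#' fold, so no fold ever sees test statistics.
#'
#' @param x Frame array `(n, W, H, C)`.
#' @param y Integer labels `0 .. G-1`.
#' @param builder Function `(fold_seed) -> gesture_model`.
#' @param cfg A [train_config()].
#' @param k Number of folds (default `cfg$k_folds`).
#' @param repetition Optional repetition ids; when given, whole repetitions
#'   are dealt into folds instead of single windows, keeping folds
#'   repetition-disjoint.
#' @return List with `accuracies` (length `k`), `mean`, `sd`, and `folds`
#'   (fold id per window).
#' @export
kfold_cv <- function(x, y, builder, cfg, k = cfg$k_folds, repetition = NULL) {
  n <- length(y)
  if (k < 2L) stop("need k >= 2 folds")
  set.seed(cfg$seed + 2L)
  fold <- integer(n)
  if (is.null(repetition)) {
    if (any(table(y) < 2L)) stop("every class needs >= 2 windows for stratified folds")
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    ids <- sample(sort(unique(repetition)))
    fid <- rep_len(seq_len(k), length(ids))
    fold <- fid[match(repetition, ids)]
  }
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < length(unique(y)))
      stop("class absent from training fold ", f, "; use fewer folds")
    sc <- fit_scaler(index_frames(x, tr))
    xtr <- apply_scaler(sc, index_frames(x, tr))
    xte <- apply_scaler(sc, index_frames(x, te))
    model <- builder(cfg$seed + 10L * f)
    fit <- train_model(model, xtr, y[tr],
                       within_cfg(cfg, seed = cfg$seed + 10L * f))
    accs[f] <- evaluate_model(fit$model, xte, y[te])$accuracy
  }
  list(accuracies = accs, mean = mean(accs), sd = stats::sd(accs), folds = fold)
}

within_cfg <- function(cfg, ...) {
  mod <- list(...)
  for (nm in names(mod)) cfg[[nm]] <- mod[[nm]]
  cfg
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided matched-pairs signed-rank test on paired per-fold (or
#' per-subject) accuracies. Zero differences are dropped, tied absolute
#' differences receive midranks, and for `n <= exact_max` retained pairs the
#' p-value comes from the exact permutation distribution of the rank sum
#' (computed by dynamic programming over all `2^n` sign assignments), not a
#' normal approximation; larger `n` falls back to the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param acc_a,acc_b Paired accuracy vectors of equal length.
#' @param alpha Significance level (default 0.05).
#' @param exact_max Largest `n` for which the exact distribution is used
#'   (default 25).
#' @return An object of class `comparison_result`: `statistic` (rank sum of
#'   positive differences), `p_value`, `n` (pairs retained), `n_zero`,
#'   `significant`, `degenerate`, `method`, plus the input vectors.
#' @export
wilcoxon_compare <- function(acc_a, acc_b, alpha = 0.05, exact_max = 25L) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors must have equal length")
  if (length(acc_a) < 5L) stop("need >= 5 pairs")
  d <- acc_a - acc_b
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L) {
    res <- list(statistic = 0, p_value = 1, n = 0L, n_zero = n_zero,
                alpha = alpha, significant = FALSE, degenerate = TRUE,
                method = "degenerate (all differences zero)",
                acc_a = acc_a, acc_b = acc_b)
    class(res) <- "comparison_result"
    return(res)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w_pos)
    method <- "exact signed-rank (dynamic programming)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  res <- list(statistic = w_pos, p_value = p, n = n, n_zero = n_zero,
              alpha = alpha, significant = p < alpha, degenerate = FALSE,
              method = method, acc_a = acc_a, acc_b = acc_b)
  class(res) <- "comparison_result"
  res
}

## exact two-sided p for the signed-rank statistic with midrank ties:
## doubled ranks are integers, so the distribution of the doubled positive
## rank sum over all 2^n sign assignments is built by convolution
signed_rank_exact_p <- function(ranks, w_pos) {
  r2 <- as.integer(round(2 * ranks))
  S <- sum(r2)
  f <- numeric(S + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(S + 1L)] <- g[(r + 1L):(S + 1L)] + f[seq_len(S + 1L - r)]
    f <- g
  }
  total <- 2^length(ranks)
  w2 <- as.integer(round(2 * w_pos))
  p_le <- sum(f[seq_len(w2 + 1L)]) / total
  p_ge <- sum(f[(w2 + 1L):(S + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> Wilcoxon matched-pairs signed-rank test\n")
  cat(sprintf("  n = %d pairs (%d zero difference%s dropped), V = %g\n",
              x$n, x$n_zero, if (x$n_zero == 1) "" else "s", x$statistic))
  cat(sprintf("  two-sided p = %.5g (%s)\n", x$p_value, x$method))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$degenerate) "degenerate: not significant"
              else if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Epochs-to-threshold efficiency comparison
#'
#' For each accuracy threshold, reports the first epoch at which each
#' model's validation accuracy reaches the threshold, together with the
#' cumulative wall-clock time up to that epoch. Epoch counts are the
#' comparable quantity; the time columns are informational only
#' (hardware-dependent) and `NA` marks a threshold never reached.
#'
#' @param history_a,history_b Training histories from [train_model()].
#' @param thresholds Numeric accuracy thresholds.
#' @param names Model names for the report columns.
#' @return Data frame with one row per threshold: `epochs_<name>` and
#'   `seconds_<name>` columns.
#' @export
efficiency_report <- function(history_a, history_b, thresholds,
                              names = c("a", "b")) {
  one <- function(h, thr) {
    hit <- which(h$val_acc >= thr)
    if (length(hit) == 0L) c(NA_integer_, NA_real_)
    else c(hit[1L], sum(h$seconds[seq_len(hit[1L])]))
  }
  rows <- lapply(thresholds, function(thr) {
    a <- one(history_a, thr); b <- one(history_b, thr)
    stats::setNames(
      data.frame(thr, a[1L], a[2L], b[1L], b[2L]),
      c("threshold",
        paste0(c("epochs_", "seconds_"), names[1L]),
        paste0(c("epochs_", "seconds_"), names[2L])))
  })
  do.call(rbind, rows)
}

#' Segment recordings into a pooled, framed, labeled dataset
#'
#' Convenience pipeline: sliding windows on each recording, frame reshaping
#' and stacking, pooled across recordings.
#'
#' @param recs A [raw_recording()] or list of them.
#' @param wcfg A [window_config()].
#' @param W,H,C_out Frame geometry for [reshape_frame()].
#' @return List with `frames`, `labels`, `repetition`, `subject`.
#' @export
prepare_frames <- function(recs, wcfg, W, H, C_out = NULL) {
  if (inherits(recs, "raw_recording")) recs <- list(recs)
  parts <- lapply(recs, function(r) frame_stack(sliding_windows(r, wcfg), W, H, C_out))
  frames <- do.call(abind4, lapply(parts, `[[`, "frames"))
  list(frames = frames,
       labels = unlist(lapply(parts, `[[`, "labels")),
       repetition = unlist(lapply(parts, `[[`, "repetition")),
       subject = unlist(lapply(parts, `[[`, "subject")))
}

## bind (n, W, H, C) arrays along the first axis
abind4 <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L) return(xs[[1L]])
  d <- dim(xs[[1L]])[-1L]
  n <- sum(vapply(xs, function(x) dim(x)[1L], integer(1)))
  out <- array(NA_real_, c(n, d))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1L]), , , ] <- x
    at <- at + dim(x)[1L]
  }
  out
}

#' Order-confusable pair experiment: CFF-RCNN vs RCNN vs amplitude baseline
#'
#' The package's central directional experiment. A two-class synthetic
#' recording is generated whose classes share per-window amplitude content
#' and differ only in temporal order ([make_confusable_pair()]). Windows are
#' segmented, framed, standardized on the training split, and both
#' architectures are trained with identical seeds and hyperparameters. An
#' amplitude-only baseline — per-channel window maxima of the rectified
#' signal, i.e. exactly the statistic a full-window max-pooling retains —
#' is classified with LDA+KNN on the same split. Because the two classes
#' are constructed to have identical per-window amplitude distributions,
#' the baseline has no usable signal, while the networks can read the
#' temporal profile inside each frame.
#'
#' Windows of one movement execution overlap by 80%, so a window-level
#' random split leaks: every held-out window has near-duplicates in the
#' training set, and the comparison then rewards shift-invariant
#' memorization rather than generalization. The experiment therefore
#' evaluates repetition-disjoint: whole repetitions are held out, and
#' validation accuracy measures transfer to unseen movement executions.
#'
#' @param seed Master seed for generation, splitting, and both trainings.
#' @param epochs Training epochs per model.
#' @param base Optional [synthetic_spec()] supplying the recording
#'   conditions (default: the package's small test-scale conditions).
#' @param fc_sizes,lstm_units,conv_filters Network widths (defaults are the
#'   reduced desk-scale widths; see the methods vignette).
#' @param verbose Print epoch progress.
#' @return List with `acc_cff`, `acc_rcnn` (validation accuracy at equal
#'   epochs), `acc_baseline`, and the two training `histories`.
#' @export
confusable_experiment <- function(seed = 1L, epochs = 30L, base = NULL,
                                  fc_sizes = c(16L, 16L, 8L),
                                  lstm_units = 6L, conv_filters = 8L,
                                  verbose = FALSE) {
  if (is.null(base)) base <- synthetic_spec(seed = seed)
  base$seed <- as.integer(seed)
  pair <- make_confusable_pair(base)
  rec <- generate_recording(pair)
  wcfg <- window_config(drop_rest = TRUE)
  ws <- sliding_windows(rec, wcfg)
  N <- ws$N
  H <- N %/% 5L
  dat <- prepare_frames(rec, wcfg, W = 5L, H = H)
  y <- dat$labels - 1L                      # two classes -> 0/1
  cfg <- train_config(epochs = epochs, seed = seed, split = "by_repetition")
  ## repetition-disjoint k-fold: each fold holds out a third of the
  ## repetitions, every window is evaluated exactly once, and both
  ## architectures share the folds, so the comparison is paired
  set.seed(seed + 1L)
  ids <- sample(sort(unique(dat$repetition)))
  k <- 3L
  fold_of <- rep_len(seq_len(k), length(ids))[match(dat$repetition, ids)]
  shape <- dim(dat$frames)[-1L]

  ## amplitude-only baseline features: the full-window max-pool statistic
  amp <- t(vapply(ws$windows, function(w) apply(abs(w), 2L, max),
                  numeric(ncol(ws$windows[[1L]]))))

  correct <- c(cff_rcnn = 0L, rcnn = 0L, baseline = 0L)
  histories <- list()
  for (f in seq_len(k)) {
    tr <- which(fold_of != f); va <- which(fold_of == f)
    sc <- fit_scaler(index_frames(dat$frames, tr))
    xtr <- apply_scaler(sc, index_frames(dat$frames, tr))
    xva <- apply_scaler(sc, index_frames(dat$frames, va))
    for (variant in c("cff_rcnn", "rcnn")) {
      ms <- model_spec(variant, input_shape = shape, num_classes = 2L,
                       conv_filters = conv_filters, fc_sizes = fc_sizes,
                       lstm_units = lstm_units)
      model <- build_model(ms, seed = seed + f)
      fit <- train_model(model, xtr, y[tr],
                         within_cfg(cfg, seed = cfg$seed + f),
                         val_x = xva, val_y = y[va], verbose = verbose)
      correct[variant] <- correct[variant] +
        as.integer(round(utils::tail(fit$history$val_acc, 1L) * length(va)))
      histories[[paste0(variant, "_fold", f)]] <- fit$history
    }
    bl <- baseline_classify(amp[tr, , drop = FALSE], y[tr],
                            amp[va, , drop = FALSE], y[va],
                            method = "lda_knn")
    correct["baseline"] <- correct["baseline"] +
      as.integer(round(bl$accuracy * length(va)))
  }
  n <- length(y)
  list(acc_cff = correct[["cff_rcnn"]] / n,
       acc_rcnn = correct[["rcnn"]] / n,
       acc_baseline = correct[["baseline"]] / n,
       histories = histories)
}

#' Pooled multi-subject robustness comparison
#'
#' Generates several synthetic subjects with jittered envelopes, pools their
#' windows, and trains both architectures on the pooled data, mirroring the
#' all-subjects protocol. The split can be window-level or subject-disjoint;
#' the report records which was used.
#'
#' @param spec A [synthetic_spec()] describing the population conditions.
#' @param n_subjects Number of synthetic subjects.
#' @param cfg A [train_config()].
#' @param subject_disjoint Hold out whole subjects for testing instead of
#'   random windows (default `FALSE`).
#' @param fc_sizes,lstm_units,conv_filters Network widths (desk-scale
#'   defaults).
#' @return List with per-model test accuracies, the split mode, and the
#'   training histories.
#' @export
robustness_run <- function(spec, n_subjects = 3L, cfg = train_config(),
                           subject_disjoint = FALSE,
                           fc_sizes = c(64L, 64L, 32L), lstm_units = 32L,
                           conv_filters = 16L) {
  recs <- generate_subjects(spec, n_subjects)
  wcfg <- window_config(drop_rest = TRUE)
  N <- window_samples(wcfg, spec$fs)$N
  dat <- prepare_frames(recs, wcfg, W = 5L, H = N %/% 5L)
  y <- dat$labels - 1L
  G <- length(unique(y))
  if (subject_disjoint) {
    te <- which(dat$subject == n_subjects)
    rest <- which(dat$subject != n_subjects)
    set.seed(cfg$seed + 3L)
    va <- sample(rest, max(1L, round(0.1 * length(rest))))
    tr <- setdiff(rest, va)
    sp <- list(train = tr, val = va, test = te)
  } else {
    sp <- split_windows(y, cfg)
  }
  sc <- fit_scaler(index_frames(dat$frames, sp$train))
  xtr <- apply_scaler(sc, index_frames(dat$frames, sp$train))
  xte <- apply_scaler(sc, index_frames(dat$frames, sp$test))
  shape <- dim(dat$frames)[-1L]
  fit_one <- function(variant) {
    ms <- model_spec(variant, input_shape = shape, num_classes = G,
                     conv_filters = conv_filters, fc_sizes = fc_sizes,
                     lstm_units = lstm_units)
    train_model(build_model(ms, seed = cfg$seed), xtr, y[sp$train], cfg)
  }
  fit_cff <- fit_one("cff_rcnn")
  fit_rcnn <- fit_one("rcnn")
  list(acc_cff = evaluate_model(fit_cff$model, xte, y[sp$test])$accuracy,
       acc_rcnn = evaluate_model(fit_rcnn$model, xte, y[sp$test])$accuracy,
       split = if (subject_disjoint) "subject_disjoint" else "random_window",
       histories = list(cff_rcnn = fit_cff$history, rcnn = fit_rcnn$history))
}
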
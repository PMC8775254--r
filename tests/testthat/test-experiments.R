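tiny_frames <- function(n = 40, G = 2, seed = 70) {
  set.seed(seed)
  x <- array(rnorm(n * 5 * 6 * 2), c(n, 5, 6, 2))
  y <- rep(seq_len(G) - 1L, length.out = n)
  x[, , , 1] <- x[, , , 1] + 1.5 * y        # separable signal
  list(x = x, y = y)
}

tiny_builder <- function(G = 2) {
  function(seed) {
    build_model(model_spec("rcnn", input_shape = c(5, 6, 2), num_classes = G,
                           conv_filters = 4, fc_sizes = c(8, 8, 6),
                           lstm_units = 4), seed = seed)
  }
}

test_that("training records one finite history row per epoch", {
  d <- tiny_frames()
  m <- tiny_builder()(1)
  fit <- train_model(m, d$x, d$y, train_config(epochs = 1, seed = 1))
  expect_equal(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$train_loss))
  ## epochs are respected and losses stay finite
  fit3 <- train_model(tiny_builder()(1), d$x, d$y,
                      train_config(epochs = 3, seed = 1))
  expect_equal(fit3$history$epoch, 1:3)
  expect_true(all(is.finite(fit3$history$train_loss)))
})

test_that("identical seeds reproduce identical training histories", {
  d <- tiny_frames()
  f1 <- train_model(tiny_builder()(5), d$x, d$y, train_config(epochs = 2, seed = 3))
  f2 <- train_model(tiny_builder()(5), d$x, d$y, train_config(epochs = 2, seed = 3))
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  f3 <- train_model(tiny_builder()(5), d$x, d$y, train_config(epochs = 2, seed = 4))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("loss decreases over the first epochs at the default learning rate", {
  ok <- 0L
  for (s in 1:5) {
    d <- tiny_frames(n = 120, seed = 80 + s)
    fit <- train_model(tiny_builder()(s), d$x, d$y,
                       train_config(epochs = 10, seed = s))
    if (utils::tail(fit$history$train_loss, 1) < fit$history$train_loss[1])
      ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("window splits respect their fractions and repetition boundaries", {
  labels <- rep(0:1, each = 100)
  reps <- rep(rep(1:5, each = 20), 2)
  cfg <- train_config(seed = 11)
  sp <- split_windows(labels, cfg)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:200)
  expect_equal(length(sp$train), 160L)
  ## repetition-level split: no repetition id on both sides
  cfg_r <- train_config(seed = 11, split = "by_repetition")
  sp_r <- split_windows(labels, cfg_r, repetition = reps)
  expect_length(intersect(unique(reps[sp_r$train]), unique(reps[sp_r$test])), 0L)
  expect_length(intersect(unique(reps[sp_r$train]), unique(reps[sp_r$val])), 0L)
  expect_error(split_windows(labels, cfg_r), "repetition")
})

test_that("stratified k-fold partitions the data into disjoint covering folds", {
  d <- tiny_frames(n = 100)
  cfg <- train_config(epochs = 2, seed = 21)
  cv <- kfold_cv(d$x, d$y, tiny_builder(), cfg, k = 5)
  expect_length(cv$accuracies, 5L)
  expect_equal(as.vector(table(cv$folds)), rep(20L, 5))
  expect_equal(cv$mean, mean(cv$accuracies))
  ## separable data: high accuracy in every fold
  cv2 <- kfold_cv(d$x, d$y, tiny_builder(),
                  within_cfg(cfg, epochs = 20, lr = 0.02), k = 5)
  expect_true(all(cv2$accuracies >= 0.9))
})

test_that("repetition-aware folds never split a repetition", {
  d <- tiny_frames(n = 100)
  reps <- rep(1:10, each = 10)
  cv <- kfold_cv(d$x, d$y, tiny_builder(), train_config(epochs = 1, seed = 2),
                 k = 5, repetition = reps)
  for (f in 1:5) {
    in_f <- unique(reps[cv$folds == f])
    out_f <- unique(reps[cv$folds != f])
    expect_length(intersect(in_f, out_f), 0L)
  }
})

test_that("the signed-rank test matches exact enumeration and closed forms", {
  ## n = 10, all differences positive: p = 2 / 2^10
  res <- wilcoxon_compare(seq(0.1, 1, by = 0.1) + 0.5, seq(0.1, 1, by = 0.1))
  expect_equal(res$p_value, 2 / 1024)
  expect_true(res$significant)
  ## identical vectors: degenerate, not significant
  res <- wilcoxon_compare(rep(0.8, 6), rep(0.8, 6))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  ## alternating equal-magnitude differences: statistic at the center, p = 1
  a <- rep(0.5, 8); b <- a + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  expect_equal(wilcoxon_compare(a, b)$p_value, 1)
  expect_error(wilcoxon_compare(1:3 / 10, 3:1 / 10), ">= 5")
})

test_that("exact p-values agree with brute-force sign enumeration for n <= 12", {
  brute_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_le <- mean(w_all <= w_obs)
    p_ge <- mean(w_all >= w_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(91)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    a <- round(runif(n), 2)
    b <- round(a + rnorm(n, sd = 0.1), 2)   # rounding forces ties and zeros
    if (all(a == b)) next
    res <- wilcoxon_compare(a, b)
    expect_equal(res$p_value, brute_p(a - b), tolerance = 1e-12,
                 info = paste("case", i))
  }
  ## and with the reference implementation when there are no ties
  set.seed(92)
  for (i in 1:10) {
    a <- runif(8); b <- runif(8)
    res <- wilcoxon_compare(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, unname(ref$statistic))
  }
})

test_that("efficiency reports locate the first epoch reaching each threshold", {
  h1 <- data.frame(epoch = 1:10,
                   val_acc = c(0.5, 0.55, 0.6, 0.65, 0.7,
                               0.75, 0.8, 0.85, 0.9, 0.95),
                   seconds = rep(1, 10))
  h2 <- data.frame(epoch = 1:10, val_acc = seq(0.3, 0.7, length.out = 10),
                   seconds = rep(2, 10))
  rep_tab <- efficiency_report(h1, h2, thresholds = c(0.6, 0.9, 0.99),
                               names = c("cff", "rcnn"))
  expect_equal(rep_tab$epochs_cff, c(3L, 9L, NA_integer_))
  expect_equal(rep_tab$epochs_rcnn, c(8L, NA_integer_, NA_integer_))
  ## cumulative time to threshold, and no exception on unreached thresholds
  expect_equal(rep_tab$seconds_cff, c(3, 9, NA_real_))
})

test_that("normalization statistics are immune to test-set mutation", {
  d <- tiny_frames(n = 60)
  tr <- 1:40
  sc1 <- fit_scaler(d$x[tr, , , , drop = FALSE])
  ## mutate the held-out windows heavily; training statistics cannot move
  d$x[41:60, , , ] <- d$x[41:60, , , ] * 100 + 7
  sc2 <- fit_scaler(d$x[tr, , , , drop = FALSE])
  expect_identical(unclass(sc1), unclass(sc2))
})

test_that("pooled multi-subject training beats chance under both split modes", {
  spec <- synthetic_spec(G = 3, C = 2, reps = 3, movement_ms = 600,
                         rest_ms = 300, seed = 2)
  cfg <- train_config(epochs = 30, seed = 2)
  res <- robustness_run(spec, n_subjects = 3, cfg = cfg)
  expect_gt(res$acc_cff, 1 / 3)
  expect_gt(res$acc_rcnn, 1 / 3)
  expect_equal(res$split, "random_window")
  ## subject-disjoint evaluation is supported and flagged
  res2 <- robustness_run(spec, n_subjects = 3, cfg = cfg,
                         subject_disjoint = TRUE)
  expect_equal(res2$split, "subject_disjoint")
  expect_gt(res2$acc_cff, 1 / 3)
  expect_gt(res2$acc_rcnn, 1 / 3)
})
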
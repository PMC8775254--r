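make_rec <- function(T_n, C = 2, fs = 2000, labels = rep(1L, T_n)) {
  set.seed(T_n + C)
  raw_recording(matrix(rnorm(T_n * C), T_n, C), fs, labels)
}

test_that("window sample counts follow the sampling rate", {
  cfg <- window_config()                   # 250 ms / 200 ms
  expect_equal(window_samples(cfg, 2000), list(N = 500L, hop = 100L))
  expect_equal(window_samples(cfg, 100), list(N = 25L, hop = 5L))
  expect_error(window_config(window_ms = 250, overlap_ms = 250), "overlap_ms")
  expect_error(window_samples(window_config(250, 249.9), 2000), "hop")
})

test_that("sliding windows enumerate all hop-aligned starts", {
  cfg <- window_config()
  ## exactly one window from a recording of exactly one window length
  ws <- sliding_windows(make_rec(500), cfg)
  expect_length(ws$windows, 1L)
  expect_equal(ws$starts, 1L)
  ## 700 samples, hop 100: windows at offsets 0, 100, 200
  ws <- sliding_windows(make_rec(700), cfg)
  expect_equal(ws$starts, c(1L, 101L, 201L))
  expect_error(sliding_windows(make_rec(499), cfg), "too short")
  ## count formula matches brute-force start enumeration
  set.seed(5)
  for (i in 1:20) {
    T_n <- sample(60:400, 1)
    fs <- 100
    win_ms <- sample(100:300, 1)
    ov_ms <- sample(0:(win_ms - 20), 1)
    cfg_i <- window_config(win_ms, ov_ms)
    nh <- window_samples(cfg_i, fs)
    if (nh$N > T_n) next
    brute <- sum((seq_len(T_n) - 1L) %% nh$hop == 0 &
                   seq_len(T_n) + nh$N - 1L <= T_n)
    ws_i <- sliding_windows(make_rec(T_n, fs = fs), cfg_i)
    expect_length(ws_i$windows, brute)
    expect_equal(length(ws_i$windows), floor((T_n - nh$N) / nh$hop) + 1)
  }
})

test_that("consecutive windows overlap in exactly N - hop samples", {
  rec <- make_rec(900)
  ws <- sliding_windows(rec, window_config())
  for (i in seq_len(length(ws$windows) - 1L)) {
    a <- ws$windows[[i]]; b <- ws$windows[[i + 1L]]
    expect_identical(a[(ws$hop + 1L):ws$N, ], b[seq_len(ws$N - ws$hop), ])
    expect_identical(b, rec$signal[ws$starts[i + 1L] + seq_len(ws$N) - 1L, ])
  }
})

test_that("window labels follow the majority rule with a purity threshold", {
  T_n <- 300
  labels <- c(rep(0L, 100), rep(2L, 200))
  rec <- make_rec(T_n, fs = 100, labels = labels)
  cfg <- window_config(250, 200)           # N = 25, hop 5
  ws <- sliding_windows(rec, cfg)
  ## every window fully inside a span takes that span's label
  expect_true(all(ws$labels[ws$starts + 24 <= 100] == 0L))
  expect_true(all(ws$labels[ws$starts >= 101] == 2L))
  ## straddling windows get the majority side
  mid <- ws$starts > 76 & ws$starts <= 100
  expect_true(all(ws$labels[mid] %in% c(0L, 2L)))
  expect_true(all(ws$purity >= 0.5))
  ## a strict purity threshold drops the straddlers
  ws_strict <- sliding_windows(rec, window_config(250, 200, purity = 1))
  expect_true(all(ws_strict$purity == 1))
  ## rest windows can be excluded
  ws_nr <- sliding_windows(rec, window_config(250, 200, drop_rest = TRUE))
  expect_true(all(ws_nr$labels != 0L))
})

test_that("frame reshaping is a bijection for both database layouts", {
  set.seed(9)
  ## 2 kHz layout: channels kept intact
  win <- matrix(rnorm(500 * 12), 500, 12)
  f <- reshape_frame(win, 5, 100)
  expect_equal(dim(f), c(5L, 100L, 12L))
  expect_identical(unshape_frame(f, 500, 12), win)
  ## each output channel is its input channel, row-major over (W, H)
  expect_equal(f[2, 3, 7], win[1 * 100 + 3, 7])
  ## 100 Hz layout: channels folded into the spatial axes
  win1 <- matrix(rnorm(25 * 10), 25, 10)
  f1 <- reshape_frame(win1, 5, 25, C_out = 2)
  expect_equal(dim(f1), c(5L, 25L, 2L))
  expect_identical(unshape_frame(f1, 25, 10), win1)
  ## identity layout
  fid <- reshape_frame(win1, 25, 1, C_out = 10)
  expect_equal(as.vector(fid), as.vector(win1))
  ## random round-trips, bit-exact
  for (i in 1:20) {
    N <- sample(c(20, 50, 100), 1); C <- sample(2:6, 1)
    w <- matrix(rnorm(N * C), N, C)
    WH <- c(5, N / 5)
    expect_identical(unshape_frame(reshape_frame(w, WH[1], WH[2]), N, C), w)
  }
  expect_error(reshape_frame(win1, 7, 11), "shape mismatch")
})

test_that("standardization statistics come from training data only", {
  set.seed(13)
  tr <- array(rnorm(200 * 4 * 5 * 3, mean = 3, sd = 2), c(200, 4, 5, 3))
  sc <- fit_scaler(tr)
  z <- apply_scaler(sc, tr)
  for (c in 1:3) {
    expect_lt(abs(mean(z[, , , c])), 0.05)
    expect_lt(abs(sd(z[, , , c]) - 1), 0.05)
  }
  ## inverse transform recovers the originals
  expect_equal(apply_scaler(sc, z, inverse = TRUE), tr, tolerance = 1e-12)
  ## applying the transform twice is not the identity
  expect_false(isTRUE(all.equal(apply_scaler(sc, z), z)))
  ## statistics never depend on test data
  te1 <- array(rnorm(60), c(5, 4, 3))
  sc2 <- fit_scaler(tr)
  expect_identical(unclass(sc), unclass(sc2))
  expect_identical(apply_scaler(sc, te1), apply_scaler(sc2, te1))
  ## serialization round-trip
  sc3 <- scaler_from_json(scaler_to_json(sc))
  expect_equal(sc3$mean, sc$mean)
  expect_equal(sc3$sd, sc$sd)
})

test_that("zero-variance channels get unit scale with a warning", {
  x <- array(rnorm(40 * 2 * 2 * 2), c(40, 2, 2, 2))
  x[, , , 2] <- 5
  expect_warning(sc <- fit_scaler(x), "zero-variance")
  z <- apply_scaler(sc, x)
  expect_true(all(z[, , , 2] == 0))
})

test_that("one-hot encoding is a left inverse of argmax", {
  expect_equal(one_hot(c(0L, 2L), 3),
               rbind(c(1L, 0L, 0L), c(0L, 0L, 1L)))
  expect_equal(one_hot(rep(0L, 4), 1), matrix(1L, 4, 1))
  expect_error(one_hot(c(0L, 3L), 3), "labels")
  set.seed(17)
  for (i in 1:20) {
    v <- sample(0:52, 40, replace = TRUE)
    oh <- one_hot(v, 53)
    expect_true(all(rowSums(oh) == 1))
    expect_identical(one_hot_decode(oh), v)
  }
})

test_that("frame containers round-trip through disk with their sidecar", {
  rec <- make_rec(900, C = 4, fs = 200, labels = rep(1:3, each = 300))
  cfg <- window_config()
  ws <- sliding_windows(rec, cfg)
  fs <- frame_stack(ws, W = 5, H = 10)
  sc <- fit_scaler(fs$frames)
  path <- tempfile(fileext = ".rds")
  save_frames(fs, path, cfg = cfg, scaler = sc)
  back <- load_frames(path)
  expect_equal(back$frames, fs$frames)
  expect_equal(back$labels, fs$labels)
  expect_equal(attr(back, "scaler")$mean, sc$mean)
  expect_equal(attr(back, "config")$window_ms, 250)
  unlink(c(path, paste0(path, ".json")))
})
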
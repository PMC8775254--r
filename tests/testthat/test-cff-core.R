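test_that("max_pool computes per-window maxima and drops within-window order", {
  expect_equal(max_pool(c(1, 3, 2, 0), size = 2), c(3, 2))
  ## reordering inside pooling windows leaves the output unchanged
  expect_equal(max_pool(c(3, 1, 0, 2), size = 2), c(3, 2))
  expect_equal(max_pool(rep(7, 4), size = 2), c(7, 7))
  ## matrix input pools channels independently
  m <- cbind(c(1, 3, 2, 0), c(5, 4, 0, 6))
  expect_equal(max_pool(m, size = 2), cbind(c(3, 2), c(5, 6)))
  ## valid mode output length
  expect_length(max_pool(rnorm(11), size = 2), 5L)
  expect_length(max_pool(rnorm(11), size = 2, ceil = TRUE), 6L)
  expect_error(max_pool(c(1), size = 2), "shorter")
})

test_that("max_pool is invariant to permutations within a pooling window", {
  set.seed(101)
  for (i in 1:1000) {
    L <- sample(4:40, 1)
    s <- sample(2:4, 1)
    L <- s * (L %/% s)
    x <- rnorm(L)
    base <- max_pool(x, size = s)
    w <- sample.int(L %/% s, 1)      # permute one pooling window
    idx <- ((w - 1) * s + 1):(w * s)
    xp <- x
    xp[idx] <- x[sample(idx)]
    expect_identical(max_pool(xp, size = s), base)
  }
})

test_that("strided_conv follows the weighted-sum definition", {
  expect_equal(strided_conv(c(1, 2, 3), rep(0, 3)), 0)
  ## the canonical collision example: kernel (-1, 1, 2)
  expect_equal(strided_conv(c(1, 1, 1), c(-1, 1, 2)), 2)
  expect_equal(strided_conv(c(3, 1, 2), c(-1, 1, 2)), 2)
  ## output lengths
  expect_length(strided_conv(rnorm(10), rnorm(3), stride = 1), 8L)
  expect_length(strided_conv(rnorm(10), rnorm(3), stride = 2), 4L)
  expect_length(strided_conv(rnorm(10), rnorm(3), stride = 2, padding = "same"), 5L)
  expect_error(strided_conv(c(1, 2), rnorm(3)), "shorter")
  ## constant input with a rescaled kernel reproduces the original output
  set.seed(7)
  ker <- rnorm(4); x <- rnorm(4); a <- 2.5
  y <- strided_conv(x, ker)
  ker2 <- ker * x / a
  expect_equal(strided_conv(rep(a, 4), ker2), y)
})

test_that("find_collision constructs distinct inputs with identical outputs", {
  col <- find_collision(c(-1, 1, 2), c(1, 1, 1))
  expect_true(col$possible)
  expect_equal(col$x_prime, c(3, 1, 2))
  expect_equal(sum(c(-1, 1, 2) * col$x_prime), col$y)
  ## size-1 kernels are injective
  expect_false(find_collision(c(2), c(5))$possible)
  expect_error(find_collision(c(0, 0), c(1, 1)), "degenerate")
  ## property: the constructed collision always verifies
  for (s in 1:100) {
    set.seed(s)
    k <- sample(2:6, 1)
    ker <- rnorm(k)
    ker[sample(k, sample(0:(k - 2), 1))] <- 0   # some zero weights allowed
    x <- rnorm(k)
    col <- find_collision(ker, x)
    expect_true(col$possible)
    expect_false(all(col$x_prime == x))
    expect_equal(sum(ker * col$x_prime), sum(ker * x), tolerance = 1e-10)
  }
})

test_that("receptive_field matches brute-force sensitivity of stacked convolutions", {
  expect_identical(receptive_field(1, 3), 3L)
  expect_identical(receptive_field(2, 3), 5L)
  expect_identical(receptive_field(3, 3), 7L)
  ## oracle: count which input positions influence the first output of an
  ## n-layer 1-stride valid convolution stack
  compose <- function(x, kernels) {
    for (ker in kernels) x <- strided_conv(x, ker)
    x
  }
  set.seed(11)
  for (n in 1:4) for (k in 2:5) {
    kernels <- replicate(n, rnorm(k) + 0.1, simplify = FALSE)
    L <- n * (k - 1) + 1 + 3              # slack beyond the receptive field
    x <- rnorm(L)
    y1 <- compose(x, kernels)[1]
    sens <- 0L
    for (i in seq_len(L)) {
      xp <- x; xp[i] <- xp[i] + 1
      if (abs(compose(xp, kernels)[1] - y1) > 1e-9) sens <- sens + 1L
    }
    expect_identical(sens, receptive_field(n, k))
  }
})

test_that("cff_block fuses pool and conv branches with pool channels first", {
  set.seed(3)
  x <- matrix(rnorm(10 * 64), 10, 64)
  w <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  fused <- cff_block(x, w)
  expect_equal(dim(fused), c(5L, 128L))
  expect_equal(fused[, 1:64], max_pool(x, size = 2, ceil = TRUE))
  ## all-zero input: pool branch zero, conv branch zero without bias
  expect_equal(cff_block(matrix(0, 10, 64), w), matrix(0, 5, 128))
  ## 2-D input
  x3 <- array(rnorm(6 * 10 * 4), c(6, 10, 4))
  w4 <- array(rnorm(3 * 3 * 4 * 8), c(3, 3, 4, 8))
  expect_equal(dim(cff_block(x3, w4)), c(3L, 5L, 12L))
  ## parameter accounting: conv branch only
  expect_identical(cff_block_params(3, 64, 64, ndim = 1, bias = FALSE), 12288L)
  expect_identical(cff_block_params(3, 64, 64, ndim = 2, bias = TRUE),
                   3L * 3L * 64L * 64L + 64L)
})

test_that("cff_block discriminates inputs that collide under either single branch", {
  ## three single-channel inputs: (1) the base case, (2) a within-window
  ## reordering (pool collision with 1), (3) a mass-transfer construction
  ## (conv collision with 1 on the first step)
  ker <- c(-1, 1, 2)
  x1 <- c(1, 1, 1, 4, 2, 0)
  x2 <- c(1, 1, 4, 1, 2, 0)             # swap inside pooling window 2
  col <- find_collision(ker, x1[1:3])
  x3 <- c(col$x_prime, x1[4:6])          # (3, 1, 2, ...)
  w <- array(0, c(3, 1, 1)); w[, 1, 1] <- ker
  f1 <- cff_block(matrix(x1, ncol = 1), w)
  f2 <- cff_block(matrix(x2, ncol = 1), w)
  f3 <- cff_block(matrix(x3, ncol = 1), w)
  ## pool branch cannot tell 1 from 2; conv branch can
  expect_equal(f1[, 1], f2[, 1])
  expect_false(isTRUE(all.equal(f1[, 2], f2[, 2])))
  ## fused maps are pairwise distinct
  expect_false(isTRUE(all.equal(f1, f2)))
  expect_false(isTRUE(all.equal(f1, f3)))
  expect_false(isTRUE(all.equal(f2, f3)))

  ## randomized search: no joint collision among constructed case triples
  set.seed(23)
  for (i in 1:200) {
    ## kernel with distinct nonzero leading weights: a swap inside the first
    ## pooling window must be visible to the convolution branch
    ker <- rnorm(3)
    while (any(abs(ker) < 0.1) || abs(ker[1] - ker[2]) < 0.1) ker <- rnorm(3)
    x <- rnorm(6)
    xp <- x; xp[1:2] <- x[2:1]                      # pool-window permutation
    colr <- find_collision(ker, x[1:3])
    xq <- c(colr$x_prime, x[4:6])
    w <- array(0, c(3, 1, 1)); w[, 1, 1] <- ker
    fa <- cff_block(matrix(x, ncol = 1), w)
    fb <- cff_block(matrix(xp, ncol = 1), w)
    fc <- cff_block(matrix(xq, ncol = 1), w)
    if (!all(xp == x)) expect_false(isTRUE(all.equal(fa, fb)))
    expect_false(isTRUE(all.equal(fa, fc)))
  }
})
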
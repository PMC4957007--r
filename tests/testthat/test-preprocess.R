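test_that("convolution of a constant image with a zero-sum kernel vanishes in the interior", {
  img <- matrix(7, 5, 5)
  out <- convolve2d(img, sobel_kernel("v"))
  expect_equal(out[2:4, 2:4], matrix(0, 3, 3))
  out_h <- convolve2d(img, sobel_kernel("h"))
  expect_equal(out_h[2:4, 2:4], matrix(0, 3, 3))
})

test_that("impulse response distinguishes convolution from correlation", {
  img <- matrix(0, 5, 5)
  img[3, 3] <- 1
  k <- matrix(1:9, 3, 3)
  out <- convolve2d(img, k)
  # true convolution reproduces the kernel around the impulse; correlation
  # would stamp the index-reversed kernel instead
  expect_equal(out[2:4, 2:4], k)
  expect_equal(out[2:4, 2:4], conv_oracle(img, k)[2:4, 2:4])
})

test_that("convolution matches the brute-force direct-summation oracle", {
  set.seed(42)
  for (n in c(5, 9, 16)) {
    img <- matrix(runif(n * n), n, n)
    for (which in c("v", "h")) {
      k <- sobel_kernel(which)
      expect_lt(max(abs(convolve2d(img, k) - conv_oracle(img, k))), 1e-10)
    }
  }
  # a non-symmetric kernel exercises the index reversal
  k <- matrix(c(1, -2, 3, 0, 5, 1, -1, 2, 4), 3, 3)
  img <- matrix(rnorm(100), 10, 10)
  expect_lt(max(abs(convolve2d(img, k) - conv_oracle(img, k))), 1e-10)
})

test_that("convolution is linear", {
  set.seed(7)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  k <- sobel_kernel("v")
  lhs <- convolve2d(2.5 * a - 1.2 * b, k)
  rhs <- 2.5 * convolve2d(a, k) - 1.2 * convolve2d(b, k)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("gradient magnitude of a ramp is the stencil weight sum", {
  # f(k1, k2) = k2: unit step per column; |h| = 8 at interior pixels
  img <- matrix(rep(0:9, each = 10), 10, 10, byrow = TRUE)
  img <- t(img)
  g <- sobel_magnitude(img)
  expect_equal(g$H[3:8, 3:8], matrix(8, 6, 6))
  expect_equal(g$h_h[3:8, 3:8], matrix(0, 6, 6))
  # constant image: H = 0 everywhere in the interior
  gc <- sobel_magnitude(matrix(1, 6, 6))
  expect_equal(gc$H[2:5, 2:5], matrix(0, 4, 4))
})

test_that("H is invariant to kernel sign and to 90-degree rotation", {
  set.seed(11)
  img <- matrix(runif(144), 12, 12)
  g <- sobel_magnitude(img)
  # sign convention cannot change H
  neg_v <- convolve2d(img, -sobel_kernel("v"))
  neg_h <- convolve2d(img, -sobel_kernel("h"))
  expect_lt(max(abs(sqrt(neg_v^2 + neg_h^2) - g$H)), 1e-9)
  # rotate image, compute H, rotate back: interior must agree
  rot <- t(img)[ncol(img):1, ]                     # 90 deg clockwise
  g_rot <- sobel_magnitude(rot)
  back <- t(g_rot$H[nrow(g_rot$H):1, ])            # undo rotation
  expect_lt(max(abs(back[2:11, 2:11] - g$H[2:11, 2:11])), 1e-9)
})

test_that("H agrees with the composed oracle on seeded random images", {
  set.seed(5)
  img <- matrix(runif(15 * 13), 15, 13)
  g <- sobel_magnitude(img)
  H_oracle <- sqrt(conv_oracle(img, sobel_kernel("v"))^2 +
                     conv_oracle(img, sobel_kernel("h"))^2)
  expect_lt(max(abs(g$H - H_oracle)), 1e-9)
})

test_that("normalize_gradient rescales linearly and survives degenerate input", {
  H <- matrix(c(2, 6, 10, 4), 2, 2)
  out <- normalize_gradient(H)
  expect_equal(out[2, 1], 0.5)           # 6 maps to (6-2)/(10-2)
  expect_equal(range(out), c(0, 1))
  expect_equal(normalize_gradient(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("invalid preprocessing inputs are rejected", {
  expect_error(convolve2d(matrix(c(1, NA, 1, 1), 2, 2), sobel_kernel("v")),
               "non-finite")
  expect_error(convolve2d(matrix(1, 2, 2), sobel_kernel("v")), "larger")
  expect_error(sobel_magnitude(matrix(1, 2, 5)), "at least")
  expect_error(convolve2d(matrix(1, 5, 5), matrix(1, 2, 3)), "odd")
})
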
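# brute-force direct-summation 2D convolution, written independently of the
# package implementation: h(n) = sum_k f(k) g(n - k), zero outside the image
conv_oracle <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1) %/% 2; cc <- (kc + 1) %/% 2
  out <- matrix(0, nr, nc)
  for (n1 in seq_len(nr)) {
    for (n2 in seq_len(nc)) {
      acc <- 0
      for (i in seq_len(kr)) {
        for (j in seq_len(kc)) {
          k1 <- n1 - (i - cr)
          k2 <- n2 - (j - cc)
          if (k1 >= 1 && k1 <= nr && k2 >= 1 && k2 <= nc) {
            acc <- acc + img[k1, k2] * kernel[i, j]
          }
        }
      }
      out[n1, n2] <- acc
    }
  }
  out
}

# model-II slope by explicit eigen decomposition of the 2x2 covariance:
# the major axis is the first principal eigenvector
ma_eigen_oracle <- function(x, y) {
  ev <- eigen(stats::cov(cbind(x, y)))
  v <- ev$vectors[, 1L]
  v[2L] / v[1L]
}

# filled axis-aligned rectangle mask
bar_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# X-shaped cross of two 3-px-wide diagonal bars
cross_mask <- function(n = 81, half = 30, w = 1) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1) %/% 2
  for (d in -half:half) {
    for (o in -w:w) {
      m[c0 + d + o, c0 + d] <- TRUE
      m[c0 - d + o, c0 + d] <- TRUE
    }
  }
  m
}

# straight synthetic curve fixtures for reconnection tests: a filament_curve
# along a line through `start` with direction `dir`, sampled per px
line_curve <- function(start, dir, length_px, um_per_px = 0.32, width_um = 4) {
  dir <- dir / sqrt(sum(dir^2))
  tt <- seq(0, length_px, by = 1)
  pts <- cbind(start[1] + tt * dir[1], start[2] + tt * dir[2])
  cv <- fit_spline(pts, smoothing = 0, um_per_px = um_per_px)
  cv$mean_width_um <- width_um
  cv
}

default_scene <- function(seed, ...) {
  generate_scene(scene_config(seed = seed, ...))
}
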
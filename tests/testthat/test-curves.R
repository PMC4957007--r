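test_that("collinear points fit exactly and reproduce the segment", {
  pts <- cbind(seq(2, 51), seq(12, 110, length.out = 50))
  cv <- fit_spline(pts)
  expect_lt(cv$rms, 1e-8)
  chord <- sqrt(sum((pts[50, ] - pts[1, ])^2))
  expect_equal(cv$arc_length_px, chord, tolerance = 1e-6)
})

test_that("points sampled from a cubic are interpolated at smoothing zero", {
  t <- seq(0, 4, length.out = 60)
  pts <- cbind(t^3 - 2 * t^2 + 3, 5 * t)
  cv <- fit_spline(pts, smoothing = 0)
  expect_lt(cv$rms, 1e-8)
})

test_that("jittered circle samples fit within 1 px RMS at the default budget", {
  set.seed(77)
  th <- seq(0, pi, length.out = 150)
  pts <- cbind(60 + 40 * sin(th), 60 + 40 * cos(th)) +
    matrix(rnorm(300, 0, 0.5), ncol = 2)
  cv <- fit_spline(pts)
  expect_lte(cv$rms, 1.0)
})

test_that("arc length calibrates pixel chains to micrometres", {
  cv <- fit_spline(cbind(rep(5, 101), 0:100))
  len <- arc_length(cv)
  expect_equal(unname(len["px"]), 100, tolerance = 1e-6)
  expect_equal(unname(len["um"]), 32, tolerance = 1e-6)
})

test_that("semicircle arc length is within 0.5% of pi r", {
  th <- seq(0, pi, length.out = 400)
  pts <- cbind(80 + 50 * sin(th), 80 + 50 * cos(th))
  cv <- fit_spline(pts, smoothing = 0)
  expect_lt(abs(cv$arc_length_px - pi * 50) / (pi * 50), 0.005)
})

test_that("arc length dominates the endpoint chord", {
  set.seed(13)
  for (i in 1:10) {
    th <- sort(runif(50, 0, 2))
    pts <- cbind(cumsum(runif(50, 0.5, 2)), 20 * sin(th))
    cv <- fit_spline(pts)
    ep <- endpoint_geometry(cv)
    chord <- sqrt((ep$row[2] - ep$row[1])^2 + (ep$col[2] - ep$col[1])^2)
    expect_gte(cv$arc_length_px + 1e-9, chord)
  }
})

test_that("outward endpoint tangents of a horizontal segment point left and right", {
  cv <- fit_spline(cbind(rep(10, 60), 1:60))
  ep <- endpoint_geometry(cv)
  expect_equal(ep$tangent_row, c(0, 0), tolerance = 1e-9)
  expect_equal(ep$tangent_col, c(-1, 1), tolerance = 1e-9)
})

test_that("curvature of a circular arc matches 1/r within 5%", {
  th <- seq(0.2, 2.5, length.out = 200)
  r <- 40
  pts <- cbind(50 + r * sin(th), 50 + r * cos(th))
  cv <- fit_spline(pts, smoothing = 0)
  ep <- endpoint_geometry(cv)
  expect_lt(abs(ep$curvature[1] - 1 / r), 0.05 / r)
  expect_lt(abs(ep$curvature[2] - 1 / r), 0.05 / r)
})

test_that("reversing the point order flips endpoint pairing but keeps outwardness", {
  pts <- cbind(seq(5, 50), 10 + 0.2 * seq(5, 50)^1.2)
  cv <- fit_spline(pts)
  cv_rev <- fit_spline(pts[nrow(pts):1, ])
  a <- endpoint_geometry(cv)
  b <- endpoint_geometry(cv_rev)
  expect_equal(a$row, rev(b$row), tolerance = 1e-6)
  expect_equal(c(a$tangent_row[1], a$tangent_col[1]),
               c(b$tangent_row[2], b$tangent_col[2]), tolerance = 1e-6)
})

test_that("width along a bar and a line is recovered from the distance transform", {
  bar <- bar_mask(30, 220, 13, 17, 10, 209)      # 200 x 5 bar
  cv <- fit_spline(cbind(rep(15, 180), 21:200))
  w <- width_profile(cv, bar)
  expect_equal(w / 0.32, 5, tolerance = 0.1)     # 5 px -> 1.6 um
  expect_equal(w, 1.6, tolerance = 0.16)
  line <- matrix(FALSE, 20, 120)
  line[10, 10:110] <- TRUE
  cvl <- fit_spline(cbind(rep(10, 80), 21:100))
  expect_equal(width_profile(cvl, line) / 0.32, 1, tolerance = 0.1)
  # a curve nowhere near the mask is rejected
  far <- fit_spline(cbind(rep(3, 50), 1:50))
  expect_error(width_profile(far, bar), "outside")
})

test_that("generator filament widths are recovered within 15%", {
  truth <- default_scene(41, n_filaments = 3, n_blobs = 0)
  nr <- truth$config$height_px
  for (f in truth$filaments) {
    m <- matrix(FALSE, nr, truth$config$width_px)
    m[unlist(f$piece_px)] <- TRUE
    cv <- fit_spline(f$backbone)
    w <- width_profile(cv, m)
    expect_lt(abs(w - f$width_um) / f$width_um, 0.15)
  }
})

test_that("fitting is equivariant to translation and rotation", {
  set.seed(99)
  th <- seq(0, 1.5, length.out = 80)
  pts <- cbind(30 + 25 * sin(th), 30 + 25 * cos(th)) +
    matrix(rnorm(160, 0, 0.3), ncol = 2)
  cv <- fit_spline(pts)
  shifted <- fit_spline(pts + matrix(rep(c(7, -4), each = 80), ncol = 2))
  expect_equal(shifted$arc_length_px, cv$arc_length_px, tolerance = 1e-6)
  rotated <- fit_spline(cbind(pts[, 2], -pts[, 1]))
  expect_equal(rotated$arc_length_px, cv$arc_length_px, tolerance = 1e-6)
})

test_that("short paths fall back to flagged polylines", {
  cv <- fit_spline(rbind(c(1, 1), c(4, 5), c(9, 9)))
  expect_equal(cv$degree, 1L)
  expect_equal(cv$flagged, "polyline")
  expect_equal(cv$arc_length_px, 5 + sqrt(41), tolerance = 1e-9)
  # coincident consecutive points are deduplicated first
  cv2 <- fit_spline(rbind(c(1, 1), c(1, 1), c(4, 5), c(4, 5), c(9, 9)))
  expect_equal(cv2$arc_length_px, cv$arc_length_px, tolerance = 1e-9)
})

test_that("the fitted residual respects the smoothing budget", {
  set.seed(55)
  pts <- cbind(seq(1, 120), 30 + 10 * sin(seq(0, 4, length.out = 120))) +
    matrix(rnorm(240, 0, 0.4), ncol = 2)
  for (budget in c(120 * 0.25, 60, 200)) {
    cv <- fit_spline(pts, smoothing = budget)
    expect_lte(cv$rms^2 * nrow(pts), budget + 1e-6)
  }
})
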
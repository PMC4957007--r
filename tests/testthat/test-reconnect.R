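test_that("two collinear segments with a small gap give exactly one candidate", {
  a <- line_curve(c(50, 10), c(0, 1), 60)
  b <- line_curve(c(50, 85), c(0, 1), 60)    # 15 px gap, collinear
  cand <- candidate_joins(list(a, b))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gap_um, 15 * 0.32, tolerance = 1e-6)
  expect_lt(cand$angle_a_deg, 5)
})

test_that("far perpendicular segments give no candidates", {
  a <- line_curve(c(20, 10), c(0, 1), 60)
  b <- line_curve(c(120, 300), c(1, 0), 60)
  expect_equal(nrow(candidate_joins(list(a, b))), 0L)
})

test_that("straight-through pairing at a crossing is cheaper than the bent one", {
  ctr <- c(100, 100)
  n <- line_curve(ctr, c(-1, 0), 60)   # branch pointing north, junction at ctr
  s <- line_curve(ctr, c(1, 0), 60)
  e <- line_curve(ctr, c(0, 1), 60)
  w <- line_curve(ctr, c(0, -1), 60)
  cand <- candidate_joins(list(n, s, e, w))
  pair_key <- paste(cand$curve_a, cand$curve_b)
  straight <- cand$cost[pair_key %in% c("1 2", "3 4")]
  bent <- cand$cost[!pair_key %in% c("1 2", "3 4")]
  expect_true(all(max(straight) < bent))
})

test_that("three collinear fragments chain-merge into one curve", {
  frags <- list(
    line_curve(c(40, 10), c(0, 1), 80),
    line_curve(c(40, 110), c(0, 1), 80),
    line_curve(c(40, 210), c(0, 1), 80)
  )
  res <- resolve_joins(frags)
  expect_equal(length(res$curves), 1L)
  expect_equal(res$record$n_joined, 2L)
  expect_gte(res$record$n_break_events, res$record$n_joined)
  # total length grows to cover the bridged gaps
  expect_gte(res$curves[[1]]$arc_length_px, 80 * 3)
})

test_that("an X crossing resolves into two curves through the junction", {
  ctr <- c(100, 100)
  branches <- list(
    line_curve(ctr, c(-1, -0.15), 60), line_curve(ctr, c(1, 0.15), 60),
    line_curve(ctr, c(-0.15, 1), 60), line_curve(ctr, c(0.15, -1), 60)
  )
  res <- resolve_joins(branches)
  expect_equal(length(res$curves), 2L)
  expect_equal(res$record$n_joined, 2L)
})

test_that("a curve is never joined to itself", {
  th <- seq(0, 1.9 * pi, length.out = 300)
  pts <- cbind(100 + 40 * sin(th), 100 + 40 * cos(th))  # near-closed loop
  cv <- fit_spline(pts, smoothing = 0)
  cv$mean_width_um <- 4
  expect_equal(nrow(candidate_joins(list(cv))), 0L)
  res <- resolve_joins(list(cv))
  expect_equal(length(res$curves), 1L)
  expect_equal(res$record$n_joined, 0L)
})

test_that("joins never increase the filament count and never lose length", {
  frags <- list(
    line_curve(c(40, 10), c(0, 1), 80),
    line_curve(c(40, 110), c(0, 1), 80),
    line_curve(c(140, 10), c(0.3, 1), 90)
  )
  before_len <- sum(vapply(frags, function(cv) cv$arc_length_px, numeric(1)))
  res <- resolve_joins(frags)
  expect_lte(length(res$curves), length(frags))
  after_len <- sum(vapply(res$curves, function(cv) cv$arc_length_px,
                          numeric(1)))
  expect_gte(after_len + 1e-6, before_len)
})

test_that("resolution is deterministic", {
  mk <- function() list(
    line_curve(c(40, 10), c(0, 1), 80),
    line_curve(c(40, 110), c(0, 1), 80),
    line_curve(c(80, 10), c(0, 1), 50),
    line_curve(c(80, 80), c(0, 1), 50)
  )
  r1 <- resolve_joins(mk())
  r2 <- resolve_joins(mk())
  expect_identical(r1$record, r2$record)
  expect_equal(vapply(r1$curves, function(cv) cv$arc_length_px, numeric(1)),
               vapply(r2$curves, function(cv) cv$arc_length_px, numeric(1)))
})

test_that("pooled reconstruction rate is joined over events with NA degenerate", {
  recs <- data.frame(n_joined = c(2, 2, 2), n_break_events = c(2, 2, 4))
  expect_equal(reconstruction_rate(recs), 75)
  zero <- data.frame(n_joined = c(0, 0), n_break_events = c(0, 0))
  expect_true(is.na(reconstruction_rate(zero)))
  expect_error(reconstruction_rate(data.frame()), "records")
  tab <- data.frame(rec_joined = c(1, 3), rec_events = c(2, 3))
  expect_equal(reconstruction_rate(tab), 80)
})

test_that("reconnection is the identity on clean scenes", {
  for (s in c(2, 4)) {
    truth <- default_scene(s, n_filaments = 8, n_blobs = 0)
    rep <- process_scene(render_scene(truth), pipeline_config())
    expect_equal(rep$summary$rec_joined, 0L)
    expect_equal(rep$summary$a_count, truth$n_filaments)
  }
})

test_that("inserted gaps are bridged and fragments reunited", {
  truth <- default_scene(104, n_filaments = 20, n_breaks = 10, n_blobs = 0)
  rep <- process_scene(render_scene(truth), pipeline_config())
  expect_equal(rep$summary$a_count, truth$n_filaments)
  expect_gte(rep$summary$rec_joined, 8L)
  expect_gte(rep$summary$rec_events, rep$summary$rec_joined)
})
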
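test_that("a perfect identity relation fits slope 1, intercept 0, r2 1", {
  d <- data.frame(x = c(1, 3, 7, 9, 12), y = c(1, 3, 7, 9, 12))
  fit <- major_axis_fit(d, x, y, n_perm = 0)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n, 5L)
})

test_that("degenerate inputs are rejected", {
  expect_error(major_axis_fit(data.frame(x = 1:2, y = 2:3), x, y), "3 points")
  expect_error(major_axis_fit(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "variance")
  expect_error(
    major_axis_fit(data.frame(x = c(-1, 0, 1), y = c(1, -2, 1)), x, y,
                   n_perm = 0),
    "covariance")
})

test_that("axis swap reciprocity and scale equivariance hold", {
  set.seed(31)
  for (i in 1:25) {
    d <- data.frame(x = rnorm(12), y = rnorm(12))
    f_xy <- major_axis_fit(d, x, y, n_perm = 0)
    f_yx <- major_axis_fit(d, y, x, n_perm = 0)
    expect_equal(f_xy$slope * f_yx$slope, 1, tolerance = 1e-9)
    s <- major_axis_fit(dplyr::mutate(d, x = 3.7 * x, y = 3.7 * y), x, y,
                        n_perm = 0)
    expect_equal(s$slope, f_xy$slope, tolerance = 1e-9)
    expect_equal(s$r2, f_xy$r2, tolerance = 1e-12)
  }
})

test_that("the slope equals the covariance eigenvector oracle", {
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(15)
    y <- 0.8 * x + rnorm(15, 0, runif(1, 0.1, 2))
    fit <- major_axis_fit(data.frame(x, y), x, y, n_perm = 0)
    expect_equal(fit$slope, ma_eigen_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("r2 is 1 exactly when the points are collinear", {
  d <- data.frame(x = c(1, 2, 5, 9), y = 3 - 2 * c(1, 2, 5, 9))
  expect_equal(major_axis_fit(d, x, y, n_perm = 0)$r2, 1, tolerance = 1e-12)
  set.seed(2)
  noisy <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_lt(major_axis_fit(noisy, x, y, n_perm = 0)$r2, 1)
})

test_that("permutation p-values are deterministic and detect strong relations", {
  d <- validation_table() |> dplyr::filter(station == "Caprarola")
  f1 <- major_axis_fit(d, manual_count, a_count, n_perm = 999)
  f2 <- major_axis_fit(d, manual_count, a_count, n_perm = 999)
  expect_equal(f1$p_value, f2$p_value)
  expect_lt(f1$p_value, 0.01)
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- data.frame(m = c(2, 4, 7, 8, 11), a = c(2.2, 3.7, 7.5, 7.8, 11.4))
  fit <- major_axis_fit(d, m, a, n_perm = 0)
  td <- tidy(fit)
  expect_equal(td$term, c("slope", "intercept"))
  gl <- glance(fit)
  expect_equal(gl$n, 5L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the packaged validation table obeys its schema and invariants", {
  tab <- validation_table()
  expect_equal(nrow(tab), 40L)
  expect_equal(as.integer(table(tab$station)), rep(10L, 4))
  expect_true(all(tab$rec_joined <= tab$rec_events))
  expect_true(all(tab$afil_aobj_pct >= 0 & tab$afil_aobj_pct <= 100))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(station = "x", image_no = 1), bad, row.names = FALSE)
  expect_error(read_comparison_table(bad), "lacks columns")
})

test_that("station fits recover the reference agreement statistics of the validation campaign", {
  fits <- station_fit_suite(validation_table())
  expect_equal(nrow(fits), 8L)
  nemi <- fits[fits$station == "Nemi" & fits$response == "abundance", ]
  expect_equal(round(nemi$slope, 2), 0.75)
  expect_equal(round(nemi$r2, 2), 0.72)
  capr <- fits[fits$station == "Caprarola" & fits$response == "abundance", ]
  expect_equal(round(capr$slope, 2), 0.99)
  expect_equal(round(capr$r2, 2), 0.97)
})

test_that("a station with identical manual and automated columns fits exactly", {
  tab <- validation_table()
  tab$a_count <- tab$manual_count
  tab$a_tl_um <- tab$manual_tl_um
  fits <- station_fit_suite(tab)
  expect_true(all(abs(fits$slope - 1) < 1e-9))
  expect_true(all(abs(fits$r2 - 1) < 1e-9))
})

test_that("pooled summaries handle zero denominators as missing", {
  tab <- validation_table()
  tab$rec_events <- 0L
  tab$rec_joined <- 0L
  ps <- pooled_summaries(tab)
  expect_true(is.na(ps$overall$reconstruction_pct))
  tab$fil_obj <- 0L
  ps2 <- pooled_summaries(tab)
  expect_true(all(is.na(ps2$by_station$pooled_interest_fraction_pct)))
})
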
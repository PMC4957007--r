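test_that("otsu thresholding separates a bimodal image exactly", {
  set.seed(3)
  img <- matrix(0, 20, 20)
  ones <- sample(400, 120)
  img[ones] <- 1
  mask <- binarize(img, "otsu")
  expect_equal(which(mask), sort(ones))
  # all-zero image: empty mask, no failure
  expect_false(any(binarize(matrix(0, 8, 8), "otsu")))
})

test_that("noisy two-level image is recovered to at least 99% pixel agreement", {
  set.seed(21)
  truth <- matrix(FALSE, 40, 40)
  truth[10:30, 5:35] <- TRUE
  img <- ifelse(truth, 0.9, 0.1) + rnorm(1600, 0, 0.02)
  img <- pmin(pmax(img, 0), 1)
  for (method in c("otsu", "triangle")) {
    mask <- binarize(img, method)
    expect_gte(mean(mask == truth), 0.99)
  }
})

test_that("fixed thresholding requires a threshold", {
  expect_error(binarize(matrix(0.5, 4, 4), "fixed"), "threshold")
  expect_true(all(binarize(matrix(0.5, 4, 4), "fixed", threshold = 0.5)))
})

test_that("labeling counts components and filters small ones", {
  m <- matrix(FALSE, 50, 50)
  m[5:14, 5:14] <- TRUE        # 100 px blob
  m[30:39, 30:39] <- TRUE      # 100 px blob
  objs <- label_objects(m, min_object_area = 30)
  expect_equal(nrow(objs$objects), 2L)
  expect_equal(sort(unique(as.vector(objs$label_map))), c(0L, 1L, 2L))
  m2 <- matrix(FALSE, 20, 20)
  m2[10, 8:10] <- TRUE         # 3 px
  expect_equal(nrow(label_objects(m2, min_object_area = 10)$objects), 0L)
})

test_that("generator scenes label exactly the number of rendered objects", {
  truth <- default_scene(31, n_filaments = 4, n_blobs = 6)
  img <- render_scene(truth)
  rep <- process_scene(img, pipeline_config(), keep_intermediates = TRUE)
  objs <- attr(rep, "intermediates")$objects
  expect_equal(nrow(objs$objects), 4L + 6L)
})

test_that("elongation separates filaments from compact objects", {
  bar <- bar_mask(40, 220, 18, 21, 10, 209)      # 200 x 4 bar
  objs <- classify_objects(label_objects(bar), min_elongation = 5,
                           min_length_um = 50, um_per_px = 0.32)
  expect_true(objs$objects$is_filamentous[1])
  expect_gt(objs$objects$elongation[1], 5)

  disc <- matrix(FALSE, 40, 40)
  ctr <- expand.grid(r = 1:40, c = 1:40)
  disc[as.matrix(ctr[(ctr$r - 20)^2 + (ctr$c - 20)^2 <= 100, ])] <- TRUE
  objs_d <- classify_objects(label_objects(disc))
  expect_false(objs_d$objects$is_filamentous[1])

  expect_error(classify_objects(label_objects(bar), um_per_px = 0),
               "positive")
})

test_that("area fractions are plain arithmetic with NA degenerate case", {
  m <- matrix(FALSE, 60, 260)
  m[28:31, 10:249] <- TRUE     # 240x4 of-interest bar, 960 px
  m[10:17, 10:17] <- TRUE      # 64 px square noise (but >= min area)
  objs <- classify_objects(label_objects(m, min_object_area = 30))
  fr <- area_fractions(objs)
  o <- objs$objects
  expect_equal(fr$filamentous_area_fraction,
               100 * sum(o$area_px[o$is_filamentous]) / sum(o$area_px))
  expect_true(fr$filament_area_fraction >= 0 &&
                fr$filament_area_fraction <= 100)
  # every object of interest -> 100%  (bar wide enough for the width band)
  only <- classify_objects(label_objects(bar_mask(40, 260, 14, 23, 10, 249)))
  expect_equal(area_fractions(only)$filament_area_fraction, 100)
  # no objects -> undefined, reported as NA, not 0
  none <- label_objects(matrix(FALSE, 10, 10))
  expect_true(is.na(area_fractions(none)$filament_area_fraction))
})

test_that("raising min_elongation never increases the filamentous count", {
  truth <- default_scene(17, n_filaments = 5, n_blobs = 15)
  rep <- process_scene(render_scene(truth), pipeline_config(),
                       keep_intermediates = TRUE)
  objs <- attr(rep, "intermediates")$objects
  counts <- vapply(c(1, 3, 5, 10, 30), function(e)
    sum(classify_objects(objs, min_elongation = e)$objects$is_filamentous),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("area fractions are invariant to translation and rotation of the scene", {
  m <- matrix(FALSE, 80, 80)
  m[10:13, 5:70] <- TRUE       # bar
  m[40:47, 40:47] <- TRUE      # square
  frac <- function(mask) {
    area_fractions(classify_objects(label_objects(mask)))$filamentous_area_fraction
  }
  f0 <- frac(m)
  shifted <- matrix(FALSE, 80, 80)
  shifted[(10:47) + 20, ] <- m[10:47, ]
  expect_equal(frac(shifted), f0)
  expect_equal(frac(t(m)[ncol(m):1, ]), f0)
})

test_that("removing a noise object leaves surviving objects' features unchanged", {
  m <- matrix(FALSE, 60, 200)
  m[28:31, 10:150] <- TRUE
  m[8:15, 170:177] <- TRUE
  both <- object_features(label_objects(m))
  alone <- object_features(label_objects(m & row(m) > 20))
  b <- both$objects[both$objects$area_px > 200, ]
  a <- alone$objects[1, ]
  expect_equal(b$skeleton_length_px, a$skeleton_length_px)
  expect_equal(b$mean_width_px, a$mean_width_px)
})
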
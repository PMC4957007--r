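#' Threshold a normalized gradient image
#'
#' Produces a binary foreground mask from an edge-energy image on `[0, 1]`.
#' `method = "otsu"` selects the threshold by Otsu's between-class variance
#' criterion; `method = "triangle"` uses the triangle (Zack) construction on
#' the intensity histogram, which is the more robust choice for edge-energy
#' images whose histogram is a large near-zero background mode with a long
#' bright tail (Otsu then tends to split the tail rather than separate it
#' from the background); `method = "fixed"` uses the supplied value. An
#' optional Gaussian pre-smoothing can be applied before thresholding, since
#' edge-energy images of noisy micrographs are sometimes easier to threshold
#' after slight smoothing; it is off by default.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param method `"otsu"`, `"triangle"` or `"fixed"`.
#' @param threshold Threshold in `[0, 1]`; required for `method = "fixed"`.
#' @param presmooth_sigma Standard deviation (px) of an optional Gaussian
#'   smoothing applied before thresholding; `0` disables it.
#' @return A logical matrix, `TRUE` where intensity >= threshold.
#' @export
binarize <- function(img, method = c("otsu", "triangle", "fixed"),
                     threshold = NULL, presmooth_sigma = 0) {
  method <- match.arg(method)
  validate_gray(img)
  if (presmooth_sigma > 0) {
    img <- from_ebimage(EBImage::gblur(as_ebimage(img), sigma = presmooth_sigma))
  }
  if (method == "fixed") {
    if (is.null(threshold)) {
      stop("method = \"fixed\" requires a threshold", call. = FALSE)
    }
    thr <- threshold
  } else {
    if (max(img) <= min(img)) {
      # constant image: nothing to separate
      return(matrix(FALSE, nrow(img), ncol(img)))
    }
    thr <- if (method == "otsu") {
      EBImage::otsu(as_ebimage(img), range = c(0, 1))
    } else {
      triangle_threshold(img)
    }
  }
  img >= thr
}

# triangle (Zack) threshold on a 256-bin histogram: maximal distance between
# the histogram and the chord from its peak to the far end of its tail
triangle_threshold <- function(img, n_bins = 256L) {
  h <- tabulate(pmin(floor(img * n_bins) + 1L, n_bins), nbins = n_bins)
  peak <- which.max(h)
  nz <- which(h > 0L)
  tail_end <- if (max(nz) > peak) max(nz) else min(nz)
  if (tail_end == peak) return(peak / n_bins)
  span <- if (tail_end > peak) peak:tail_end else tail_end:peak
  # distance from (bin, count) to the peak-to-tail chord
  x1 <- peak; y1 <- h[peak]; x2 <- tail_end; y2 <- h[tail_end]
  d <- abs((y2 - y1) * span - (x2 - x1) * h[span] + x2 * y1 - y2 * x1)
  (span[which.max(d)] + 0.5) / n_bins
}

#' Label connected foreground objects
#'
#' Applies a morphological closing (to seal the thin outlines that
#' gradient-magnitude segmentation produces around objects), optionally fills
#' enclosed holes so object areas refer to whole particles rather than their
#' outlines, optionally smooths object boundaries with an opening (ragged
#' boundaries otherwise sprout skeleton spurs), labels 8-connected
#' components, and discards components below a minimum area.
#'
#' @param mask Logical or 0/1 matrix.
#' @param min_object_area Minimum component area in pixels (default 30 px; at
#'   0.32 um/px this is under 10 um^2, far below any filament of interest).
#' @param closing_radius Radius (px) of the disc structuring element for the
#'   closing; `0` disables it.
#' @param fill_holes Fill enclosed background holes before labeling.
#' @param opening_radius Radius (px) of a boundary-smoothing opening applied
#'   after hole filling; `0` disables it.
#' @return An object of class `labeled_objects`: a list with `label_map`
#'   (integer matrix, 0 = background, labels consecutive) and `objects`, a
#'   tibble with one row per object (`label`, `area_px`, `touches_border`).
#' @export
label_objects <- function(mask, min_object_area = 30, closing_radius = 1,
                          fill_holes = TRUE, opening_radius = 0) {
  m <- mask * 1
  storage.mode(m) <- "double"
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    m <- from_ebimage(EBImage::closing(as_ebimage(m), brush))
  }
  img <- as_ebimage(m)
  if (fill_holes) img <- EBImage::fillHull(img)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    img <- EBImage::opening(img, brush)
  }
  lab <- from_ebimage(EBImage::bwlabel(img))
  storage.mode(lab) <- "integer"
  keep <- which(tabulate(lab[lab > 0L]) >= min_object_area)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  objects <- object_table(lab)
  structure(list(label_map = lab, objects = objects),
            class = "labeled_objects")
}

# thin each labeled object inside its own bounding box (thinning cost scales
# with box area, and objects cover a small fraction of a field of view)
skeletonize_objects <- function(lab) {
  out <- matrix(FALSE, nrow(lab), ncol(lab))
  n <- max(lab, 0L)
  if (n == 0L) return(out)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[idx]
  for (l in seq_len(n)) {
    px <- idx[labs == l, , drop = FALSE]
    if (nrow(px) == 0L) next
    r0 <- max(1L, min(px[, 1L]) - 1L); r1 <- min(nrow(lab), max(px[, 1L]) + 1L)
    c0 <- max(1L, min(px[, 2L]) - 1L); c1 <- min(ncol(lab), max(px[, 2L]) + 1L)
    sub <- lab[r0:r1, c0:c1] == l
    sk <- skeletonize(sub)
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] | sk
  }
  out
}

# base per-object bookkeeping from a label map
object_table <- function(lab) {
  n <- max(lab, 0L)
  if (n == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  touches_border = logical()))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  tibble(
    label = seq_len(n),
    area_px = as.integer(areas),
    touches_border = seq_len(n) %in% border[border > 0L]
  )
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat("<labeled_objects> ", nrow(x$objects), " objects in ",
      nrow(x$label_map), "x", ncol(x$label_map), " px label map\n", sep = "")
  print(x$objects, ...)
  invisible(x)
}

#' Compute skeleton-based shape features for labeled objects
#'
#' Adds per-object skeleton length, mean width (from the Euclidean distance
#' transform sampled along the skeleton; for a ribbon of width w the medial
#' distance is (w+1)/2 px, hence width = 2 d - 1) and elongation
#' (skeleton length / mean width) to the object table.
#'
#' @param objs A `labeled_objects` object.
#' @return The `labeled_objects` with columns `skeleton_length_px`,
#'   `mean_width_px` and `elongation` added to `$objects`.
#' @export
object_features <- function(objs) {
  stopifnot(inherits(objs, "labeled_objects"))
  lab <- objs$label_map
  mask <- lab > 0L
  n <- nrow(objs$objects)
  if (n == 0L) {
    objs$objects$skeleton_length_px <- numeric()
    objs$objects$mean_width_px <- numeric()
    objs$objects$elongation <- numeric()
    return(objs)
  }
  skel <- skeletonize_objects(lab)
  dist <- from_ebimage(EBImage::distmap(as_ebimage(mask * 1)))
  attr(objs, "skeleton") <- skel
  attr(objs, "distmap") <- dist
  sk_lab <- lab[skel]
  sk_dist <- dist[skel]
  len <- vapply(seq_len(n), function(l) sum(sk_lab == l), numeric(1))
  wid <- vapply(seq_len(n), function(l) {
    d <- sk_dist[sk_lab == l]
    if (length(d) == 0L) max(dist[lab == l]) else mean(d)
  }, numeric(1))
  wid <- pmax(2 * wid - 1, 1)
  objs$objects$skeleton_length_px <- len
  objs$objects$mean_width_px <- wid
  objs$objects$elongation <- ifelse(wid > 0, len / wid, 0)
  # bias-corrected area: edge-energy segmentation dilates every object by
  # a few pixels of edge band; eroding by that margin (counting pixels
  # deeper than 3 px) recovers areas close to the underlying particles'
  deep <- dist > 3
  objs$objects$area_corrected_px <- vapply(seq_len(n), function(l)
    sum(lab[deep] == l), numeric(1))
  objs
}

#' Classify objects as filamentous and as filaments of interest
#'
#' Two-tier classification: an object is *filamentous* when its elongation
#' (skeleton length over mean width) reaches `min_elongation`; a filamentous
#' object is *of interest* when additionally its skeleton length reaches
#' `min_length_um` and its mean width falls inside `width_range_um`. The
#' defaults separate trichomes of common planktic toxigenic genera from cells
#' and detritus; all are configurable.
#'
#' @param objs A `labeled_objects` object (features are computed if missing).
#' @param min_elongation Minimum elongation for a filamentous object.
#' @param min_length_um Minimum skeleton length (um) for a filament of
#'   interest.
#' @param width_range_um Length-2 numeric, admissible mean width band (um).
#' @param um_per_px Calibration, micrometres per pixel (> 0).
#' @return The `labeled_objects` with logical columns `is_filamentous` and
#'   `is_of_interest` added to `$objects`.
#' @export
classify_objects <- function(objs, min_elongation = 5, min_length_um = 50,
                             width_range_um = c(2, 12), um_per_px = 0.32) {
  stopifnot(inherits(objs, "labeled_objects"))
  if (!is.numeric(um_per_px) || um_per_px <= 0) {
    stop("um_per_px must be positive", call. = FALSE)
  }
  if (is.null(objs$objects[["elongation"]])) objs <- object_features(objs)
  o <- objs$objects
  len_um <- o$skeleton_length_px * um_per_px
  wid_um <- o$mean_width_px * um_per_px
  o$is_filamentous <- o$elongation >= min_elongation
  o$is_of_interest <- o$is_filamentous &
    len_um >= min_length_um &
    wid_um >= width_range_um[1L] & wid_um <= width_range_um[2L]
  objs$objects <- o
  objs
}

#' Area and count fractions of filamentous objects
#'
#' `filament_area_fraction` is the percentage of total object area contributed
#' by filaments of interest; `filamentous_area_fraction` the same for all
#' filamentous objects (the Afil/Aobj statistic of the validation table);
#' `filamentous_object_fraction` is the percentage of objects (by count) that
#' are filamentous. With no objects all fractions are undefined and reported
#' as `NA`, not 0.
#'
#' @param objs A classified `labeled_objects`.
#' @param corrected Use the dilation-corrected object areas (see
#'   [object_features()]) when available; raw pixel areas otherwise.
#' @return A one-row tibble with columns `filament_area_fraction`,
#'   `filamentous_area_fraction`, `filamentous_object_fraction`, all percent.
#' @export
area_fractions <- function(objs, corrected = FALSE) {
  stopifnot(inherits(objs, "labeled_objects"))
  o <- objs$objects
  if (nrow(o) == 0L || is.null(o[["is_filamentous"]])) {
    if (nrow(o) > 0L) stop("objects must be classified first", call. = FALSE)
    return(tibble(filament_area_fraction = NA_real_,
                  filamentous_area_fraction = NA_real_,
                  filamentous_object_fraction = NA_real_))
  }
  area <- if (corrected && !is.null(o[["area_corrected_px"]])) {
    o$area_corrected_px
  } else {
    o$area_px
  }
  total <- sum(area)
  if (total == 0) total <- 1
  tibble(
    filament_area_fraction = 100 * sum(area[o$is_of_interest]) / total,
    filamentous_area_fraction = 100 * sum(area[o$is_filamentous]) / total,
    filamentous_object_fraction = 100 * mean(o$is_filamentous)
  )
}
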
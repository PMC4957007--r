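#' Pipeline configuration
#'
#' Bundles every tunable parameter of the processing chain with its default.
#' All defaults are documented on the stage functions; the configuration can
#' be round-tripped through YAML with [write_config()] / [read_config()].
#'
#' @param um_per_px Calibration, micrometres per pixel.
#' @param threshold_method `"triangle"`, `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (only used with `"fixed"`).
#' @param presmooth_sigma Gaussian sigma before thresholding (0 = off).
#' @param min_object_area Minimum object area, px.
#' @param closing_radius Morphological closing radius, px.
#' @param opening_radius Boundary-smoothing opening radius, px.
#' @param min_elongation Filamentous-object elongation gate.
#' @param min_length_um,width_range_um Filament-of-interest gates.
#' @param prune_px Skeleton spur-pruning length, px.
#' @param smoothing Spline smoothing budget (`NULL` = default rule).
#' @param max_gap_um,max_angle_deg,width_ratio_max Reconnection gates.
#' @param border_margin_px Width (px) of the frame border zeroed in the
#'   edge-energy image before thresholding. The zero-padded convolution makes
#'   the frame border an artificial strong edge; discarding this margin keeps
#'   it out of the normalization and the mask.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(um_per_px = 0.32,
                            threshold_method = "triangle",
                            threshold = NULL,
                            presmooth_sigma = 1.5,
                            min_object_area = 30,
                            closing_radius = 2,
                            opening_radius = 2,
                            min_elongation = 5,
                            min_length_um = 50,
                            width_range_um = c(2, 12),
                            prune_px = 8,
                            smoothing = NULL,
                            max_gap_um = 15,
                            max_angle_deg = 30,
                            width_ratio_max = 1.8,
                            border_margin_px = 2) {
  cfg <- list(um_per_px = um_per_px, threshold_method = threshold_method,
              threshold = threshold, presmooth_sigma = presmooth_sigma,
              min_object_area = min_object_area,
              closing_radius = closing_radius,
              opening_radius = opening_radius,
              min_elongation = min_elongation,
              min_length_um = min_length_um,
              width_range_um = width_range_um, prune_px = prune_px,
              smoothing = smoothing, max_gap_um = max_gap_um,
              max_angle_deg = max_angle_deg,
              width_ratio_max = width_ratio_max,
              border_margin_px = border_margin_px)
  if (cfg$um_per_px <= 0) stop("um_per_px must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(v)) "default" else paste(v, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Process one grayscale scene matrix through the full chain
#'
#' Runs preprocessing (Sobel gradient magnitude), segmentation, object
#' classification, skeleton tracing, spline parameterization, reconnection
#' and measurement, and returns the per-FOV report. Deterministic given the
#' image and configuration.
#'
#' @param img Numeric matrix on `[0, 1]` (row, col orientation).
#' @param config A `pipeline_config`.
#' @param image_id Identifier for the report.
#' @param keep_intermediates If `TRUE`, attach gradient, mask, objects,
#'   graph and curves to the result as attribute `"intermediates"`.
#' @return A `fov_report`.
#' @export
process_scene <- function(img, config = pipeline_config(),
                          image_id = "scene", keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_gray(img, min_dim = 3L)
  calib <- calibration(config$um_per_px, ncol(img), nrow(img))
  grad <- sobel_magnitude(img)
  H <- grad$H
  b <- config$border_margin_px
  if (b > 0) {
    nr <- nrow(H); nc <- ncol(H)
    H[c(seq_len(b), nr - seq_len(b) + 1L), ] <- 0
    H[, c(seq_len(b), nc - seq_len(b) + 1L)] <- 0
  }
  # a featureless image leaves only floating-point residue in H; do not let
  # normalization blow that up to full scale
  if (max(H) < 1e-9) H[] <- 0
  H <- normalize_gradient(H)
  mask <- binarize(H, method = config$threshold_method,
                   threshold = config$threshold,
                   presmooth_sigma = config$presmooth_sigma)
  objs <- label_objects(mask, min_object_area = config$min_object_area,
                        closing_radius = config$closing_radius,
                        opening_radius = config$opening_radius)
  if (nrow(objs$objects) == 0L) {
    rep <- measure_fov(list(), NULL, NULL, calib, image_id)
    if (keep_intermediates) {
      attr(rep, "intermediates") <- list(gradient = grad, mask = mask,
                                         objects = objs, curves = list())
    }
    return(rep)
  }
  objs <- classify_objects(objs, min_elongation = config$min_elongation,
                           min_length_um = config$min_length_um,
                           width_range_um = config$width_range_um,
                           um_per_px = config$um_per_px)
  skel <- attr(objs, "skeleton")
  dist <- attr(objs, "distmap")
  graph <- build_graph(skel, prune_px = config$prune_px)
  paths <- split_at_junctions(graph)
  paths <- Filter(function(p) nrow(p) >= 2L, paths)
  lab <- objs$label_map
  obj_mask <- lab > 0L
  curves <- lapply(paths, function(p) {
    src <- lab[p[1L, 1L], p[1L, 2L]]
    # march free skeleton ends on to the object boundary, undoing the
    # end erosion of thinning; the path then runs cap tip to cap tip
    kinds <- attr(p, "end_kinds") %||% c("endpoint", "endpoint")
    caps <- kinds == "endpoint"
    if (caps[1L]) p <- extend_path_end(p, obj_mask, 1L)
    if (caps[2L]) p <- extend_path_end(p, obj_mask, 2L)
    cv <- fit_spline(p, smoothing = config$smoothing,
                     um_per_px = config$um_per_px)
    cv$source_ids <- src
    cv$end_cap <- caps
    cv$mean_width_um <- tryCatch(
      width_from_distmap(cv, dist, config$um_per_px),
      error = function(e) NA_real_)
    cv
  })
  res <- resolve_joins(curves, max_gap_um = config$max_gap_um,
                       max_angle_deg = config$max_angle_deg,
                       width_ratio_max = config$width_ratio_max,
                       um_per_px = config$um_per_px,
                       smoothing = config$smoothing)
  final <- classify_curves(res$curves, min_length_um = config$min_length_um,
                           width_range_um = config$width_range_um)
  rep <- measure_fov(final, objs, res$record, calib, image_id)
  if (keep_intermediates) {
    attr(rep, "intermediates") <- list(gradient = grad, mask = mask,
                                       objects = objs, graph = graph,
                                       curves = final)
  }
  rep
}

#' Process a micrograph file
#'
#' @param path Path to a TIFF/PNG micrograph.
#' @param config A `pipeline_config`.
#' @return A `fov_report` (the file name becomes the image id).
#' @export
process_image <- function(path, config = pipeline_config()) {
  img <- read_micrograph(path)
  process_scene(img, config, image_id = basename(path))
}

#' Batch-process a directory of micrographs
#'
#' Processes every TIFF/PNG in `dir` (or an explicit vector of paths) in
#' stable filename order; unreadable files are skipped with a warning and the
#' batch continues.
#'
#' @param dir Directory of images, or a character vector of file paths.
#' @param config A `pipeline_config`.
#' @return A tibble with one [fov_csv_row()] per successfully processed image.
#' @export
batch_process <- function(dir, config = pipeline_config()) {
  paths <- if (length(dir) == 1L && dir.exists(dir)) {
    list.files(dir, pattern = "\\.(tiff?|png)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    dir
  }
  paths <- sort(paths)
  if (length(paths) == 0L) stop("no images to process", call. = FALSE)
  rows <- lapply(paths, function(p) {
    tryCatch(fov_csv_row(process_image(p, config)),
             error = function(e) {
               warning("skipping ", p, ": ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
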
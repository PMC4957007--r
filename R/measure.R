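#' Microscope calibration
#'
#' Defaults correspond to bright-field imaging at 10x with an 18 Mpx camera:
#' 0.32 um/px and a 5184 x 3456 px field of view.
#'
#' @param um_per_px Micrometres per pixel (> 0).
#' @param fov_width_px,fov_height_px Field-of-view size in pixels.
#' @return An object of class `calibration`.
#' @export
calibration <- function(um_per_px = 0.32, fov_width_px = 5184L,
                        fov_height_px = 3456L) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0) {
    stop("um_per_px must be a positive number", call. = FALSE)
  }
  structure(list(um_per_px = um_per_px,
                 fov_width_px = as.integer(fov_width_px),
                 fov_height_px = as.integer(fov_height_px)),
            class = "calibration")
}

#' Field-of-view area in square millimetres
#'
#' Computed as `width_px * height_px * um_per_px^2 / 1e6`. Note that with the
#' default calibration this gives 1.834 mm^2 while the nominal coverage of
#' the reference setup is usually quoted as 1.82 mm^2; the discrepancy comes
#' from rounding in the quoted resolution, and this function always computes
#' from the calibration.
#'
#' @param calib A `calibration`.
#' @return Area in mm^2.
#' @examples
#' fov_area_mm2(calibration())        # 1.834
#' fov_area_mm2(calibration(1, 1000, 1000))  # 1
#' @export
fov_area_mm2 <- function(calib) {
  stopifnot(inherits(calib, "calibration"))
  calib$fov_width_px * calib$fov_height_px * calib$um_per_px^2 / 1e6
}

#' Flag filaments of interest among reconnected curves
#'
#' A curve is a filament of interest when its arc length reaches
#' `min_length_um` and its mean width lies inside `width_range_um` (curves
#' with unknown width pass the width gate). Classification happens after
#' reconnection so that fragments of an interrupted filament are judged by
#' the length of the recombined filament, not of its pieces.
#'
#' @param curves List of `filament_curve` objects.
#' @param min_length_um Minimum arc length (um).
#' @param width_range_um Admissible width band (um).
#' @return The list with `$is_of_interest` set on each curve.
#' @export
classify_curves <- function(curves, min_length_um = 50,
                            width_range_um = c(2, 12)) {
  lapply(curves, function(cv) {
    w_ok <- is.na(cv$mean_width_um) ||
      (cv$mean_width_um >= width_range_um[1L] &&
       cv$mean_width_um <= width_range_um[2L])
    cv$is_of_interest <- curve_length_um(cv) >= min_length_um && w_ok
    cv
  })
}

#' Assemble the per-FOV morphometric report
#'
#' Collects the automated analogue of one validation-table row from one
#' image: count and total length of filaments of interest, reconnection
#' bookkeeping, number of filamentous objects and the filamentous area
#' fraction, plus a per-filament detail table.
#'
#' @param curves List of curves after [resolve_joins()] and
#'   [classify_curves()].
#' @param objects A classified `labeled_objects` (or `NULL` for an empty
#'   image).
#' @param record Reconnection record tibble (or `NULL`).
#' @param calib A `calibration`.
#' @param image_id Identifier carried into the report.
#' @return An object of class `fov_report`: list with `summary` (one-row
#'   tibble: `image_id`, `a_count`, `a_tl_um`, `rec_joined`, `rec_events`,
#'   `fil_obj`, `afil_aobj_pct`) and `filaments` (tibble with `length_um`,
#'   `width_um`, `touches_border` per filament of interest).
#' @export
measure_fov <- function(curves, objects, record, calib,
                        image_id = "fov") {
  if (!inherits(calib, "calibration")) {
    stop("a calibration is required", call. = FALSE)
  }
  interest <- Filter(function(cv) isTRUE(cv$is_of_interest), curves)
  nr_border <- function(cv) {
    p <- cv$points
    any(p[, 1L] <= 1 | p[, 2L] <= 1 |
        p[, 1L] >= calib$fov_height_px | p[, 2L] >= calib$fov_width_px)
  }
  filaments <- if (length(interest) == 0L) {
    tibble(length_um = numeric(), width_um = numeric(),
           touches_border = logical())
  } else {
    tibble(
      length_um = vapply(interest, curve_length_um, numeric(1)),
      width_um = vapply(interest, function(cv) cv$mean_width_um, numeric(1)),
      touches_border = vapply(interest, nr_border, logical(1))
    )
  }
  afil <- NA_real_
  fil_obj <- 0L
  if (!is.null(objects) && nrow(objects$objects) > 0L) {
    fr <- area_fractions(objects, corrected = TRUE)
    afil <- fr$filamentous_area_fraction
    fil_obj <- sum(objects$objects$is_filamentous)
  }
  summary <- tibble(
    image_id = image_id,
    a_count = nrow(filaments),
    a_tl_um = sum(filaments$length_um),
    rec_joined = if (is.null(record)) 0L else record$n_joined,
    rec_events = if (is.null(record)) 0L else record$n_break_events,
    fil_obj = fil_obj,
    afil_aobj_pct = afil
  )
  structure(list(summary = summary, filaments = filaments,
                 calibration = calib),
            class = "fov_report")
}

#' @export
print.fov_report <- function(x, ...) {
  s <- x$summary
  cat("<fov_report> ", s$image_id, ": ", s$a_count,
      " filaments of interest, total length ", round(s$a_tl_um, 1),
      " um, reconnected ", s$rec_joined, "/", s$rec_events,
      ", ", s$fil_obj, " filamentous objects",
      if (!is.na(s$afil_aobj_pct))
        paste0(", Afil/Aobj ", round(s$afil_aobj_pct, 1), "%"),
      "\n", sep = "")
  invisible(x)
}

#' One CSV row for a FOV report
#'
#' Serializes the report summary with the fixed header
#' `image_id,a_count,a_tl_um,rec_joined,rec_events,fil_obj,afil_aobj_pct`.
#' Total length is rounded to the nearest micrometre (matching the integer
#' lengths of the printed validation tables); full precision stays in the
#' report object.
#'
#' @param report A `fov_report`.
#' @return A one-row tibble with the CSV schema above.
#' @export
fov_csv_row <- function(report) {
  stopifnot(inherits(report, "fov_report"))
  s <- report$summary
  tibble(
    image_id = s$image_id,
    a_count = s$a_count,
    a_tl_um = round(s$a_tl_um),
    rec_joined = s$rec_joined,
    rec_events = s$rec_events,
    fil_obj = s$fil_obj,
    afil_aobj_pct = round(s$afil_aobj_pct, 1)
  )
}
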
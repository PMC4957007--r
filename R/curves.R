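#' Fit a least-squares spline curve to an ordered point path
#'
#' Parameterizes an ordered 2D pixel path by cumulative chord length and fits
#' a cubic least-squares B-spline to each coordinate. Knots are escalated
#' (interior knots at chord-length quantiles, doubling in number) until the
#' summed squared residual falls within the smoothing budget; `smoothing = 0`
#' requests interpolation. Fewer than 4 distinct points fall back to a
#' degree-1 polyline representation, flagged in the result.
#'
#' The default smoothing budget is `n * (0.5 px)^2`, which absorbs pixel
#' quantization noise without straightening real curvature.
#'
#' @param points An n x 2 matrix or data frame of (row, col) coordinates in
#'   path order. Coincident consecutive points are deduplicated.
#' @param smoothing Non-negative smoothing budget (total squared residual,
#'   px^2); `NULL` uses the default rule.
#' @param um_per_px Calibration used for the micrometre arc length.
#' @return An object of class `filament_curve`: degree, knot vector,
#'   coefficient matrix, chord-length domain, residual RMS (px), arc length
#'   (px and um), the source points, and bookkeeping fields (`source_ids`,
#'   `mean_width_um`, `flagged`).
#' @examples
#' pts <- cbind(rep(5, 50), seq(1, 50))
#' cv <- fit_spline(pts)
#' cv$arc_length_px
#' @export
fit_spline <- function(points, smoothing = NULL, um_per_px = 0.32) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  # deduplicate coincident consecutive points
  if (nrow(pts) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < 2L) {
    return(new_curve(degree = 1L, knots = c(0, 0, 1, 1),
                     coef = rbind(pts[1L, ], pts[1L, ]), t_range = c(0, 1),
                     pts = pts, rms = 0, um_per_px = um_per_px,
                     flagged = "degenerate"))
  }
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (is.null(smoothing)) smoothing <- n * 0.25
  if (smoothing < 0) stop("smoothing must be >= 0", call. = FALSE)
  if (n < 4L) {
    knots <- c(tt[1L], tt, tt[n])
    return(new_curve(degree = 1L, knots = knots, coef = pts,
                     t_range = range(tt), pts = pts, rms = 0,
                     um_per_px = um_per_px, flagged = "polyline"))
  }
  max_int <- n - 4L
  if (smoothing == 0) {
    cand <- max_int
  } else {
    cand <- 0L
    while (tail(cand, 1L) < max_int) {
      nxt <- max(2L, 2L * tail(cand, 1L))
      cand <- c(cand, min(nxt, max_int))
    }
  }
  best <- NULL
  for (k in cand) {
    interior <- if (k == max_int) {
      tt[3:(n - 2L)]
    } else if (k > 0L) {
      unique(quantile(tt, (1:k) / (k + 1), names = FALSE, type = 7))
    } else {
      numeric(0)
    }
    interior <- interior[interior > tt[1L] & interior < tt[n]]
    knots <- c(rep(tt[1L], 4L), interior, rep(tt[n], 4L))
    X <- splines::splineDesign(knots, tt, ord = 4L)
    fit <- tryCatch(qr(X), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(X)) next
    coef <- qr.coef(fit, pts)
    ss <- sum((X %*% coef - pts)^2)
    best <- list(knots = knots, coef = coef, ss = ss)
    if (ss <= smoothing) break
  }
  if (is.null(best)) {
    # all bases singular (pathological spacing): fall back to polyline
    return(new_curve(degree = 1L, knots = c(tt[1L], tt, tt[n]), coef = pts,
                     t_range = range(tt), pts = pts, rms = 0,
                     um_per_px = um_per_px, flagged = "polyline"))
  }
  new_curve(degree = 3L, knots = best$knots, coef = best$coef,
            t_range = range(tt), pts = pts,
            rms = sqrt(best$ss / n), um_per_px = um_per_px)
}

new_curve <- function(degree, knots, coef, t_range, pts, rms, um_per_px,
                      flagged = NULL, source_ids = integer()) {
  cv <- structure(
    list(degree = degree, knots = knots, coef = coef, t_range = t_range,
         n_points = nrow(pts), points = pts, rms = rms,
         um_per_px = um_per_px, arc_length_px = NA_real_,
         arc_length_um = NA_real_, mean_width_um = NA_real_,
         source_ids = source_ids, flagged = flagged,
         end_cap = c(FALSE, FALSE)),
    class = "filament_curve"
  )
  len <- curve_arc_length_px(cv)
  cv$arc_length_px <- len
  cv$arc_length_um <- len * um_per_px
  cv$ends <- compute_endpoints(cv)
  cv
}

#' Evaluate a filament curve (or its derivatives)
#'
#' @param curve A `filament_curve`.
#' @param t Parameter values inside the curve domain (chord length, px).
#' @param deriv Derivative order (0, 1 or 2).
#' @return A length(t) x 2 matrix of (row, col) values.
#' @export
curve_eval <- function(curve, t, deriv = 0L) {
  t <- pmin(pmax(t, curve$t_range[1L]), curve$t_range[2L])
  ord <- curve$degree + 1L
  if (deriv >= ord) {
    return(matrix(0, length(t), 2L))
  }
  X <- splines::splineDesign(curve$knots, t, ord = ord,
                             derivs = rep(as.integer(deriv), length(t)))
  unname(X %*% curve$coef)
}

# arc length in px by composite 10-point Gauss-Legendre per knot span
curve_arc_length_px <- function(curve) {
  spans <- unique(curve$knots)
  if (length(spans) < 2L || diff(curve$t_range) <= 0) return(0)
  total <- 0
  for (i in seq_len(length(spans) - 1L)) {
    gl <- pracma::gaussLegendre(10L, spans[i], spans[i + 1L])
    d <- curve_eval(curve, gl$x, deriv = 1L)
    total <- total + sum(gl$w * sqrt(rowSums(d^2)))
  }
  total
}

#' Arc length of a filament curve
#'
#' Numerical quadrature of the norm of the curve derivative over the domain
#' (10-point Gauss-Legendre per knot span).
#'
#' @param curve A `filament_curve`.
#' @return Named numeric vector with elements `px` and `um`.
#' @examples
#' cv <- fit_spline(cbind(rep(1, 101), 0:100))
#' arc_length(cv)  # 100 px = 32 um at the default calibration
#' @export
arc_length <- function(curve) {
  stopifnot(inherits(curve, "filament_curve"))
  c(px = curve$arc_length_px, um = curve$arc_length_px * curve$um_per_px)
}

#' Endpoint positions, outward tangents and curvature
#'
#' Tangents are unit vectors oriented away from the curve body (so two
#' fragments of one interrupted filament have near-opposite outward
#' tangents). For robustness to pixel-scale wiggle at spline boundaries the
#' tangent direction is taken as the chord over a short end segment (up to
#' 8 px of arc) rather than the pointwise boundary derivative; curvature
#' comes from the analytic spline derivatives. A degenerate zero-length
#' chord falls back to the analytic derivative and is flagged.
#'
#' @param curve A `filament_curve`.
#' @return A tibble with two rows (`end` = 1, 2) and columns `row`, `col`,
#'   `tangent_row`, `tangent_col`, `curvature`, `flagged`.
#' @export
endpoint_geometry <- function(curve) {
  stopifnot(inherits(curve, "filament_curve"))
  if (!is.null(curve$ends)) return(curve$ends)
  compute_endpoints(curve)
}

compute_endpoints <- function(curve) {
  tr <- curve$t_range
  seg <- min(12, diff(tr) / 2)
  out <- lapply(1:2, function(end) {
    t0 <- tr[end]
    sgn <- if (end == 1L) -1 else 1  # outward direction
    pos <- curve_eval(curve, t0)
    t_in <- if (end == 1L) t0 + seg else t0 - seg
    chord <- pos - curve_eval(curve, t_in)
    d1 <- curve_eval(curve, t0, 1L)
    d2 <- curve_eval(curve, t0, 2L)
    flag <- FALSE
    dir <- chord
    if (sqrt(sum(dir^2)) < 1e-9) {
      dir <- sgn * d1
      flag <- TRUE
    }
    nrm <- sqrt(sum(dir^2))
    tangent <- if (nrm < 1e-300) c(0, 0) else dir / nrm
    spd <- sqrt(sum(d1^2))
    curv <- abs(d1[1L] * d2[2L] - d1[2L] * d2[1L]) / max(spd^3, 1e-300)
    tibble(end = end, row = pos[1L], col = pos[2L],
           tangent_row = tangent[1L], tangent_col = tangent[2L],
           curvature = curv, flagged = flag)
  })
  dplyr::bind_rows(out)
}

#' Mean filament width along a curve
#'
#' Samples the Euclidean distance transform of the object mask along the
#' curve. For a ribbon of width w the medial distance-transform value is
#' (w+1)/2 px (pixel-centre offset), so the width estimate is `2 d - 1`
#' converted to micrometres.
#'
#' @param curve A `filament_curve` lying inside an object of `mask`.
#' @param mask Logical/0-1 matrix of the segmented objects.
#' @param um_per_px Calibration; defaults to the curve's.
#' @param n_samples Number of sampling points along the curve.
#' @return Mean width in micrometres (scalar).
#' @export
width_profile <- function(curve, mask, um_per_px = curve$um_per_px,
                          n_samples = 100L) {
  stopifnot(inherits(curve, "filament_curve"))
  dist <- from_ebimage(EBImage::distmap(as_ebimage((mask > 0) * 1)))
  width_from_distmap(curve, dist, um_per_px, n_samples)
}

# internal variant reusing a precomputed distance transform
width_from_distmap <- function(curve, dist, um_per_px, n_samples = 100L) {
  tt <- seq(curve$t_range[1L], curve$t_range[2L], length.out = n_samples)
  pos <- curve_eval(curve, tt)
  r <- pmin(pmax(round(pos[, 1L]), 1L), nrow(dist))
  cc <- pmin(pmax(round(pos[, 2L]), 1L), ncol(dist))
  d <- dist[cbind(r, cc)]
  if (mean(d > 0) < 0.5) {
    stop("curve lies outside the mask", call. = FALSE)
  }
  d <- d[d > 0]
  max(2 * mean(d) - 1, 1) * um_per_px
}

# extend a pixel path end through the mask to the object boundary: discrete
# thinning erodes skeleton ends by roughly the local half-width, so the path
# is marched on along its local direction until it leaves the object. After
# extension the path ends at the cap tip, which for a round-capped ribbon
# lies half a width beyond the true centerline end (see curve_length_um).
extend_path_end <- function(path, mask, which_end, max_steps = 25L,
                            trim = 2L, dir_span = 15L, reach_credit = 18L) {
  n <- nrow(path)
  if (n < 4L) return(path)
  if (which_end == 1L) path <- path[rev(seq_len(n)), , drop = FALSE]
  # thinning often leaves a short diagonal hook at the very tip: drop it and
  # take the marching direction from a longer stretch of the path
  if (n > trim + 3L) {
    path <- path[seq_len(n - trim), , drop = FALSE]
    n <- nrow(path)
  }
  k <- min(dir_span, n - 1L)
  dir <- path[n, ] - path[n - k, ]
  nrm <- sqrt(sum(dir^2))
  if (nrm > 1e-9) {
    dir <- dir / nrm
    pos <- path[n, ]
    nr <- nrow(mask); nc <- ncol(mask)
    reach_along <- function(d) {
      reach <- 0L
      for (s in seq_len(max_steps)) {
        p <- round(pos + s * d)
        if (p[1L] < 1 || p[1L] > nr || p[2L] < 1 || p[2L] > nc ||
            !mask[p[1L], p[2L]]) break
        reach <- s
      }
      reach
    }
    # the local chord direction is noisy at eroded tips; fan rays around it
    # and follow the one that stays inside the object longest. The reach
    # credit is capped (a cap is at most about a filament width deep) and
    # ties resolve toward the smallest deviation, so long body-ward rays do
    # not out-compete the true cap axis.
    base_ang <- atan2(dir[1L], dir[2L])
    devs <- seq(-40, 40, by = 5) * pi / 180
    best <- c(-1, 0, 0)
    for (dv in devs[order(abs(devs))]) {
      d <- c(sin(base_ang + dv), cos(base_ang + dv))
      r <- reach_along(d)
      if (min(r, reach_credit) > best[1L]) best <- c(min(r, reach_credit), base_ang + dv, r)
    }
    if (best[1L] > 0) {
      d <- c(sin(best[2L]), cos(best[2L]))
      extra <- lapply(seq_len(min(best[3L], reach_credit)), function(s)
        round(pos + s * d))
      path <- rbind(path, do.call(rbind, extra))
    }
  }
  if (which_end == 1L) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  path
}

# filament length in micrometres: spline arc length runs cap tip to cap tip
# on extended paths, so half the local width is trimmed per capped free end
curve_length_um <- function(curve) {
  caps <- sum(curve$end_cap %||% FALSE)
  w <- curve$mean_width_um
  if (!is.finite(w)) w <- 0
  max(curve$arc_length_um - caps * w / 2, 0)
}

#' @export
print.filament_curve <- function(x, ...) {
  cat("<filament_curve> degree ", x$degree, ", ", x$n_points, " points, ",
      "arc length ", round(x$arc_length_px, 1), " px (",
      round(x$arc_length_um, 1), " um), rms ", signif(x$rms, 3), " px",
      if (!is.null(x$flagged)) paste0(" [", x$flagged, "]"), "\n", sep = "")
  invisible(x)
}
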
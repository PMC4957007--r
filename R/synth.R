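#' Configuration for a synthetic bright-field scene
#'
#' Describes a seeded synthetic field of view emulating bright-field
#' micrographs of sedimented phytoplankton: curved dark filaments of varying
#' length and width on a bright background with a smooth illumination
#' gradient, optional filament crossings, interrupted (broken) filaments,
#' non-filamentous particle distractors and additive Gaussian noise. The
#' default frame is a 1/4-linear-scale field of view (1296 x 864 px at
#' 0.32 um/px); filament widths default to the 3-6 um band typical of
#' planktic toxigenic filamentous genera and lengths to a truncated
#' log-normal with median near 120 um.
#'
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @param width_px,height_px Frame size in pixels.
#' @param um_per_px Calibration.
#' @param n_filaments Number of filaments (crossing filaments included).
#' @param length_meanlog,length_sdlog Log-normal parameters of filament
#'   length (um).
#' @param length_range_um Truncation range for filament length (um).
#' @param width_range_um Uniform range of filament width (um).
#' @param curvature_sd Heading diffusion (radians per 2-px step) of the
#'   backbone random walk; larger values give wigglier filaments.
#' @param n_crossings Number of filaments constructed to cross an existing
#'   filament.
#' @param n_breaks Number of filaments interrupted by one gap each.
#' @param gap_range_um Uniform range of the visible gap (um) between the two
#'   fragments of a broken filament.
#' @param n_blobs Number of non-filamentous particle distractors.
#' @param blob_radius_px Range of blob semi-axes (px).
#' @param background Background intensity of the bright field.
#' @param gradient_amplitude Peak-to-peak amplitude of the smooth background
#'   gradient.
#' @param contrast Intensity drop of a filament below the local background.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param margin_px Wall-steering margin from the frame border; walks that
#'   still come within half this margin of the border are rejected outright,
#'   so object masks never touch the frame edge.
#' @param max_tries Packing retries per object before giving up.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         width_px = 1296L, height_px = 864L,
                         um_per_px = 0.32,
                         n_filaments = 12L,
                         length_meanlog = log(120), length_sdlog = 0.45,
                         length_range_um = c(60, 320),
                         width_range_um = c(3, 6),
                         curvature_sd = 0.05,
                         n_crossings = 0L,
                         n_breaks = 0L,
                         gap_range_um = c(4, 12),
                         n_blobs = 20L,
                         blob_radius_px = c(2, 8),
                         background = 0.85,
                         gradient_amplitude = 0.15,
                         contrast = 0.3,
                         noise_sd = 0.01,
                         margin_px = 55L,
                         max_tries = 500L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_filaments >= 0, cfg$n_crossings >= 0, cfg$n_breaks >= 0,
            cfg$n_blobs >= 0, cfg$noise_sd >= 0,
            cfg$n_crossings <= cfg$n_filaments,
            cfg$n_breaks <= cfg$n_filaments,
            cfg$width_range_um[1] > 0, cfg$length_range_um[1] > 0,
            cfg$um_per_px > 0)
  structure(cfg, class = "scene_config")
}

# curved backbone random walk with arc-like wall steering; returns n x 2
# (row, col). Near the frame margin the heading is biased toward the centre
# by at most max_wall_turn per step, so wall avoidance bends the filament on
# a radius larger than any filament width instead of folding it.
backbone_walk <- function(start, heading, length_px, curvature_sd,
                          nr, nc, margin, step = 2, max_wall_turn = 0.09) {
  n_steps <- max(2L, ceiling(length_px / step))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- start
  pos <- start
  for (i in seq_len(n_steps)) {
    heading <- heading + rnorm(1L, 0, curvature_sd)
    near_wall <- pos[1L] < margin || pos[1L] > nr - margin ||
      pos[2L] < margin || pos[2L] > nc - margin
    if (near_wall) {
      to_center <- atan2(nr / 2 - pos[1L], nc / 2 - pos[2L])
      delta <- ((to_center - heading + pi) %% (2 * pi)) - pi
      heading <- heading + sign(delta) * min(abs(delta), max_wall_turn)
    }
    cand <- pos + step * c(sin(heading), cos(heading))
    cand[1L] <- min(max(cand[1L], 3), nr - 2)
    cand[2L] <- min(max(cand[2L], 3), nc - 2)
    pos <- cand
    pts[i + 1L, ] <- pos
  }
  pts
}

# TRUE when two backbone points separated by more than arc_skip along the
# curve come closer than min_sep in the plane (a fold or self-approach)
self_approaches <- function(bb, min_sep, arc_skip, step = 2) {
  n <- nrow(bb)
  skip <- ceiling(arc_skip / step)
  if (n <= skip + 1L) return(FALSE)
  d2 <- as.matrix(stats::dist(bb))
  idx <- abs(row(d2) - col(d2)) > skip
  any(d2[idx] < min_sep)
}

# pixels within `radius` of a polyline, as linear indices into the frame
ribbon_pixels <- function(pts, radius, nr, nc) {
  pad <- ceiling(radius) + 2L
  r0 <- max(1L, floor(min(pts[, 1L])) - pad)
  r1 <- min(nr, ceiling(max(pts[, 1L])) + pad)
  c0 <- max(1L, floor(min(pts[, 2L])) - pad)
  c1 <- min(nc, ceiling(max(pts[, 2L])) + pad)
  box <- matrix(1, r1 - r0 + 1L, c1 - c0 + 1L)
  pr <- pmin(pmax(round(pts[, 1L]) - r0 + 1L, 1L), nrow(box))
  pc <- pmin(pmax(round(pts[, 2L]) - c0 + 1L, 1L), ncol(box))
  box[cbind(pr, pc)] <- 0
  d <- from_ebimage(EBImage::distmap(as_ebimage(box)))
  hit <- which(d <= radius, arr.ind = TRUE)
  (hit[, 2L] + c0 - 2L) * nr + (hit[, 1L] + r0 - 1L)
}

# pixels of a rotated ellipse, as linear indices
ellipse_pixels <- function(center, r1, r2, angle, nr, nc) {
  pad <- ceiling(max(r1, r2)) + 1L
  rr <- max(1L, floor(center[1L]) - pad):min(nr, ceiling(center[1L]) + pad)
  cc <- max(1L, floor(center[2L]) - pad):min(nc, ceiling(center[2L]) + pad)
  g <- expand.grid(r = rr, c = cc)
  dr <- g$r - center[1L]; dc <- g$c - center[2L]
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  inside <- (u / r1)^2 + (v / r2)^2 <= 1
  (g$c[inside] - 1L) * nr + g$r[inside]
}

#' Generate the ground truth of a synthetic scene
#'
#' Places filament backbones (integrated random-walk headings with bounded
#' curvature and mutual clearance), constructs the requested crossings by
#' growing a filament through a point of an existing one, cuts the requested
#' breaks out of backbones (the registered gap is the visible gap between the
#' two fragment masks), and scatters non-overlapping blob distractors. Fully
#' reproducible from the config seed; packing failures raise an error after
#' bounded retries.
#'
#' @param config A `scene_config`.
#' @return An object of class `scene_truth`: config, per-filament truth
#'   (backbone, width, length, fragment pixel sets), break / crossing / blob
#'   registries and pooled truth statistics.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  # sequential random packing can dead-end on unlucky draws; restart the
  # whole placement from a seed-derived stream, deterministically
  last <- NULL
  for (attempt in 0:5) {
    truth <- tryCatch(
      generate_scene_attempt(config, config$seed + attempt * 1000003L),
      error = function(e) e
    )
    if (!inherits(truth, "error")) return(truth)
    last <- truth
  }
  stop(conditionMessage(last), call. = FALSE)
}

generate_scene_attempt <- function(config, seed_val) {
  set.seed(seed_val)
  nr <- config$height_px; nc <- config$width_px
  upp <- config$um_per_px
  margin <- config$margin_px
  occupied <- matrix(FALSE, nr, nc)
  # free filament tips must stay out of joining range of other tips,
  # otherwise the true filament count is not identifiable from the image
  # (a chance end-to-end alignment is indistinguishable from a real break)
  tips <- matrix(numeric(0), 0L, 2L)
  end_clear <- 70
  filaments <- list()
  crossings <- list()
  n_free <- config$n_filaments - config$n_crossings

  sample_length_px <- function() {
    for (i in 1:100) {
      L <- rlnorm(1L, config$length_meanlog, config$length_sdlog)
      if (L >= config$length_range_um[1L] && L <= config$length_range_um[2L]) {
        return(L / upp)
      }
    }
    mean(config$length_range_um) / upp
  }

  place_filament <- function(id, through = NULL, L_fixed = NULL) {
    for (try in seq_len(config$max_tries)) {
      L_px <- if (is.null(L_fixed)) sample_length_px() else L_fixed
      # on crowded frames fall back to shorter filaments so that packing
      # terminates; the length distribution is preserved while space allows
      if (try > config$max_tries * 0.7) {
        L_px <- min(L_px, 70 / upp)
      } else if (try > config$max_tries * 0.4) {
        L_px <- min(L_px, 100 / upp)
      }
      w_um <- runif(1L, config$width_range_um[1L], config$width_range_um[2L])
      w_px <- w_um / upp
      if (is.null(through)) {
        start <- c(runif(1L, margin, nr - margin),
                   runif(1L, margin, nc - margin))
        heading <- runif(1L, 0, 2 * pi)
        bb <- backbone_walk(start, heading, L_px, config$curvature_sd,
                            nr, nc, margin)
      } else {
        # grow both halves from the crossing point, at an oblique angle
        ang <- through$tangent + sample(c(-1, 1), 1L) * runif(1L, 0.7, 1.5)
        h1 <- backbone_walk(through$point, ang, L_px / 2,
                            config$curvature_sd, nr, nc, margin)
        h2 <- backbone_walk(through$point, ang + pi, L_px / 2,
                            config$curvature_sd, nr, nc, margin)
        bb <- rbind(h2[rev(seq_len(nrow(h2))), ], h1[-1L, , drop = FALSE])
      }
      # clearance must exceed the segmentation dilation (edge band plus
      # smoothing) so distinct filaments stay distinct objects
      if (min(bb[, 1L], nc - bb[, 2L], nr - bb[, 1L], bb[, 2L]) <
          margin / 2) next
      px_clear <- ribbon_pixels(bb, w_px / 2 + 8, nr, nc)
      # reject backbones that pass close to themselves: any two points far
      # apart along the arc but close in the plane would merge after the
      # segmentation dilation into one blobby object
      if (self_approaches(bb, min_sep = w_px + 18, arc_skip = 3 * w_px)) next
      hit <- px_clear[occupied[px_clear]]
      if (length(hit) > 0L) {
        if (is.null(through)) next
        # crossings are allowed to overlap near the crossing point only
        hr <- (hit - 1L) %% nr + 1L
        hc <- (hit - 1L) %/% nr + 1L
        dist_p <- sqrt((hr - through$point[1L])^2 + (hc - through$point[2L])^2)
        if (any(dist_p > 25)) next
      }
      cand_tips <- bb[c(1L, nrow(bb)), , drop = FALSE]
      if (nrow(tips) > 0L) {
        d <- sqrt(outer(cand_tips[, 1L], tips[, 1L], `-`)^2 +
                    outer(cand_tips[, 2L], tips[, 2L], `-`)^2)
        if (min(d) < end_clear) next
      }
      seg <- sqrt(rowSums(diff(bb)^2))
      occupied[px_clear] <<- TRUE
      tips <<- rbind(tips, cand_tips)
      return(list(id = id, width_um = w_um, backbone = bb,
                  length_um = sum(seg) * upp, pieces = list(bb)))
    }
    stop("infeasible packing: could not place filament ", id, call. = FALSE)
  }

  # place longer filaments first: sequential packing then degrades
  # gracefully as the frame fills
  lens <- sort(vapply(seq_len(n_free), function(i) sample_length_px(),
                      numeric(1)), decreasing = TRUE)
  for (i in seq_len(n_free)) {
    filaments[[i]] <- place_filament(i, L_fixed = lens[i])
  }
  for (k in seq_len(config$n_crossings)) {
    host <- filaments[[sample(length(filaments), 1L)]]
    bb <- host$backbone
    j <- sample(seq(5L, nrow(bb) - 5L), 1L)
    # heading convention of backbone_walk: atan2(d_row, d_col)
    tangent <- atan2(bb[j + 1L, 1L] - bb[j - 1L, 1L],
                     bb[j + 1L, 2L] - bb[j - 1L, 2L])
    id <- length(filaments) + 1L
    filaments[[id]] <- place_filament(
      id, through = list(point = bb[j, ], tangent = tangent))
    crossings[[k]] <- tibble(filament_a = host$id, filament_b = id,
                             row = bb[j, 1L], col = bb[j, 2L])
  }

  breaks <- list()
  if (config$n_breaks > 0L) {
    broken_ids <- sample(seq_along(filaments), config$n_breaks)
    for (b in seq_along(broken_ids)) {
      f <- filaments[[broken_ids[b]]]
      bb <- f$backbone
      s <- c(0, cumsum(sqrt(rowSums(diff(bb)^2))))
      gap_um <- runif(1L, config$gap_range_um[1L], config$gap_range_um[2L])
      cut_frac <- runif(1L, 0.3, 0.7)
      half <- (gap_um + f$width_um) / upp / 2  # visible gap = registered gap
      s0 <- cut_frac * max(s)
      keep1 <- s <= s0 - half
      keep2 <- s >= s0 + half
      if (sum(keep1) >= 2L && sum(keep2) >= 2L) {
        f$pieces <- list(bb[keep1, , drop = FALSE], bb[keep2, , drop = FALSE])
        filaments[[broken_ids[b]]] <- f
        breaks[[length(breaks) + 1L]] <-
          tibble(filament = f$id, cut_frac = cut_frac, gap_um = gap_um)
      }
    }
  }

  # rasterize filament fragments
  fil_px <- logical(nr * nc)
  for (i in seq_along(filaments)) {
    f <- filaments[[i]]
    f$piece_px <- lapply(f$pieces, function(p)
      ribbon_pixels(p, f$width_um / upp / 2, nr, nc))
    filaments[[i]] <- f
    fil_px[unlist(f$piece_px)] <- TRUE
  }

  blobs <- list()
  for (b in seq_len(config$n_blobs)) {
    for (try in seq_len(config$max_tries)) {
      r1 <- runif(1L, config$blob_radius_px[1L], config$blob_radius_px[2L])
      r2 <- runif(1L, config$blob_radius_px[1L], config$blob_radius_px[2L])
      center <- c(runif(1L, margin, nr - margin),
                  runif(1L, margin, nc - margin))
      angle <- runif(1L, 0, pi)
      px <- ellipse_pixels(center, r1 + 3, r2 + 3, angle, nr, nc)
      if (any(occupied[px])) next
      occupied[px] <- TRUE
      blobs[[b]] <- tibble(row = center[1L], col = center[2L], r1 = r1,
                           r2 = r2, angle = angle,
                           darkness = runif(1L, 0.5, 1) * config$contrast,
                           px = list(ellipse_pixels(center, r1, r2, angle,
                                                    nr, nc)))
      break
    }
  }

  blob_px <- logical(nr * nc)
  for (b in blobs) blob_px[b$px[[1L]]] <- TRUE

  structure(list(
    config = config,
    filaments = filaments,
    breaks = if (length(breaks)) dplyr::bind_rows(breaks) else
      tibble(filament = integer(), cut_frac = numeric(), gap_um = numeric()),
    crossings = if (length(crossings)) dplyr::bind_rows(crossings) else
      tibble(filament_a = integer(), filament_b = integer(),
             row = numeric(), col = numeric()),
    blobs = if (length(blobs)) dplyr::bind_rows(blobs) else
      tibble(row = numeric(), col = numeric(), r1 = numeric(),
             r2 = numeric(), angle = numeric(), darkness = numeric(),
             px = list()),
    n_filaments = length(filaments),
    total_length_um = sum(vapply(filaments, `[[`, numeric(1), "length_um")),
    filament_area_fraction =
      if (sum(fil_px) + sum(blob_px & !fil_px) == 0) NA_real_ else
        100 * sum(fil_px) / (sum(fil_px) + sum(blob_px & !fil_px))
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", x$n_filaments, " filaments (total ",
      round(x$total_length_um), " um), ", nrow(x$breaks), " breaks, ",
      nrow(x$crossings), " crossings, ", nrow(x$blobs), " blobs\n", sep = "")
  invisible(x)
}

#' Render a synthetic scene to a grayscale image
#'
#' Paints the truth onto a bright background with a smooth planar intensity
#' gradient: filaments as constant-width dark ribbons, blobs as darker
#' ellipses, plus seeded additive Gaussian noise. Deterministic given the
#' truth (the noise stream is derived from the scene seed).
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @return A numeric matrix on `[0, 1]` (rows = height).
#' @export
render_scene <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  cfg <- truth$config
  nr <- cfg$height_px; nc <- cfg$width_px
  set.seed(cfg$seed + 7777L)
  phi <- runif(1L, 0, 2 * pi)
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), nc), nr, nc)
  plane <- cos(phi) * X / nc + sin(phi) * Y / nr
  plane <- plane - min(plane)
  rng <- max(plane)
  img <- cfg$background - cfg$gradient_amplitude / 2 +
    cfg$gradient_amplitude * (if (rng > 0) plane / rng else plane)
  for (f in truth$filaments) {
    for (px in f$piece_px) img[px] <- img[px] - cfg$contrast
  }
  if (nrow(truth$blobs) > 0L) {
    for (b in seq_len(nrow(truth$blobs))) {
      px <- truth$blobs$px[[b]]
      img[px] <- img[px] - truth$blobs$darkness[b]
    }
  }
  if (cfg$noise_sd > 0) {
    img <- img + matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  }
  pmin(pmax(img, 0), 1)
}

#' Truth summary of a synthetic scene
#'
#' @param truth A `scene_truth`.
#' @return One-row tibble: `n_filaments`, `total_length_um`, `n_breaks`,
#'   `n_crossings`, `n_blobs`, `filament_area_fraction`.
#' @export
scene_summary <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  tibble(
    n_filaments = truth$n_filaments,
    total_length_um = truth$total_length_um,
    n_breaks = nrow(truth$breaks),
    n_crossings = nrow(truth$crossings),
    n_blobs = nrow(truth$blobs),
    filament_area_fraction = truth$filament_area_fraction
  )
}
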
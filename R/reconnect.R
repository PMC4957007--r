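# endpoint bookkeeping for a pool of curves: one row per curve end
endpoint_pool <- function(curves, idx = seq_along(curves)) {
  rows <- lapply(idx, function(i) {
    eg <- endpoint_geometry(curves[[i]])
    eg$curve <- i
    eg$width_um <- curves[[i]]$mean_width_um
    eg
  })
  dplyr::bind_rows(rows)
}

# vectorized gate-and-cost evaluation for endpoint index pairs (i, j) of ep
score_pairs <- function(ep, i, j, max_gap_um, max_angle_deg,
                        width_ratio_max, um_per_px) {
  gap_px <- sqrt((ep$row[i] - ep$row[j])^2 + (ep$col[i] - ep$col[j])^2)
  gap_um <- gap_px * um_per_px
  keep <- gap_um <= max_gap_um
  i <- i[keep]; j <- j[keep]
  gap_px <- gap_px[keep]; gap_um <- gap_um[keep]
  if (length(i) == 0L) return(NULL)
  ta <- cbind(ep$tangent_row[i], ep$tangent_col[i])
  tb <- cbind(ep$tangent_row[j], ep$tangent_col[j])
  vr <- ep$row[j] - ep$row[i]
  vc <- ep$col[j] - ep$col[i]
  deg <- function(cosang) acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # alignment is gated on the tangent-tangent deviation from straight-through
  # continuation, split evenly between the two ends, plus an explicit
  # lateral-offset gate (the displacement component perpendicular to the
  # joint axis). This decomposition is robust at short gaps, where the
  # direction between the two endpoints is dominated by pixel-scale lateral
  # tip offset, and the lateral gate keeps parallel neighbours apart.
  dev <- (180 - deg(ta[, 1L] * tb[, 1L] + ta[, 2L] * tb[, 2L])) / 2
  ang_a <- dev
  ang_b <- dev
  axis_r <- ta[, 1L] - tb[, 1L]
  axis_c <- ta[, 2L] - tb[, 2L]
  axis_n <- pmax(sqrt(axis_r^2 + axis_c^2), 1e-12)
  lateral_um <- abs(vr * axis_c / axis_n - vc * axis_r / axis_n) * um_per_px
  wa <- ep$width_um[i]; wb <- ep$width_um[j]
  wr <- ifelse(is.na(wa) | is.na(wb), 1,
               pmax(wa, wb) / pmax(pmin(wa, wb), 1e-9))
  keep2 <- ang_a <= max_angle_deg & ang_b <= max_angle_deg &
    wr <= width_ratio_max & lateral_um <= 6
  if (!any(keep2)) return(NULL)
  tibble(
    curve_a = ep$curve[i][keep2], end_a = ep$end[i][keep2],
    curve_b = ep$curve[j][keep2], end_b = ep$end[j][keep2],
    gap_um = gap_um[keep2],
    angle_a_deg = ang_a[keep2], angle_b_deg = ang_b[keep2],
    cost = gap_um[keep2] / max_gap_um +
      (ang_a[keep2] + ang_b[keep2]) / (2 * max_angle_deg) +
      abs(log(wr[keep2]))
  )
}

sort_candidates <- function(cand) {
  dplyr::arrange(cand, .data$cost, .data$curve_a, .data$end_a,
                 .data$curve_b, .data$end_b)
}

empty_candidates <- function() {
  tibble(curve_a = integer(), end_a = integer(),
         curve_b = integer(), end_b = integer(),
         gap_um = numeric(), angle_a_deg = numeric(),
         angle_b_deg = numeric(), cost = numeric())
}

#' Enumerate endpoint pairs eligible for reconnection
#'
#' Considers every pair of endpoints on distinct curves and keeps those whose
#' gap, alignment angles and width ratio pass the gates. The alignment angle
#' of an endpoint is measured between its outward tangent and the direction
#' toward the partner endpoint; for branch pairs sharing a junction point
#' (negligible gap) the deviation from straight-through continuation is used
#' instead. The cost is
#'
#'   gap / max_gap + (angle_a + angle_b) / (2 max_angle) + |log width ratio|
#'
#' and candidates are sorted by ascending cost with a deterministic tie-break
#' on (curve, endpoint) ids.
#'
#' @param curves List of `filament_curve` objects (widths, if known, are used
#'   for the width-ratio gate; unknown widths pass).
#' @param max_gap_um Maximum endpoint gap (um) bridged by a join.
#' @param max_angle_deg Maximum alignment angle (degrees) at each end.
#' @param width_ratio_max Maximum ratio of the two mean widths.
#' @param um_per_px Calibration (defaults to the first curve's).
#' @return A tibble of candidates: `curve_a`, `end_a`, `curve_b`, `end_b`,
#'   `gap_um`, `angle_a_deg`, `angle_b_deg`, `cost`, sorted by cost.
#' @export
candidate_joins <- function(curves, max_gap_um = 15, max_angle_deg = 30,
                            width_ratio_max = 1.8, um_per_px = NULL) {
  if (length(curves) < 2L) return(empty_candidates())
  if (is.null(um_per_px)) um_per_px <- curves[[1L]]$um_per_px
  ep <- endpoint_pool(curves)
  n <- nrow(ep)
  pair <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  diff_curve <- ep$curve[i] != ep$curve[j]
  i <- i[diff_curve]; j <- j[diff_curve]
  cand <- score_pairs(ep, i, j, max_gap_um, max_angle_deg,
                      width_ratio_max, um_per_px)
  if (is.null(cand)) return(empty_candidates())
  sort_candidates(cand)
}

# orient a curve's points so that the given end is last (1) or first (2)
oriented_points <- function(curve, end, join_end_last) {
  p <- curve$points
  at_end2 <- end == 2L
  if (join_end_last != at_end2) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

#' Resolve reconnection candidates into merged filaments
#'
#' Greedy acceptance in cost order: the cheapest surviving candidate is
#' accepted, the two fragments are merged (the union of their point paths is
#' refit as one spline, bridging the gap), and the merged curve re-enters the
#' pool with recomputed endpoint geometry before surviving candidates are
#' re-evaluated. Each free endpoint is used at most once per join; a curve is
#' never joined to itself (no cyclic merges). The returned record counts
#' accepted joins and eligible break events (accepted joins plus leftover
#' endpoint pairs that pass the gap gate but were never joined, greedily
#' matched by gap), so `n_joined <= n_break_events` by construction.
#'
#' @param curves List of `filament_curve` objects.
#' @param max_gap_um,max_angle_deg,width_ratio_max,um_per_px Gate parameters,
#'   as in [candidate_joins()].
#' @param smoothing Smoothing budget rule forwarded to the refit; `NULL` for
#'   the default.
#' @return A list with `curves` (the merged pool) and `record`, a one-row
#'   tibble with `n_joined` and `n_break_events`; the accepted pairs tibble
#'   is attached as attribute `"pairs"`.
#' @export
resolve_joins <- function(curves, max_gap_um = 15, max_angle_deg = 30,
                          width_ratio_max = 1.8, um_per_px = NULL,
                          smoothing = NULL) {
  if (is.null(um_per_px) && length(curves) > 0L) {
    um_per_px <- curves[[1L]]$um_per_px
  }
  pool <- curves
  active <- rep(TRUE, length(pool))
  cand <- candidate_joins(pool, max_gap_um, max_angle_deg,
                          width_ratio_max, um_per_px)
  accepted <- list()
  n_joined <- 0L
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    a <- pool[[top$curve_a]]; b <- pool[[top$curve_b]]
    pa <- oriented_points(a, top$end_a, join_end_last = TRUE)
    pb <- oriented_points(b, top$end_b, join_end_last = FALSE)
    merged <- fit_spline(rbind(pa, pb), smoothing = smoothing,
                         um_per_px = um_per_px)
    la <- a$arc_length_um; lb <- b$arc_length_um
    wa <- a$mean_width_um; wb <- b$mean_width_um
    merged$mean_width_um <- if (is.na(wa) || is.na(wb)) NA_real_ else
      (wa * la + wb * lb) / max(la + lb, 1e-9)
    merged$source_ids <- unique(c(a$source_ids, b$source_ids))
    cap_a <- (a$end_cap %||% c(FALSE, FALSE))[if (top$end_a == 1L) 2L else 1L]
    cap_b <- (b$end_cap %||% c(FALSE, FALSE))[if (top$end_b == 1L) 2L else 1L]
    merged$end_cap <- c(cap_a, cap_b)
    active[c(top$curve_a, top$curve_b)] <- FALSE
    pool[[length(pool) + 1L]] <- merged
    active[length(pool)] <- TRUE
    accepted[[length(accepted) + 1L]] <- top
    n_joined <- n_joined + 1L
    # drop candidates touching the consumed curves, add ones for the merge
    cand <- cand[cand$curve_a != top$curve_a & cand$curve_a != top$curve_b &
                 cand$curve_b != top$curve_a & cand$curve_b != top$curve_b, ]
    others <- which(active)
    others <- others[others != length(pool)]
    if (length(others) > 0L) {
      ep <- endpoint_pool(pool, c(length(pool), others))
      new_idx <- which(ep$curve == length(pool))
      old_idx <- which(ep$curve != length(pool))
      pair <- expand.grid(i = new_idx, j = old_idx)
      extra <- score_pairs(ep, pair$i, pair$j, max_gap_um, max_angle_deg,
                           width_ratio_max, um_per_px)
      if (!is.null(extra)) cand <- dplyr::bind_rows(cand, extra)
    }
    cand <- sort_candidates(cand)
  }
  # rescue pass: pairs that pass the gap and width gates but fail the angle
  # gates (endpoint tangents are noisy on eroded tips) are still accepted
  # when the trial fit shows the two fragments continue each other smoothly
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    ep <- endpoint_pool(pool, act)
    n <- nrow(ep)
    pair <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    i <- pair[, 1L]; j <- pair[, 2L]
    ok <- ep$curve[i] != ep$curve[j]
    i <- i[ok]; j <- j[ok]
    if (length(i) == 0L) break
    gap <- sqrt((ep$row[i] - ep$row[j])^2 + (ep$col[i] - ep$col[j])^2) *
      um_per_px
    wa <- ep$width_um[i]; wb <- ep$width_um[j]
    wr <- ifelse(is.na(wa) | is.na(wb), 1,
                 pmax(wa, wb) / pmax(pmin(wa, wb), 1e-9))
    ok <- gap <= max_gap_um & wr <= width_ratio_max
    i <- i[ok]; j <- j[ok]
    if (length(i) == 0L) break
    rms <- vapply(seq_along(i), function(k)
      trial_rms(pool[[ep$curve[i[k]]]], ep$end[i[k]],
                pool[[ep$curve[j[k]]]], ep$end[j[k]]), numeric(1))
    if (min(rms) > 1.2) break
    k <- which.min(rms)
    top <- tibble(curve_a = ep$curve[i[k]], end_a = ep$end[i[k]],
                  curve_b = ep$curve[j[k]], end_b = ep$end[j[k]],
                  gap_um = gap[k], angle_a_deg = NA_real_,
                  angle_b_deg = NA_real_, cost = NA_real_)
    a <- pool[[top$curve_a]]; b <- pool[[top$curve_b]]
    pa <- oriented_points(a, top$end_a, join_end_last = TRUE)
    pb <- oriented_points(b, top$end_b, join_end_last = FALSE)
    merged <- fit_spline(rbind(pa, pb), smoothing = smoothing,
                         um_per_px = um_per_px)
    la <- a$arc_length_um; lb <- b$arc_length_um
    wa1 <- a$mean_width_um; wb1 <- b$mean_width_um
    merged$mean_width_um <- if (is.na(wa1) || is.na(wb1)) NA_real_ else
      (wa1 * la + wb1 * lb) / max(la + lb, 1e-9)
    merged$source_ids <- unique(c(a$source_ids, b$source_ids))
    cap_a <- (a$end_cap %||% c(FALSE, FALSE))[if (top$end_a == 1L) 2L else 1L]
    cap_b <- (b$end_cap %||% c(FALSE, FALSE))[if (top$end_b == 1L) 2L else 1L]
    merged$end_cap <- c(cap_a, cap_b)
    active[c(top$curve_a, top$curve_b)] <- FALSE
    pool[[length(pool) + 1L]] <- merged
    active[length(pool)] <- TRUE
    accepted[[length(accepted) + 1L]] <- top
    n_joined <- n_joined + 1L
  }
  final <- pool[active]
  n_missed <- count_missed_events(final, max_gap_um, um_per_px)
  record <- tibble(n_joined = n_joined,
                   n_break_events = n_joined + n_missed)
  attr(record, "pairs") <- if (length(accepted)) dplyr::bind_rows(accepted) else
    tibble()
  list(curves = final, record = record)
}

# least-squares continuity test for a tentative join: fit one cubic spline
# with widely spaced knots to the two end segments and the bridge between
# them; a true continuation fits with sub-pixel residual, while kinked or
# laterally offset pairings cannot be absorbed by the sparse knots
trial_rms <- function(a, end_a, b, end_b, window_px = 60L, knot_px = 25,
                      min_side_px = 20L) {
  pa <- oriented_points(a, end_a, join_end_last = TRUE)
  pb <- oriented_points(b, end_b, join_end_last = FALSE)
  # continuity cannot be assessed on stubs (e.g. compact debris): both sides
  # must contribute a real stretch of path
  if (nrow(pa) < min_side_px || nrow(pb) < min_side_px) return(Inf)
  pa <- pa[max(1L, nrow(pa) - window_px + 1L):nrow(pa), , drop = FALSE]
  pb <- pb[seq_len(min(nrow(pb), window_px)), , drop = FALSE]
  pts <- rbind(pa, pb)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 8L) return(Inf)
  tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  n_int <- max(1L, floor(tt[n] / knot_px) - 1L)
  interior <- quantile(tt, (1:n_int) / (n_int + 1), names = FALSE)
  interior <- interior[interior > tt[1L] & interior < tt[n]]
  knots <- c(rep(tt[1L], 4L), interior, rep(tt[n], 4L))
  X <- try(splines::splineDesign(knots, tt, ord = 4L), silent = TRUE)
  if (inherits(X, "try-error")) return(Inf)
  fit <- qr(X)
  if (fit$rank < ncol(X)) return(Inf)
  res <- X %*% qr.coef(fit, pts) - pts
  sqrt(sum(res^2) / n)
}

# leftover endpoint pairs that pass the gap gate alone, greedily matched
count_missed_events <- function(pool, max_gap_um, um_per_px) {
  if (length(pool) < 2L) return(0L)
  if (is.null(um_per_px)) um_per_px <- pool[[1L]]$um_per_px
  ep <- endpoint_pool(pool)
  n <- nrow(ep)
  pair <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  keep <- ep$curve[i] != ep$curve[j]
  i <- i[keep]; j <- j[keep]
  gap <- sqrt((ep$row[i] - ep$row[j])^2 + (ep$col[i] - ep$col[j])^2) *
    um_per_px
  keep <- gap <= max_gap_um
  if (!any(keep)) return(0L)
  ord <- order(gap[keep])
  i <- i[keep][ord]; j <- j[keep][ord]
  used <- logical(n)
  missed <- 0L
  for (r in seq_along(i)) {
    if (used[i[r]] || used[j[r]]) next
    used[i[r]] <- used[j[r]] <- TRUE
    missed <- missed + 1L
  }
  missed
}

#' Pooled reconstruction rate
#'
#' Percentage of eligible break/cross events that were successfully joined,
#' pooled over a set of reconnection records (or any data frame with
#' `n_joined`/`n_break_events` or `rec_joined`/`rec_events` columns). With a
#' zero denominator the rate is undefined and `NA` is returned, not 0.
#'
#' @param records A data frame of reconnection records.
#' @return Percent joined (scalar), or `NA` if there were no events.
#' @examples
#' reconstruction_rate(data.frame(n_joined = c(2, 2, 2),
#'                                n_break_events = c(2, 2, 4)))  # 75
#' @export
reconstruction_rate <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records supplied", call. = FALSE)
  }
  joined <- records[["n_joined"]] %||% records[["rec_joined"]]
  events <- records[["n_break_events"]] %||% records[["rec_events"]]
  if (is.null(joined) || is.null(events)) {
    stop("records must carry joined/event counts", call. = FALSE)
  }
  if (sum(events) == 0) return(NA_real_)
  100 * sum(joined) / sum(events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
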
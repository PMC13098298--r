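#' Rectangular lever zone
#'
#' The region of interest around a lever, a rectangle of `center +/-
#' half_extent` pixels (default +/-30 in x, +/-18 in y). Membership is
#' half-open (`lower <= p < upper` componentwise) so a point on the shared
#' edge of two adjacent zones belongs to exactly one.
#'
#' @param center Zone center `(x, y)` in px (the lever node position).
#' @param half_extent Half-widths `(x, y)` in px, both > 0.
#' @param role `"active"` or `"inactive"`.
#' @return An object of class `lever_zone`.
#' @export
lever_zone <- function(center, half_extent = c(30, 18),
                       role = c("active", "inactive")) {
  role <- match.arg(role)
  stopifnot(length(center) == 2L, length(half_extent) == 2L)
  if (any(!is.finite(half_extent)) || any(half_extent <= 0)) {
    stop("`half_extent` must be positive", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), half_extent = as.numeric(half_extent),
         role = role),
    class = "lever_zone"
  )
}

#' @export
print.lever_zone <- function(x, ...) {
  lo <- x$center - x$half_extent
  hi <- x$center + x$half_extent
  cat(sprintf("<lever_zone:%s> x in [%g, %g), y in [%g, %g)\n",
              x$role, lo[1L], hi[1L], lo[2L], hi[2L]))
  invisible(x)
}

#' Test points for zone membership
#' @param zone A [lever_zone()].
#' @param xy Two-column matrix of points (px).
#' @return Logical vector; half-open test `center - h <= p < center + h`.
#' @export
zone_contains <- function(zone, xy) {
  lo <- zone$center - zone$half_extent
  hi <- zone$center + zone$half_extent
  xy[, 1L] >= lo[1L] & xy[, 1L] < hi[1L] &
    xy[, 2L] >= lo[2L] & xy[, 2L] < hi[2L]
}

#' Derive a lever zone from a tracked lever node
#'
#' Levers are physically fixed, so the zone is anchored at the per-session
#' median of the lever node's tracked coordinates: the median is robust to
#' occasional tracking flicker, and a per-frame anchor would jitter the ROI.
#'
#' @param track A [pose_track()].
#' @param role `"active"` or `"inactive"`; reads node `lever_<role>`.
#' @param half_extent Zone half-widths in px.
#' @return A [lever_zone()].
#' @export
zone_from_lever_node <- function(track, role = c("active", "inactive"),
                                 half_extent = c(30, 18)) {
  role <- match.arg(role)
  xy <- node_xy(track, paste0("lever_", role))
  ok <- stats::complete.cases(xy)
  if (!any(ok)) {
    stop("lever node `lever_", role, "` has no observed frames",
         call. = FALSE)
  }
  lever_zone(c(median(xy[ok, 1L]), median(xy[ok, 2L])),
             half_extent = half_extent, role = role)
}

#' Count nose entrances into a lever zone
#'
#' An entrance is a frame where the node's inside-zone flag switches from
#' false to true; consecutive inside frames count once, and a track that
#' starts inside contributes no entrance until it first exits and re-enters.
#'
#' @param track An interpolated [pose_track()].
#' @param zone A [lever_zone()].
#' @param node Node tested for membership (default `"nose"`).
#' @param min_dwell_frames Optional debounce: an entrance only counts when
#'   the animal stays inside at least this many frames. The default (1)
#'   applies no debounce.
#' @return An `entrance_series`: `entrance_count`, 0-based
#'   `entrance_frames`, the node and the zone role.
#' @export
count_entrances <- function(track, zone, node = "nose",
                            min_dwell_frames = 1L) {
  xy <- node_xy(track, node)
  if (anyNA(xy)) {
    stop("track has missing ", node,
         " coordinates; run interpolate_track() first", call. = FALSE)
  }
  inside <- zone_contains(zone, xy)
  n <- length(inside)
  starts <- which(inside & !c(FALSE, inside[-n]))
  if (length(starts) && inside[1L]) starts <- starts[starts != 1L]
  if (min_dwell_frames > 1L && length(starts)) {
    r <- rle(inside)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    dwell <- r$lengths[r$values][match(starts, run_start[r$values])]
    starts <- starts[dwell >= min_dwell_frames]
  }
  structure(
    list(entrance_count = length(starts),
         entrance_frames = track$data$frame[starts],
         node = node, role = zone$role),
    class = "entrance_series"
  )
}

#' @export
print.entrance_series <- function(x, ...) {
  cat(sprintf("<entrance_series> %d entrances of %s into %s zone\n",
              x$entrance_count, x$node, x$role))
  invisible(x)
}

#' Entrances normalized by distance traveled
#'
#' Dividing zone entrances by locomotion separates directed seeking from
#' general hyperactivity. Below a minimal locomotion the ratio is undefined
#' and `NA` is returned (never 0 or Inf); downstream stages exclude such
#' recordings with a reason code.
#'
#' @param series An `entrance_series` from [count_entrances()], or a bare
#'   entrance count.
#' @param locomotion_m Distance traveled (m) over the same frames.
#' @param min_locomotion_m Smallest locomotion for which the ratio is
#'   defined (default 0.01 m).
#' @return Entrances per meter, or `NA` when locomotion is below the floor.
#' @export
entrances_per_meter <- function(series, locomotion_m,
                                min_locomotion_m = 0.01) {
  count <- if (inherits(series, "entrance_series")) {
    series$entrance_count
  } else {
    series
  }
  if (!is.finite(locomotion_m) || locomotion_m <= min_locomotion_m) {
    return(NA_real_)
  }
  count / locomotion_m
}
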
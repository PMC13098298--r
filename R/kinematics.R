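# Centered moving average with a symmetrically shrinking window at the
# edges, so output length equals input length. For even windows the extra
# frame sits on the trailing side.
smooth_ma <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 2L) return(x)
  left <- floor((window - 1) / 2)
  right <- window - 1L - left
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Path length of a tracked node
#'
#' Total distance traveled by a node, in meters: coordinates are smoothed by
#' a centered moving average of `window` frames (suppressing sub-pixel
#' tracking jitter before differencing), then frame-to-frame Euclidean
#' displacements are summed and converted with the cm/px calibration factor.
#' Locomotion is conventionally measured on the catheter (body anchor) node
#' and nose motion on the nose node.
#'
#' @param track An interpolated [pose_track()].
#' @param node Node name.
#' @param window Smoothing window in frames (>= 1; 1 disables smoothing).
#'   Edges use a symmetrically shrinking window so no frames are lost.
#' @param cm_per_px Conversion factor in cm per pixel.
#' @param smooth Whether the moving average is applied to the coordinates
#'   before differencing (default) or to the per-frame displacement series.
#' @return Distance in meters.
#' @export
path_length <- function(track, node = "catheter", window = 10,
                        cm_per_px = default_geometry()$cm_per_px,
                        smooth = c("coordinates", "displacements")) {
  smooth <- match.arg(smooth)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  xy <- node_xy(track, node)
  if (anyNA(xy)) {
    stop("track has missing ", node,
         " coordinates; run interpolate_track() first", call. = FALSE)
  }
  if (nrow(xy) < 2L) return(0)
  if (smooth == "coordinates") {
    d <- sqrt(diff(smooth_ma(xy[, 1L], window))^2 +
                diff(smooth_ma(xy[, 2L], window))^2)
  } else {
    d <- smooth_ma(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2), window)
  }
  sum(d) * cm_per_px / 100
}

#' Occupancy map of a tracked node
#'
#' Two-dimensional histogram of a node's pixel positions over a recording,
#' the building block of cohort-level "where did the animals spend time"
#' heatmaps. Maps with identical bin edges can be pooled across subjects or
#' sessions with [pool_occupancy()].
#'
#' @param track An interpolated [pose_track()].
#' @param node Node name.
#' @param bins Number of bins per axis, `c(nx, ny)` (a single value is
#'   recycled).
#' @param xlim,ylim Binning range; defaults to the chamber extent of
#'   `geometry` so maps from different recordings share edges.
#' @param geometry A [default_geometry()] supplying the default range.
#' @return An `occupancy_map`: counts matrix (`nx` rows, `ny` columns) plus
#'   bin edges and the number of contributing frames.
#' @export
occupancy_map <- function(track, node = "nose", bins = c(54, 45),
                          xlim = NULL, ylim = NULL,
                          geometry = default_geometry()) {
  if (length(bins) == 1L) bins <- rep(bins, 2L)
  if (any(bins < 1)) stop("`bins` must be >= 1", call. = FALSE)
  bins <- as.integer(bins)
  xy <- node_xy(track, node)
  if (anyNA(xy)) {
    stop("track has missing ", node,
         " coordinates; run interpolate_track() first", call. = FALSE)
  }
  if (is.null(xlim)) xlim <- c(0, geometry$chamber_px[1L])
  if (is.null(ylim)) ylim <- c(0, geometry$chamber_px[2L])
  xe <- seq(xlim[1L], xlim[2L], length.out = bins[1L] + 1L)
  ye <- seq(ylim[1L], ylim[2L], length.out = bins[2L] + 1L)
  ix <- findInterval(xy[, 1L], xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2L], ye, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- xy[, 1L] >= xlim[1L] & xy[, 1L] <= xlim[2L] &
    xy[, 2L] >= ylim[1L] & xy[, 2L] <= ylim[2L]
  counts <- matrix(0L, nrow = bins[1L], ncol = bins[2L])
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_len(bins[1L])),
                 factor(iy[keep], levels = seq_len(bins[2L])))
    counts <- matrix(as.integer(tab), nrow = bins[1L])
  }
  structure(
    list(counts = counts, xedges = xe, yedges = ye, n_frames = sum(keep)),
    class = "occupancy_map"
  )
}

#' Pool occupancy maps by summing counts
#' @param ... `occupancy_map` objects with identical bin edges, or a single
#'   list of them.
#' @return A pooled `occupancy_map`.
#' @export
pool_occupancy <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1L]], "occupancy_map")) {
    maps <- maps[[1L]]
  }
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (!isTRUE(all.equal(m$xedges, ref$xedges)) ||
        !isTRUE(all.equal(m$yedges, ref$yedges))) {
      stop("occupancy maps must share bin edges to be pooled", call. = FALSE)
    }
    ref$counts <- ref$counts + m$counts
    ref$n_frames <- ref$n_frames + m$n_frames
  }
  ref
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d bins, %d frames\n",
              nrow(x$counts), ncol(x$counts), x$n_frames))
  invisible(x)
}

#' @export
plot.occupancy_map <- function(x, ...) {
  graphics::image(x = x$xedges, y = x$yedges, z = x$counts,
                  ylim = rev(range(x$yedges)),  # image convention: y down
                  xlab = "x (px)", ylab = "y (px)", ...)
  invisible(x)
}

#' Write an occupancy map as plain-text matrix
#' @param map An `occupancy_map`.
#' @param path Output path (tab-separated counts; bin edges in `#` header).
#' @export
write_occupancy <- function(map, path) {
  writeLines(c(
    sprintf("# xedges: %s", paste(format(map$xedges), collapse = ",")),
    sprintf("# yedges: %s", paste(format(map$yedges), collapse = ","))
  ), path)
  utils::write.table(map$counts, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
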
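#' Per-frame pose track
#'
#' A `pose_track` holds one recording's pose-estimation output: one row per
#' frame, one `(x, y)` pixel-coordinate pair per tracked node, plus the frame
#' rate and a session reference. Missing detections are `NA`; after
#' [interpolate_track()] a track is gap-free. Pixel coordinates follow the
#' image convention (origin top-left, y increasing downward); frame indices
#' are 0-based.
#'
#' @param data A data frame with a `frame` column (0-based integers) and,
#'   for every node, `<node>.x` / `<node>.y` numeric columns. Gaps in the
#'   frame sequence are filled with all-missing rows so the stored index is
#'   strictly increasing and gap-free.
#' @param frame_rate Frames per second (> 0).
#' @param session_ref Identifier linking the track to a session record.
#' @return An object of class `pose_track`.
#' @seealso [read_pose_table()], [interpolate_track()], [align_to_lever()]
#' @export
pose_track <- function(data, frame_rate, session_ref = NA_character_) {
  stopifnot(is.data.frame(data), "frame" %in% names(data))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  coord_cols <- setdiff(names(data), "frame")
  bad <- coord_cols[!grepl("\\.(x|y)$", coord_cols)]
  if (length(bad)) {
    stop("non-coordinate columns in pose table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$frame <- as.integer(data$frame)
  if (is.unsorted(data$frame, strictly = TRUE)) {
    data <- data[order(data$frame), ]
    if (anyDuplicated(data$frame)) {
      stop("duplicated frame indices in pose table", call. = FALSE)
    }
  }
  # make the frame index gap-free: absent frames become all-missing rows
  full <- seq(data$frame[1L], data$frame[nrow(data)])
  if (length(full) != nrow(data)) {
    template <- tibble::tibble(frame = full)
    data <- dplyr::left_join(template, data, by = "frame")
  }
  for (cl in coord_cols) data[[cl]] <- as.numeric(data[[cl]])
  structure(
    list(data = data, frame_rate = frame_rate, session_ref = session_ref),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf(
    "<pose_track> %d frames @ %g fps, %d nodes (%s), %.1f%% missing\n",
    n_frames(x), x$frame_rate, length(track_nodes(x)), x$session_ref,
    100 * mean(is.na(as.matrix(x$data[-1L])))
  ))
  invisible(x)
}

#' Nodes tracked in a pose track
#' @param track A [pose_track()].
#' @return Character vector of node names.
#' @export
track_nodes <- function(track) {
  unique(sub("\\.(x|y)$", "", setdiff(names(track$data), "frame")))
}

#' Number of frames in a pose track
#' @param track A [pose_track()].
#' @export
n_frames <- function(track) nrow(track$data)

#' Extract one node's coordinates as a two-column matrix
#' @param track A [pose_track()].
#' @param node Node name, e.g. `"nose"`.
#' @return A `n_frames x 2` numeric matrix with columns `x`, `y`.
#' @export
node_xy <- function(track, node) {
  cx <- paste0(node, ".x")
  cy <- paste0(node, ".y")
  if (!all(c(cx, cy) %in% names(track$data))) {
    stop("unknown node: ", node, call. = FALSE)
  }
  cbind(x = track$data[[cx]], y = track$data[[cy]])
}

subset_track <- function(track, idx) {
  out <- track
  out$data <- track$data[idx, , drop = FALSE]
  out
}

#' Write a pose track as delimited text
#'
#' The dialect is a plain CSV with a `frame,<node>.x,<node>.y,...` header,
#' preceded by `#`-prefixed metadata lines carrying the frame rate and the
#' session reference. Missing coordinates are written as empty cells.
#'
#' @param track A [pose_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path) {
  meta <- c(
    "# prelever pose table v1",
    sprintf("# frame_rate: %s", format(track$frame_rate, digits = 15)),
    sprintf("# session_ref: %s", track$session_ref)
  )
  writeLines(meta, path)
  data.table::fwrite(track$data, path, append = TRUE, col.names = TRUE,
                     na = "", quote = FALSE)
  invisible(path)
}

#' Read a delimited pose table
#'
#' Parses the delimited dialect written by [write_pose_table()] (SLEAP-style
#' per-frame node coordinates). Cells that cannot be parsed as numbers become
#' missing values; gaps in the frame index are filled with all-missing rows.
#'
#' @param path File path.
#' @param required_nodes Nodes that must be present; a missing one raises a
#'   format error naming it.
#' @param frame_rate Fallback frame rate when the file carries none.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, required_nodes = "nose", frame_rate = NULL) {
  if (!file.exists(path)) stop("no such pose table: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty pose table: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta <- grep("^#", head_lines, value = TRUE)
  session_ref <- NA_character_
  for (ln in meta) {
    if (grepl("^#\\s*frame_rate:", ln)) {
      frame_rate <- as.numeric(sub("^#\\s*frame_rate:\\s*", "", ln))
    } else if (grepl("^#\\s*session_ref:", ln)) {
      session_ref <- trimws(sub("^#\\s*session_ref:\\s*", "", ln))
    }
  }
  if (is.null(frame_rate) || is.na(frame_rate)) {
    stop("pose table carries no frame rate and none was supplied: ", path,
         call. = FALSE)
  }
  df <- data.table::fread(path, skip = length(meta), na.strings = c("", "NA"),
                          data.table = FALSE)
  if (!nrow(df)) stop("pose table has no frames: ", path, call. = FALSE)
  if (!"frame" %in% names(df)) {
    stop("pose table lacks a `frame` column: ", path, call. = FALSE)
  }
  for (cl in setdiff(names(df), "frame")) {
    if (!is.numeric(df[[cl]])) {
      df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
    }
  }
  have <- unique(sub("\\.(x|y)$", "", setdiff(names(df), "frame")))
  absent <- setdiff(required_nodes, have)
  if (length(absent)) {
    stop("pose table is missing required node(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pose_track(df, frame_rate = frame_rate, session_ref = session_ref)
}

#' Fill missing coordinates by interpolation
#'
#' Interior gaps are filled per coordinate by linear interpolation between the
#' nearest observed frames; leading and trailing gaps take the nearest
#' observed value. Observed coordinates are never altered.
#'
#' @param track A [pose_track()].
#' @return A gap-free [pose_track()].
#' @export
interpolate_track <- function(track) {
  out <- track
  for (cl in setdiff(names(track$data), "frame")) {
    x <- track$data[[cl]]
    if (all(is.na(x))) {
      stop("node has no observed frames: ", sub("\\.(x|y)$", "", cl),
           call. = FALSE)
    }
    if (anyNA(x)) {
      out$data[[cl]] <- if (sum(!is.na(x)) == 1L) {
        rep(x[!is.na(x)], length(x))
      } else {
        zoo::na.approx(x, na.rm = FALSE, rule = 2)
      }
    }
  }
  out
}

#' Pixel-to-centimeter conversion factor
#'
#' Because a fisheye lens distorts the chamber image, the conversion factor is
#' the mean of five independent cm/px ratios: two length measurements against
#' the known physical length and three width measurements (top, middle,
#' bottom) against the known physical width.
#'
#' @param length_px Two pixel measurements of the chamber length.
#' @param width_px Three pixel measurements of the chamber width.
#' @param known_length_cm,known_width_cm Physical grid dimensions in cm.
#' @return The conversion factor in cm per pixel.
#' @export
compute_cm_per_px <- function(length_px, width_px, known_length_cm,
                              known_width_cm) {
  if (length(length_px) != 2L || length(width_px) != 3L) {
    stop("expected two length and three width pixel measurements",
         call. = FALSE)
  }
  vals <- c(length_px, width_px, known_length_cm, known_width_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all measurements must be positive and finite", call. = FALSE)
  }
  mean(c(known_length_cm / length_px, known_width_cm / width_px))
}
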
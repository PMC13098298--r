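#' Structured exclusion record
#'
#' Recordings that cannot be analyzed are never dropped silently: every stage
#' that rejects a recording returns a reason-coded exclusion that the
#' pipeline collects into an audit table.
#'
#' @param reason Short machine-readable reason code.
#' @param session_ref Session identifier, if known.
#' @param subject_id Subject identifier, if known.
#' @param details Free-text detail.
#' @return An object of class `prelever_exclusion`.
#' @export
new_exclusion <- function(reason, session_ref = NA_character_,
                          subject_id = NA_character_, details = "") {
  structure(
    list(reason = reason, session_ref = session_ref,
         subject_id = subject_id, details = details),
    class = "prelever_exclusion"
  )
}

#' @rdname new_exclusion
#' @param x Object to test.
#' @export
is_exclusion <- function(x) inherits(x, "prelever_exclusion")

#' @export
print.prelever_exclusion <- function(x, ...) {
  cat(sprintf("<exclusion> %s (%s/%s) %s\n", x$reason,
              x$subject_id, x$session_ref, x$details))
  invisible(x)
}

#' Align a recording to lever extension
#'
#' Self-administration recordings are trimmed to a fixed window around the
#' moment the levers extend into the chamber: exactly `pre_min` minutes of
#' frames before extension and `post_min` after, so every session contributes
#' segments of consistent length. Noncontingent recordings have no lever
#' extension and are instead trimmed symmetrically to `nc_trim_min` minutes.
#'
#' @param track A [pose_track()] (interpolated or not).
#' @param record The matching session record; its `lever_extension_min` field
#'   ( `NA` for noncontingent phases) drives the alignment.
#' @param pre_min,post_min Segment lengths in minutes around lever extension.
#' @param nc_trim_min Trimmed length for noncontingent recordings.
#' @return An `aligned_session` (fields `pre`, `post`, `full`,
#'   `lever_extension_frame`) or a reason-coded [new_exclusion()] when the
#'   extension sits too close to a recording edge.
#' @export
align_to_lever <- function(track, record, pre_min = 12.5, post_min = 12.5,
                           nc_trim_min = 25) {
  fr <- track$frame_rate
  n <- n_frames(track)
  ext_min <- record$lever_extension_min
  if (is.null(ext_min) || is.na(ext_min)) {
    n_keep <- min(n, round(nc_trim_min * 60 * fr))
    drop <- floor((n - n_keep) / 2)
    seg <- subset_track(track, seq.int(drop + 1L, drop + n_keep))
    return(structure(
      list(pre = NULL, post = NULL, full = seg, lever_extension_frame = NA),
      class = "aligned_session"
    ))
  }
  ext_f <- round(ext_min * 60 * fr)  # 0-based frame of extension
  n_pre <- round(pre_min * 60 * fr)
  n_post <- round(post_min * 60 * fr)
  first <- track$data$frame[1L]
  ext_row <- ext_f - first + 1L      # row holding the first post-lever frame
  if (ext_row - n_pre < 1L) {
    return(new_exclusion("insufficient pre-lever span", record$session_id,
                         record$subject_id,
                         sprintf("extension at %.2f min", ext_min)))
  }
  if (ext_row + n_post - 1L > n) {
    return(new_exclusion("insufficient post-lever span", record$session_id,
                         record$subject_id,
                         sprintf("extension at %.2f min", ext_min)))
  }
  structure(
    list(
      pre = subset_track(track, seq.int(ext_row - n_pre, ext_row - 1L)),
      post = subset_track(track, seq.int(ext_row, ext_row + n_post - 1L)),
      full = NULL,
      lever_extension_frame = ext_f
    ),
    class = "aligned_session"
  )
}

#' @export
print.aligned_session <- function(x, ...) {
  if (is.null(x$pre)) {
    cat(sprintf("<aligned_session> noncontingent, %d trimmed frames\n",
                n_frames(x$full)))
  } else {
    cat(sprintf("<aligned_session> %d pre + %d post frames around frame %d\n",
                n_frames(x$pre), n_frames(x$post), x$lever_extension_frame))
  }
  invisible(x)
}
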
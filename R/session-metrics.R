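#' Infusions in the loading window
#'
#' Counts infusion onsets in the first `window_min` minutes after lever
#' extension (half-open window), the span of maximal drug intake ("loading
#' behavior") that also matches the pre-lever observation length. The window
#' can alternatively be anchored at recording start.
#'
#' @param record A `session_record`.
#' @param window_min Window length in minutes.
#' @param from Anchor: `"extension"` (default) or `"recording"` start.
#' @return Integer count.
#' @export
first15_infusions <- function(record, window_min = 15,
                              from = c("extension", "recording")) {
  from <- match.arg(from)
  t0 <- if (from == "extension" && !is.na(record$lever_extension_min)) {
    record$lever_extension_min
  } else 0
  sum(record$infusions$time_min >= t0 &
        record$infusions$time_min < t0 + window_min)
}

#' Abstinence code for an inter-session gap
#'
#' Snaps the gap between the end of one session and the start of the next to
#' the standard codes: 18 h (consecutive weekdays), 66 h (two-day weekend)
#' or 90 h (three-day weekend), provided the gap falls within `tol_h` hours
#' of a code. A gap outside every band is a schedule anomaly and raises an
#' error.
#'
#' @param prev_end,next_start `POSIXct` session boundary times (vectorized),
#'   or numeric gaps in hours via `gap_h`.
#' @param tol_h Snapping tolerance in hours.
#' @param gap_h Optional precomputed gaps in hours (overrides the times).
#' @return Numeric vector of codes in `c(18, 66, 90)`.
#' @export
abstinence_code <- function(prev_end = NULL, next_start = NULL, tol_h = 6,
                            gap_h = NULL) {
  if (is.null(gap_h)) {
    gap_h <- as.numeric(difftime(next_start, prev_end, units = "hours"))
  }
  if (any(gap_h <= 0)) {
    stop("session gap must be positive", call. = FALSE)
  }
  bands <- c(18, 66, 90)
  idx <- apply(abs(outer(gap_h, bands, "-")), 1L, which.min)
  dev <- abs(gap_h - bands[idx])
  if (any(dev > tol_h)) {
    bad <- which(dev > tol_h)[1L]
    stop(sprintf(
      "schedule anomaly: gap of %.1f h is outside every abstinence band",
      gap_h[bad]), call. = FALSE)
  }
  bands[idx]
}

#' Percent difference from a baseline
#'
#' `100 * (value - baseline) / baseline`, vectorized. A nonpositive baseline
#' leaves the difference undefined and yields `NA` (excluded downstream),
#' never an infinity.
#'
#' @param value,baseline Numeric vectors (recycled).
#' @return Percent differences.
#' @export
percent_diff <- function(value, baseline) {
  n <- max(length(value), length(baseline))
  value <- rep_len(value, n)
  baseline <- rep_len(baseline, n)
  out <- rep(NA_real_, n)
  ok <- is.finite(baseline) & baseline > 0
  out[ok] <- 100 * (value[ok] - baseline[ok]) / baseline[ok]
  out
}

#' Progressive-ratio response requirement
#'
#' Presses required for the n-th infusion under the exponential progressive
#' ratio schedule `5 * exp(0.2 * n) - 5`, rounded to the nearest integer
#' (half away from zero) and floored at one press.
#'
#' @param injection_number 1-based injection number (vectorized).
#' @return Integer press requirements.
#' @export
pr_requirement <- function(injection_number) {
  if (any(injection_number < 1) ||
      any(injection_number != round(injection_number))) {
    stop("`injection_number` must be a positive integer", call. = FALSE)
  }
  v <- 5 * exp(0.2 * injection_number) - 5
  pmax(1L, as.integer(floor(v + 0.5)))
}

#' Progressive-ratio breakpoint
#'
#' The requirement of the last ratio completed before the first 60-min span
#' with no completed ratio (at which point the session ends); if the whole
#' session passes without such a lapse, the last completed ratio. A session
#' with no completions has breakpoint 0 by convention.
#'
#' @param record A progressive-ratio `session_record` whose infusions carry
#'   completion times (and requirements, recomputed when absent).
#' @param lapse_min Lapse length defining the breakpoint.
#' @return The breakpoint ratio (presses).
#' @export
pr_breakpoint <- function(record, lapse_min = 60) {
  inf <- record$infusions
  if (!nrow(inf)) return(0L)
  ord <- order(inf$time_min)
  times <- inf$time_min[ord]
  reqs <- inf$requirement[ord]
  if (anyNA(reqs)) reqs <- pr_requirement(seq_along(times))
  t0 <- if (is.na(record$lever_extension_min)) 0 else {
    record$lever_extension_min
  }
  gaps <- diff(c(t0, times))
  lapse_at <- which(gaps >= lapse_min)
  if (length(lapse_at)) {
    j <- lapse_at[1L]
    if (j == 1L) return(0L)
    return(reqs[j - 1L])
  }
  reqs[length(reqs)]
}

#' Derive all per-session scalars for one recording
#'
#' Runs the full metric stage for a single (pose track, session record)
#' pair: interpolation, lever-zone construction, alignment to lever
#' extension, smoothed path lengths, zone entrances per meter, intake
#' windows and (for progressive-ratio sessions) the breakpoint.
#' Self-administration recordings yield pre-/post-lever metrics;
#' noncontingent recordings are treated as all pre-lever and yield
#' whole-segment metrics. Unusable recordings return a reason-coded
#' [new_exclusion()] instead of a row.
#'
#' @param track A [pose_track()].
#' @param record The matching `session_record`.
#' @param geometry A [default_geometry()].
#' @param window Coordinate smoothing window (frames) for path lengths.
#' @param half_extent Lever-zone half-widths (px).
#' @param min_locomotion_m Locomotion floor below which entrances per meter
#'   are undefined.
#' @return A one-row tibble of session metrics, or an exclusion.
#' @export
compute_session_metrics <- function(track, record,
                                    geometry = default_geometry(),
                                    window = 10, half_extent = c(30, 18),
                                    min_locomotion_m = 0.01) {
  track <- interpolate_track(track)
  cmpx <- geometry$cm_per_px
  zones <- list(
    active = zone_from_lever_node(track, "active", half_extent),
    inactive = zone_from_lever_node(track, "inactive", half_extent)
  )
  aligned <- align_to_lever(track, record)
  if (is_exclusion(aligned)) return(aligned)

  seg_metrics <- function(seg) {
    loco <- path_length(seg, "catheter", window = window, cm_per_px = cmpx)
    act <- count_entrances(seg, zones$active)
    inact <- count_entrances(seg, zones$inactive)
    list(
      locomotion_m = loco,
      nose_motion_m = path_length(seg, "nose", window = window,
                                  cm_per_px = cmpx),
      active_entrances = act$entrance_count,
      inactive_entrances = inact$entrance_count,
      active_epm = entrances_per_meter(act, loco, min_locomotion_m),
      inactive_epm = entrances_per_meter(inact, loco, min_locomotion_m)
    )
  }

  base <- tibble::tibble(
    subject_id = record$subject_id,
    session_id = record$session_id,
    session_key = record$session_key,
    type = record$type,
    index = record$index,
    phase = record$phase %||% NA_character_,
    infusions_total = nrow(record$infusions),
    infusions_first15 = first15_infusions(record),
    shocks_total = sum(record$infusions$shocked),
    breakpoint = if (identical(record$type, "PR")) pr_breakpoint(record)
                 else NA_integer_
  )
  if (is.null(aligned$pre)) {
    m <- seg_metrics(aligned$full)
    dplyr::bind_cols(base, tibble::tibble(
      pre_lever_locomotion_m = NA_real_,
      pre_lever_nose_motion_m = NA_real_,
      pre_active_entrances = NA_integer_,
      pre_inactive_entrances = NA_integer_,
      pre_active_epm = NA_real_,
      pre_inactive_epm = NA_real_,
      post_lever_locomotion_m = NA_real_,
      locomotion_m = m$locomotion_m,
      nose_motion_m = m$nose_motion_m,
      active_entrances = m$active_entrances,
      inactive_entrances = m$inactive_entrances,
      active_epm = m$active_epm,
      inactive_epm = m$inactive_epm
    ))
  } else {
    pre <- seg_metrics(aligned$pre)
    post_loco <- path_length(aligned$post, "catheter", window = window,
                             cm_per_px = cmpx)
    dplyr::bind_cols(base, tibble::tibble(
      pre_lever_locomotion_m = pre$locomotion_m,
      pre_lever_nose_motion_m = pre$nose_motion_m,
      pre_active_entrances = pre$active_entrances,
      pre_inactive_entrances = pre$inactive_entrances,
      pre_active_epm = pre$active_epm,
      pre_inactive_epm = pre$inactive_epm,
      post_lever_locomotion_m = post_loco,
      locomotion_m = NA_real_,
      nose_motion_m = NA_real_,
      active_entrances = NA_integer_,
      inactive_entrances = NA_integer_,
      active_epm = NA_real_,
      inactive_epm = NA_real_
    ))
  }
}

#' Assemble the long-format cohort table
#'
#' Binds per-recording metric rows and joins the per-session abstinence
#' codes from the schedule. One row per (subject, recording) minus
#' reason-coded exclusions.
#'
#' @param metric_rows List or tibble of [compute_session_metrics()] rows.
#' @param schedule The `schedule_spec` the cohort followed (for abstinence
#'   codes); `NULL` skips the join.
#' @param tol_h Abstinence snapping tolerance.
#' @return A tibble (the cohort table).
#' @export
build_cohort_table <- function(metric_rows, schedule = NULL, tol_h = 6) {
  tbl <- if (is.data.frame(metric_rows)) {
    tibble::as_tibble(metric_rows)
  } else {
    dplyr::bind_rows(metric_rows)
  }
  if (!is.null(schedule)) {
    tbl <- dplyr::left_join(tbl, schedule_abstinence(schedule, tol_h),
                            by = "session_key")
  }
  tbl
}
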
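#' Study protocol constants
#'
#' Drug, infusion and session-structure constants used by the event
#' generator and the metric stages: the self-administration unit dose (0.5
#' mg/kg over a 6-s infusion followed by a 20-s timeout, giving a 26-s
#' minimum between infusion onsets), the noncontingent challenge dose (1.5
#' mg/kg, three times the self-administration unit dose), the 30% footshock
#' contingency of Shock sessions, lever extension after 15 min of recording,
#' and the loading-window intake multiplier.
#'
#' @param sa_unit_dose_mg_kg Per-infusion dose during self-administration.
#' @param noncontingent_dose_mg_kg Single noncontingent challenge dose.
#' @param infusion_duration_s,timeout_s Infusion length and post-infusion
#'   timeout; their sum is the refractory period between infusion onsets.
#' @param shock_prob Probability that a Shock-session infusion is paired
#'   with a footshock.
#' @param lever_extension_min Minutes of recording before levers extend.
#' @param loading_window_min,loading_multiplier First-minutes window of
#'   elevated intake and its rate multiplier relative to session baseline.
#' @param base_infusions Expected infusions for the first session of each
#'   fixed-ratio session type (before escalation).
#' @param pr_lapse_min Progressive-ratio lapse defining the breakpoint.
#' @param drug_effect Multiplicative locomotor response to the first
#'   noncontingent drug challenge (subsequent challenges scale it by the
#'   subject's sensitization slope).
#' @param nc_seek_gain Per-challenge scaling of lever-zone attraction during
#'   noncontingent sessions (seeking emerges over repeated challenges).
#' @param prelever_speed_gain Pre-lever locomotor gain per unit of salience
#'   weight (anticipatory hyperactivity).
#' @param post_lever_speed_mult Locomotor multiplier once drug is on board
#'   during self-administration.
#' @return A list of class `study_protocol`.
#' @export
default_protocol <- function(sa_unit_dose_mg_kg = 0.5,
                             noncontingent_dose_mg_kg = 1.5,
                             infusion_duration_s = 6,
                             timeout_s = 20,
                             shock_prob = 0.3,
                             lever_extension_min = 15,
                             loading_window_min = 15,
                             loading_multiplier = 3,
                             base_infusions = c(ShA = 20, LgA = 45,
                                                Preshock = 15, Shock = 15),
                             pr_lapse_min = 60,
                             drug_effect = 2,
                             nc_seek_gain = c(0.2, 0.5, 1),
                             prelever_speed_gain = 0.15,
                             post_lever_speed_mult = 1.6) {
  structure(
    list(sa_unit_dose_mg_kg = sa_unit_dose_mg_kg,
         noncontingent_dose_mg_kg = noncontingent_dose_mg_kg,
         infusion_duration_s = infusion_duration_s,
         timeout_s = timeout_s,
         min_gap_s = infusion_duration_s + timeout_s,
         shock_prob = shock_prob,
         lever_extension_min = lever_extension_min,
         loading_window_min = loading_window_min,
         loading_multiplier = loading_multiplier,
         base_infusions = base_infusions,
         pr_lapse_min = pr_lapse_min,
         drug_effect = drug_effect,
         nc_seek_gain = nc_seek_gain,
         prelever_speed_gain = prelever_speed_gain,
         post_lever_speed_mult = post_lever_speed_mult),
    class = "study_protocol"
  )
}

sa_session_types <- function() c("ShA", "LgA", "PR", "Preshock", "Shock")

recording_row <- function(session_key, type, index, phase, date, start_hour,
                          duration_min, recording_min, lever_extension_min) {
  tibble::tibble(
    session_id = if (is.na(phase)) session_key else {
      paste0(session_key, "_", phase)
    },
    session_key = session_key, type = type, index = index, phase = phase,
    date = date,
    start_time = as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC") +
      start_hour * 3600,
    duration_min = duration_min, recording_min = recording_min,
    lever_extension_min = lever_extension_min
  )
}

#' Cohort session schedule
#'
#' Builds the default experimental calendar: weekday (Mon-Fri) sessions
#' comprising 3 noncontingent sessions (each a Baseline/Saline/Drug triplet
#' of 30-min recordings), 10 two-hour Short Access, 15 six-hour Long Access,
#' 3 progressive-ratio, one Preshock and one Shock session — 30
#' self-administration sessions in all, every one video-recorded for 30 min
#' with levers extending after 15 min. Noncontingent 01 precedes Short
#' Access 01; Noncontingent 02 follows Short Access 09 (so Short Access
#' 07-09 are the last Short Access sessions of that week); one holiday
#' Monday during Long Access produces a three-day (90-h) abstinence gap in
#' addition to the routine 18-h weekday and 66-h weekend gaps.
#'
#' @param start_date First session date (a Monday).
#' @param start_hour Daily session start hour (24-h clock).
#' @param geometry A [default_geometry()] carried along with the calendar.
#' @return A `schedule_spec`: a list with a `sessions` tibble (one row per
#'   recording; noncontingent sessions contribute three rows) and the
#'   geometry.
#' @export
default_schedule <- function(start_date = as.Date("2024-01-01"),
                             start_hour = 8,
                             geometry = default_geometry()) {
  if (format(start_date, "%u") != "1") {
    stop("`start_date` must be a Monday", call. = FALSE)
  }
  # weekday offsets (days from start) laid out week by week; NA = holiday
  day_of <- function(week, dow) start_date + (week - 1L) * 7L + (dow - 1L)
  plan <- list()
  add <- function(type, index, week, dow, duration) {
    plan[[length(plan) + 1L]] <<- list(type = type, index = index,
                                       date = day_of(week, dow),
                                       duration = duration)
  }
  add("NC", 1L, 1L, 1L, 110)
  for (k in 1:4) add("ShA", k, 1L, k + 1L, 120)
  for (k in 5:9) add("ShA", k, 2L, k - 4L, 120)
  add("NC", 2L, 3L, 1L, 110)
  add("ShA", 10L, 3L, 2L, 120)
  for (k in 1:3) add("LgA", k, 3L, k + 2L, 360)
  for (k in 4:8) add("LgA", k, 4L, k - 3L, 360)
  for (k in 9:12) add("LgA", k, 5L, k - 7L, 360)   # Monday holiday (90 h gap)
  for (k in 13:15) add("LgA", k, 6L, k - 12L, 360)
  add("NC", 3L, 6L, 4L, 110)
  add("PR", 1L, 6L, 5L, 360)
  add("PR", 2L, 7L, 1L, 360)
  add("PR", 3L, 7L, 2L, 360)
  add("Preshock", 1L, 7L, 3L, 60)
  add("Shock", 1L, 7L, 4L, 60)

  rows <- lapply(plan, function(s) {
    key <- sprintf("%s_%02d", s$type, s$index)
    if (s$type == "NC") {
      dplyr::bind_rows(lapply(seq_along(c("Baseline", "Saline", "Drug")),
        function(j) {
          phase <- c("Baseline", "Saline", "Drug")[j]
          recording_row(key, s$type, s$index, phase, s$date,
                        start_hour + (j - 1L) * 40 / 60,
                        duration_min = 30, recording_min = 30,
                        lever_extension_min = NA_real_)
        }))
    } else {
      recording_row(key, s$type, s$index, NA_character_, s$date, start_hour,
                    duration_min = s$duration, recording_min = 30,
                    lever_extension_min = 15)
    }
  })
  sessions <- dplyr::bind_rows(rows)
  structure(list(sessions = sessions, geometry = geometry),
            class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  s <- x$sessions
  cat(sprintf("<schedule_spec> %d recordings over %d sessions (%s to %s)\n",
              nrow(s), length(unique(s$session_key)),
              min(s$date), max(s$date)))
  print(table(s$type))
  invisible(x)
}

#' Per-session abstinence codes for a schedule
#'
#' Computes the gap between the end of each session and the start of the
#' next and snaps it to the standard abstinence codes via
#' [abstinence_code()]. The first session has no code.
#'
#' @param schedule A [default_schedule()]-style `schedule_spec`.
#' @param tol_h Snapping tolerance in hours.
#' @param strict Raise an error on a gap outside every band (the behavior of
#'   [abstinence_code()]); the default codes such gaps `NA`, which keeps
#'   partial schedules (session subsets) usable.
#' @return Tibble with `session_key` and `abstinence_h` (NA for the first).
#' @export
schedule_abstinence <- function(schedule, tol_h = 6, strict = FALSE) {
  s <- schedule$sessions
  s$end_time <- s$start_time + ifelse(s$type == "NC", s$recording_min,
                                      s$duration_min) * 60
  per <- dplyr::summarise(
    dplyr::group_by(s, .data$session_key),
    start = min(.data$start_time), end = max(.data$end_time),
    .groups = "drop"
  )
  per <- per[order(per$start), ]
  gaps <- as.numeric(difftime(per$start[-1L], per$end[-nrow(per)],
                              units = "hours"))
  codes <- if (strict) {
    abstinence_code(gap_h = gaps, tol_h = tol_h)
  } else {
    vapply(gaps, function(g) {
      tryCatch(abstinence_code(gap_h = g, tol_h = tol_h),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  tibble::tibble(session_key = per$session_key,
                 abstinence_h = c(NA_real_, codes))
}
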
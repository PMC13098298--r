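# Small builders shared across the suite.

make_track <- function(coords, frame_rate = 10, frame = NULL,
                       session_ref = "test") {
  # coords: named list node -> n x 2 matrix (or data frame columns directly)
  n <- nrow(coords[[1L]])
  cols <- list(frame = if (is.null(frame)) 0:(n - 1L) else frame)
  for (nd in names(coords)) {
    cols[[paste0(nd, ".x")]] <- coords[[nd]][, 1L]
    cols[[paste0(nd, ".y")]] <- coords[[nd]][, 2L]
  }
  pose_track(tibble::as_tibble(cols), frame_rate = frame_rate,
             session_ref = session_ref)
}

# constant-position matrix
const_xy <- function(n, x, y) cbind(rep(x, n), rep(y, n))

make_record <- function(type = "ShA", index = 1L, phase = NA_character_,
                        infusion_times = numeric(), shocked = NULL,
                        requirement = NULL, duration_min = 120,
                        lever_extension_min = 15,
                        subject_id = "R001",
                        session_id = sprintf("%s_%02d", type, index)) {
  k <- length(infusion_times)
  structure(
    list(subject_id = subject_id, session_id = session_id,
         session_key = session_id, type = type, index = index, phase = phase,
         start_time = as.POSIXct("2024-01-02 08:00:00", tz = "UTC"),
         duration_min = duration_min, recording_min = 30,
         lever_extension_min = lever_extension_min,
         unit_dose_mg_kg = 0.5,
         infusions = tibble::tibble(
           time_min = infusion_times,
           shocked = shocked %||% rep(FALSE, k),
           requirement = requirement %||% rep(NA_integer_, k))),
    class = "session_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_subject <- function(salience_weight = 1, baseline_speed = 3,
                         sensitization_slope = 1, escalation_rate = 0.5,
                         rng_seed = 42L, subject_id = "R001") {
  tibble::tibble(subject_id = subject_id, baseline_speed = baseline_speed,
                 salience_weight = salience_weight,
                 sensitization_slope = sensitization_slope,
                 escalation_rate = escalation_rate, press_rate = 3,
                 sex = "M", rng_seed = rng_seed)
}

test_session <- function(type = "ShA", index = 1L, phase = NA_character_,
                         duration_min = 120, recording_min = 30,
                         lever_extension_min = if (type == "NC") NA_real_
                                               else 15,
                         session_id = if (is.na(phase)) {
                           sprintf("%s_%02d", type, index)
                         } else sprintf("%s_%02d_%s", type, index, phase)) {
  list(session_id = session_id, session_key = sprintf("%s_%02d", type, index),
       type = type, index = index, phase = phase,
       duration_min = duration_min, recording_min = recording_min,
       lever_extension_min = lever_extension_min)
}
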
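new_session_record <- function(subject_id, session, infusions,
                               unit_dose_mg_kg, lever_extension_min,
                               duration_min) {
  session <- as.list(session)
  structure(
    list(subject_id = subject_id,
         session_id = session$session_id %||% NA_character_,
         session_key = session$session_key %||% session$session_id,
         type = session$type, index = session$index,
         phase = session$phase %||% NA_character_,
         start_time = session$start_time %||% as.POSIXct(NA),
         duration_min = duration_min,
         recording_min = session$recording_min %||% 30,
         lever_extension_min = lever_extension_min,
         unit_dose_mg_kg = unit_dose_mg_kg,
         infusions = infusions),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s %s: %d infusions over %g min\n",
              x$subject_id, x$session_id, nrow(x$infusions), x$duration_min))
  invisible(x)
}

empty_infusions <- function() {
  tibble::tibble(time_min = numeric(), shocked = logical(),
                 requirement = integer())
}

# Draw infusion onsets on [t0, t_end) minutes from a rate process with an
# enforced refractory gap and an elevated rate in the loading window.
draw_infusion_times <- function(t0, t_end, rate_per_min, min_gap_min,
                                loading_end, loading_multiplier) {
  if (rate_per_min <= 0 || t_end <= t0) return(numeric())
  times <- numeric()
  t <- t0
  first <- TRUE
  repeat {
    r <- rate_per_min * if (t < loading_end) loading_multiplier else 1
    gap <- rexp(1, r) + if (first) 0 else min_gap_min
    t <- t + gap
    first <- FALSE
    if (t >= t_end) break
    times <- c(times, t)
  }
  times
}

#' Simulate one session's operant event log
#'
#' Generates the session record for one subject-session. Fixed-ratio
#' sessions (Short Access, Long Access, Preshock, Shock) draw infusion
#' onsets from a rate process with a tripled rate in the first 15 min after
#' lever extension (loading behavior), a per-session escalation trend set by
#' the subject's escalation rate, and an enforced minimum inter-onset gap of
#' 26 s (6-s infusion plus 20-s timeout). During Shock sessions each
#' infusion is independently paired with a footshock with probability 0.30.
#' Progressive-ratio sessions simulate ratio completions under the
#' exponential response requirement (see [pr_requirement()]) and end at the
#' first 60-min lapse. Noncontingent phases carry a single
#' experimenter-delivered infusion (saline or a drug dose three times the
#' self-administration unit dose) at time zero; Baseline phases have none.
#' Levers extend 15 min after recording start for self-administration
#' sessions.
#'
#' @inheritParams generate_trajectory
#' @param rng_seed RNG seed; defaults to a value derived from
#'   `params$rng_seed` and the session identifier (offset so the event
#'   stream is independent of the trajectory stream).
#' @return A `session_record`.
#' @export
generate_event_log <- function(params, session, rng_seed = NULL,
                               protocol = default_protocol()) {
  params <- as.list(params)
  session <- as.list(session)
  type <- session$type
  if (!type %in% c(sa_session_types(), "NC")) {
    stop("unrecognized session type: ", type, call. = FALSE)
  }
  if (is.null(rng_seed)) {
    rng_seed <- derive_seed((params$rng_seed %||% 0L) + 7919L,
                            session$session_id %||% "S")
  }
  set.seed(rng_seed)
  duration <- session$duration_min %||% 120
  min_gap_min <- protocol$min_gap_s / 60

  if (type == "NC") {
    phase <- session$phase %||% "Baseline"
    inf <- switch(phase,
      Baseline = empty_infusions(),
      Saline = tibble::tibble(time_min = 0, shocked = FALSE,
                              requirement = NA_integer_),
      Drug = tibble::tibble(time_min = 0, shocked = FALSE,
                            requirement = NA_integer_)
    )
    dose <- if (identical(phase, "Drug")) protocol$noncontingent_dose_mg_kg
            else 0
    return(new_session_record(params$subject_id %||% NA_character_, session,
                              inf, dose, NA_real_, duration))
  }

  t_ext <- protocol$lever_extension_min
  if (type == "PR") {
    lapse <- protocol$pr_lapse_min
    press_rate <- (params$press_rate %||% 3) *
      (1 + 0.2 * (params$salience_weight %||% 0))
    t <- t_ext
    times <- numeric()
    reqs <- integer()
    k <- 0L
    repeat {
      k <- k + 1L
      req <- pr_requirement(k)
      work <- (req / press_rate) * exp(rnorm(1, 0, 0.15)) +
        rexp(1, 2) + if (k == 1L) 0 else min_gap_min
      if (work >= lapse || t + work > duration) break
      t <- t + work
      times <- c(times, t)
      reqs <- c(reqs, req)
    }
    inf <- tibble::tibble(time_min = times, shocked = FALSE,
                          requirement = reqs)
    return(new_session_record(params$subject_id %||% NA_character_, session,
                              inf, protocol$sa_unit_dose_mg_kg, t_ext,
                              duration))
  }

  base <- unname(protocol$base_infusions[type])
  esc <- if (type %in% c("ShA", "LgA")) {
    (params$escalation_rate %||% 0) * (session$index - 1)
  } else 0
  target <- max(0, base + esc)
  window <- duration - t_ext
  load_win <- min(protocol$loading_window_min, window)
  rate <- target / (window + (protocol$loading_multiplier - 1) * load_win)
  times <- draw_infusion_times(t_ext, duration, rate, min_gap_min,
                               t_ext + load_win, protocol$loading_multiplier)
  shocked <- if (type == "Shock") {
    runif(length(times)) < protocol$shock_prob
  } else {
    rep(FALSE, length(times))
  }
  inf <- tibble::tibble(time_min = times, shocked = shocked,
                        requirement = NA_integer_)
  new_session_record(params$subject_id %||% NA_character_, session, inf,
                     protocol$sa_unit_dose_mg_kg, t_ext, duration)
}

#' Write / read a session log as YAML
#'
#' The session-log format is a small YAML document: session metadata plus a
#' list of infusion events (onset minute, shock flag, and the completed
#' response requirement for progressive-ratio sessions).
#'
#' @param record A `session_record`.
#' @param path File path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `session_record`.
#' @export
write_session_log <- function(record, path) {
  x <- unclass(record)
  x$start_time <- format(x$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  x$infusions <- lapply(seq_len(nrow(record$infusions)), function(i) {
    as.list(record$infusions[i, ])
  })
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  x <- yaml::read_yaml(path)
  inf <- if (length(x$infusions)) {
    dplyr::bind_rows(lapply(x$infusions, function(e) {
      tibble::tibble(time_min = as.numeric(e$time_min),
                     shocked = isTRUE(e$shocked),
                     requirement = if (is.null(e$requirement) ||
                                       is.na(e$requirement)) {
                       NA_integer_
                     } else as.integer(e$requirement))
    }))
  } else {
    empty_infusions()
  }
  x$infusions <- inf
  x$start_time <- as.POSIXct(x$start_time, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  for (f in c("duration_min", "recording_min", "lever_extension_min",
              "unit_dose_mg_kg")) {
    x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
  }
  class(x) <- "session_record"
  x
}
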
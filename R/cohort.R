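#' Simulate a full cohort
#'
#' Generates every recording (pose track + event log) for `n_subjects`
#' subjects following a session schedule, with subject-level heterogeneity
#' drawn from `population` and full ground truth returned for
#' parameter-recovery studies. The default study design — 37 subjects over
#' 30 self-administration sessions plus 3 noncontingent triplets — emits
#' 1110 self-administration and 333 noncontingent recordings.
#'
#' Recordings can be voluminous, so three delivery modes are supported:
#' with `sink` each (track, record) pair is handed to a callback and then
#' discarded (constant memory; the mode [run_pipeline()] uses); with
#' `out_dir` recordings are written as delimited pose tables and YAML
#' session logs and the manifest records the paths; otherwise (small
#' cohorts only) tracks and records are returned as manifest list-columns.
#' The whole simulation is deterministic under `seed`.
#'
#' @param n_subjects Number of subjects (>= 2; downstream classification is
#'   undefined for fewer).
#' @param schedule A [default_schedule()]-style `schedule_spec`.
#' @param population A [default_population()]-style `population_spec`.
#' @param seed Integer seed governing every random draw.
#' @param out_dir Optional directory to write recordings into.
#' @param sink Optional `function(track, record, subject, recording_row)`
#'   called once per recording.
#' @param protocol A [default_protocol()].
#' @param missing_rate Per-frame per-node dropout rate for the tracks.
#' @return A `cohort_sim`: `subjects` (ground-truth parameter table),
#'   `manifest` (one row per recording), `schedule`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 37, schedule = default_schedule(),
                            population = default_population(), seed = 1,
                            out_dir = NULL, sink = NULL,
                            protocol = default_protocol(),
                            missing_rate = 0.02) {
  if (n_subjects < 2) {
    stop("`n_subjects` must be at least 2", call. = FALSE)
  }
  set.seed(seed)
  subjects <- draw_subjects(n_subjects, population)
  recs <- schedule$sessions
  geometry <- schedule$geometry
  keep_memory <- is.null(out_dir) && is.null(sink)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  manifest <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    subj <- subjects[i, ]
    man <- tibble::tibble(
      subject_id = subj$subject_id,
      session_id = recs$session_id, session_key = recs$session_key,
      type = recs$type, index = recs$index, phase = recs$phase,
      start_time = recs$start_time
    )
    if (!is.null(out_dir)) {
      man$pose_path <- file.path(out_dir, sprintf(
        "%s_%s_pose.csv", subj$subject_id, recs$session_id))
      man$log_path <- file.path(out_dir, sprintf(
        "%s_%s_events.yaml", subj$subject_id, recs$session_id))
    }
    if (keep_memory) {
      man$track <- vector("list", nrow(recs))
      man$record <- vector("list", nrow(recs))
    }
    for (j in seq_len(nrow(recs))) {
      srow <- recs[j, ]
      track <- generate_trajectory(subj, srow, geometry = geometry,
                                   protocol = protocol,
                                   missing_rate = missing_rate)
      record <- generate_event_log(subj, srow, protocol = protocol)
      record$subject_id <- subj$subject_id
      if (!is.null(sink)) {
        sink(track, record, subj, man[j, ])
      } else if (!is.null(out_dir)) {
        write_pose_table(track, man$pose_path[j])
        write_session_log(record, man$log_path[j])
      } else {
        man$track[[j]] <- track
        man$record[[j]] <- record
      }
    }
    manifest[[i]] <- man
  }
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir)) {
    data.table::fwrite(
      manifest[, c("subject_id", "session_id", "session_key", "type",
                   "index", "phase", "pose_path", "log_path")],
      file.path(out_dir, "cohort_manifest.csv")
    )
    data.table::fwrite(subjects, file.path(out_dir, "subjects.csv"))
  }
  structure(
    list(subjects = subjects, manifest = manifest, schedule = schedule,
         seed = seed),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects x %d recordings (seed %d)\n",
              nrow(x$subjects), nrow(x$manifest) / nrow(x$subjects), x$seed))
  invisible(x)
}
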
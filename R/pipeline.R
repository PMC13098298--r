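#' Pipeline configuration
#'
#' Validated bag of every knob the end-to-end pipeline uses. Unknown fields
#' are rejected; numeric fields are range-checked on construction.
#'
#' @param n_subjects Cohort size when simulating.
#' @param seed Master seed.
#' @param input_dir Directory of previously written recordings (see
#'   [generate_cohort()]); `NULL` simulates instead.
#' @param out_dir Optional directory for result tables.
#' @param schedule,population,protocol Study design objects.
#' @param window Path-length smoothing window (frames).
#' @param half_extent Lever-zone half-widths (px).
#' @param winsor Upper winsorization percentile.
#' @param alpha Normality-gate level for correlations.
#' @param abstinence_tol_h Abstinence snapping tolerance (h).
#' @param min_locomotion_m Locomotion floor for entrances per meter.
#' @param missing_rate Simulated tracking dropout rate.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 37, seed = 1, input_dir = NULL,
                            out_dir = NULL, schedule = default_schedule(),
                            population = default_population(),
                            protocol = default_protocol(),
                            window = 10, half_extent = c(30, 18),
                            winsor = 0.95, alpha = 0.05,
                            abstinence_tol_h = 6, min_locomotion_m = 0.01,
                            missing_rate = 0.02) {
  stopifnot(n_subjects >= 2, window >= 1, length(half_extent) == 2L,
            all(half_extent > 0), winsor > 0, winsor <= 1,
            alpha > 0, alpha < 1, abstinence_tol_h > 0,
            min_locomotion_m >= 0, missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_subjects = n_subjects, seed = seed, input_dir = input_dir,
         out_dir = out_dir, schedule = schedule, population = population,
         protocol = protocol, window = window, half_extent = half_extent,
         winsor = winsor, alpha = alpha,
         abstinence_tol_h = abstinence_tol_h,
         min_locomotion_m = min_locomotion_m, missing_rate = missing_rate),
    class = "pipeline_config"
  )
}

exclusion_row <- function(e) {
  tibble::tibble(subject_id = e$subject_id %||% NA_character_,
                 session_id = e$session_ref %||% NA_character_,
                 reason = e$reason, details = e$details %||% "")
}

#' Process a manifest of on-disk recordings
#'
#' Reads each pose table and session log named in a cohort manifest and
#' derives its session metrics. A recording that fails to parse or align is
#' converted into a reason-coded exclusion; processing always continues.
#'
#' @param manifest Tibble with `pose_path` and `log_path` columns (as
#'   written by [generate_cohort()] in file mode).
#' @param config A [pipeline_config()].
#' @return List with `metrics` (tibble) and `exclusions` (tibble).
#' @export
process_recordings <- function(manifest, config = pipeline_config()) {
  rows <- list()
  excl <- list()
  for (j in seq_len(nrow(manifest))) {
    res <- tryCatch({
      track <- read_pose_table(manifest$pose_path[j])
      record <- read_session_log(manifest$log_path[j])
      compute_session_metrics(
        track, record, geometry = config$schedule$geometry,
        window = config$window, half_extent = config$half_extent,
        min_locomotion_m = config$min_locomotion_m
      )
    }, error = function(e) {
      new_exclusion("unreadable recording", manifest$session_id[j],
                    manifest$subject_id[j], conditionMessage(e))
    })
    if (is_exclusion(res)) excl[[length(excl) + 1L]] <- exclusion_row(res)
    else rows[[length(rows) + 1L]] <- res
  }
  list(metrics = dplyr::bind_rows(rows), exclusions = dplyr::bind_rows(excl))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the full analysis: simulate a cohort (or read one from
#' `input_dir`), derive per-recording session metrics, assemble the cohort
#' table with abstinence codes, classify subjects
#' (sensitization/tolerance and high/low pre-lever activity), compute the
#' noncontingent percent-difference summaries, correlate the pre-lever
#' activity z-score with intake (normality-gated, Benjamini-Yekutieli
#' adjusted), and — when a mixed-model backend is installed — run a small
#' default model suite. Every unusable recording appears in the exclusion
#' audit; the run is deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `cohort` (metric table),
#'   `assignments`, `correlations`, `nc_summary`, `model_suite`,
#'   `exclusions`, `subjects` (ground truth when simulated), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- list()
  excl <- list()
  subjects <- NULL
  if (!is.null(config$input_dir)) {
    manifest <- data.table::fread(
      file.path(config$input_dir, "cohort_manifest.csv"),
      data.table = FALSE)
    res <- process_recordings(manifest, config)
    rows <- list(res$metrics)
    excl <- list(res$exclusions)
    subj_path <- file.path(config$input_dir, "subjects.csv")
    if (file.exists(subj_path)) {
      subjects <- tibble::as_tibble(data.table::fread(subj_path,
                                                      data.table = FALSE))
    }
  } else {
    sim <- generate_cohort(
      n_subjects = config$n_subjects, schedule = config$schedule,
      population = config$population, seed = config$seed,
      protocol = config$protocol, missing_rate = config$missing_rate,
      sink = function(track, record, subject, row) {
        res <- tryCatch(
          compute_session_metrics(
            track, record, geometry = config$schedule$geometry,
            window = config$window, half_extent = config$half_extent,
            min_locomotion_m = config$min_locomotion_m),
          error = function(e) new_exclusion("metric failure",
                                            record$session_id,
                                            record$subject_id,
                                            conditionMessage(e))
        )
        if (is_exclusion(res)) {
          excl[[length(excl) + 1L]] <<- exclusion_row(res)
        } else {
          rows[[length(rows) + 1L]] <<- res
        }
      })
    subjects <- sim$subjects
  }
  cohort <- build_cohort_table(dplyr::bind_rows(rows), config$schedule,
                               config$abstinence_tol_h)
  exclusions <- dplyr::bind_rows(excl)

  assignments <- tryCatch(classify_cohort(cohort),
                          error = function(e) NULL)

  # noncontingent percent-difference summaries (locomotion vs each
  # session's Baseline phase; entrances per meter vs the cohort-mean of the
  # first noncontingent session)
  nc <- dplyr::filter(cohort, .data$type == "NC")
  nc_summary <- NULL
  if (nrow(nc)) {
    base <- dplyr::select(
      dplyr::filter(nc, .data$phase == "Baseline"),
      "subject_id", "index", baseline_locomotion_m = "locomotion_m")
    nc_summary <- dplyr::mutate(
      dplyr::left_join(nc, base, by = c("subject_id", "index")),
      locomotion_pct_vs_baseline = percent_diff(.data$locomotion_m,
                                                .data$baseline_locomotion_m)
    )
    nc01_mean <- list(
      active = mean(nc_summary$active_epm[nc_summary$index == 1],
                    na.rm = TRUE),
      inactive = mean(nc_summary$inactive_epm[nc_summary$index == 1],
                      na.rm = TRUE)
    )
    nc_summary$active_epm_pct_vs_nc01 <-
      percent_diff(nc_summary$active_epm, nc01_mean$active)
    nc_summary$inactive_epm_pct_vs_nc01 <-
      percent_diff(nc_summary$inactive_epm, nc01_mean$inactive)
    nc_summary <- dplyr::select(
      nc_summary, "subject_id", "session_id", "index", "phase",
      "locomotion_m", "locomotion_pct_vs_baseline",
      "active_epm_pct_vs_nc01", "inactive_epm_pct_vs_nc01")
  }

  correlations <- NULL
  if (!is.null(assignments) && "prelever_z" %in% names(assignments)) {
    intake <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(cohort, .data$type %in% c("ShA", "LgA")),
        .data$subject_id, .data$type),
      infusions = mean(.data$infusions_total, na.rm = TRUE),
      infusions_first15 = mean(.data$infusions_first15, na.rm = TRUE),
      .groups = "drop")
    z <- assignments[, c("subject_id", "prelever_z")]
    cors <- list()
    for (ty in unique(intake$type)) {
      for (vv in c("infusions", "infusions_first15")) {
        d <- dplyr::inner_join(intake[intake$type == ty, ], z,
                               by = "subject_id")
        ct <- tryCatch(gated_correlation(d$prelever_z, d[[vv]],
                                         alpha = config$alpha),
                       error = function(e) NULL)
        if (!is.null(ct)) {
          ct$contrast <- paste0("prelever_z~", vv, ":", ty)
          cors[[length(cors) + 1L]] <- ct
        }
      }
    }
    if (length(cors)) {
      correlations <- dplyr::bind_rows(cors)
      correlations$p_by <- by_adjust(correlations$p_raw)
    }
  }

  suite <- NULL
  if (requireNamespace("lmerTest", quietly = TRUE)) {
    sa <- dplyr::filter(cohort, .data$type %in% c("ShA", "LgA"),
                        is.finite(.data$pre_lever_locomotion_m))
    if (nrow(sa) > 20 && length(unique(sa$subject_id)) > 3) {
      suite <- tryCatch(
        run_model_suite(sa, list(list(
          name = "prelever_locomotion",
          formula = pre_lever_locomotion_m ~ type + index +
            (1 | subject_id))), winsor = config$winsor),
        error = function(e) NULL)
    }
  }

  result <- structure(
    list(cohort = cohort, assignments = assignments,
         correlations = correlations, nc_summary = nc_summary,
         model_suite = suite, exclusions = exclusions, subjects = subjects,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    data.table::fwrite(cohort, file.path(od, "cohort_metrics.csv"))
    if (!is.null(assignments)) {
      data.table::fwrite(assignments, file.path(od, "assignments.csv"))
    }
    if (!is.null(correlations)) {
      data.table::fwrite(correlations, file.path(od, "correlations.csv"))
    }
    if (!is.null(nc_summary)) {
      data.table::fwrite(nc_summary, file.path(od, "nc_percent_diff.csv"))
    }
    data.table::fwrite(
      if (nrow(exclusions)) exclusions else
        tibble::tibble(subject_id = character(), session_id = character(),
                       reason = character(), details = character()),
      file.path(od, "exclusions.csv"))
    yaml::write_yaml(
      list(seed = config$seed, n_subjects = config$n_subjects,
           window = config$window, winsor = config$winsor,
           alpha = config$alpha,
           half_extent = as.numeric(config$half_extent)),
      file.path(od, "provenance.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d metric rows, %d exclusions, %d subjects\n",
    nrow(x$cohort), nrow(x$exclusions),
    length(unique(x$cohort$subject_id))))
  invisible(x)
}
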
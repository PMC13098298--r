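#' Sensitization / tolerance label from noncontingent challenges
#'
#' A subject whose locomotor response to an identical noncontingent drug
#' challenge increased from the first to the third challenge expresses
#' psychomotor sensitization; one whose response decreased expresses
#' tolerance. An exact tie or a missing challenge is labelled
#' `indeterminate` and excluded downstream with a reason code rather than
#' forced onto a side.
#'
#' @param drug01_m,drug03_m Locomotion (m) during the first and third
#'   noncontingent drug recordings (vectorized).
#' @return Character vector: `"Sensitization"`, `"Tolerance"` or
#'   `"indeterminate"`.
#' @export
assign_sensitization <- function(drug01_m, drug03_m) {
  dplyr::case_when(
    is.na(drug01_m) | is.na(drug03_m) ~ "indeterminate",
    drug03_m > drug01_m ~ "Sensitization",
    drug03_m < drug01_m ~ "Tolerance",
    TRUE ~ "indeterminate"
  )
}

#' Pre-lever activity z-score
#'
#' The incentive-salience index: for each subject, pre-lever locomotion and
#' pre-lever active-lever entrances per meter are averaged over the chosen
#' sessions (over whichever of them the subject has), each variable is then
#' z-standardized across the cohort (mean 0, sd 1, n-1 denominator), and
#' the two z-scores are averaged. Higher scores mean more pre-session
#' activity directed at the drug-associated lever.
#'
#' @param cohort A [build_cohort_table()] tibble.
#' @param sessions Session identifiers to average over (default the three
#'   Short Access sessions 07-09).
#' @return Tibble with per-subject variable means, per-variable z-scores and
#'   the averaged `prelever_z`.
#' @export
prelever_activity_zscore <- function(cohort,
                                     sessions = c("ShA_07", "ShA_08",
                                                  "ShA_09")) {
  sub <- dplyr::filter(cohort, .data$session_id %in% sessions)
  per <- dplyr::summarise(
    dplyr::group_by(sub, .data$subject_id),
    mean_locomotion = mean(.data$pre_lever_locomotion_m, na.rm = TRUE),
    mean_epm = mean(.data$pre_active_epm, na.rm = TRUE),
    .groups = "drop"
  )
  per <- dplyr::filter(per, is.finite(.data$mean_locomotion),
                       is.finite(.data$mean_epm))
  if (nrow(per) < 2L) {
    stop("need at least two subjects with pre-lever data in the chosen ",
         "sessions", call. = FALSE)
  }
  z <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero cohort variance; z-score undefined", call. = FALSE)
    }
    (x - mean(x)) / s
  }
  per$z_locomotion <- z(per$mean_locomotion)
  per$z_epm <- z(per$mean_epm)
  per$prelever_z <- (per$z_locomotion + per$z_epm) / 2
  per
}

#' Median split into high / low groups
#'
#' `"high"` for values greater than or equal to the sample median (for even
#' n, the midpoint of the central pair), `"low"` below it. With an odd
#' number of distinct values this necessarily yields `(n + 1) / 2` highs.
#'
#' @param z Numeric vector (>= 2 values).
#' @return Character vector of `"high"` / `"low"`.
#' @export
median_split <- function(z) {
  if (length(z) < 2L) stop("need at least two subjects", call. = FALSE)
  ifelse(z >= median(z), "high", "low")
}

#' Classify a cohort
#'
#' Applies both subject-grouping procedures to a cohort table: the
#' sensitization/tolerance dichotomy from the first versus third
#' noncontingent drug challenge, and the high/low incentive-salience split
#' from the median of the pre-lever activity z-score.
#'
#' @param cohort A [build_cohort_table()] tibble.
#' @param sessions Sessions feeding [prelever_activity_zscore()].
#' @return Tibble with one row per subject: drug-challenge locomotion,
#'   `sens_tol` label, `prelever_z` and `prelever_group`.
#' @export
classify_cohort <- function(cohort,
                            sessions = c("ShA_07", "ShA_08", "ShA_09")) {
  drug <- dplyr::filter(cohort, .data$type == "NC",
                        .data$phase == "Drug")
  wide <- tidyr::pivot_wider(
    dplyr::select(drug, "subject_id", "index", "locomotion_m"),
    names_from = "index", values_from = "locomotion_m",
    names_prefix = "drug"
  )
  if (!"drug1" %in% names(wide)) wide$drug1 <- NA_real_
  if (!"drug3" %in% names(wide)) wide$drug3 <- NA_real_
  zs <- prelever_activity_zscore(cohort, sessions)
  out <- dplyr::full_join(
    dplyr::select(wide, "subject_id",
                  drug01_locomotion_m = "drug1",
                  drug03_locomotion_m = "drug3"),
    dplyr::select(zs, "subject_id", "prelever_z"),
    by = "subject_id"
  )
  out$sens_tol <- assign_sensitization(out$drug01_locomotion_m,
                                       out$drug03_locomotion_m)
  out$prelever_group <- NA_character_
  has_z <- is.finite(out$prelever_z)
  if (sum(has_z) >= 2L) {
    out$prelever_group[has_z] <- median_split(out$prelever_z[has_z])
  }
  out
}
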
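# Derive a deterministic per-recording seed from a subject seed and a
# session identifier (kept below 2^31).
derive_seed <- function(base_seed, session_id) {
  h <- sum(utf8ToInt(as.character(session_id)) *
             seq_along(utf8ToInt(as.character(session_id))))
  as.integer((as.numeric(base_seed) + 131 * h) %% (.Machine$integer.max - 1))
}

# Behavioral state (speed multiplier, zone-attraction weight) for each
# segment of a recording, by session type/phase.
trajectory_segments <- function(params, session, n, geometry, protocol) {
  fr <- geometry$frame_rate
  w <- params$salience_weight
  if (!is.na(session$phase %||% NA_character_)) {
    gain <- protocol$nc_seek_gain[min(session$index,
                                      length(protocol$nc_seek_gain))]
    mult <- switch(session$phase,
      Baseline = 1,
      Saline = 1,
      Drug = protocol$drug_effect *
        params$sensitization_slope^(session$index - 1)
    )
    return(list(list(n = n, speed_mult = mult, attr_weight = w * gain)))
  }
  ext_f <- round((session$lever_extension_min %||% NA_real_) * 60 * fr)
  if (is.na(ext_f) || ext_f <= 0L || ext_f >= n) {
    return(list(list(n = n, speed_mult = 1, attr_weight = w)))
  }
  list(
    list(n = ext_f, speed_mult = 1 + protocol$prelever_speed_gain * w,
         attr_weight = w),
    list(n = n - ext_f, speed_mult = protocol$post_lever_speed_mult,
         attr_weight = w)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one recording's pose track
#'
#' Generates a 13-node pose track for a single 30-min (by default) video
#' recording. The body anchor (catheter node) follows a discrete-time
#' mean-reverting (Ornstein-Uhlenbeck-style) velocity process with
#' reflecting chamber walls and a drift toward the active-lever zone center
#' proportional to the subject's salience weight; the nose wanders around
#' the anchor with its own smooth jitter; the remaining body nodes ride on
#' the anchor with fixed offsets plus tracking noise; lever and cue-light
#' nodes are static up to sub-pixel noise and rare large flicker. A
#' configurable fraction of frames per node is masked missing (independent
#' dropouts plus occasional multi-frame gaps) to exercise interpolation.
#' Identical parameters and seed give a bit-identical track.
#'
#' @param params One row of [draw_subjects()] (or an equivalent list) with
#'   `baseline_speed`, `salience_weight`, `sensitization_slope`, `rng_seed`.
#' @param session One row of a [default_schedule()] `sessions` tibble (or an
#'   equivalent list with `session_id`, `type`, `index`, `phase`,
#'   `recording_min`, `lever_extension_min`).
#' @param zone Target [lever_zone()]; defaults to the active lever of
#'   `geometry`. Must lie inside the chamber.
#' @param duration_min Recording length; defaults to the session's
#'   `recording_min` (30 min).
#' @param geometry A [default_geometry()].
#' @param protocol A [default_protocol()].
#' @param missing_rate Independent per-frame per-node dropout probability.
#' @param seed RNG seed; defaults to a value derived from `params$rng_seed`
#'   and the session identifier.
#' @param ou_rho Per-frame velocity autocorrelation of the anchor walk.
#' @param attraction_gain Drift speed toward the zone center per unit of
#'   attraction weight, as a fraction of the subject's own speed scale (so a
#'   motionless subject feels no pull).
#' @param nose_sd_px,nose_rho Stationary spread (px) and per-frame
#'   autocorrelation of the nose's wander around the anchor.
#' @return A [pose_track()].
#' @export
generate_trajectory <- function(params, session, zone = NULL,
                                duration_min = NULL,
                                geometry = default_geometry(),
                                protocol = default_protocol(),
                                missing_rate = 0.02, seed = NULL,
                                ou_rho = 0.9, attraction_gain = 0.05,
                                nose_sd_px = 10, nose_rho = 0.99) {
  params <- as.list(params)
  session <- as.list(session)
  if (is.null(zone)) zone <- lever_zone(geometry$lever_px$active)
  W <- geometry$chamber_px[1L]
  H <- geometry$chamber_px[2L]
  lo <- zone$center - zone$half_extent
  hi <- zone$center + zone$half_extent
  if (any(lo < 0) || hi[1L] > W || hi[2L] > H) {
    stop("lever zone lies outside the chamber bounds", call. = FALSE)
  }
  duration_min <- duration_min %||% session$recording_min %||% 30
  if (duration_min <= 0) stop("`duration_min` must be > 0", call. = FALSE)
  fr <- geometry$frame_rate
  n <- round(duration_min * 60 * fr)
  if (is.null(seed)) seed <- derive_seed(params$rng_seed %||% 0L,
                                         session$session_id %||% "S")
  set.seed(seed)

  # anchor walk: OU velocity, calibrated so the stationary mean speed equals
  # baseline_speed (cm/s) times the segment's behavioral multiplier
  rho <- ou_rho
  soft_radius <- 30
  k_attr <- attraction_gain
  start <- c(runif(1, 0, W), runif(1, 0, H))
  segs <- trajectory_segments(params, session, n, geometry, protocol)
  pos <- matrix(NA_real_, n, 2L)
  v <- c(0, 0)
  at <- 0L
  for (sg in segs) {
    s_px <- (params$baseline_speed * sg$speed_mult) / (geometry$cm_per_px * fr)
    tau <- s_px / sqrt(pi / 2)
    sigma <- tau * sqrt(1 - rho^2)
    attr <- k_attr * sg$attr_weight * tau * (1 - rho)
    noise <- matrix(rnorm(sg$n * 2L), sg$n, 2L)
    res <- ou_walk_cpp(start, v, rho, sigma, attr, zone$center, soft_radius,
                       c(0, 0), c(W, H), noise)
    pos[at + seq_len(sg$n), ] <- res$pos
    start <- res$pos[sg$n, ]
    v <- res$v_end
    at <- at + sg$n
  }

  # nose: smooth zero-mean jitter around the anchor, folded into the chamber
  rho_n <- nose_rho
  sd_n <- nose_sd_px
  jit <- matrix(rnorm(n * 2L, 0, sd_n * sqrt(1 - rho_n^2)), n, 2L)
  jit[, 1L] <- stats::filter(jit[, 1L], rho_n, method = "recursive")
  jit[, 2L] <- stats::filter(jit[, 2L], rho_n, method = "recursive")
  nose <- cbind(fold_into(pos[, 1L] + jit[, 1L], 0, W),
                fold_into(pos[, 2L] + jit[, 2L], 0, H))

  cols <- list(frame = 0:(n - 1L))
  put <- function(node, xy) {
    cols[[paste0(node, ".x")]] <<- xy[, 1L]
    cols[[paste0(node, ".y")]] <<- xy[, 2L]
  }
  put("nose", nose)
  offs <- body_node_offsets()
  for (nd in names(offs)) {
    xy <- cbind(
      fold_into(pos[, 1L] + offs[[nd]][1L] + rnorm(n, 0, 1.5), 0, W),
      fold_into(pos[, 2L] + offs[[nd]][2L] + rnorm(n, 0, 1.5), 0, H)
    )
    put(nd, xy)
  }
  put("catheter", pos)
  static_node <- function(center) {
    xy <- cbind(center[1L] + rnorm(n, 0, 0.7), center[2L] + rnorm(n, 0, 0.7))
    flick <- runif(n) < 0.003
    if (any(flick)) {
      xy[flick, ] <- xy[flick, , drop = FALSE] +
        matrix(rnorm(2L * sum(flick), 0, 40), ncol = 2L)
    }
    cbind(fold_into(xy[, 1L], 0, W), fold_into(xy[, 2L], 0, H))
  }
  put("lever_active", static_node(geometry$lever_px$active))
  put("lever_inactive", static_node(geometry$lever_px$inactive))
  put("cue_light", static_node(geometry$cue_light_px))

  df <- tibble::as_tibble(cols)
  # missingness: independent dropouts plus occasional multi-frame gaps
  if (missing_rate > 0) {
    for (nd in pose_nodes()) {
      drop <- runif(n) < missing_rate
      n_gaps <- rpois(1, n / (fr * 60 * 15))   # ~1 gap per 15 min
      if (n_gaps > 0) {
        gs <- sample.int(n, n_gaps)
        for (g in gs) {
          len <- 3L + stats::rgeom(1, 0.25)
          drop[seq.int(g, min(n, g + len - 1L))] <- TRUE
        }
      }
      if (all(drop)) drop[1L] <- FALSE  # keep at least one observed frame
      if (any(drop)) {
        df[[paste0(nd, ".x")]][drop] <- NA_real_
        df[[paste0(nd, ".y")]][drop] <- NA_real_
      }
    }
  }
  pose_track(df, frame_rate = fr,
             session_ref = session$session_id %||% "sim")
}
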
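test_that("trajectory generation is bit-identical under a fixed seed", {
  subj <- test_subject(rng_seed = 1234L)
  ses <- test_session("ShA", 2L, duration_min = 120, recording_min = 2)
  a <- generate_trajectory(subj, ses, duration_min = 2)
  b <- generate_trajectory(subj, ses, duration_min = 2)
  expect_identical(a$data, b$data)
  rec_a <- generate_event_log(subj, ses)
  rec_b <- generate_event_log(subj, ses)
  expect_identical(rec_a$infusions, rec_b$infusions)
})

test_that("generated coordinates stay inside the chamber", {
  geo <- default_geometry()
  subj <- test_subject(baseline_speed = 8, salience_weight = 4,
                       rng_seed = 7L)
  trk <- generate_trajectory(subj, test_session("ShA", 1L), duration_min = 5)
  for (nd in track_nodes(trk)) {
    xy <- node_xy(trk, nd)
    xy <- xy[stats::complete.cases(xy), ]
    expect_true(all(xy[, 1] >= 0 & xy[, 1] <= geo$chamber_px[1]))
    expect_true(all(xy[, 2] >= 0 & xy[, 2] <= geo$chamber_px[2]))
  }
})

test_that("a motionless subject travels zero meters", {
  subj <- test_subject(baseline_speed = 0, salience_weight = 3,
                       rng_seed = 11L)
  trk <- interpolate_track(generate_trajectory(subj, test_session("ShA", 1L),
                                               duration_min = 2))
  expect_equal(path_length(trk, "catheter", window = 1,
                           cm_per_px = 0.111), 0)
})

test_that("a zone outside the chamber is rejected", {
  subj <- test_subject()
  bad <- lever_zone(c(260, 220), role = "active")  # box exceeds bounds
  expect_error(generate_trajectory(subj, test_session("ShA", 1L),
                                   zone = bad, duration_min = 1),
               "chamber")
})

test_that("zero-salience occupancy matches the zone/chamber area ratio", {
  # interior zone; 20 replicates x 10 min at 10 fps >= 1e5 frames total;
  # tolerance is 3 standard errors of the replicate mean
  geo <- default_geometry()
  zone <- lever_zone(c(135, 112), role = "active")
  occ <- vapply(1:20, function(s) {
    subj <- test_subject(salience_weight = 0, rng_seed = 1000L + s)
    trk <- generate_trajectory(subj, test_session("ShA", 1L), zone = zone,
                               duration_min = 10, missing_rate = 0)
    mean(zone_contains(zone, node_xy(trk, "nose")))
  }, numeric(1))
  area_ratio <- (60 * 36) / prod(geo$chamber_px)
  se <- stats::sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - area_ratio), 3 * se + 1e-9)
})

test_that("zone occupancy increases with salience weight", {
  # rank correlation across a 5-point grid, 20 replicates
  grid <- c(0, 1, 2, 3, 4)
  occ <- matrix(NA_real_, 20, length(grid))
  for (s in 1:20) {
    for (j in seq_along(grid)) {
      subj <- test_subject(salience_weight = grid[j],
                           rng_seed = 5000L + s)
      trk <- generate_trajectory(subj, test_session("ShA", 1L),
                                 duration_min = 5, missing_rate = 0)
      zone <- lever_zone(default_geometry()$lever_px$active)
      occ[s, j] <- mean(zone_contains(zone, node_xy(trk, "nose")))
    }
  }
  rc <- stats::cor(rep(grid, each = 20), as.vector(occ),
                   method = "spearman")
  expect_gt(rc, 0)
  # and the two extreme weights separate in the mean
  expect_gt(mean(occ[, 5]), mean(occ[, 1]))
})

test_that("high-salience subjects make more entrances per meter", {
  geo <- default_geometry()
  epm_for <- function(w, s) {
    subj <- test_subject(salience_weight = w, rng_seed = 9000L + s)
    trk <- interpolate_track(
      generate_trajectory(subj, test_session("ShA", 1L), duration_min = 10))
    zone <- zone_from_lever_node(trk, "active")
    loco <- path_length(trk, "catheter", 10, geo$cm_per_px)
    entrances_per_meter(count_entrances(trk, zone), loco)
  }
  hi <- vapply(1:8, function(s) epm_for(5, s), numeric(1))
  lo <- vapply(1:8, function(s) epm_for(0, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("event logs respect the infusion refractory period", {
  set.seed(113)
  for (s in 1:25) {
    ty <- sample(c("ShA", "LgA", "Shock"), 1)
    subj <- test_subject(escalation_rate = runif(1, 0, 3),
                         rng_seed = 100L + s)
    ses <- test_session(ty, sample(1:10, 1),
                        duration_min = if (ty == "Shock") 60 else 120)
    rec <- generate_event_log(subj, ses)
    if (nrow(rec$infusions) > 1) {
      expect_gte(min(diff(sort(rec$infusions$time_min))) * 60, 26 - 1e-9)
    }
    # no infusions before lever extension
    expect_true(all(rec$infusions$time_min >= 15))
    expect_true(all(rec$infusions$time_min < rec$duration_min))
  }
})

test_that("a zero-rate session yields an empty log", {
  subj <- test_subject(escalation_rate = 0)
  proto <- default_protocol(base_infusions = c(ShA = 0, LgA = 0,
                                               Preshock = 0, Shock = 0))
  rec <- generate_event_log(subj, test_session("ShA", 1L), protocol = proto)
  expect_equal(nrow(rec$infusions), 0L)
  expect_error(generate_event_log(subj, test_session("XX", 1L)),
               "unrecognized")
})

test_that("only Shock sessions flag shocked infusions", {
  subj <- test_subject(rng_seed = 17L)
  pre <- generate_event_log(subj, test_session("Preshock", 1L,
                                               duration_min = 60))
  expect_false(any(pre$infusions$shocked))
  sh <- generate_event_log(subj, test_session("Shock", 1L,
                                              duration_min = 60))
  expect_true(nrow(sh$infusions) > 0)
})

test_that("escalation raises expected intake across sessions", {
  subj <- test_subject(escalation_rate = 2, rng_seed = 19L)
  early <- vapply(1:12, function(s) {
    nrow(generate_event_log(test_subject(escalation_rate = 2,
                                         rng_seed = 100L + s),
                            test_session("LgA", 1L, duration_min = 360)
                            )$infusions)
  }, numeric(1))
  late <- vapply(1:12, function(s) {
    nrow(generate_event_log(test_subject(escalation_rate = 2,
                                         rng_seed = 100L + s),
                            test_session("LgA", 15L, duration_min = 360)
                            )$infusions)
  }, numeric(1))
  expect_gt(mean(late), mean(early))
})

test_that("progressive-ratio logs carry completions and a valid breakpoint", {
  subj <- test_subject(rng_seed = 23L)
  rec <- generate_event_log(subj, test_session("PR", 1L,
                                               duration_min = 360))
  expect_true(nrow(rec$infusions) > 0)
  expect_equal(rec$infusions$requirement,
               pr_requirement(seq_len(nrow(rec$infusions))))
  bp <- pr_breakpoint(rec)
  expect_gte(bp, 1)
})

test_that("session logs round-trip through YAML", {
  subj <- test_subject(rng_seed = 29L)
  for (ses in list(test_session("Shock", 1L, duration_min = 60),
                   test_session("PR", 2L, duration_min = 360),
                   test_session("NC", 1L, phase = "Baseline",
                                duration_min = 30))) {
    rec <- generate_event_log(subj, ses)
    rec$subject_id <- "R001"
    path <- withr::local_tempfile(fileext = ".yaml")
    write_session_log(rec, path)
    back <- read_session_log(path)
    expect_equal(back$infusions$time_min, rec$infusions$time_min,
                 tolerance = 1e-9)
    expect_equal(back$infusions$shocked, rec$infusions$shocked)
    expect_equal(back$type, rec$type)
    expect_equal(back$lever_extension_min, rec$lever_extension_min)
  }
})

test_that("cohort generation is deterministic and guards its preconditions", {
  sch <- default_schedule()
  sch$sessions <- sch$sessions[sch$sessions$session_id %in%
                                 c("ShA_01", "NC_01_Drug"), ]
  a <- generate_cohort(3, sch, seed = 5)
  b <- generate_cohort(3, sch, seed = 5)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$manifest$track[[1]]$data, b$manifest$track[[1]]$data)
  expect_error(generate_cohort(1, sch), "at least 2")
})

test_that("noncontingent drug phases scale locomotion by the expressed slope", {
  geo <- default_geometry()
  loco_nc <- function(slope, idx, s) {
    subj <- test_subject(sensitization_slope = slope, rng_seed = 400L + s)
    trk <- interpolate_track(generate_trajectory(
      subj, test_session("NC", idx, phase = "Drug", duration_min = 30),
      duration_min = 10))
    path_length(trk, "catheter", 10, geo$cm_per_px)
  }
  sens3 <- vapply(1:6, function(s) loco_nc(1.4, 3L, s), numeric(1))
  sens1 <- vapply(1:6, function(s) loco_nc(1.4, 1L, s), numeric(1))
  tol3 <- vapply(1:6, function(s) loco_nc(0.7, 3L, s), numeric(1))
  tol1 <- vapply(1:6, function(s) loco_nc(0.7, 1L, s), numeric(1))
  expect_gt(mean(sens3), mean(sens1))
  expect_lt(mean(tol3), mean(tol1))
})
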
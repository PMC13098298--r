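test_that("loading-window intake uses a half-open window after extension", {
  rec <- make_record(infusion_times = 15 + c(1, 14.9, 15.0))
  expect_equal(first15_infusions(rec), 2L)
  expect_equal(first15_infusions(make_record()), 0L)
})

test_that("loading-window counts match brute force on random logs", {
  set.seed(61)
  for (rep in 1:100) {
    k <- sample(0:40, 1)
    times <- sort(runif(k, 0, 120))
    rec <- make_record(infusion_times = times)
    expect_equal(first15_infusions(rec), oracle_first15(times, 15))
    # window split reconciles with the total
    post <- sum(times >= 30)
    pre_ext <- sum(times < 15)
    expect_equal(first15_infusions(rec) + post + pre_ext, length(times))
  }
})

test_that("abstinence gaps snap to 18/66/90 h within tolerance", {
  t0 <- as.POSIXct("2024-01-02 10:00:00", tz = "UTC")
  expect_equal(abstinence_code(t0, t0 + 18.4 * 3600), 18)
  expect_equal(abstinence_code(t0, t0 + 66 * 3600), 66)
  expect_equal(abstinence_code(t0, t0 + 93 * 3600), 90)
  expect_equal(abstinence_code(gap_h = c(22, 70, 90)), c(18, 66, 90))
  expect_error(abstinence_code(t0, t0 + 40 * 3600), "anomaly")
  expect_error(abstinence_code(t0, t0 - 3600), "positive")
})

test_that("the default calendar yields only in-band abstinence codes", {
  ab <- schedule_abstinence(default_schedule(), strict = TRUE)
  expect_true(is.na(ab$abstinence_h[1]))
  expect_true(all(ab$abstinence_h[-1] %in% c(18, 66, 90)))
  # the calendar includes weekend and holiday abstinence, not just 18 h
  expect_setequal(unique(ab$abstinence_h[-1]), c(18, 66, 90))
})

test_that("percent difference handles baselines and undefined cases", {
  expect_equal(percent_diff(100, 100), 0)
  expect_equal(percent_diff(150, 100), 50)
  expect_equal(percent_diff(50, 100), -50)
  expect_true(is.na(percent_diff(5, 0)))
  expect_true(is.na(percent_diff(5, -2)))
  # group-mean baseline variant on a 3-subject toy table:
  # values (2, 4, 9) against the group mean of (2, 4, 6) = 4
  vals <- c(2, 4, 9)
  base_mean <- mean(c(2, 4, 6))
  expect_equal(percent_diff(vals, base_mean), c(-50, 0, 125))
})

test_that("progressive-ratio requirements follow the exponential schedule", {
  # 5e^0.2 - 5 = 1.107 -> 1 ; 5e^1 - 5 = 8.591 -> 9
  expect_equal(pr_requirement(1), 1L)
  expect_equal(pr_requirement(5), 9L)
  expect_equal(pr_requirement(c(1, 5, 10)), c(1L, 9L, 32L))
  reqs <- pr_requirement(1:30)
  expect_true(all(diff(reqs) >= 0))
  expect_error(pr_requirement(0), "positive")
})

test_that("breakpoint is the last ratio before a 60-min lapse", {
  # completions early in a long session: last completion stands
  rec <- make_record(type = "PR", duration_min = 360,
                     infusion_times = 15 + c(5, 20, 50),
                     requirement = pr_requirement(1:3))
  expect_equal(pr_breakpoint(rec), pr_requirement(3))
  # empty log -> 0 by convention
  expect_equal(pr_breakpoint(make_record(type = "PR",
                                         duration_min = 360)), 0L)
  # planted 61-min lapse after k completions -> requirement(k)
  k <- 4
  times <- 15 + cumsum(rep(5, k))
  times <- c(times, times[k] + 61, times[k] + 66)
  rec2 <- make_record(type = "PR", duration_min = 360,
                      infusion_times = times,
                      requirement = pr_requirement(seq_along(times)))
  expect_equal(pr_breakpoint(rec2), pr_requirement(k))
})

test_that("breakpoint matches a brute-force lapse scan on random logs", {
  set.seed(67)
  for (rep in 1:200) {
    k <- sample(0:25, 1)
    gaps <- rexp(k, rate = 1 / 20)
    times <- 15 + cumsum(gaps)
    reqs <- pr_requirement(seq_len(k))
    rec <- make_record(type = "PR", duration_min = 360,
                       infusion_times = times, requirement = reqs)
    expect_equal(pr_breakpoint(rec),
                 oracle_breakpoint(times, reqs, 15))
  }
})

test_that("session metrics assemble into one row per usable recording", {
  subj <- test_subject(rng_seed = 101L)
  ses <- test_session("ShA", 3L)
  trk <- generate_trajectory(subj, ses)
  rec <- generate_event_log(subj, ses)
  m <- compute_session_metrics(trk, rec)
  expect_s3_class(m, "tbl_df")
  expect_equal(nrow(m), 1L)
  expect_gt(m$pre_lever_locomotion_m, 0)
  expect_true(is.finite(m$pre_active_epm))
  expect_equal(m$infusions_total, nrow(rec$infusions))
  expect_true(is.na(m$locomotion_m))  # NC-only column

  nc_ses <- test_session("NC", 1L, phase = "Drug", duration_min = 30)
  nc_trk <- generate_trajectory(subj, nc_ses)
  nc_rec <- generate_event_log(subj, nc_ses)
  m2 <- compute_session_metrics(nc_trk, nc_rec)
  expect_gt(m2$locomotion_m, 0)
  expect_true(is.na(m2$pre_lever_locomotion_m))
})
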
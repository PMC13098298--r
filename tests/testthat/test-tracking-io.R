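test_that("pose table round-trips through the delimited dialect", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    coords <- list(
      nose = cbind(runif(n, 0, 270), runif(n, 0, 225)),
      catheter = cbind(runif(n, 0, 270), runif(n, 0, 225))
    )
    trk <- make_track(coords, frame_rate = sample(c(10, 30), 1))
    # punch random holes
    for (cl in c("nose.x", "nose.y")) {
      idx <- sample(n, size = sample(0:(n %/% 3), 1))
      trk$data[[cl]][idx] <- NA_real_
    }
    path <- withr::local_tempfile(fileext = ".csv")
    write_pose_table(trk, path)
    back <- read_pose_table(path)
    expect_equal(back$data, trk$data, tolerance = 1e-12)
    expect_equal(back$frame_rate, trk$frame_rate)
    expect_equal(back$session_ref, trk$session_ref)
  }
})

test_that("unparseable cells become missing and required nodes are enforced", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# frame_rate: 10",
    "frame,nose.x,nose.y,catheter.x,catheter.y",
    "0,1.5,2.5,3,4",
    "1,,garbage,3,4",
    "2,2.5,3.5,3,4"
  ), path)
  trk <- read_pose_table(path)
  expect_equal(n_frames(trk), 3L)
  expect_true(is.na(trk$data$nose.x[2]))
  expect_true(is.na(trk$data$nose.y[2]))
  expect_false(anyNA(trk$data$catheter.x))
  expect_error(read_pose_table(path, required_nodes = c("nose", "paw")),
               "paw")
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_pose_table(empty), "empty")
})

test_that("frame gaps are filled with missing rows on ingestion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# frame_rate: 10",
    "frame,nose.x,nose.y",
    "0,1,1",
    "3,4,4"
  ), path)
  trk <- read_pose_table(path)
  expect_equal(trk$data$frame, 0:3)
  expect_true(all(is.na(trk$data$nose.x[2:3])))
})

test_that("interpolation fills interior gaps linearly and edges by nearest", {
  trk <- make_track(list(nose = rbind(c(0, 0), c(NA, NA), c(2, 2))))
  out <- interpolate_track(trk)
  expect_equal(unname(node_xy(out, "nose")[2, ]), c(1, 1))

  # leading/trailing gaps take the nearest observed value
  trk2 <- make_track(list(nose = rbind(c(NA, NA), c(5, 7), c(NA, NA))))
  out2 <- interpolate_track(trk2)
  expect_equal(unname(node_xy(out2, "nose")[1, ]), c(5, 7))
  expect_equal(unname(node_xy(out2, "nose")[3, ]), c(5, 7))

  # no missing frames: identity
  trk3 <- make_track(list(nose = cbind(1:5, 6:10)))
  expect_identical(interpolate_track(trk3)$data, trk3$data)

  # all-missing node errors with its name
  trk4 <- make_track(list(nose = cbind(rep(NA_real_, 3), rep(NA_real_, 3))))
  expect_error(interpolate_track(trk4), "nose")
})

test_that("interpolation matches a brute-force per-gap linear fill", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    x <- cumsum(rnorm(n))
    y <- cumsum(rnorm(n))
    mask <- runif(n) < 0.3
    mask[sample(n, 1)] <- FALSE  # keep at least one observation
    x[mask] <- NA
    y[mask] <- NA
    trk <- make_track(list(nose = cbind(x, y)))
    out <- node_xy(interpolate_track(trk), "nose")
    expect_equal(out[, 1], oracle_interpolate(x), tolerance = 1e-12)
    expect_equal(out[, 2], oracle_interpolate(y), tolerance = 1e-12)
    # observed values never altered
    expect_identical(out[!mask, 1], x[!mask])
  }
})

test_that("conversion factor is the mean of the five cm/px ratios", {
  # all ratios identical
  expect_equal(compute_cm_per_px(c(300, 300), c(200, 200, 200), 33.3, 22.2),
               0.111, tolerance = 1e-12)
  # hand-computed mixed ratios: {0.10, 0.12, 0.10, 0.12, 0.11} -> 0.11
  expect_equal(
    compute_cm_per_px(c(33 / 0.10, 33 / 0.12), c(22 / 0.10, 22 / 0.12,
                                                 22 / 0.11), 33, 22),
    0.11, tolerance = 1e-12)
  # scale consistency: doubling pixel measurements halves the factor
  a <- compute_cm_per_px(c(310, 290), c(195, 205, 210), 33, 22)
  b <- compute_cm_per_px(2 * c(310, 290), 2 * c(195, 205, 210), 33, 22)
  expect_equal(b, a / 2, tolerance = 1e-12)
  expect_error(compute_cm_per_px(c(-1, 300), c(200, 200, 200), 33, 22),
               "positive")
  expect_error(compute_cm_per_px(c(300, 300), c(200, 200), 33, 22), "three")
})

test_that("alignment emits exact 12.5-min segments around lever extension", {
  n <- 30 * 60 * 10
  trk <- make_track(list(nose = cbind(runif(n), runif(n))))
  rec <- make_record(infusion_times = c(20, 40))
  al <- align_to_lever(trk, rec)
  expect_equal(n_frames(al$pre), 7500)
  expect_equal(n_frames(al$post), 7500)
  expect_equal(al$lever_extension_frame, 9000)
  # contiguity: last pre frame + 1 == first post frame
  expect_equal(tail(al$pre$data$frame, 1) + 1L, al$post$data$frame[1])
})

test_that("an extension too close to a recording edge yields an exclusion", {
  n <- 30 * 60 * 10
  trk <- make_track(list(nose = cbind(runif(n), runif(n))))
  rec <- make_record(lever_extension_min = 5)
  out <- align_to_lever(trk, rec)
  expect_true(is_exclusion(out))
  expect_match(out$reason, "pre-lever")
  rec2 <- make_record(lever_extension_min = 25)
  out2 <- align_to_lever(trk, rec2)
  expect_true(is_exclusion(out2))
  expect_match(out2$reason, "post-lever")
})

test_that("alignment segments are contiguous and idempotent", {
  set.seed(7)
  fr <- 10
  for (rep in 1:10) {
    n_min <- sample(26:40, 1)
    ext <- runif(1, 12.6, n_min - 12.6)
    n <- n_min * 60 * fr
    trk <- make_track(list(nose = cbind(runif(n), runif(n))))
    rec <- make_record(lever_extension_min = ext)
    al <- align_to_lever(trk, rec)
    expect_equal(n_frames(al$pre) + n_frames(al$post), 25 * 60 * fr)
    frames <- c(al$pre$data$frame, al$post$data$frame)
    expect_equal(frames, seq(frames[1], by = 1, length.out = length(frames)))
    # idempotence: realigning the 25-min concatenation reproduces it
    joined <- make_track(list(nose = rbind(node_xy(al$pre, "nose"),
                                           node_xy(al$post, "nose"))),
                         frame = frames)
    rec2 <- make_record(lever_extension_min = al$lever_extension_frame /
                          (60 * fr))
    al2 <- align_to_lever(joined, rec2)
    expect_false(is_exclusion(al2))
    expect_equal(node_xy(al2$pre, "nose"), node_xy(al$pre, "nose"))
    expect_equal(node_xy(al2$post, "nose"), node_xy(al$post, "nose"))
  }
})

test_that("noncontingent recordings trim to a single 25-min segment", {
  n <- 30 * 60 * 10
  trk <- make_track(list(nose = cbind(runif(n), runif(n))))
  rec <- make_record(type = "NC", phase = "Drug", lever_extension_min = NA,
                     duration_min = 30)
  al <- align_to_lever(trk, rec)
  expect_null(al$pre)
  expect_equal(n_frames(al$full), 25 * 60 * 10)
  # symmetric trim: 2.5 min dropped from each end
  expect_equal(al$full$data$frame[1], 1500)
})
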
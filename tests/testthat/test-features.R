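test_that("confidence filter removes strictly-below-threshold points, keeps the boundary, and is idempotent", {
  faces <- list(
    test_face(list(`21` = c(500, 350, 0.69), `22` = c(500, 350, 0.70))),
    test_face(list(`21` = c(500, 350, 0.71), `27` = c(500, 400, 0.1)))
  )
  s <- test_series(2, faces = faces)
  f <- filter_by_confidence(s, 0.7)
  expect_true(is.na(f$face[22, "x", 1])) # 0.69 removed
  expect_false(is.na(f$face[23, "x", 1])) # 0.70 kept (boundary)
  expect_false(is.na(f$face[22, "x", 2])) # 0.71 kept
  expect_true(is.na(f$face[28, "x", 2])) # nose at 0.1 removed
  expect_identical(filter_by_confidence(f, 0.7), f)
})

test_that("filter removal count matches a brute-force scan on random confidences", {
  withr::local_seed(7)
  faces <- lapply(1:12, function(i) {
    f <- test_face()
    f[, "confidence"] <- runif(70)
    f
  })
  s <- test_series(12, faces = faces)
  filtered <- filter_by_confidence(s, 0.7)
  # oracle: count confidences < 0.7 frame by frame, point by point
  oracle <- sum(vapply(faces, function(f) sum(f[, "confidence"] < 0.7), numeric(1)))
  expect_equal(sum(is.na(filtered$face[, "x", ])), oracle)
  # all-high-confidence series passes through unchanged
  expect_identical(filter_by_confidence(s, 0), s)
})

test_that("nose-relative distance is the Euclidean two-norm", {
  f <- test_frame(face = test_face(list(`21` = c(503, 404), `27` = c(500, 400))))
  expect_equal(nose_relative_distance(f, 21), 5) # 3-4-5 triangle
  f0 <- test_frame(face = test_face(list(`21` = c(500, 400), `27` = c(500, 400))))
  expect_equal(nose_relative_distance(f0, 21), 0)
  fm <- test_frame(face = test_face(list(`21` = c(503, 404, 0))))
  expect_true(is.na(nose_relative_distance(fm, 21))) # undetected point

  withr::local_seed(11)
  for (i in 1:25) {
    b <- runif(2, 0, 1280)
    n <- runif(2, 0, 720)
    f <- test_frame(face = test_face(list(`18` = b, `27` = n)))
    expect_equal(nose_relative_distance(f, 18), sqrt(sum((b - n)^2)))
  }
})

test_that("edge trimming retains n - 2*floor(f*n) central frames, positionally", {
  s <- test_series(100)
  t1 <- trim_edges(s, 0.2)
  expect_equal(n_frames_kept <- length(t1$frame_index), 60L)
  expect_equal(t1$frame_index, 20:79)
  expect_identical(trim_edges(s, 0), s)
  # positional, not index-valued: gaps do not change the count
  s2 <- s
  s2$frame_index <- s$frame_index * 3L
  expect_equal(length(trim_edges(s2, 0.2)$frame_index), 60L)

  withr::local_seed(3)
  for (n in sample(1:500, 25)) {
    frac <- runif(1, 0, 0.49)
    kept <- length(trim_edges(test_series(n), frac)$frame_index)
    expect_equal(kept, n - 2 * floor(frac * n))
  }
})

test_that("internal/external are side means; missing-side and asymmetry rules hold", {
  # nose at (500, 400); point 21 at distance 30, point 22 at distance 34
  f <- test_face(list(`21` = c(500, 370), `22` = c(500, 366)))
  ff <- eyebrow_frame_features(test_frame(face = f))
  expect_equal(ff$internal, 32)
  expect_equal(ff$asymmetry_internal, 34 - 30) # left minus right

  # mirror-symmetric face: zero asymmetry
  fs <- test_face(list(
    `21` = c(490, 370), `22` = c(510, 370),
    `18` = c(450, 350), `25` = c(550, 350)
  ))
  ffs <- eyebrow_frame_features(test_frame(face = fs))
  expect_equal(ffs$asymmetry_internal, 0)
  expect_equal(ffs$asymmetry_external, 0)

  # one side missing: internal unavailable when both sides are required
  fm <- test_face(list(`21` = c(500, 370), `22` = c(500, 366, 0)))
  ffm <- eyebrow_frame_features(test_frame(face = fm))
  expect_true(is.na(ffm$internal))
  ffm2 <- eyebrow_frame_features(test_frame(face = fm), feature_config(require_both_sides = FALSE))
  expect_equal(ffm2$internal, 30)
})

test_that("per-video summary equals a brute-force mean over retained frames", {
  faces <- lapply(1:3, function(i) {
    test_face(list(`21` = c(500, 400 - 10 * i), `22` = c(500, 400 - 10 * i)))
  })
  s <- test_series(3, faces = faces)
  expect_equal(summarize_video(s)$mean_internal, 20) # mean(10, 20, 30)

  withr::local_seed(19)
  faces <- lapply(1:40, function(i) {
    f <- test_face()
    f[, 1:2] <- f[, 1:2] + rnorm(140, 0, 15)
    f[, 3] <- runif(70, 0.4, 1)
    f
  })
  s <- test_series(40, faces = faces)
  cfg <- feature_config()
  got <- extract_features(list(s), cfg)
  # oracle: plain loops over the retained frames
  keep <- 9:32 # floor(0.2*40)=8 trimmed each side
  vals <- vapply(keep, function(i) {
    f <- faces[[i]]
    ok <- function(id) f[id + 1, 3] >= 0.7
    d <- function(id) sqrt(sum((f[id + 1, 1:2] - f[28, 1:2])^2))
    if (ok(21) && ok(22) && ok(27)) (d(21) + d(22)) / 2 else NA_real_
  }, numeric(1))
  expect_equal(got$mean_internal, mean(vals, na.rm = TRUE))
  expect_equal(got$n_frames_used_internal, sum(!is.na(vals)))
  expect_equal(got$n_frames_total, 24L)
})

test_that("summary means lie within the range of contributing frame values", {
  withr::local_seed(23)
  faces <- lapply(1:30, function(i) {
    f <- test_face()
    f[, 1:2] <- f[, 1:2] + rnorm(140, 0, 8)
    f
  })
  s <- test_series(30, faces = faces)
  ff <- video_frame_features(trim_edges(s, 0.2))
  sm <- summarize_video(trim_edges(s, 0.2))
  expect_gte(sm$mean_internal, min(ff$internal, na.rm = TRUE))
  expect_lte(sm$mean_internal, max(ff$internal, na.rm = TRUE))
})

test_that("a video with all face confidences below threshold is dropped", {
  faces <- lapply(1:10, function(i) {
    f <- test_face()
    f[, "confidence"] <- 0.5
    f
  })
  s <- test_series(10, faces = faces)
  out <- extract_features(list(s))
  expect_true(out$dropped)
  expect_true(is.na(out$mean_internal) && is.na(out$mean_external))
  expect_equal(out$n_frames_used_internal, 0L)
})

test_that("filter and trim commute when confidences are independent of position", {
  withr::local_seed(31)
  faces <- lapply(1:25, function(i) {
    f <- test_face()
    f[, 3] <- runif(70)
    f
  })
  s <- test_series(25, faces = faces)
  a <- trim_edges(filter_by_confidence(s, 0.7), 0.2)
  b <- filter_by_confidence(trim_edges(s, 0.2), 0.7)
  expect_identical(a, b)
})

test_that("hand activity profile tracks wrist elevation and has one value per frame", {
  # static hands: flat zero profile
  s <- test_series(10)
  prof <- hand_activity_profile(s)
  expect_length(prof, 10)
  expect_equal(prof, rep(0, 10))

  # elevation bumps only in the edge spans
  n <- 20
  elev <- c(60, 120, 60, 30, rep(0, 12), 30, 60, 120, 60)
  poses <- lapply(seq_len(n), function(i) test_pose(wrist_y = c(640, 640) - elev[i]))
  s2 <- test_series(n, poses = poses)
  prof2 <- hand_activity_profile(s2)
  expect_equal(prof2, elev)
  expect_true(all(prof2[5:16] == 0))

  # all wrists undetected: all-missing profile
  poses3 <- lapply(seq_len(5), function(i) test_pose(conf = 0))
  s3 <- test_series(5, poses = poses3)
  expect_true(all(is.na(hand_activity_profile(s3))))
})
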
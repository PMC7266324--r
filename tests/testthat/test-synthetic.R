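test_that("generated frame documents are valid OpenPose input with 70 face points", {
  dir <- withr::local_tempdir()
  st <- generate_study(tiny_config(frames_per_video = 4L), seed = 2, level = "keypoints", dir = dir)
  vid <- st$metadata$video_id[1]
  files <- list.files(file.path(dir, vid), full.names = TRUE)
  expect_length(files, 4L)
  fr <- read_openpose_frame(files[1])
  expect_true(fr$person_present)
  expect_equal(nrow(fr$face), 70L)
  expect_equal(nrow(fr$pose), 25L)
  # and the whole directory loads as a series matching the in-memory one
  s <- load_video(file.path(dir, vid), st$videos[[vid]]$metadata)
  expect_equal(s$face, st$videos[[vid]]$face, tolerance = 1e-12)
})

test_that("same seed gives identical output; different seeds differ", {
  a <- generate_study(tiny_config(frames_per_video = 5L), seed = 31, level = "keypoints")
  b <- generate_study(tiny_config(frames_per_video = 5L), seed = 31, level = "keypoints")
  expect_identical(a$videos, b$videos)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- generate_study(tiny_config(frames_per_video = 5L), seed = 32, level = "keypoints")
  expect_false(identical(a$videos, c_$videos))
  # byte-identical frame files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(tiny_config(frames_per_video = 2L), seed = 8, level = "keypoints", dir = d1)
  generate_study(tiny_config(frames_per_video = 2L), seed = 8, level = "keypoints", dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("noiseless pipeline summaries equal the analytic ground truth exactly", {
  st <- generate_study(noiseless_config(), seed = 4, level = "keypoints")
  fe <- extract_features(st$videos)
  expect_equal(fe$mean_internal, st$ground_truth$mu_internal, tolerance = 1e-10)
  expect_equal(fe$mean_external, st$ground_truth$mu_external, tolerance = 1e-10)
  expect_false(any(fe$dropped))
})

test_that("expected condition-cell means equal the analytic sum of injected effects", {
  # no random effects or noise: per-video mu is exactly X %*% beta for all
  # 18 condition x group cells
  st <- generate_study(noiseless_config(), seed = 1, level = "summary")
  des <- build_design(st$metadata)
  bt <- attr(st$ground_truth, "beta_internal")
  expect_equal(st$ground_truth$mu_internal, as.vector(des$fixed %*% bt[colnames(des$fixed)]))
  cells <- aggregate(
    st$ground_truth$mu_internal,
    st$metadata[c("emotion", "sentence_type", "group")], mean
  )
  expect_equal(nrow(cells), 18L)
  # spot-check two cells against hand-computed contrast sums
  mu_cell <- function(emo, sty, grp) {
    sch <- contrast_scheme()
    x_e <- sch$emotion[emo, ]
    x_s <- sch$sentence_type[sty, ]
    x_g <- sch$group[grp, ]
    eff <- function(term) {
      e <- default_effect_params()
      if (term %in% e$term) e$internal[e$term == term] else 0
    }
    45 + x_e["NvA"] * eff("emotionNvA") + x_e["SvNA"] * eff("emotionSvNA") +
      x_s["WvS"] * eff("sentence_typeWvS") + x_s["PvSW"] * eff("sentence_typePvSW") +
      x_s["PvSW"] * x_g * eff("sentence_typePvSW:groupDvH")
  }
  got <- function(emo, sty, grp) {
    cells$x[cells$emotion == emo & cells$sentence_type == sty & cells$group == grp]
  }
  expect_equal(got("surprise", "polar", "deaf"), unname(mu_cell("surprise", "polar", "deaf")))
  expect_equal(got("anger", "wh", "hearing"), unname(mu_cell("anger", "wh", "hearing")))
})

test_that("the study emits one video per signer x sentence x condition", {
  cfg <- tiny_config()
  st <- generate_study(cfg, seed = 1, level = "summary")
  expect_equal(nrow(st$metadata), 4 * 2 * 9)
  expect_false(anyDuplicated(st$metadata$video_id) > 0)
  key <- st$metadata[, c("signer_id", "sentence_id", "emotion", "sentence_type")]
  expect_false(anyDuplicated(key) > 0)
})

test_that("voided videos have all confidences below the cutoff and are dropped by the pipeline", {
  st <- generate_study(tiny_config(n_voided = 3L, frames_per_video = 8L),
    seed = 12, level = "keypoints"
  )
  voided <- st$ground_truth$video_id[st$ground_truth$voided]
  expect_length(voided, 3L)
  for (v in voided) {
    expect_true(all(st$videos[[v]]$face[, "confidence", ] < 0.7))
  }
  fe <- extract_features(st$videos)
  expect_setequal(fe$video_id[fe$dropped], voided)
  expect_equal(sum(!fe$dropped), nrow(st$metadata) - 3L)
})

test_that("wrist elevation is confined to the edge spans the trim removes", {
  st <- generate_study(noiseless_config(frames_per_video = 30L),
    seed = 3, level = "keypoints"
  )
  prof <- hand_activity_profile(st$videos[[1]])
  k <- floor(0.2 * 30)
  expect_true(all(prof[(k + 1):(30 - k)] <= 1e-9))
  expect_gt(max(prof[1:k]), 50)
  expect_gt(max(prof[(30 - k + 1):30]), 50)
})

test_that("edge frames carry perturbed eyebrows, so trimming changes the estimate", {
  st <- generate_study(noiseless_config(), seed = 2, level = "keypoints")
  s <- st$videos[[1]]
  untrimmed <- summarize_video(s)$mean_internal
  trimmed <- summarize_video(trim_edges(s, 0.2))$mean_internal
  expect_equal(trimmed, st$ground_truth$mu_internal[1], tolerance = 1e-10)
  # untrimmed mean is pulled by the -5 px edge offset over 40% of frames
  expect_equal(untrimmed, trimmed - 5 * 0.4, tolerance = 1e-10)
})

test_that("rating generator respects its confusion distributions and determinism", {
  tab <- generate_ratings(n_videos = 81L, n_raters = 5L, seed = 9)
  expect_equal(nrow(tab), 405L)
  expect_identical(tab, generate_ratings(n_videos = 81L, n_raters = 5L, seed = 9))
  # identity confusion: accuracy 1
  conf <- confusion_from_accuracy(c(statement = 1, polar = 1, wh = 1))
  expect_equal(accuracy(generate_ratings(conf, n_videos = 45L, seed = 1)), 1)
  # uniform over the three true labels: accuracy near 1/3
  u <- confusion_from_accuracy(c(statement = 1 / 3, polar = 1 / 3, wh = 1 / 3))
  u[, c("neutral", "surprised", "angry")] <- 1 / 3
  u$other <- 0
  big <- generate_ratings(u, n_videos = 3000L, n_raters = 1L, seed = 10)
  expect_equal(accuracy(big), 1 / 3, tolerance = 0.1)
  # invalid distribution rejected
  bad <- confusion_from_accuracy()
  bad$other[1] <- bad$other[1] + 0.01
  expect_error(generate_ratings(bad), "sum to 1")
})
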
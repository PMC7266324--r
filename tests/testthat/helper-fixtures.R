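# Fixtures are built in code: hand-placed keypoint frames with known
# geometry, and small synthetic-study configurations.

test_metadata <- function(video_id = "v1", signer_id = "D1", group = "deaf",
                          sentence_id = "s01", emotion = "neutral",
                          sentence_type = "statement") {
  video_metadata(video_id, signer_id, group, sentence_id, emotion, sentence_type)
}

# 70-point face with every point at (500, 400), confidence 1, then selected
# 0-based ids overridden as c(x, y) or c(x, y, conf).
test_face <- function(override = list()) {
  m <- matrix(rep(c(500, 400, 1), each = 70), 70, 3)
  colnames(m) <- c("x", "y", "confidence")
  for (id in names(override)) {
    v <- override[[id]]
    row <- as.integer(id) + 1L
    m[row, seq_along(v)] <- v
  }
  m
}

test_hand <- function(conf = 1) {
  m <- matrix(rep(c(600, 500, conf), each = 21), 21, 3)
  colnames(m) <- c("x", "y", "confidence")
  m
}

test_pose <- function(wrist_y = c(640, 640), conf = 1) {
  m <- matrix(rep(c(640, 400, conf), each = 25), 25, 3)
  colnames(m) <- c("x", "y", "confidence")
  m[5, 2] <- wrist_y[1] # BODY_25 id 4, right wrist
  m[8, 2] <- wrist_y[2] # id 7, left wrist
  m
}

test_frame <- function(frame_index = 0L, face = test_face(),
                       pose = test_pose()) {
  frame_keypoints(face, test_hand(), test_hand(), pose,
    frame_index = frame_index
  )
}

# series of n frames with constant geometry unless per-frame faces given
test_series <- function(n = 10L, faces = NULL, poses = NULL,
                        metadata = test_metadata()) {
  frames <- lapply(seq_len(n), function(i) {
    test_frame(
      frame_index = i - 1L,
      face = if (is.null(faces)) test_face() else faces[[i]],
      pose = if (is.null(poses)) test_pose() else poses[[i]]
    )
  })
  keypoint_series(frames, metadata)
}

# small, fast synthetic-study configuration
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_signers_deaf = 2L, n_signers_hearing = 2L, n_sentences = 2L,
      frames_per_video = 20L, n_voided = 0L
    ),
    list(...)
  )
  do.call(synthetic_config, args)
}

noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(sd_frame = 0, sd_signer = 0, sd_sentence = 0, p_lowconf = 0),
    list(...)
  )
  do.call(tiny_config, args)
}
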
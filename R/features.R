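#' Feature-extraction configuration
#'
#' Constants of the eyebrow-position pipeline. Landmarks with detection
#' confidence strictly below `confidence_threshold` are discarded (a point at
#' exactly the threshold is kept, matching a strictly-below removal rule).
#' The first and last `trim_fraction` of each video's frames are dropped
#' because signers raise and lower their hands there. Eyebrow height is the
#' Euclidean distance from the nose-top landmark, averaged over the two
#' eyebrows: inner points 21/22 give the internal measure (AU1/AU4
#' territory), outer points 18/25 the external one (AU2).
#'
#' @param confidence_threshold keep points with confidence >= this (default
#'   0.7).
#' @param trim_fraction fraction of frames removed from each end (default
#'   0.2; must be in `[0, 0.5)`).
#' @param internal_ids,external_ids 0-based face indices of the inner / outer
#'   eyebrow points, ordered (right side, left side).
#' @param nose_id 0-based face index of the nose top.
#' @param require_both_sides if TRUE (default) a frame contributes an
#'   internal (external) value only when both eyebrows' distances are
#'   available; one-sided dropout would otherwise bias the mean given facial
#'   asymmetry.
#' @param normalize_interocular if TRUE, distances are divided by the
#'   inter-ocular distance (outer eye corners, face points 36 and 45).
#'   Defaults off: with a fixed camera and seated signer, raw pixels are the
#'   natural unit.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(confidence_threshold = 0.7, trim_fraction = 0.2,
                           internal_ids = FACE_INTERNAL_IDS,
                           external_ids = FACE_EXTERNAL_IDS,
                           nose_id = FACE_NOSE_TOP_ID,
                           require_both_sides = TRUE,
                           normalize_interocular = FALSE) {
  stopifnot(
    confidence_threshold >= 0, confidence_threshold <= 1,
    trim_fraction >= 0, trim_fraction < 0.5,
    length(internal_ids) == 2L, length(external_ids) == 2L, length(nose_id) == 1L
  )
  ids <- c(internal_ids, external_ids, nose_id)
  if (any(ids < 0 | ids >= FACE_N_POINTS)) stop("face indices must be in [0, 70)")
  if (anyDuplicated(ids)) stop("internal, external and nose indices must be disjoint")
  structure(list(
    confidence_threshold = confidence_threshold, trim_fraction = trim_fraction,
    internal_ids = as.integer(internal_ids), external_ids = as.integer(external_ids),
    nose_id = as.integer(nose_id), require_both_sides = isTRUE(require_both_sides),
    normalize_interocular = isTRUE(normalize_interocular)
  ), class = "feature_config")
}

.mask_low_conf <- function(a, threshold) {
  if (!length(a)) {
    return(a)
  }
  conf <- a[, "confidence", , drop = FALSE]
  low <- !is.na(conf) & conf < threshold
  # mark as undetected: coordinates NA, confidence 0
  a[, "x", ][low[, 1, ]] <- NA_real_
  a[, "y", ][low[, 1, ]] <- NA_real_
  a[, "confidence", ][low[, 1, ]] <- 0
  a
}

#' Remove low-confidence keypoints
#'
#' Marks every keypoint whose confidence is strictly below `threshold` as
#' undetected (coordinates `NA`, confidence 0). Points at exactly the
#' threshold are kept. Idempotent.
#'
#' @param series a [keypoint_series()].
#' @param threshold confidence cutoff in `[0, 1]` (default 0.7).
#' @return the filtered series.
#' @export
filter_by_confidence <- function(series, threshold = 0.7) {
  stopifnot(inherits(series, "keypoint_series"), threshold >= 0, threshold <= 1)
  for (part in c("face", "left_hand", "right_hand", "pose")) {
    series[[part]] <- .mask_low_conf(series[[part]], threshold)
  }
  series
}

#' Trim the edges of a video
#'
#' Drops the first and last `floor(fraction * n)` frames by position in the
#' sequence (not by `frame_index` value): with `n` frames, positions
#' `k, ..., n - k - 1` (0-based, `k = floor(fraction * n)`) are retained in
#' order. The retained count is therefore `n - 2 * floor(fraction * n)`,
#' never less than one frame for `fraction < 0.5`.
#'
#' @param series a [keypoint_series()].
#' @param fraction fraction to remove at each end, in `[0, 0.5)`.
#' @return the trimmed series.
#' @export
trim_edges <- function(series, fraction = 0.2) {
  stopifnot(inherits(series, "keypoint_series"), fraction >= 0, fraction < 0.5)
  n <- n_frames(series)
  k <- floor(fraction * n)
  .subset_series(series, seq.int(k + 1L, n - k))
}

# x/y of one 0-based face point across frames; NA where undetected.
.face_xy <- function(series, id0) {
  row <- id0 + 1L
  x <- series$face[row, "x", ]
  y <- series$face[row, "y", ]
  conf <- series$face[row, "confidence", ]
  miss <- is.na(x) | is.na(conf) | conf == 0
  x[miss] <- NA_real_
  y[miss] <- NA_real_
  cbind(x = x, y = y)
}

# Euclidean distance of a face point from the nose top, per frame.
.nose_distance_series <- function(series, id0, nose0) {
  p <- .face_xy(series, id0)
  n <- .face_xy(series, nose0)
  sqrt((p[, "x"] - n[, "x"])^2 + (p[, "y"] - n[, "y"])^2)
}

#' Distance of a face landmark from the nose top
#'
#' Euclidean distance (both x and y coordinates) between a face point and
#' the nose-top point, in pixels; `NA` if either point is undetected.
#'
#' @param frame a [frame_keypoints()].
#' @param face_id 0-based face index of the landmark.
#' @param nose_id 0-based face index of the nose top (default 27).
#' @return distance in pixels, or `NA`.
#' @export
nose_relative_distance <- function(frame, face_id, nose_id = FACE_NOSE_TOP_ID) {
  stopifnot(inherits(frame, "frame_keypoints"))
  if (!frame$person_present) {
    return(NA_real_)
  }
  stopifnot(face_id >= 0, face_id < FACE_N_POINTS, nose_id >= 0, nose_id < FACE_N_POINTS)
  b <- frame$face[face_id + 1L, ]
  n <- frame$face[nose_id + 1L, ]
  if (anyNA(c(b[c("x", "y")], n[c("x", "y")])) || b["confidence"] == 0 || n["confidence"] == 0) {
    return(NA_real_)
  }
  unname(sqrt((b["x"] - n["x"])^2 + (b["y"] - n["y"])^2))
}

# combine the two sides of one measure according to the availability rule
.combine_sides <- function(d_right, d_left, require_both) {
  if (require_both) {
    out <- (d_right + d_left) / 2
  } else {
    out <- rowMeans(cbind(d_right, d_left), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
  }
  out
}

#' Per-frame eyebrow features for a whole series
#'
#' Computes, for every frame: the four eyebrow-to-nose distances
#' (`d_internal_right` = point 21, `d_internal_left` = point 22,
#' `d_external_right` = point 18, `d_external_left` = point 25 under the
#' default layout), their per-measure averages `internal` and `external`,
#' and the left-minus-right asymmetries. With
#' `config$require_both_sides` a measure is present in a frame only when
#' both side distances are.
#'
#' @param series a [keypoint_series()] (already confidence-filtered and
#'   trimmed in the standard pipeline).
#' @param config a [feature_config()].
#' @return data.frame with one row per frame.
#' @export
video_frame_features <- function(series, config = feature_config()) {
  stopifnot(inherits(series, "keypoint_series"), inherits(config, "feature_config"))
  d_ir <- .nose_distance_series(series, config$internal_ids[1], config$nose_id)
  d_il <- .nose_distance_series(series, config$internal_ids[2], config$nose_id)
  d_er <- .nose_distance_series(series, config$external_ids[1], config$nose_id)
  d_el <- .nose_distance_series(series, config$external_ids[2], config$nose_id)
  if (config$normalize_interocular) {
    eye_r <- .face_xy(series, 36L)
    eye_l <- .face_xy(series, 45L)
    iod <- sqrt((eye_r[, "x"] - eye_l[, "x"])^2 + (eye_r[, "y"] - eye_l[, "y"])^2)
    d_ir <- d_ir / iod
    d_il <- d_il / iod
    d_er <- d_er / iod
    d_el <- d_el / iod
  }
  data.frame(
    frame_index = series$frame_index,
    d_internal_right = d_ir, d_internal_left = d_il,
    d_external_right = d_er, d_external_left = d_el,
    internal = .combine_sides(d_ir, d_il, config$require_both_sides),
    external = .combine_sides(d_er, d_el, config$require_both_sides),
    asymmetry_internal = d_il - d_ir,
    asymmetry_external = d_el - d_er
  )
}

#' Eyebrow features for a single frame
#'
#' @param frame a [frame_keypoints()].
#' @param config a [feature_config()].
#' @param metadata optional [video_metadata()]; any valid one suffices as the
#'   features do not depend on it.
#' @return one-row data.frame as in [video_frame_features()].
#' @export
eyebrow_frame_features <- function(frame, config = feature_config(),
                                   metadata = NULL) {
  if (is.null(metadata)) {
    metadata <- video_metadata("frame", "s", "deaf", "1", "neutral", "statement")
  }
  video_frame_features(keypoint_series(list(frame), metadata), config)
}

#' Summarise one video to its mean eyebrow positions
#'
#' Arithmetic mean of the per-frame internal and external values over frames
#' where they are available. A measure with zero contributing frames is
#' `NA`; `dropped` is TRUE when both are. Expects confidence filtering and
#' edge trimming to have been applied already (as [extract_features()]
#' does).
#'
#' @param series a [keypoint_series()].
#' @param config a [feature_config()].
#' @return one-row data.frame: metadata columns, `mean_internal`,
#'   `mean_external`, `mean_asymmetry_internal`, `mean_asymmetry_external`,
#'   `n_frames_total`, `n_frames_used_internal`, `n_frames_used_external`,
#'   `dropped`.
#' @export
summarize_video <- function(series, config = feature_config()) {
  ff <- video_frame_features(series, config)
  avg <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  out <- data.frame(
    video_id = series$metadata$video_id, signer_id = series$metadata$signer_id,
    group = series$metadata$group, sentence_id = series$metadata$sentence_id,
    emotion = series$metadata$emotion, sentence_type = series$metadata$sentence_type,
    mean_internal = avg(ff$internal), mean_external = avg(ff$external),
    mean_asymmetry_internal = avg(ff$asymmetry_internal),
    mean_asymmetry_external = avg(ff$asymmetry_external),
    n_frames_total = nrow(ff),
    n_frames_used_internal = sum(!is.na(ff$internal)),
    n_frames_used_external = sum(!is.na(ff$external)),
    stringsAsFactors = FALSE
  )
  out$dropped <- is.na(out$mean_internal) & is.na(out$mean_external)
  out
}

#' Per-video feature table for a collection of videos
#'
#' Runs the standard pipeline — confidence filter, edge trim, per-frame
#' features, per-video mean — over a list of series.
#'
#' @param videos list of [keypoint_series()].
#' @param config a [feature_config()].
#' @return data.frame with one row per video (see [summarize_video()]).
#' @export
extract_features <- function(videos, config = feature_config()) {
  stopifnot(length(videos) >= 1L)
  rows <- lapply(videos, function(s) {
    s <- filter_by_confidence(s, config$confidence_threshold)
    s <- trim_edges(s, config$trim_fraction)
    summarize_video(s, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hand-elevation diagnostic profile
#'
#' Mean wrist height above a resting baseline, per frame, from the BODY_25
#' wrist keypoints (indices 4 and 7). The baseline is the 95th percentile of
#' the per-frame mean wrist y (y grows downward, so the largest y is the
#' lowest, resting position). Used to inspect whether hand raising and
#' lowering is confined to the video edges and hence whether the fixed
#' trim fraction is adequate; it does not set the trim automatically.
#'
#' @param series a [keypoint_series()].
#' @return numeric vector, one elevation (pixels, >= 0 up to noise) per
#'   frame; `NA` where no wrist was detected.
#' @export
hand_activity_profile <- function(series) {
  stopifnot(inherits(series, "keypoint_series"))
  wrist_y <- function(id0) {
    if (dim(series$pose)[1] <= id0) {
      return(rep(NA_real_, n_frames(series)))
    }
    y <- series$pose[id0 + 1L, "y", ]
    conf <- series$pose[id0 + 1L, "confidence", ]
    y[is.na(conf) | conf == 0] <- NA_real_
    y
  }
  ys <- cbind(wrist_y(POSE_WRIST_IDS[1]), wrist_y(POSE_WRIST_IDS[2]))
  mean_y <- rowMeans(ys, na.rm = TRUE)
  mean_y[is.nan(mean_y)] <- NA_real_
  if (all(is.na(mean_y))) {
    return(mean_y)
  }
  baseline <- quantile(mean_y, 0.95, na.rm = TRUE, names = FALSE)
  baseline - mean_y
}
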
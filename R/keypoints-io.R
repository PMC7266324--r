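# OpenPose landmark indices consumed downstream (0-based, 70-point face
# layout): inner eyebrow points 21/22, outer points 18/25, nose top 27.
# These are the only face indices the feature stage reads; everything else is
# carried through untouched.
FACE_N_POINTS <- 70L
FACE_INTERNAL_IDS <- c(21L, 22L)
FACE_EXTERNAL_IDS <- c(18L, 25L)
FACE_NOSE_TOP_ID <- 27L
HAND_N_POINTS <- 21L
POSE_WRIST_IDS <- c(4L, 7L) # BODY_25 right / left wrist
KP_COLS <- c("x", "y", "confidence")

.kp_matrix <- function(flat, n_expected, what, file = NULL) {
  if (length(flat) != 3L * n_expected) {
    stop(
      "malformed keypoint array '", what, "'",
      if (!is.null(file)) paste0(" in ", file),
      ": expected ", 3L * n_expected, " numbers, got ", length(flat)
    )
  }
  m <- matrix(as.numeric(flat), ncol = 3L, byrow = TRUE)
  colnames(m) <- KP_COLS
  m
}

.empty_kp <- function(n) {
  m <- matrix(numeric(0), ncol = 3L, nrow = 0L)
  colnames(m) <- KP_COLS
  m
}

#' A single frame of OpenPose keypoints
#'
#' @param face 70 x 3 matrix (x, y, confidence); confidence 0 marks an
#'   undetected point.
#' @param left_hand,right_hand 21 x 3 matrices.
#' @param pose pose keypoints; 25 x 3 (BODY_25) or 24 x 3 accepted.
#' @param frame_index non-negative integer.
#' @param person_present FALSE for frames where no person was detected; all
#'   matrices are then empty.
#' @return object of class `frame_keypoints`.
#' @export
frame_keypoints <- function(face, left_hand, right_hand, pose,
                            frame_index = 0L, person_present = TRUE) {
  if (person_present && nrow(face) != FACE_N_POINTS) {
    stop("face must have exactly ", FACE_N_POINTS, " points")
  }
  structure(list(
    frame_index = as.integer(frame_index),
    person_present = isTRUE(person_present),
    face = face, left_hand = left_hand, right_hand = right_hand, pose = pose
  ), class = "frame_keypoints")
}

#' Read one OpenPose per-frame JSON document
#'
#' Parses the standard OpenPose output schema: a top-level `people` array
#' whose entries carry flat `[x1, y1, c1, x2, ...]` arrays
#' `face_keypoints_2d` (210 numbers), `hand_left_keypoints_2d` /
#' `hand_right_keypoints_2d` (63 each) and `pose_keypoints_2d` (75 for
#' BODY_25; 72 also accepted). An empty `people` array yields a frame with
#' `person_present = FALSE`. If several people were detected the first is
#' taken (recordings contain a single signer) and a message is logged.
#'
#' @param x path to a `.json` file, or a JSON string.
#' @param frame_index frame number; when `x` is a file whose name ends in
#'   `<digits>_keypoints.json` (the OpenPose convention) the index is parsed
#'   from the name and this argument is ignored.
#' @return a [frame_keypoints()] object.
#' @export
read_openpose_frame <- function(x, frame_index = 0L) {
  is_file <- length(x) == 1L && !grepl("{", x, fixed = TRUE) && file.exists(x)
  file <- if (is_file) x else NULL
  txt <- if (is_file) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON", if (!is.null(file)) paste0(" in ", file), ": ", conditionMessage(e))
  )
  if (is.null(doc$people)) {
    stop("document has no 'people' array", if (!is.null(file)) paste0(" (", file, ")"))
  }
  if (is_file) {
    m <- regmatches(basename(x), regexec("(\\d+)_keypoints\\.json$", basename(x)))[[1]]
    if (length(m) == 2L) frame_index <- as.integer(m[2])
  }
  if (length(doc$people) == 0L) {
    return(frame_keypoints(.empty_kp(), .empty_kp(), .empty_kp(), .empty_kp(),
      frame_index = frame_index, person_present = FALSE
    ))
  }
  if (length(doc$people) > 1L) {
    message("frame ", frame_index, ": ", length(doc$people), " people detected; taking the first")
  }
  p <- doc$people[[1]]
  pose_flat <- unlist(p$pose_keypoints_2d)
  if (!length(pose_flat) %in% c(72L, 75L)) {
    stop(
      "malformed keypoint array 'pose_keypoints_2d'",
      if (!is.null(file)) paste0(" in ", file),
      ": expected 72 or 75 numbers, got ", length(pose_flat)
    )
  }
  frame_keypoints(
    face = .kp_matrix(unlist(p$face_keypoints_2d), FACE_N_POINTS, "face_keypoints_2d", file),
    left_hand = .kp_matrix(unlist(p$hand_left_keypoints_2d), HAND_N_POINTS, "hand_left_keypoints_2d", file),
    right_hand = .kp_matrix(unlist(p$hand_right_keypoints_2d), HAND_N_POINTS, "hand_right_keypoints_2d", file),
    pose = .kp_matrix(pose_flat, length(pose_flat) %/% 3L, "pose_keypoints_2d", file),
    frame_index = frame_index, person_present = TRUE
  )
}

#' Write one frame back to the OpenPose JSON dialect
#'
#' Inverse of [read_openpose_frame()]: `read_openpose_frame(write_openpose_frame(f, path))`
#' reproduces `f`'s values exactly.
#'
#' @param frame a [frame_keypoints()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_openpose_frame <- function(frame, path) {
  stopifnot(inherits(frame, "frame_keypoints"))
  flat <- function(m) as.vector(t(m))
  people <- if (!frame$person_present) list() else list(list(
    person_id = list(-1L),
    pose_keypoints_2d = flat(frame$pose),
    face_keypoints_2d = flat(frame$face),
    hand_left_keypoints_2d = flat(frame$left_hand),
    hand_right_keypoints_2d = flat(frame$right_hand)
  ))
  jsonlite::write_json(list(version = 1.3, people = people), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Video metadata record
#'
#' @param video_id unique video identifier.
#' @param signer_id signer identifier.
#' @param group `"deaf"` or `"hearing"`.
#' @param sentence_id sentence identifier.
#' @param emotion one of `"neutral"`, `"anger"`, `"surprise"`.
#' @param sentence_type one of `"statement"`, `"polar"`, `"wh"`.
#' @return object of class `video_metadata`.
#' @export
video_metadata <- function(video_id, signer_id, group, sentence_id, emotion,
                           sentence_type) {
  group <- match.arg(group, GROUP_LEVELS)
  emotion <- match.arg(emotion, EMOTION_LEVELS)
  sentence_type <- match.arg(sentence_type, SENTENCE_TYPE_LEVELS)
  structure(list(
    video_id = as.character(video_id), signer_id = as.character(signer_id),
    group = group, sentence_id = as.character(sentence_id),
    emotion = emotion, sentence_type = sentence_type
  ), class = "video_metadata")
}

.meta_fields <- c("video_id", "signer_id", "group", "sentence_id", "emotion", "sentence_type")

#' Keypoint time series for one video
#'
#' Stacks per-frame keypoints into arrays (`n_points x 3 x n_frames`) for
#' fast vectorized feature extraction. Frames where no person was detected
#' are kept as all-`NA` slices with `person_present = FALSE`.
#'
#' @param frames list of [frame_keypoints()], any order; sorted by
#'   `frame_index` ascending.
#' @param metadata a [video_metadata()] object.
#' @param fps frames per second (default 30).
#' @return object of class `keypoint_series` with fields `metadata`, `fps`,
#'   `frame_index`, `person_present`, and arrays `face`, `left_hand`,
#'   `right_hand`, `pose`.
#' @export
keypoint_series <- function(frames, metadata, fps = 30) {
  stopifnot(fps > 0, length(frames) >= 1L, inherits(metadata, "video_metadata"))
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (anyDuplicated(idx)) stop("duplicated frame_index values")
  frames <- frames[order(idx)]
  idx <- sort(idx)
  present <- vapply(frames, `[[`, logical(1), "person_present")
  n <- length(frames)
  n_pose <- if (any(present)) nrow(frames[[which(present)[1]]]$pose) else 25L
  mk_arr <- function(part, np) {
    a <- array(NA_real_, dim = c(np, 3L, n), dimnames = list(NULL, KP_COLS, NULL))
    for (i in seq_len(n)) {
      if (present[i] && nrow(frames[[i]][[part]]) == np) a[, , i] <- frames[[i]][[part]]
    }
    a
  }
  structure(list(
    metadata = metadata, fps = fps, frame_index = idx, person_present = present,
    face = mk_arr("face", FACE_N_POINTS),
    left_hand = mk_arr("left_hand", HAND_N_POINTS),
    right_hand = mk_arr("right_hand", HAND_N_POINTS),
    pose = mk_arr("pose", n_pose)
  ), class = "keypoint_series")
}

#' @export
#' @method print keypoint_series
print.keypoint_series <- function(x, ...) {
  cat(
    "<keypoint_series> video", x$metadata$video_id, "-", length(x$frame_index),
    "frames @", x$fps, "fps;", sum(x$person_present), "with person\n"
  )
  invisible(x)
}

n_frames <- function(series) length(series$frame_index)

# Positional subset of a series (used by trim_edges).
.subset_series <- function(series, keep) {
  series$frame_index <- series$frame_index[keep]
  series$person_present <- series$person_present[keep]
  for (part in c("face", "left_hand", "right_hand", "pose")) {
    series[[part]] <- series[[part]][, , keep, drop = FALSE]
  }
  series
}

#' Load a directory of per-frame OpenPose files as one video
#'
#' Frame files are recognised by the OpenPose naming convention
#' `<anything><digits>_keypoints.json`; the final digit group is the frame
#' index, so shuffled or unpadded listings sort correctly. Unreadable files
#' are skipped with a warning; gaps in the index sequence are reported with a
#' message and allowed.
#'
#' @param directory path containing the frame files.
#' @param metadata a [video_metadata()] for the video.
#' @param fps frames per second.
#' @return a [keypoint_series()].
#' @export
load_video <- function(directory, metadata, fps = 30) {
  files <- list.files(directory, pattern = "\\d+_keypoints\\.json$", full.names = TRUE)
  if (!length(files)) stop("no OpenPose frame files found in ", directory)
  frames <- list()
  for (f in files) {
    fr <- tryCatch(read_openpose_frame(f), error = function(e) {
      warning("skipping unreadable frame file ", basename(f), ": ",
        conditionMessage(e),
        call. = FALSE
      )
      NULL
    })
    if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
  }
  if (!length(frames)) stop("no parseable frame files in ", directory)
  s <- keypoint_series(frames, metadata, fps)
  if (any(diff(s$frame_index) > 1L)) {
    message(
      "video ", metadata$video_id, ": gaps in frame indices (",
      length(files) - length(frames), " unreadable, ",
      max(s$frame_index) - min(s$frame_index) + 1L - n_frames(s), " missing)"
    )
  }
  s
}

#' Write a collection of videos as one combined flat table
#'
#' One row per (video, frame, keypoint): `video_id`, metadata columns,
#' `frame_index`, `part` (face / left_hand / right_hand / pose),
#' `point_index` (0-based), `x`, `y`, `confidence`. Coordinates are written
#' with 6 decimal places; [read_combined_table()] restores the collection up
#' to that precision. Frames with no detected person contribute no rows.
#'
#' @param videos list of [keypoint_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_combined_table <- function(videos, path) {
  tabs <- lapply(videos, function(s) {
    keep <- which(s$person_present)
    parts <- c("face", "left_hand", "right_hand", "pose")
    part_tab <- lapply(parts, function(part) {
      a <- s[[part]]
      np <- dim(a)[1]
      if (!length(keep) || np == 0L) {
        return(NULL)
      }
      data.table::data.table(
        frame_index = rep(s$frame_index[keep], each = np),
        part = part,
        point_index = rep(0:(np - 1L), times = length(keep)),
        x = as.vector(a[, "x", keep]),
        y = as.vector(a[, "y", keep]),
        confidence = as.vector(a[, "confidence", keep])
      )
    })
    tab <- data.table::rbindlist(part_tab)
    if (!nrow(tab)) {
      return(NULL)
    }
    for (f in .meta_fields) tab[[f]] <- s$metadata[[f]]
    data.table::setcolorder(tab, c(.meta_fields, "frame_index", "part", "point_index", "x", "y", "confidence"))
    tab
  })
  out <- data.table::rbindlist(tabs)
  if (!nrow(out)) {
    out <- data.table::setnames(
      data.table::as.data.table(matrix(numeric(0), 0, 12)),
      c(.meta_fields, "frame_index", "part", "point_index", "x", "y", "confidence")
    )
  } else {
    for (col in c("x", "y", "confidence")) out[[col]] <- round(out[[col]], 6)
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a combined flat table back into keypoint series
#'
#' @param path CSV written by [write_combined_table()].
#' @param fps frames per second to stamp on the series (not stored in the
#'   table).
#' @return named list of [keypoint_series()], one per `video_id`.
#' @export
read_combined_table <- function(path, fps = 30) {
  tab <- data.table::fread(path)
  need <- c(.meta_fields, "frame_index", "part", "point_index", "x", "y", "confidence")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("combined table is missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(tab)) {
    return(list())
  }
  out <- list()
  for (vid in unique(tab$video_id)) {
    vt <- tab[tab$video_id == vid, ]
    md <- video_metadata(
      vid, vt$signer_id[1], vt$group[1], vt$sentence_id[1],
      vt$emotion[1], vt$sentence_type[1]
    )
    frames <- lapply(sort(unique(vt$frame_index)), function(fi) {
      ft <- vt[vt$frame_index == fi, ]
      get_part <- function(part, np) {
        pt <- ft[ft$part == part, ]
        pt <- pt[order(pt$point_index), ]
        if (nrow(pt) != np) stop("frame ", fi, " of ", vid, ": ", part, " has ", nrow(pt), " points, expected ", np)
        m <- as.matrix(pt[, c("x", "y", "confidence")])
        colnames(m) <- KP_COLS
        m
      }
      n_pose <- sum(ft$part == "pose")
      frame_keypoints(
        face = get_part("face", FACE_N_POINTS),
        left_hand = get_part("left_hand", HAND_N_POINTS),
        right_hand = get_part("right_hand", HAND_N_POINTS),
        pose = get_part("pose", n_pose),
        frame_index = fi, person_present = TRUE
      )
    })
    out[[vid]] <- keypoint_series(frames, md, fps)
  }
  out
}
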
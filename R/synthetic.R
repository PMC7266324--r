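#' Configuration of the synthetic eyebrow study
#'
#' Defines the simulated study: 9 native signers (5 deaf, 4 hearing) each
#' signing 10 sentences under 9 conditions (3 emotions x 3 sentence types),
#' one video per cell — 810 videos — recorded at 30 fps on a 1280x720
#' canvas. Condition effects are injected in the same contrast space the
#' model estimates (see [contrast_scheme()]), with defaults equal to the
#' estimates the analysis is expected to recover; by-signer and by-sentence
#' random intercepts and slopes, frame-level noise, low-confidence dropouts,
#' hand raise/lower bumps at the video edges, and a configurable number of
#' intentionally voided videos (all detections below the confidence cutoff)
#' complete the statistical structure the pipeline assumes.
#'
#' @param n_signers_deaf,n_signers_hearing signers per group (defaults 5, 4).
#' @param n_sentences sentences (default 10).
#' @param frames_per_video frames per video (default 90, i.e. 3 s at 30 fps).
#' @param fps frames per second (default 30).
#' @param baseline_internal,baseline_external grand-mean eyebrow-to-nose
#'   distances in pixels (defaults 45, 75).
#' @param effects data.frame of injected fixed effects in pixels per contrast
#'   term (see [default_effect_params()]).
#' @param sd_signer,sd_sentence random-intercept standard deviations
#'   (pixels); random slopes get `slope_frac` times the same.
#' @param slope_frac ratio of slope to intercept random sd (default 0.4).
#' @param sd_frame frame-level Gaussian keypoint noise, pixels (default 3).
#' @param p_lowconf probability that a keypoint's confidence falls below the
#'   0.7 cutoff (default 0.05).
#' @param n_voided videos rendered with all confidences below the cutoff so
#'   the pipeline drops them (default 5, reproducing an 805-of-810 yield).
#' @param hand_ramp_fraction fraction of frames at each video edge carrying
#'   the hand raise/lower bump and the eyebrow edge perturbation (default
#'   0.2, matching the feature pipeline's trim).
#' @param edge_brow_offset eyebrow displacement (pixels) applied outside the
#'   central span, so that trimming measurably matters (default -5, lowered
#'   brows during preparation/retraction).
#' @param canvas image width and height in pixels.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_signers_deaf = 5L, n_signers_hearing = 4L,
                             n_sentences = 10L, frames_per_video = 90L,
                             fps = 30, baseline_internal = 45,
                             baseline_external = 75,
                             effects = default_effect_params(),
                             sd_signer = 3, sd_sentence = 2, slope_frac = 0.4,
                             sd_frame = 3, p_lowconf = 0.05, n_voided = 5L,
                             hand_ramp_fraction = 0.2, edge_brow_offset = -5,
                             canvas = c(1280, 720)) {
  stopifnot(
    n_signers_deaf >= 1, n_signers_hearing >= 1, n_sentences >= 1,
    frames_per_video >= 1, fps > 0, sd_signer >= 0, sd_sentence >= 0,
    sd_frame >= 0, p_lowconf >= 0, p_lowconf <= 1, n_voided >= 0,
    hand_ramp_fraction >= 0, hand_ramp_fraction < 0.5
  )
  structure(list(
    n_signers_deaf = as.integer(n_signers_deaf),
    n_signers_hearing = as.integer(n_signers_hearing),
    n_sentences = as.integer(n_sentences),
    frames_per_video = as.integer(frames_per_video), fps = fps,
    baseline_internal = baseline_internal, baseline_external = baseline_external,
    effects = effects, sd_signer = sd_signer, sd_sentence = sd_sentence,
    slope_frac = slope_frac, sd_frame = sd_frame, p_lowconf = p_lowconf,
    n_voided = as.integer(n_voided), hand_ramp_fraction = hand_ramp_fraction,
    edge_brow_offset = edge_brow_offset, canvas = canvas
  ), class = "synthetic_config")
}

#' Default injected fixed effects, in pixels per contrast
#'
#' One row per non-zero design term. Internal: neutral − anger 3.7 px,
#' surprise − mean(neutral, anger) 4.0 px, wh − statement 0.3 px, polar −
#' mean(statement, wh) 2.3 px, and a −1.8 px polar-contrast x group
#' interaction (deaf raise less than hearing). External: 0.45, 2.5, 0.09 and
#' 2.5 px analogues, a −2.0 px surprise x wh interaction, −1.8 px wh x group
#' and −2.3 px polar x group interactions, and a +3.3 px surprise x wh x
#' group three-way. All other terms (including the group main effect) are
#' zero. Terms are named as in the fixed design matrix of [build_design()].
#'
#' @return data.frame with columns `term`, `internal`, `external`.
#' @export
default_effect_params <- function() {
  data.frame(
    term = c(
      "emotionNvA", "emotionSvNA", "sentence_typeWvS", "sentence_typePvSW",
      "emotionSvNA:sentence_typeWvS",
      "sentence_typeWvS:groupDvH", "sentence_typePvSW:groupDvH",
      "emotionSvNA:sentence_typeWvS:groupDvH"
    ),
    internal = c(3.7, 4.0, 0.3, 2.3, 0, 0, -1.8, 0),
    external = c(0.45, 2.5, 0.09, 2.5, -2.0, -1.8, -2.3, 3.3),
    stringsAsFactors = FALSE
  )
}

# named 18-vector of true fixed effects for one outcome
.effect_vector <- function(config, outcome, design_colnames) {
  beta <- setNames(numeric(length(design_colnames)), design_colnames)
  beta["(Intercept)"] <- config[[paste0("baseline_", outcome)]]
  eff <- config$effects
  unknown <- setdiff(eff$term, design_colnames)
  if (length(unknown)) stop("effect term(s) not in design: ", paste(unknown, collapse = ", "))
  beta[eff$term] <- eff[[outcome]]
  beta
}

.study_metadata <- function(config) {
  signers <- c(
    paste0("D", seq_len(config$n_signers_deaf)),
    paste0("H", seq_len(config$n_signers_hearing))
  )
  groups <- rep(GROUP_LEVELS, c(config$n_signers_deaf, config$n_signers_hearing))
  md <- expand.grid(
    emotion = EMOTION_LEVELS, sentence_type = SENTENCE_TYPE_LEVELS,
    sentence_id = sprintf("s%02d", seq_len(config$n_sentences)),
    signer_id = signers,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  md$group <- groups[match(md$signer_id, signers)]
  md$video_id <- paste(md$signer_id, md$sentence_id, md$emotion, md$sentence_type, sep = "_")
  md[, c("video_id", "signer_id", "group", "sentence_id", "emotion", "sentence_type")]
}

# 70-point schematic face on the canvas. Eyebrow points sit at their
# baseline distance from the nose top along per-point radial directions, so
# a radial displacement of delta changes the measured distance by exactly
# delta (ground truth is analytic). Non-eyebrow points are static scenery.
.face_template <- function(config) {
  cx <- config$canvas[1] / 2
  nose <- c(cx, 300)
  pts <- matrix(NA_real_, FACE_N_POINTS, 2)
  # jaw 0-16: half-ellipse
  th <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, ] <- cbind(cx + 130 * cos(th), 330 - 160 * sin(th))
  # eyebrows 17-26: angles from upward vertical, right brow negative
  ang_deg <- c(-60, -45, -30, -18, -8, 8, 18, 30, 45, 60)
  r_int <- config$baseline_internal
  r_ext <- config$baseline_external
  rad <- r_int + (r_ext - r_int) * pmin(1, pmax(0, (abs(ang_deg) - 8) / (45 - 8)))
  a <- ang_deg * pi / 180
  pts[18:27, ] <- cbind(nose[1] + rad * sin(a), nose[2] - rad * cos(a))
  # nose bridge 27-30 and base 31-35
  pts[28:31, ] <- cbind(cx, seq(300, 360, length.out = 4))
  pts[32:36, ] <- cbind(cx + seq(-20, 20, length.out = 5), 372)
  # eyes 36-41 (right), 42-47 (left)
  eye <- function(x0) cbind(x0 + c(-18, -9, 9, 18, 9, -9), 285 + c(0, -6, -6, 0, 6, 6))
  pts[37:42, ] <- eye(cx - 55)
  pts[43:48, ] <- eye(cx + 55)
  # mouth 48-67
  th2 <- seq(0, 2 * pi, length.out = 21)[-21]
  pts[49:68, ] <- cbind(cx + 40 * cos(th2), 420 + 14 * sin(th2))
  # pupils 68-69
  pts[69:70, ] <- rbind(c(cx - 55, 285), c(cx + 55, 285))
  unit <- matrix(0, FACE_N_POINTS, 2)
  brow_rows <- 18:27
  dirs <- sweep(pts[brow_rows, ], 2, nose)
  unit[brow_rows, ] <- dirs / sqrt(rowSums(dirs^2))
  list(points = pts, nose = nose, unit = unit, brow_rows = brow_rows)
}

.pose_template <- function(config) {
  cx <- config$canvas[1] / 2
  m <- matrix(c(cx, 240), 25, 2, byrow = TRUE)
  m[2, ] <- c(cx, 360) # neck
  m[3, ] <- c(cx - 80, 370)
  m[4, ] <- c(cx - 120, 500)
  m[5, ] <- c(cx - 110, 640) # R arm
  m[6, ] <- c(cx + 80, 370)
  m[7, ] <- c(cx + 120, 500)
  m[8, ] <- c(cx + 110, 640) # L arm
  m[9:25, ] <- cbind(cx + seq(-60, 60, length.out = 17), 700)
  m
}

.hand_template <- function() {
  # 21 points: wrist at origin, 4 points per finger fanned out
  ang <- rep(seq(-0.6, 0.6, length.out = 5), each = 4)
  len <- rep(c(15, 30, 45, 55), times = 5)
  rbind(c(0, 0), cbind(sin(ang) * len, -cos(ang) * len))
}

.draw_confidence <- function(n, p_lowconf) {
  low <- runif(n) < p_lowconf
  conf <- 0.7 + 0.3 * rbeta(n, 5, 2)
  conf[low] <- runif(sum(low), 0.05, 0.695)
  conf
}

# triangular hand-elevation bump confined to each edge span (the prep /
# retraction movement the edge trim exists for); zero in the central span
.edge_bump <- function(n, k, amplitude) {
  e <- numeric(n)
  if (k >= 1) {
    up <- seq_len(k)
    e[up] <- amplitude * (1 - abs(2 * (up - 0.5) / k - 1))
    dn <- seq.int(n - k + 1L, n)
    e[dn] <- amplitude * (1 - abs(2 * (dn - (n - k) - 0.5) / k - 1))
  }
  e
}

.render_video <- function(meta, mu_int, mu_ext, voided, config, tmpl, pose_tmpl, hand_tmpl) {
  n <- config$frames_per_video
  k <- floor(config$hand_ramp_fraction * n)
  edge <- rep(FALSE, n)
  if (k >= 1) edge[c(seq_len(k), seq.int(n - k + 1L, n))] <- TRUE

  off <- matrix(0, FACE_N_POINTS, n)
  off_int <- mu_int - config$baseline_internal + edge * config$edge_brow_offset
  off_ext <- mu_ext - config$baseline_external + edge * config$edge_brow_offset
  off_mix <- (off_int + off_ext) / 2
  for (id0 in 17:26) {
    row <- id0 + 1L
    off[row, ] <- if (id0 %in% config_ids$internal) {
      off_int
    } else if (id0 %in% config_ids$external) off_ext else off_mix
  }

  face <- array(NA_real_, c(FACE_N_POINTS, 3, n), dimnames = list(NULL, KP_COLS, NULL))
  face[, "x", ] <- tmpl$points[, 1] + tmpl$unit[, 1] * off + rnorm(FACE_N_POINTS * n, 0, config$sd_frame)
  face[, "y", ] <- tmpl$points[, 2] + tmpl$unit[, 2] * off + rnorm(FACE_N_POINTS * n, 0, config$sd_frame)
  face[, "confidence", ] <- if (voided) {
    runif(FACE_N_POINTS * n, 0.05, 0.695)
  } else {
    .draw_confidence(FACE_N_POINTS * n, config$p_lowconf)
  }

  elev <- .edge_bump(n, k, 150)
  pose <- array(NA_real_, c(25, 3, n), dimnames = list(NULL, KP_COLS, NULL))
  pose[, "x", ] <- pose_tmpl[, 1] + rnorm(25 * n, 0, config$sd_frame)
  pose[, "y", ] <- pose_tmpl[, 2] + rnorm(25 * n, 0, config$sd_frame)
  for (w in POSE_WRIST_IDS) pose[w + 1L, "y", ] <- pose[w + 1L, "y", ] - elev
  pose[, "confidence", ] <- if (voided) {
    runif(25 * n, 0.05, 0.695)
  } else {
    .draw_confidence(25 * n, config$p_lowconf)
  }

  mk_hand <- function(wrist_row) {
    h <- array(NA_real_, c(HAND_N_POINTS, 3, n), dimnames = list(NULL, KP_COLS, NULL))
    wx <- pose[wrist_row, "x", ]
    wy <- pose[wrist_row, "y", ]
    h[, "x", ] <- rep(wx, each = HAND_N_POINTS) + hand_tmpl[, 1] + rnorm(HAND_N_POINTS * n, 0, config$sd_frame)
    h[, "y", ] <- rep(wy, each = HAND_N_POINTS) + hand_tmpl[, 2] + rnorm(HAND_N_POINTS * n, 0, config$sd_frame)
    h[, "confidence", ] <- if (voided) {
      runif(HAND_N_POINTS * n, 0.05, 0.695)
    } else {
      .draw_confidence(HAND_N_POINTS * n, config$p_lowconf)
    }
    h
  }

  structure(list(
    metadata = video_metadata(
      meta$video_id, meta$signer_id, meta$group,
      meta$sentence_id, meta$emotion, meta$sentence_type
    ),
    fps = config$fps, frame_index = 0:(n - 1L), person_present = rep(TRUE, n),
    face = face,
    left_hand = mk_hand(POSE_WRIST_IDS[2] + 1L),
    right_hand = mk_hand(POSE_WRIST_IDS[1] + 1L),
    pose = pose
  ), class = "keypoint_series")
}

# measured landmark ids used by the renderer (kept in sync with the feature
# defaults and asserted in tests)
config_ids <- list(internal = FACE_INTERNAL_IDS, external = FACE_EXTERNAL_IDS)

#' Extract one frame of a series
#'
#' @param series a [keypoint_series()].
#' @param i frame position (1-based).
#' @return a [frame_keypoints()].
#' @export
series_frame <- function(series, i) {
  stopifnot(i >= 1, i <= n_frames(series))
  grab <- function(part) {
    m <- series[[part]][, , i, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3, dimnames = list(NULL, KP_COLS))
    m
  }
  if (!series$person_present[i]) {
    return(frame_keypoints(.empty_kp(), .empty_kp(), .empty_kp(), .empty_kp(),
      frame_index = series$frame_index[i], person_present = FALSE
    ))
  }
  frame_keypoints(grab("face"), grab("left_hand"), grab("right_hand"), grab("pose"),
    frame_index = series$frame_index[i], person_present = TRUE
  )
}

#' Generate a synthetic eyebrow study
#'
#' Produces the full crossed design (signers x sentences x emotions x
#' sentence types) with known ground truth. Two levels of realism:
#' \describe{
#'   \item{`"keypoints"`}{renders every video as OpenPose-style keypoint
#'     series — schematic face with eyebrow landmarks displaced radially
#'     from the nose top by the injected condition mean, per-frame Gaussian
#'     noise, confidence dropouts, perturbed eyebrows and hand bumps at the
#'     video edges — optionally written to disk as per-frame JSON files.}
#'   \item{`"summary"`}{draws per-video mean internal/external values
#'     directly from the same linear model (fixed effects + random effects +
#'     residual), with residual sd `sd_frame * sqrt(1.5 / n_eff)` where
#'     `n_eff` is the expected number of retained frames after trimming and
#'     confidence filtering — the analytic consequence of averaging the
#'     rendered frames. Used for simulation studies where rendering every
#'     frame would be wasteful.}
#' }
#' Random effects are drawn per signer (intercept + emotion, sentence-type
#' and interaction slopes) and per sentence (intercept + emotion, group and
#' interaction slopes), iid normal with sds `sd_signer` / `sd_sentence` for
#' intercepts and `slope_frac` times that for slopes. `n_voided` videos are
#' rendered with all confidences below 0.7 so the feature pipeline drops
#' them.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @param level `"keypoints"` or `"summary"`.
#' @param dir optional directory: per-frame JSON files are written under
#'   `dir/<video_id>/` (keypoint level only).
#' @return object of class `synthetic_study`: list with `metadata`,
#'   `ground_truth` (per-video expected means, `voided` flag; attributes
#'   `beta_internal`, `beta_external`, `b_signer`, `b_sentence`), `videos`
#'   (keypoint level) or `summaries` (summary level; same columns as
#'   [extract_features()] output), `config`, `seed`, `level`.
#' @export
generate_study <- function(config = synthetic_config(), seed = 1L,
                           level = c("keypoints", "summary"), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  level <- match.arg(level)
  md <- .study_metadata(config)
  des <- build_design(md)
  X <- des$fixed
  beta_int <- .effect_vector(config, "internal", colnames(X))
  beta_ext <- .effect_vector(config, "external", colnames(X))
  n_signers <- config$n_signers_deaf + config$n_signers_hearing

  withr::with_seed(seed, {
    sd_sig <- c(config$sd_signer, rep(config$sd_signer * config$slope_frac, 8))
    sd_sen <- c(config$sd_sentence, rep(config$sd_sentence * config$slope_frac, 5))
    b_signer_int <- matrix(rnorm(n_signers * 9, 0, rep(sd_sig, each = n_signers)), n_signers, 9)
    b_signer_ext <- matrix(rnorm(n_signers * 9, 0, rep(sd_sig, each = n_signers)), n_signers, 9)
    b_sent_int <- matrix(rnorm(config$n_sentences * 6, 0, rep(sd_sen, each = config$n_sentences)), config$n_sentences, 6)
    b_sent_ext <- matrix(rnorm(config$n_sentences * 6, 0, rep(sd_sen, each = config$n_sentences)), config$n_sentences, 6)

    si <- as.integer(des$data$signer_id)
    se <- as.integer(des$data$sentence_id)
    Zsig <- des$random$signer_id
    Zsen <- des$random$sentence_id
    mu_int <- as.vector(X %*% beta_int) +
      rowSums(Zsig * b_signer_int[si, , drop = FALSE]) +
      rowSums(Zsen * b_sent_int[se, , drop = FALSE])
    mu_ext <- as.vector(X %*% beta_ext) +
      rowSums(Zsig * b_signer_ext[si, , drop = FALSE]) +
      rowSums(Zsen * b_sent_ext[se, , drop = FALSE])

    voided <- rep(FALSE, nrow(md))
    if (config$n_voided > 0) {
      voided[sample.int(nrow(md), min(config$n_voided, nrow(md)))] <- TRUE
    }

    gt <- data.frame(
      video_id = md$video_id, mu_internal = mu_int,
      mu_external = mu_ext, voided = voided, stringsAsFactors = FALSE
    )
    attr(gt, "beta_internal") <- beta_int
    attr(gt, "beta_external") <- beta_ext
    attr(gt, "b_signer") <- list(internal = b_signer_int, external = b_signer_ext)
    attr(gt, "b_sentence") <- list(internal = b_sent_int, external = b_sent_ext)

    out <- list(
      metadata = md, ground_truth = gt, config = config,
      seed = seed, level = level
    )

    if (level == "summary") {
      n <- config$frames_per_video
      n_ret <- n - 2L * floor(config$hand_ramp_fraction * n)
      n_eff <- max(1, round(n_ret * (1 - config$p_lowconf)^3))
      resid_sd <- config$sd_frame * sqrt(1.5 / n_eff)
      summaries <- md
      summaries$mean_internal <- mu_int + rnorm(nrow(md), 0, resid_sd)
      summaries$mean_external <- mu_ext + rnorm(nrow(md), 0, resid_sd)
      summaries$mean_internal[voided] <- NA_real_
      summaries$mean_external[voided] <- NA_real_
      summaries$n_frames_total <- n
      summaries$n_frames_used_internal <- ifelse(voided, 0L, n_eff)
      summaries$n_frames_used_external <- ifelse(voided, 0L, n_eff)
      summaries$dropped <- voided
      out$summaries <- summaries
    } else {
      tmpl <- .face_template(config)
      pose_tmpl <- .pose_template(config)
      hand_tmpl <- .hand_template()
      out$videos <- lapply(seq_len(nrow(md)), function(i) {
        .render_video(
          md[i, ], mu_int[i], mu_ext[i], voided[i], config,
          tmpl, pose_tmpl, hand_tmpl
        )
      })
      names(out$videos) <- md$video_id
      if (!is.null(dir)) {
        for (s in out$videos) {
          vd <- file.path(dir, s$metadata$video_id)
          dir.create(vd, recursive = TRUE, showWarnings = FALSE)
          for (i in seq_len(n_frames(s))) {
            write_openpose_frame(
              series_frame(s, i),
              file.path(vd, sprintf(
                "%s_%012d_keypoints.json",
                s$metadata$video_id, s$frame_index[i]
              ))
            )
          }
        }
      }
    }
    structure(out, class = "synthetic_study")
  })
}

#' @export
#' @method print synthetic_study
print.synthetic_study <- function(x, ...) {
  cat(
    "<synthetic_study>", nrow(x$metadata), "videos (", x$level, "level ), seed",
    x$seed, ";", sum(x$ground_truth$voided), "voided\n"
  )
  invisible(x)
}

#' Confusion distributions from per-stratum correctness
#'
#' Builds the rating confusion table for [generate_ratings()]: for each
#' (intended emotion, sentence type) cell the intended label gets the
#' stratum's correctness probability and the remaining mass is spread
#' uniformly over the other three answer options.
#'
#' @param p_by_sentence_type named correctness probabilities, default
#'   `c(statement = 0.73, polar = 0.58, wh = 0.56)`.
#' @return data.frame with columns `intended`, `sentence_type`, and one
#'   probability column per answer option.
#' @export
confusion_from_accuracy <- function(p_by_sentence_type = c(statement = 0.73, polar = 0.58, wh = 0.56)) {
  stopifnot(setequal(names(p_by_sentence_type), SENTENCE_TYPE_LEVELS))
  grid <- expand.grid(
    intended = INTENDED_LABELS, sentence_type = SENTENCE_TYPE_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  probs <- matrix(0, nrow(grid), length(CHOICE_LABELS),
    dimnames = list(NULL, CHOICE_LABELS)
  )
  for (i in seq_len(nrow(grid))) {
    p <- p_by_sentence_type[[grid$sentence_type[i]]]
    probs[i, ] <- (1 - p) / 3
    probs[i, grid$intended[i]] <- p
  }
  cbind(grid, as.data.frame(probs))
}

#' Generate a synthetic validation rating table
#'
#' Emulates the validation experiment: `n_videos` clips with balanced
#' intended emotion x sentence type assignment are each judged by
#' `n_raters` raters, who choose among neutral / surprised / angry / other
#' according to the given confusion distributions.
#'
#' @param confusion data.frame as from [confusion_from_accuracy()]: columns
#'   `intended`, `sentence_type` and one probability column per answer
#'   option; each row must sum to 1 (tolerance 1e-9).
#' @param n_videos number of videos (default 81, 9 per design cell).
#' @param n_raters number of raters (default 5).
#' @param seed integer seed.
#' @return data.frame: `video_id`, `intended`, `sentence_type`, `rater_id`,
#'   `chosen`.
#' @export
generate_ratings <- function(confusion = confusion_from_accuracy(),
                             n_videos = 81L, n_raters = 5L, seed = 1L) {
  stopifnot(all(c("intended", "sentence_type", CHOICE_LABELS) %in% names(confusion)))
  pm <- as.matrix(confusion[, CHOICE_LABELS])
  if (any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop("confusion distributions must each sum to 1")
  }
  cells <- expand.grid(
    intended = INTENDED_LABELS, sentence_type = SENTENCE_TYPE_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- rep_len(seq_len(nrow(cells)), n_videos)
  videos <- data.frame(
    video_id = sprintf("v%03d", seq_len(n_videos)),
    intended = cells$intended[idx], sentence_type = cells$sentence_type[idx],
    stringsAsFactors = FALSE
  )
  key <- paste(videos$intended, videos$sentence_type)
  conf_key <- paste(confusion$intended, confusion$sentence_type)
  row_of <- match(key, conf_key)
  if (anyNA(row_of)) stop("confusion table lacks a row for some (intended, sentence_type) cell")
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      chosen <- vapply(row_of, function(j) {
        sample(CHOICE_LABELS, 1L, prob = pm[j, ])
      }, character(1))
      data.frame(videos,
        rater_id = sprintf("R%d", r), chosen = chosen,
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}
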
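# Factor levels used throughout the package. Order matters: contrast matrices
# below are defined against these orderings.
EMOTION_LEVELS <- c("neutral", "anger", "surprise")
SENTENCE_TYPE_LEVELS <- c("statement", "polar", "wh")
GROUP_LEVELS <- c("deaf", "hearing")

# Build a contrast matrix from a hypothesis matrix L whose rows are the
# intercept (a mean over levels) and the named comparisons. With C =
# solve(L)[, -1], the regression coefficient for each contrast column equals
# the corresponding row-comparison of cell means, in outcome units (pixels).
.contrast_from_hypothesis <- function(L) {
  C <- solve(L)[, -1, drop = FALSE]
  rownames(C) <- colnames(L)
  C
}

#' Contrast scheme for the factorial eyebrow model
#'
#' Defines the comparison-coded contrasts used both to fit the model and to
#' inject effects in the synthetic generator, so that every coefficient is a
#' named difference in pixels:
#' \describe{
#'   \item{emotion}{`NvA` = neutral − anger; `SvNA` = surprise − mean(neutral,
#'     anger).}
#'   \item{sentence_type}{`WvS` = wh − statement; `PvSW` = polar −
#'     mean(statement, wh).}
#'   \item{group}{`DvH` = deaf − hearing (sum-to-zero, ±1/2 coding).}
#' }
#' Positive estimates mean higher eyebrows (larger nose distance) for the
#' first-named side of the comparison.
#'
#' @return An object of class `contrast_scheme`: a list of contrast matrices
#'   (one per factor) plus human-readable labels for reporting.
#' @examples
#' sch <- contrast_scheme()
#' colSums(sch$emotion) # each contrast column sums to zero over levels
#' @export
contrast_scheme <- function() {
  emo_L <- rbind(int = c(1, 1, 1) / 3, NvA = c(1, -1, 0), SvNA = c(-0.5, -0.5, 1))
  colnames(emo_L) <- EMOTION_LEVELS
  sty_L <- rbind(int = c(1, 1, 1) / 3, WvS = c(-1, 0, 1), PvSW = c(-0.5, 1, -0.5))
  colnames(sty_L) <- SENTENCE_TYPE_LEVELS
  grp_L <- rbind(int = c(0.5, 0.5), DvH = c(1, -1))
  colnames(grp_L) <- GROUP_LEVELS
  structure(list(
    emotion = .contrast_from_hypothesis(emo_L),
    sentence_type = .contrast_from_hypothesis(sty_L),
    group = .contrast_from_hypothesis(grp_L),
    labels = c(
      NvA = "neutral - anger",
      SvNA = "surprise - mean(neutral, anger)",
      WvS = "wh - statement",
      PvSW = "polar - mean(statement, wh)",
      DvH = "deaf - hearing"
    )
  ), class = "contrast_scheme")
}

#' Coerce the design factors and attach the scheme's contrasts
#'
#' @param data data.frame with columns `emotion`, `sentence_type`, `group`
#'   (character or factor) and grouping columns `signer_id`, `sentence_id`.
#' @param scheme a [contrast_scheme()].
#' @return `data` with the three design columns as factors carrying the
#'   scheme's contrasts, and grouping columns as factors.
#' @export
apply_contrast_scheme <- function(data, scheme = contrast_scheme()) {
  stopifnot(inherits(scheme, "contrast_scheme"))
  for (col in c("emotion", "sentence_type", "group")) {
    if (!col %in% names(data)) stop("missing design column: ", col)
    levs <- rownames(scheme[[col]])
    vals <- as.character(data[[col]])
    bad <- setdiff(unique(vals), levs)
    if (length(bad)) {
      stop("unknown ", col, " level: ", paste(bad, collapse = ", "))
    }
    f <- factor(vals, levels = levs)
    contrasts(f) <- scheme[[col]]
    data[[col]] <- f
  }
  for (col in intersect(c("signer_id", "sentence_id"), names(data))) {
    data[[col]] <- factor(as.character(data[[col]]))
  }
  data
}

#' Fixed and random design matrices for the factorial model
#'
#' Builds the full-factorial fixed design (18 columns: intercept, 2 emotion
#' contrasts, 2 sentence-type contrasts, 1 group contrast, and all
#' interactions) and the random-effect design matrices used by the
#' by-sentence (emotion x group, 6 columns) and by-signer
#' (emotion x sentence type, 9 columns) slope structures.
#'
#' @inheritParams apply_contrast_scheme
#' @return list with elements `fixed` (n x 18 matrix), `random` (list with
#'   `sentence_id` and `signer_id` matrices), and `data` (the contrast-coded
#'   data).
#' @export
build_design <- function(data, scheme = contrast_scheme()) {
  d <- apply_contrast_scheme(data, scheme)
  for (col in c("emotion", "sentence_type", "group")) {
    if (nlevels(droplevels(d[[col]])) < 2) {
      stop("need at least 2 observed levels of ", col)
    }
  }
  list(
    fixed = model.matrix(~ emotion * sentence_type * group, d),
    random = list(
      sentence_id = model.matrix(~ emotion * group, d),
      signer_id = model.matrix(~ emotion * sentence_type, d)
    ),
    data = d
  )
}
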
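INTENDED_LABELS <- c("neutral", "surprised", "angry")
CHOICE_LABELS <- c("neutral", "surprised", "angry", "other")

.check_rating_table <- function(table) {
  need <- c("video_id", "intended", "rater_id", "chosen")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("rating table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(table)) stop("rating table is empty")
  bad <- setdiff(unique(as.character(table$intended)), INTENDED_LABELS)
  if (length(bad)) stop("intended labels outside {", paste(INTENDED_LABELS, collapse = ", "), "}: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(table$chosen)), CHOICE_LABELS)
  if (length(bad)) stop("chosen labels outside {", paste(CHOICE_LABELS, collapse = ", "), "}: ", paste(bad, collapse = ", "))
  if (anyDuplicated(table[, c("video_id", "rater_id")])) {
    stop("duplicate (video_id, rater_id) pairs in rating table")
  }
  invisible(table)
}

#' Emotion-identification accuracy
#'
#' Proportion of ratings whose chosen label equals the intended emotion,
#' overall or per stratum. A chosen label of `"other"` is never correct
#' (intended labels exclude it); all responses, including `"other"`, stay in
#' the denominator.
#'
#' @param table rating table: columns `video_id`, `intended`, `rater_id`,
#'   `chosen`, optionally `sentence_type`.
#' @param by optional stratifier column name (e.g. `"intended"` or
#'   `"sentence_type"`).
#' @return overall proportion, or a named vector of per-stratum proportions
#'   (`NA` for an empty stratum).
#' @export
accuracy <- function(table, by = NULL) {
  .check_rating_table(table)
  correct <- as.character(table$chosen) == as.character(table$intended)
  if (is.null(by)) {
    return(mean(correct))
  }
  if (!by %in% names(table)) stop("stratifier column not found: ", by)
  tapply(correct, as.character(table[[by]]), function(v) if (length(v)) mean(v) else NA_real_)
}

#' Cohen's kappa between two label sequences
#'
#' Unweighted chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with
#' expected agreement `p_e` from the product of the two raters' marginal
#' proportions over the shared label universe (the union of observed
#' labels, or `levels` if given). If both sequences are constant and
#' identical (`p_o = p_e = 1`) the kappa is defined as 1 and a note is
#' logged.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param levels optional shared label universe.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b, levels = NULL) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 1L)
  if (is.null(levels)) levels <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  tab <- table(
    factor(as.character(labels_a), levels = levels),
    factor(as.character(labels_b), levels = levels)
  )
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    message("both raters constant and identical; kappa defined as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Light's kappa across multiple raters
#'
#' Arithmetic mean of Cohen's kappa over all unordered rater pairs, each
#' pair computed on the videos both raters rated (rows missing for either
#' rater are dropped pairwise).
#'
#' @param table rating table (see [accuracy()]); needs >= 2 raters.
#' @param levels shared label universe (default: the four answer options).
#' @return mean pairwise kappa.
#' @export
light_kappa <- function(table, levels = CHOICE_LABELS) {
  .check_rating_table(table)
  raters <- unique(as.character(table$rater_id))
  if (length(raters) < 2L) stop("Light's kappa needs at least 2 raters")
  by_rater <- lapply(raters, function(r) {
    sub <- table[as.character(table$rater_id) == r, c("video_id", "chosen")]
    setNames(as.character(sub$chosen), as.character(sub$video_id))
  })
  pairs <- utils::combn(length(raters), 2L)
  ks <- apply(pairs, 2L, function(ij) {
    a <- by_rater[[ij[1]]]
    b <- by_rater[[ij[2]]]
    shared <- intersect(names(a), names(b))
    if (!length(shared)) {
      return(NA_real_)
    }
    cohen_kappa(a[shared], b[shared], levels = levels)
  })
  mean(ks, na.rm = TRUE)
}

#' Chance-corrected identification accuracy
#'
#' The emotion-recognition literature's correction
#' `(p_correct - 1/k) / (1 - 1/k)` for a forced choice among `k` options:
#' 0 at chance level, 1 at perfect accuracy, negative below chance.
#'
#' @param p_correct proportion correct in `[0, 1]`.
#' @param n_choices number of answer options, `k >= 2`.
#' @return corrected proportion.
#' @examples
#' chance_corrected_accuracy(0.61, 3) # 0.415
#' chance_corrected_accuracy(0.61, 4) # 0.48
#' @export
chance_corrected_accuracy <- function(p_correct, n_choices) {
  stopifnot(p_correct >= 0, p_correct <= 1, n_choices >= 2)
  (p_correct - 1 / n_choices) / (1 - 1 / n_choices)
}

#' Full rater-agreement report
#'
#' Bundles the validation statistics: overall accuracy, accuracy by intended
#' emotion and by sentence type (when present), Cohen's kappa of each rater
#' against the intended labels, Light's kappa across raters, and the
#' chance-corrected accuracy under both 3 choices (the true emotions) and 4
#' (including the `"other"` option), with the matching 33% / 25% chance
#' baselines.
#'
#' @param table rating table (see [accuracy()]).
#' @return object of class `agreement_report` (a list).
#' @export
agreement_report <- function(table) {
  .check_rating_table(table)
  overall <- accuracy(table)
  raters <- unique(as.character(table$rater_id))
  kpr <- vapply(raters, function(r) {
    sub <- table[as.character(table$rater_id) == r, ]
    cohen_kappa(sub$intended, sub$chosen, levels = CHOICE_LABELS)
  }, numeric(1))
  structure(list(
    overall_accuracy = overall,
    accuracy_by_emotion = accuracy(table, by = "intended"),
    accuracy_by_sentence_type = if ("sentence_type" %in% names(table)) {
      accuracy(table, by = "sentence_type")
    },
    kappa_per_rater = kpr,
    light_kappa = if (length(raters) >= 2L) light_kappa(table) else NA_real_,
    chance_level = c(`3` = 1 / 3, `4` = 1 / 4),
    chance_corrected = c(
      `3` = chance_corrected_accuracy(overall, 3),
      `4` = chance_corrected_accuracy(overall, 4)
    ),
    n_ratings = nrow(table), n_raters = length(raters)
  ), class = "agreement_report")
}

#' @export
#' @method print agreement_report
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$n_ratings, "ratings by", x$n_raters, "raters\n")
  cat(sprintf("  overall accuracy: %.3f (chance 1/3 = 0.333, 1/4 = 0.250)\n", x$overall_accuracy))
  cat(sprintf(
    "  chance-corrected: %.3f (3 choices), %.3f (4 choices)\n",
    x$chance_corrected[["3"]], x$chance_corrected[["4"]]
  ))
  if (!is.null(x$accuracy_by_sentence_type)) {
    cat("  accuracy by sentence type:\n")
    print(round(x$accuracy_by_sentence_type, 3))
  }
  cat("  kappa vs intended, per rater:\n")
  print(round(x$kappa_per_rater, 3))
  cat(sprintf("  Light's kappa across raters: %.3f\n", x$light_kappa))
  invisible(x)
}
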
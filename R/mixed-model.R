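# Random-effect structures, from the full design downwards. On optimizer
# failure the ladder is walked in order: drop the emotion:sentence_type slope
# by signer, then the emotion:group slope by sentence, then all slopes.
.re_ladder <- list(
  full = "(emotion * group | sentence_id) + (emotion * sentence_type | signer_id)",
  no_signer_interaction = "(emotion * group | sentence_id) + (emotion + sentence_type | signer_id)",
  no_sentence_interaction = "(emotion + group | sentence_id) + (emotion + sentence_type | signer_id)",
  intercepts = "(1 | sentence_id) + (1 | signer_id)"
)

.model_formula <- function(structure) {
  as.formula(paste(
    ".outcome ~ emotion * sentence_type * group +",
    .re_ladder[[structure]]
  ))
}

# Penalized REML deviance: -2 * log improper-Wishart(nu = p + 2.5, scale = Inf)
# prior on each random-effect covariance block reduces to
# -(nu - p - 1) * log det(Sigma_j) = -3 * sum(log diag(Lambda_j)) up to a
# constant, which diverges to +Inf as any block approaches singularity.
.fit_penalized <- function(form, data, penalty_weight = 3,
                           maxeval = 50000L, xtol = 1e-6) {
  lf <- lme4::lFormula(form,
    data = data, REML = TRUE,
    control = lme4::lmerControl(
      check.nobs.vs.nlev = "ignore",
      check.nobs.vs.nRE = "ignore"
    )
  )
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  lower <- lf$reTrms$lower
  di <- which(lower == 0)
  obj <- function(theta) {
    d <- theta[di]
    if (any(d < 1e-10)) {
      theta[di] <- pmax(d, 1e-10)
      return(devfun(theta) + 1e4)
    }
    devfun(theta) - penalty_weight * sum(log(d))
  }
  opt <- lme4::nloptwrap(lf$reTrms$theta, obj,
    lower = lower, upper = rep(Inf, length(lower)),
    control = list(maxeval = maxeval, xtol_abs = xtol, ftol_abs = 1e-8)
  )
  if (!is.finite(opt$fval)) stop("penalized REML optimization diverged: ", opt$message)
  devfun(opt$par) # leave the deviance environment at the optimum
  fit <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  list(model = fit, converged = opt$conv >= 0 && is.finite(opt$fval))
}

.fit_plain <- function(form, data) {
  fit <- lme4::lmer(form,
    data = data, REML = TRUE,
    control = lme4::lmerControl(
      check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
      check.conv.singular = "ignore", calc.derivs = FALSE
    )
  )
  list(model = fit, converged = TRUE)
}

#' Fit the factorial mixed-effects eyebrow model
#'
#' Fits, by restricted maximum likelihood, the model
#' `outcome ~ emotion * sentence_type * group +
#' (emotion * group | sentence_id) + (emotion * sentence_type | signer_id)`
#' to per-video eyebrow summaries, with the comparison-coded contrasts of
#' [contrast_scheme()] so every coefficient is a named difference in pixels.
#'
#' With few random-effect levels (here 9 signers and 10 sentences) unpenalized
#' fits of rich slope structures routinely land on singular covariance
#' estimates. With `regularize = TRUE` (default) the REML criterion is
#' penalized by the log-prior of an improper Wishart distribution
#' (`nu = p + 2.5`, infinite scale) on each random-effect covariance block —
#' a weak penalty, `-3 * sum(log diag(Lambda))` on the relative covariance
#' factor, that diverges at the singular boundary and so makes a singular
#' estimate impossible while leaving interior estimates essentially
#' untouched.
#'
#' If the optimizer fails, simpler random structures are tried in a fixed
#' order (drop the by-signer interaction slope, then the by-sentence
#' interaction slope, then all slopes), each step logged with `message()`.
#'
#' @param table per-video feature table (from [extract_features()] or
#'   [generate_study()]); must contain `mean_<outcome>` or `<outcome>`,
#'   `emotion`, `sentence_type`, `group`, `signer_id`, `sentence_id`.
#'   Rows with a missing outcome are dropped.
#' @param outcome `"internal"` or `"external"`. The two outcomes are fitted
#'   as separate univariate models with identical right-hand sides.
#' @param scheme a [contrast_scheme()].
#' @param regularize use the singularity-excluding covariance penalty
#'   (default TRUE).
#' @param random_structure starting random-effect structure: `"full"`
#'   (default), `"no_signer_interaction"`, `"no_sentence_interaction"` or
#'   `"intercepts"`.
#' @param penalty_weight multiplier of the log-diagonal penalty; 3
#'   corresponds to the Wishart prior above.
#' @param maxeval,xtol optimizer budget and tolerance for the penalized fit.
#' @return object of class `brow_fit`: list with the underlying `merMod`
#'   `model`, `coefficients` (term, estimate, se, t), `converged`,
#'   `singular`, `n_obs`, `outcome`, `random_structure` (after any
#'   fallback), `regularized`, and the `scheme`.
#' @export
fit_mixed_model <- function(table, outcome = c("internal", "external"),
                            scheme = contrast_scheme(), regularize = TRUE,
                            random_structure = names(.re_ladder)[1],
                            penalty_weight = 3, maxeval = 50000L, xtol = 1e-6) {
  outcome <- match.arg(outcome)
  random_structure <- match.arg(random_structure, names(.re_ladder))
  ycol <- if (paste0("mean_", outcome) %in% names(table)) paste0("mean_", outcome) else outcome
  if (!ycol %in% names(table)) stop("outcome column ", outcome, " not found")
  d <- apply_contrast_scheme(as.data.frame(table), scheme)
  d$.outcome <- as.numeric(d[[ycol]])
  d <- d[!is.na(d$.outcome), , drop = FALSE]
  if (!nrow(d)) stop("outcome ", outcome, " is all-missing")
  if (nlevels(droplevels(d$signer_id)) < 2L || nlevels(droplevels(d$sentence_id)) < 2L) {
    stop("need at least 2 signers and 2 sentences")
  }

  ladder <- names(.re_ladder)
  ladder <- ladder[seq(match(random_structure, ladder), length(ladder))]
  fit <- NULL
  used <- NULL
  errs <- character()
  for (rung in ladder) {
    res <- tryCatch(
      if (regularize) {
        .fit_penalized(.model_formula(rung), d,
          penalty_weight = penalty_weight, maxeval = maxeval, xtol = xtol
        )
      } else {
        .fit_plain(.model_formula(rung), d)
      },
      error = function(e) e
    )
    if (!inherits(res, "error")) {
      fit <- res
      used <- rung
      break
    }
    errs <- c(errs, conditionMessage(res))
    message(
      "random structure '", rung, "' failed (", conditionMessage(res),
      "); falling back"
    )
  }
  if (is.null(fit)) {
    stop("mixed-model fit failed at every random structure: ", paste(errs, collapse = " | "))
  }
  if (used != random_structure) {
    message("fitted with reduced random structure '", used, "'")
  }

  fe <- lme4::fixef(fit$model)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  structure(list(
    model = fit$model,
    coefficients = data.frame(
      term = names(fe), estimate = unname(fe), se = unname(se),
      t = unname(fe / se), stringsAsFactors = FALSE
    ),
    converged = fit$converged,
    singular = lme4::isSingular(fit$model, tol = 1e-4),
    n_obs = nrow(d),
    outcome = outcome,
    random_structure = used,
    regularized = regularize,
    scheme = scheme
  ), class = "brow_fit")
}

#' @export
#' @method print brow_fit
print.brow_fit <- function(x, ...) {
  cat(
    "<brow_fit> outcome:", x$outcome, "| n_obs:", x$n_obs,
    "| random:", x$random_structure,
    "|", if (x$regularized) "penalized REML" else "REML",
    if (x$singular) "| SINGULAR" else "", "\n"
  )
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Wald chi-square tests for the fixed-effect terms
#'
#' Term-level Wald chi-square tests of the factorial fixed effects, via
#' `car::Anova` on the underlying mixed model. Degrees of freedom are the
#' number of contrast columns per term: 2 (emotion), 2 (sentence type),
#' 1 (group), 4, 2, 2 and 4 for the interactions. Type II (default) tests
#' each term after the others at its level; Type III tests each term's
#' coefficients directly in the comparison coding.
#'
#' @param fit a [fit_mixed_model()] result; must have converged.
#' @param type `"II"` (default) or `"III"`.
#' @return data.frame of class `anova_table`: `term`, `chisq`, `df`,
#'   `p_value`.
#' @export
anova_wald <- function(fit, type = c("II", "III")) {
  stopifnot(inherits(fit, "brow_fit"))
  type <- match.arg(type)
  if (!fit$converged) stop("fit did not converge; Wald tests unavailable")
  a <- car::Anova(fit$model, type = type, test.statistic = "Chisq")
  keep <- rownames(a) != "(Intercept)"
  out <- data.frame(
    term = rownames(a)[keep],
    chisq = a$Chisq[keep],
    df = a$Df[keep],
    p_value = a$`Pr(>Chisq)`[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

# human-readable label for a design-matrix term name
.pretty_term <- function(term, labels) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  for (code in names(labels)) {
    parts <- sub(paste0("^(emotion|sentence_type|group)", code, "$"),
      paste0("[", labels[[code]], "]"), parts
    )
  }
  paste(parts, collapse = " x ")
}

#' Contrast estimates in reporting form
#'
#' One row per non-intercept fixed effect (17 for the full factorial) with
#' its estimate, standard error and t value in pixels, labelled by the
#' comparison it estimates. Sign convention: positive means higher eyebrows
#' for the first-named side of each contrast. Near-exact fits (|t| beyond
#' 1e6, as in noiseless data) are flagged in the `exact` column.
#'
#' @param fit a [fit_mixed_model()] result; must have converged.
#' @return data.frame: `term`, `contrast`, `estimate`, `se`, `t`, `exact`.
#' @export
report_effects <- function(fit) {
  stopifnot(inherits(fit, "brow_fit"))
  if (!fit$converged) stop("fit did not converge")
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", , drop = FALSE]
  data.frame(
    term = co$term,
    contrast = vapply(co$term, .pretty_term, character(1), labels = fit$scheme$labels),
    estimate = co$estimate, se = co$se, t = co$t,
    exact = !is.finite(co$t) | abs(co$t) > 1e6,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Variance components of a fitted model
#'
#' @param fit a [fit_mixed_model()] result.
#' @return data.frame from [lme4::VarCorr()] with grouping factor, term
#'   names, variances/covariances and sd/correlations.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "brow_fit"))
  as.data.frame(lme4::VarCorr(fit$model))
}
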
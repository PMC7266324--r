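test_that("fixed design has 18 columns, full rank, and zero-sum contrasts on balanced data", {
  md <- browprosody:::.study_metadata(synthetic_config())
  des <- build_design(md)
  expect_equal(ncol(des$fixed), 18L)
  expect_equal(qr(des$fixed)$rank, 18L)
  # each factor's contrast columns sum to zero over its balanced levels
  sch <- contrast_scheme()
  expect_equal(colSums(sch$emotion), c(NvA = 0, SvNA = 0))
  expect_equal(colSums(sch$sentence_type), c(WvS = 0, PvSW = 0))
  expect_equal(colSums(sch$group), c(DvH = 0))
  # emotion and sentence-type columns sum to zero over the (balanced-in-
  # condition) study design
  cols <- c("emotionNvA", "emotionSvNA", "sentence_typeWvS", "sentence_typePvSW")
  expect_equal(unname(colSums(des$fixed[, cols])), rep(0, 4), tolerance = 1e-10)
  # random designs: 6 columns by sentence, 9 by signer
  expect_equal(ncol(des$random$sentence_id), 6L)
  expect_equal(ncol(des$random$signer_id), 9L)
  expect_error(build_design(transform(md, emotion = "joy")), "unknown emotion level")
})

test_that("contrast coefficients estimate the named cell-mean comparisons", {
  md <- browprosody:::.study_metadata(synthetic_config())
  d <- apply_contrast_scheme(md)
  mu_emo <- c(neutral = 10, anger = 6.3, surprise = 12.15)
  mu_sty <- c(statement = 0, polar = 2.4, wh = 0.3)
  d$y <- mu_emo[as.character(d$emotion)] + mu_sty[as.character(d$sentence_type)]
  b <- coef(lm(y ~ emotion + sentence_type, d))
  expect_equal(unname(b["emotionNvA"]), 10 - 6.3) # neutral - anger
  expect_equal(unname(b["emotionSvNA"]), 12.15 - (10 + 6.3) / 2) # surprise - mean
  expect_equal(unname(b["sentence_typeWvS"]), 0.3)
  expect_equal(unname(b["sentence_typePvSW"]), 2.4 - 0.15)
  # group coefficient is the deaf - hearing difference
  d$y2 <- ifelse(d$group == "deaf", 3, 1)
  expect_equal(unname(coef(lm(y2 ~ group, d))["groupDvH"]), 2)
})

test_that("near-noiseless data recovers the injected coefficients to optimizer tolerance", {
  st <- generate_study(noiseless_config(sd_frame = 1e-4), seed = 5, level = "summary")
  fit <- fit_mixed_model(st$summaries, "internal",
    regularize = FALSE,
    random_structure = "intercepts"
  )
  bt <- attr(st$ground_truth, "beta_internal")
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
    bt[fit$coefficients$term],
    tolerance = 1e-3
  )
  # intercept absorbs a constant shift; contrast estimates are invariant
  sh <- st$summaries
  sh$mean_internal <- sh$mean_internal + 100
  fit2 <- fit_mixed_model(sh, "internal", regularize = FALSE, random_structure = "intercepts")
  expect_equal(fit2$coefficients$estimate[1], fit$coefficients$estimate[1] + 100, tolerance = 1e-6)
  expect_equal(fit2$coefficients$estimate[-1], fit$coefficients$estimate[-1], tolerance = 1e-6)
})

test_that("zero random-effect variance without regularization raises the singular flag; the penalty removes it", {
  st <- generate_study(tiny_config(sd_signer = 0, sd_sentence = 0, sd_frame = 3),
    seed = 1, level = "summary"
  )
  plain <- fit_mixed_model(st$summaries, "internal",
    regularize = FALSE,
    random_structure = "intercepts"
  )
  expect_true(plain$singular)
  pen <- fit_mixed_model(st$summaries, "internal",
    regularize = TRUE,
    random_structure = "intercepts"
  )
  expect_false(pen$singular)
})

test_that("Wald table covers all terms with the factorial degrees of freedom", {
  st <- generate_study(tiny_config(), seed = 3, level = "summary")
  fit <- fit_mixed_model(st$summaries, "internal", random_structure = "intercepts")
  a <- anova_wald(fit)
  expect_equal(a$term, c(
    "emotion", "sentence_type", "group", "emotion:sentence_type",
    "emotion:group", "sentence_type:group", "emotion:sentence_type:group"
  ))
  expect_equal(a$df, c(2, 2, 1, 4, 2, 2, 4))
  expect_true(all(a$chisq >= 0))
  expect_true(all(a$p_value >= 0 & a$p_value <= 1))
})

test_that("type III Wald chi-square equals the hand-computed quadratic form", {
  st <- generate_study(tiny_config(), seed = 13, level = "summary")
  fit <- fit_mixed_model(st$summaries, "internal", random_structure = "intercepts")
  a3 <- anova_wald(fit, type = "III")
  b <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  quad <- function(idx) as.numeric(t(b[idx]) %*% solve(V[idx, idx]) %*% b[idx])
  expect_equal(a3$chisq[a3$term == "emotion"], quad(c("emotionNvA", "emotionSvNA")))
  expect_equal(a3$chisq[a3$term == "group"], quad("groupDvH"))
  expect_equal(
    a3$chisq[a3$term == "emotion:sentence_type:group"],
    quad(grep(":sentence_type.*:groupDvH", names(b), value = TRUE))
  )
  # and the p-value is the chi-square upper tail at the term's df
  expect_equal(
    a3$p_value[a3$term == "emotion"],
    pchisq(a3$chisq[a3$term == "emotion"], 2, lower.tail = FALSE)
  )
})

test_that("effect report has 17 contrast rows matching the fit coefficients", {
  st <- generate_study(tiny_config(), seed = 17, level = "summary")
  fit <- fit_mixed_model(st$summaries, "external", random_structure = "intercepts")
  rep_ <- report_effects(fit)
  expect_equal(nrow(rep_), 17L)
  expect_equal(rep_$estimate, fit$coefficients$estimate[-1])
  expect_equal(rep_$se, fit$coefficients$se[-1])
  expect_match(
    rep_$contrast[rep_$term == "emotionNvA"],
    "neutral - anger",
    fixed = TRUE
  )
  expect_false(any(rep_$exact))
})

test_that("full random structure fits non-singular under the covariance penalty", {
  st <- generate_study(synthetic_config(n_sentences = 4L), seed = 21, level = "summary")
  fit <- fit_mixed_model(st$summaries, "internal")
  expect_true(fit$converged)
  expect_false(fit$singular)
  expect_equal(fit$random_structure, "full")
  expect_equal(fit$n_obs, sum(!is.na(st$summaries$mean_internal)))
  vc <- variance_components(fit)
  expect_true(all(vc$sdcor[is.na(vc$var2)] > 0))
})

test_that("degenerate inputs give informative fit errors", {
  st <- generate_study(tiny_config(), seed = 1, level = "summary")
  s <- st$summaries
  s$mean_internal <- NA_real_
  expect_error(fit_mixed_model(s, "internal"), "all-missing")
  one_signer <- st$summaries[st$summaries$signer_id == "D1", ]
  expect_error(fit_mixed_model(one_signer, "internal"), "at least 2 signers")
})
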
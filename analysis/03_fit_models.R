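#!/usr/bin/env Rscript
# Stage 3 — factorial mixed-effects models.
#
# Fits internal and external eyebrow position separately with the full Eq-
# style structure: emotion * sentence_type * group fixed effects,
# (emotion * group | sentence) and (emotion * sentence_type | signer) random
# slopes, penalized REML so the random-effect covariances cannot go
# singular. Writes coefficient tables, Wald chi-square term tests, and a
# JSON fit report.

suppressMessages(library(browprosody))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

features <- data.table::fread("results/features.csv")

report <- list(seed = seed)
for (outcome in c("internal", "external")) {
  fit <- fit_mixed_model(features, outcome)
  eff <- report_effects(fit)
  aov <- anova_wald(fit, type = "II")
  cat(sprintf(
    "\n== %s eyebrow position (n = %d, random: %s, singular: %s) ==\n",
    outcome, fit$n_obs, fit$random_structure, fit$singular
  ))
  key <- eff[eff$term %in% c("emotionNvA", "emotionSvNA", "sentence_typeWvS", "sentence_typePvSW"), ]
  for (i in seq_len(nrow(key))) {
    cat(sprintf(
      "  %-32s %+.2f px (se = %.2f, t = %.1f)\n",
      key$contrast[i], key$estimate[i], key$se[i], key$t[i]
    ))
  }
  emo <- aov[aov$term == "emotion", ]
  cat(sprintf(
    "  emotion term: chi^2 = %.1f, df = %d, p = %.2g\n",
    emo$chisq, emo$df, emo$p_value
  ))
  write_table_atomic(eff, sprintf("results/effects_%s.csv", outcome), seed = seed)
  write_table_atomic(aov, sprintf("results/anova_%s.csv", outcome), seed = seed)
  report[[outcome]] <- list(
    n_obs = fit$n_obs, converged = fit$converged, singular = fit$singular,
    random_structure = fit$random_structure,
    variance_components = variance_components(fit)
  )
}

jsonlite::write_json(report, "results/fit_report.json",
  auto_unbox = TRUE, digits = 6, dataframe = "rows"
)
cat("\nWrote results/effects_*.csv, results/anova_*.csv, results/fit_report.json\n")
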
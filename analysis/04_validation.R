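#!/usr/bin/env Rscript
# Stage 4 — rater-agreement validation.
#
# Simulates the validation experiment (81 clips judged by 5 raters choosing
# among neutral / surprised / angry / other, with per-sentence-type
# correctness 73% / 58% / 56%) and computes the agreement statistics:
# overall and stratified accuracy, Cohen's kappa per rater against the
# intended labels, Light's kappa across raters, and chance-corrected
# accuracy under 3 and 4 answer options.

suppressMessages(library(browprosody))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

ratings <- generate_ratings(confusion_from_accuracy(), n_videos = 81L,
                            n_raters = 5L, seed = seed)
report <- agreement_report(ratings)
print(report)

write_table_atomic(ratings, "results/ratings.csv", seed = seed)
flat <- data.frame(
  statistic = c(
    "overall_accuracy", "light_kappa",
    "chance_corrected_3", "chance_corrected_4",
    paste0("kappa_", names(report$kappa_per_rater)),
    paste0("accuracy_", names(report$accuracy_by_sentence_type))
  ),
  value = c(
    report$overall_accuracy, report$light_kappa,
    report$chance_corrected, report$kappa_per_rater,
    report$accuracy_by_sentence_type
  )
)
write_table_atomic(flat, "results/agreement.csv", seed = seed)
cat("Wrote results/ratings.csv and results/agreement.csv\n")
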
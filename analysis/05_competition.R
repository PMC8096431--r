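#!/usr/bin/env Rscript
# Stage 5: growth fold changes in the frass competition assay and their
# statistics (Welch t-test for two treatments, ANOVA + Tukey HSD for more).

suppressPackageStartupMessages(library(frasschem))
cfu <- read_cfu_csv("results/simdata/cfu.csv")
res <- analyze_cfu(cfu)

summary_rows <- list()
for (org in names(res)) {
  r <- res[[org]]
  means <- tapply(r$fold_changes$fold_change, r$fold_changes$treatment, mean)
  message(org, " mean fold changes: ",
          paste(sprintf("%s = %.2f", names(means), means), collapse = ", "))
  if (r$test$method == "welch_t") {
    message(sprintf("  Welch t = %.2f, p = %.3g", r$test$t_stat,
                    r$test$p_value))
  } else {
    message(sprintf("  ANOVA F = %.2f, p = %.3g; Tukey contrasts:",
                    r$test$anova_F, r$test$anova_p))
    print(r$test$tukey, n = Inf)
  }
  summary_rows[[org]] <- data.frame(
    organism = org, treatment = names(means), mean_fold_change = c(means),
    p_value = if (r$test$method == "welch_t") r$test$p_value else
      r$test$anova_p)
}
write_report(do.call(rbind, summary_rows), "results/competition_summary")
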
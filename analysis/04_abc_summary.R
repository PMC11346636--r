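#!/usr/bin/env Rscript
# Step 4: per-item summary of the ABC questionnaire.
#
# The simulator assigns each participant a total ABC score; here a
# synthetic 16-item response table consistent with those totals is drawn
# (item scores on the questionnaire's 0/10/20/.../100 steps, jittered
# around the participant's total and clipped), then summarized per item:
# mean score and counts of 0% and 100% responses.

library(gaitconf)

manifest <- read.csv("results/manifest_separated.csv")
set.seed(7)
items <- t(sapply(manifest$abc_score, function(total) {
  raw <- pmin(100, pmax(0, rnorm(16, mean = total, sd = 18)))
  round(raw / 10) * 10
}))

summary_df <- summarize_abc(items)
summary_df$mean_total <- round(mean(rowMeans(items)), 1)
write.csv(summary_df[, c("item", "mean_score", "n_zero", "n_full")],
          "results/abc_item_summary.csv", row.names = FALSE)
print(summary_df[, c("item", "mean_score", "n_zero", "n_full")])
cat(sprintf("mean simulated total ABC: %.1f%% (target %.1f%%)\n",
            mean(rowMeans(items)), mean(manifest$abc_score)))
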
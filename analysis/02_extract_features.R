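#!/usr/bin/env Rscript
# Step 2: signal conditioning, foot-strike cleanup, and feature extraction.
#
# Each trial is resampled to 50 Hz, low-pass filtered (zero-lag Butterworth,
# 4 Hz), foot strikes are detected from AP acceleration peaks and cleaned
# (extra-prediction removal, gap-rule missed-step insertion), and the
# 62-per-step / 248-per-trial feature scheme is computed. The full feature
# matrices go to scratch/; a per-participant stage summary goes to results/.

library(gaitconf)

for (cohort in c("separated", "null")) {
  dir <- file.path("scratch", paste0("cohort_", cohort))
  cohort_df <- read.csv(file.path(dir, "cohort.csv"))
  ids <- cohort_df$participant_id
  trials <- lapply(ids, function(id)
    preprocess_trial(file.path(dir, paste0("trial_", id, ".csv"))))
  for (i in seq_along(trials)) trials[[i]]$participant_id <- ids[i]
  feats <- cohort_features(trials)
  out <- data.frame(participant_id = ids, step_count = feats$step_counts,
                    feats$X, check.names = FALSE)
  data.table::fwrite(out, file.path("scratch",
                                    paste0("features_", cohort, ".csv")))
  summary_df <- data.frame(participant_id = ids,
                           samples = sapply(trials, `[[`, "n_samples"),
                           strikes = feats$strike_counts,
                           steps = feats$step_counts)
  write.csv(summary_df,
            file.path("results", paste0("stage_summary_", cohort, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: %d trials, %.0f-%.0f strikes, %d features per trial\n",
              cohort, length(ids), min(feats$strike_counts),
              max(feats$strike_counts), ncol(feats$X)))
}
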
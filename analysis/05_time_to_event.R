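#!/usr/bin/env Rscript
# Stage 5: Kaplan-Meier analysis of time to the MID (UAS7 reduction
# >= 11), censored at the end of treatment (week 8).

suppressMessages(library(csutrial))

cfg <- read_trial_config("results/cohort/trial_config.yaml")
profiles <- read.csv("results/cohort/profiles.csv")
profiles$arm <- factor(profiles$arm, levels = names(cfg$arms))
weekly <- read.csv("results/weekly_scores.csv")
changes <- change_from_baseline(weekly)

tte <- time_to_mid_series(changes)
km <- km_by_arm(tte, profiles)
write.csv(km, "results/km.csv", row.names = FALSE)

cat("Median weeks to MID by arm:\n")
print(attr(km, "medians"), row.names = FALSE)
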
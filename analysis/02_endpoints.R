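#!/usr/bin/env Rscript
# Stage 2: derive diary endpoints from the simulated cohort.
#
# Reads results/cohort/diary.csv, scores daily UAS and weekly
# UAS7/itch/hive, computes changes from baseline and responder records
# (well-controlled UAS7 <= 6, complete response UAS7 = 0, MID reduction
# >= 11, nonresponder rule for early discontinuations).

suppressMessages(library(csutrial))

cfg <- read_trial_config("results/cohort/trial_config.yaml")
diary <- read.csv("results/cohort/diary.csv")
profiles <- read.csv("results/cohort/profiles.csv")
profiles$arm <- factor(profiles$arm, levels = names(cfg$arms))

daily <- daily_scores(diary)
weekly <- derive_weekly_scores(daily, weeks = 0:12)
changes <- change_from_baseline(weekly)
responders <- classify_responders(changes, profiles)

dir.create("results", showWarnings = FALSE)
write.csv(weekly, "results/weekly_scores.csv", row.names = FALSE)
write.csv(responders, "results/responders.csv", row.names = FALSE)

base <- weekly[weekly$week == 0, ]
cat(sprintf("Baseline UAS7: mean %.1f (s.d. %.1f), n = %d\n",
            mean(base$uas7), sd(base$uas7), nrow(base)))
ch8 <- changes[changes$week == 8 & !is.na(changes$uas7_change), ]
arm <- profiles$arm[match(ch8$patient_id, profiles$patient_id)]
cat("Week-8 mean UAS7 change by arm:\n")
print(round(tapply(ch8$uas7_change, arm, mean), 1))
r8 <- responders[responders$week == 8, ]
arm_r <- profiles$arm[match(r8$patient_id, profiles$patient_id)]
cat("Well-controlled (UAS7 <= 6) at week 8 by arm (%):\n")
print(round(100 * tapply(r8$well_controlled, arm_r, mean)))
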
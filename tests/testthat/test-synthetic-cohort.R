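test_that("cohort generation respects configured arm sizes and baseline coverage", {
  cfg <- trial_config()
  coh <- generate_cohort(cfg, seed = 3, simulate_assays = FALSE)
  expect_equal(nrow(coh$profiles), 93)
  expect_equal(as.numeric(table(coh$profiles$arm)), c(23, 23, 24, 23))
  # every patient has the full baseline diary week (days -7 .. -1)
  base <- coh$diary[coh$diary$study_day %in% -7:-1, ]
  expect_false(any(base$missing))
  cnt <- table(base$patient_id)
  expect_true(all(cnt == 14))  # 7 days x AM/PM
  expect_true(all(coh$diary$itch_score[!coh$diary$missing] %in% 0:3))
  expect_true(all(coh$diary$hive_score[!coh$diary$missing] %in% 0:3))
})

test_that("identical (config, seed) reproduces identical cohorts", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 11)
  c2 <- generate_cohort(cfg, seed = 11)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$diary, c2$diary)
  expect_identical(c1$assays$elisa, c2$assays$elisa)
  expect_identical(c1$assays$bhra, c2$assays$bhra)
  c3 <- generate_cohort(cfg, seed = 12)
  expect_false(identical(c1$diary, c3$diary))
})

test_that("degenerate prevalence and invalid configs are handled", {
  cfg0 <- small_config(bhra_pos_prevalence = 0)
  prof <- generate_profiles(cfg0, seed = 4)
  expect_false(any(prof$autoimmune_class))
  expect_error(trial_config(arms = c(a = 0L)), "arms")
  expect_error(trial_config(dropout_rate = 1.2), "dropout_rate")
  expect_error(trial_config(visit_weeks = c(1, 1, 2)), "visit_weeks")
  expect_error(trial_config(arm_effects = c(-1, -2)), "arm_effects")
})

test_that("latent class links biomarkers: BHRA release and low IgE differ by class", {
  cfg <- trial_config(arms = c(one = 800L), arm_effects = -15,
                      autoimmune_effect_shift = 0, rr_arm_pct_change = -40)
  prof <- generate_profiles(cfg, seed = 5)
  expect_gt(mean(prof$autoimmune_class), 0.2)
  thr <- cfg$healthy_hr_mean + 2 * cfg$healthy_hr_sd
  p_pos_class <- mean(prof$true_bhra_release[prof$autoimmune_class] >= thr)
  p_pos_non <- mean(prof$true_bhra_release[!prof$autoimmune_class] >= thr)
  expect_gt(p_pos_class, p_pos_non)
  expect_gt(p_pos_class, 0.85)
  expect_lt(p_pos_non, 0.15)
  # class-conditional IgE distributions differ in location (low IgE link)
  expect_lt(median(prof$total_ige[prof$autoimmune_class]),
            median(prof$total_ige[!prof$autoimmune_class]))
  # marginal BHRA positivity tracks the configured prevalence
  p_marg <- mean(prof$true_bhra_release >= thr)
  expect_lt(abs(p_marg - 0.41), 3 * sqrt(0.41 * 0.59 / nrow(prof)) + 0.02)
})

test_that("no-effect zero-noise patients score constant weeks", {
  cfg <- trial_config(arms = c(solo = 3L), arm_effects = 0,
                      autoimmune_effect_shift = 0, rr_arm_pct_change = 0,
                      response_heterogeneity = 0, day_noise_sd = 0,
                      session_noise_sd = 0, dropout_rate = 0,
                      session_missing_rate = 0, itch_fraction = 0.5)
  coh <- generate_cohort(cfg, seed = 2, simulate_assays = FALSE)
  w <- derive_weekly_scores(daily_scores(coh$diary), weeks = 0:8)
  for (id in unique(w$patient_id))
    expect_equal(length(unique(w$uas7[w$patient_id == id])), 1)
})

test_that("week-8 mean change calibrates to the configured arm effect", {
  cfg <- trial_config(arms = c(top = 2000L), arm_effects = -20.7,
                      autoimmune_effect_shift = 0, rr_arm_pct_change = -45,
                      dropout_rate = 0, session_missing_rate = 0)
  coh <- generate_cohort(cfg, seed = 41, simulate_assays = FALSE)
  w <- derive_weekly_scores(daily_scores(coh$diary), weeks = c(0, 8))
  ch <- suppressMessages(change_from_baseline(w))
  ch8 <- ch$uas7_change[ch$week == 8]
  expect_lt(abs(mean(ch8) - (-20.7)), 1.0)
  mc_se <- sd(ch8) / sqrt(length(ch8))
  expect_lt(abs(mean(ch8) - (-20.7)), 3 * mc_se + 0.25)
  # baseline distribution matches the configured location and scale
  base <- w$uas7[w$week == 0]
  expect_lt(abs(mean(base) - 27.5), 0.8)
  expect_lt(abs(sd(base) - 7.3), 1.2)
})

test_that("autoimmune-class shift moves the class contrast, not the arm mean", {
  cfg <- trial_config(arms = c(low = 2500L), arm_effects = -11.7,
                      autoimmune_effect_shift = -5, rr_arm_pct_change = -45,
                      dropout_rate = 0, session_missing_rate = 0)
  coh <- generate_cohort(cfg, seed = 17, simulate_assays = FALSE)
  w <- derive_weekly_scores(daily_scores(coh$diary), weeks = c(0, 8))
  ch <- suppressMessages(change_from_baseline(w))
  ch8 <- ch[ch$week == 8, ]
  cls <- coh$profiles$autoimmune_class[match(ch8$patient_id,
                                             coh$profiles$patient_id)]
  diff_obs <- mean(ch8$uas7_change[cls]) - mean(ch8$uas7_change[!cls])
  se <- sqrt(var(ch8$uas7_change[cls]) / sum(cls) +
               var(ch8$uas7_change[!cls]) / sum(!cls))
  expect_lt(abs(diff_obs - (-5)), 3 * se)
  expect_lt(abs(mean(ch8$uas7_change) - (-11.7)),
            3 * sd(ch8$uas7_change) / sqrt(nrow(ch8)) + 0.25)
})

test_that("dropout and session missingness follow the configured rates and rules", {
  # completer fraction over a large profile-only sample
  cfg <- trial_config(arms = c(big = 10000L), arm_effects = -15,
                      autoimmune_effect_shift = 0, rr_arm_pct_change = -40,
                      dropout_rate = 0.14)
  prof <- generate_profiles(cfg, seed = 6)
  completer <- mean(is.na(prof$dropout_day))
  expect_lt(abs(completer - 0.86), 0.01)

  # identity when both rates are zero
  cfg0 <- small_config(dropout_rate = 0, session_missing_rate = 0)
  coh0 <- generate_cohort(cfg0, seed = 8, apply_missingness = FALSE,
                          simulate_assays = FALSE)
  coh0b <- apply_missingness_and_dropout(coh0)
  expect_identical(coh0$diary, coh0b$diary)

  # all sessions after the dropout day are missing
  cfg1 <- small_config(dropout_rate = 0.9, session_missing_rate = 0)
  coh1 <- generate_cohort(cfg1, seed = 9, simulate_assays = FALSE)
  pr <- coh1$profiles[!is.na(coh1$profiles$dropout_day), ]
  expect_gt(nrow(pr), 0)
  for (i in seq_len(nrow(pr))) {
    rows <- coh1$diary[coh1$diary$patient_id == pr$patient_id[i] &
                         coh1$diary$study_day > pr$dropout_day[i], ]
    expect_true(all(rows$missing))
    expect_true(all(is.na(rows$itch_score)))
  }
})

test_that("noise-free assay simulation round-trips through quantification", {
  cfg <- small_config(elisa_noise_sd = 0, bhra_noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 13)
  bm <- quantify_assays(coh$assays, coh$profiles)
  truth <- coh$assays$truth
  m <- merge(bm, truth, by = c("patient_id", "visit"))
  expect_equal(m$rr, m$true_rr, tolerance = 1e-8)
  # BHRA percentage release recovers the profile truth exactly
  pat <- coh$assays$bhra[coh$assays$bhra$role == "patient", ]
  pct <- 100 * pat$hr_released / pat$hr_total
  expect_equal(pct,
               coh$profiles$true_bhra_release[
                 match(pat$patient_id, coh$profiles$patient_id)],
               tolerance = 1e-10)
})

test_that("noisy assay recovery of relative reactivity is unbiased", {
  cfg <- trial_config(arms = c(one = 250L), arm_effects = -15,
                      autoimmune_effect_shift = 0, rr_arm_pct_change = -40,
                      elisa_noise_sd = 0.01)
  prof <- generate_profiles(cfg, seed = 21)
  assays <- simulate_assay_measurements(prof, cfg, seed = 21)
  bm <- quantify_assays(assays, prof)
  m <- merge(bm, assays$truth, by = c("patient_id", "visit"))
  err <- m$rr - m$true_rr
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 1e-3)
})
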
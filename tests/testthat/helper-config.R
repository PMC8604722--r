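# Small configurations used across tests. Effects carry the magnitudes
# of the default design; sizes are kept small for speed.

small_config <- function(n = 6L, ...) {
  args <- list(
    arms = c(placebo = n, active = n),
    arm_effects = c(-11.2, -20.7),
    autoimmune_effect_shift = c(0, 0),
    rr_arm_pct_change = c(20, -45),
    ...
  )
  do.call(trial_config, args)
}

# deterministic diary rows for hand-built endpoint tests
diary_rows <- function(patient_id, days, itch, hive, session = c("AM", "PM")) {
  grid <- expand.grid(session = session, study_day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(patient_id = patient_id,
             study_day = grid$study_day,
             session = grid$session,
             itch_score = rep_len(itch, nrow(grid)),
             hive_score = rep_len(hive, nrow(grid)),
             rescue_used = FALSE,
             missing = FALSE,
             stringsAsFactors = FALSE)
}

# multivariate-normal longitudinal changes for direct MMRM tests:
# n per arm, true per-arm means at each visit, unstructured covariance
simulate_longitudinal <- function(n_per_arm, arm_means, Sigma,
                                  countries = c("A", "B"), seed = 1) {
  set.seed(seed)
  arms <- names(arm_means)
  visits <- colnames(arm_means[[1]]) %||% seq_len(ncol(arm_means[[1]]))
  rows <- list()
  id <- 0
  R <- chol(Sigma)
  for (a in arms) {
    mu <- as.numeric(arm_means[[a]])
    for (i in seq_len(n_per_arm)) {
      id <- id + 1
      y <- mu + as.numeric(t(R) %*% rnorm(length(mu)))
      rows[[id]] <- data.frame(
        patient_id = sprintf("S%04d", id), arm = a,
        country = sample(countries, 1),
        visit = seq_along(mu), change = y, baseline = 27.5)
    }
  }
  d <- do.call(rbind, rows)
  d$arm <- factor(d$arm, levels = arms)
  d$country <- factor(d$country)
  d$visit <- factor(d$visit)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
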
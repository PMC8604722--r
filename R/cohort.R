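# Synthetic cohort generation: patient profiles, diary trajectories and
# raw assay measurements with the latent type IIb autoimmunity structure
# the downstream analyses assume.
#
# Diary model. Each patient carries a latent weekly-scale baseline
# severity b ~ N(baseline_uas7_mean, sd_b^2) and a patient-level
# multiplicative response factor exp(g) applied to severity. The desired
# daily-UAS mean on study day d is
#     mu(d) = (b/7) * exp(g * f(d)),
#     f(d)  = 1 - exp(-d / onset_days)  for d >= 1, else 0,
#     g ~ N(log(T) - s^2/2, s^2),  T = 1 + (arm effect + class shift)
#                                        / baseline_uas7_mean,
# with s = response_heterogeneity. E[exp(g)] = T, so the arm-level mean
# week-8 change equals the configured arm effect exactly (no floor bias
# at the 0 bound, since severities stay positive), while the lognormal
# spread of exp(g) produces the realistic mix of strong responders,
# complete remitters (including under placebo) and nonresponders.
# The class shift is centred within arm (class gets +(1-p)*shift,
# non-class -p*shift on the weekly scale) so it moves the class
# contrast, not the arm mean. Ordinal 0-3 session scores arise by
# thresholding a latent normal at 0.5/1.5/2.5; the latent location is
# set by numerically inverting the threshold-mean map so configured
# means hold in expectation despite the ordinal censoring.

DIARY_DAYS <- c(-14:-1, 1:84)
TREATMENT_END_DAY <- 56L

# class-conditional log-scale parameters of true biomarker levels,
# relative to the population healthy-panel thresholds
BHRA_CLASS_MEANLOG <- log(2);    BHRA_CLASS_SDLOG <- 0.4
BHRA_NONCLASS_MEANLOG <- log(0.4); BHRA_NONCLASS_SDLOG <- 0.45

# Expected ordinal score E[(z>0.5)+(z>1.5)+(z>2.5)] for z ~ N(m, sigma^2)
threshold_mean <- function(m, sigma) {
  stats::pnorm((m - 0.5) / sigma) + stats::pnorm((m - 1.5) / sigma) +
    stats::pnorm((m - 2.5) / sigma)
}

# Inverse of threshold_mean in m for fixed sigma, via a fine monotone grid
make_latent_calibrator <- function(sigma) {
  if (sigma < 1e-8) return(identity)
  grid_m <- seq(-4, 8, by = 0.01)
  grid_h <- threshold_mean(grid_m, sigma)
  lo <- grid_h[1] + 1e-12
  hi <- grid_h[length(grid_h)] - 1e-12
  function(target) {
    stats::approx(grid_h, grid_m, xout = pmin(pmax(target, lo), hi),
                  ties = "ordered")$y
  }
}

# Within-patient weekly-sum noise variance (approximate; rounding treated
# as additive uniform dither), used to size the between-patient component
# so the realized baseline UAS7 s.d. tracks the configured value.
weekly_noise_variance <- function(cfg) {
  s2 <- cfg$session_noise_sd^2
  d2 <- cfg$day_noise_sd^2
  if (s2 + d2 == 0) return(0)
  rho <- cfg$ar1_rho
  k <- 1:6
  v_day <- 4 * d2 * (7 + 2 * sum((7 - k) * rho^k))
  v_sess <- 7 * (s2 + 1 / 12)
  v_day + v_sess
}

# Location m of the response log-rate g ~ N(m, s^2) such that the
# group-mean week-8 change E[min(b e^g, 42)] - E[b] equals the target,
# accounting for the score ceiling and the baseline distribution
# (numeric quadrature + root finding; exact to quadrature precision).
calibrate_response_lograte <- function(target_change, s, mu_b, sd_b,
                                       cap = 42, b_range = c(0.5, 41.5)) {
  gl <- seq(b_range[1], b_range[2], length.out = 201)
  wb <- stats::dnorm(gl, mu_b, sd_b)
  wb <- wb / sum(wb)
  e_b <- sum(wb * pmin(gl, cap))   # realized (capped) baseline mean
  if (s > 0) {
    gh_z <- seq(-5, 5, length.out = 101)
    wg <- stats::dnorm(gh_z); wg <- wg / sum(wg)
  } else {
    gh_z <- 0; wg <- 1
  }
  mean_change <- function(m) {
    fac <- exp(m + s * gh_z)
    sum(wg * vapply(fac, function(f)
      sum(wb * pmin(gl * f, cap)), numeric(1))) - e_b
  }
  stats::uniroot(function(m) mean_change(m) - target_change,
                 lower = -6, upper = 2, tol = 1e-8)$root
}

# daily-UAS cap at which the larger ordinal component saturates
daily_mean_cap <- function(cfg) {
  3 / max(cfg$itch_fraction, 1 - cfg$itch_fraction)
}

class_probability <- function(prevalence) {
  r1 <- stats::pnorm(BHRA_CLASS_MEANLOG / BHRA_CLASS_SDLOG)
  r0 <- stats::pnorm(BHRA_NONCLASS_MEANLOG / BHRA_NONCLASS_SDLOG)
  min(max((prevalence - r0) / (r1 - r0), 0), 1)
}

#' Generate patient profiles
#'
#' Draws one [PatientProfile] row per configured patient: arm, country,
#' latent baseline severity, latent autoimmunity class and its linked
#' true biomarker levels (BHRA release, IgG-anti-FcERI reactivity, total
#' IgE), and the discontinuation day if the patient drops out.
#'
#' @param cfg a [trial_config()]
#' @param seed master seed (defaults to the config seed)
#' @return data.frame with one row per patient
#' @export
generate_profiles <- function(cfg, seed = cfg$seed) {
  validate_trial_config(cfg)
  n_total <- sum(cfg$arms)
  arm <- rep(names(cfg$arms), times = cfg$arms)
  sd_b <- sqrt(max(cfg$baseline_uas7_sd^2 - weekly_noise_variance(cfg), 1))
  p_class <- class_probability(cfg$bhra_pos_prevalence)
  thr_hr <- cfg$healthy_hr_mean + 2 * cfg$healthy_hr_sd
  unr_pop <- cfg$healthy_rr_mean + 3 * cfg$healthy_rr_sd

  arm_idx <- rep(seq_along(cfg$arms), times = cfg$arms)
  s_resp <- cfg$response_heterogeneity
  # per arm x class group location of the response log-rate
  m_lograte <- lapply(seq_along(cfg$arms), function(a) {
    sh <- cfg$autoimmune_effect_shift[a]
    targets <- c("class" = cfg$arm_effects[a] + (1 - p_class) * sh,
                 "nonclass" = cfg$arm_effects[a] - p_class * sh)
    vapply(targets, calibrate_response_lograte, numeric(1),
           s = s_resp, mu_b = cfg$baseline_uas7_mean, sd_b = sd_b,
           cap = 7 * daily_mean_cap(cfg))
  })

  rows <- lapply(seq_len(n_total), function(i) {
    set.seed(derive_seed(seed, i, offset = 1L))
    country <- sample(names(cfg$countries), 1, prob = cfg$countries)
    b7 <- min(max(stats::rnorm(1, cfg$baseline_uas7_mean, sd_b), 0.5), 41.5)
    auto <- cfg$bhra_pos_prevalence > 0 && stats::runif(1) < p_class
    if (auto) {
      hr <- thr_hr * exp(stats::rnorm(1, BHRA_CLASS_MEANLOG, BHRA_CLASS_SDLOG))
      ige <- stats::rlnorm(1, log(28), 0.7)
      rr <- unr_pop * exp(stats::rnorm(1, log(2.5), 0.6))
    } else {
      hr <- thr_hr * exp(stats::rnorm(1, BHRA_NONCLASS_MEANLOG,
                                      BHRA_NONCLASS_SDLOG))
      ige <- stats::rlnorm(1, log(110), 1.1)
      rr <- abs(stats::rnorm(1, 0.08, 0.05))
    }
    a <- arm_idx[i]
    m_g <- m_lograte[[a]][if (auto) "class" else "nonclass"]
    g <- if (s_resp > 0) stats::rnorm(1, m_g, s_resp) else m_g
    dropped <- stats::runif(1) < cfg$dropout_rate
    data.frame(
      patient_id = sprintf("P%04d", i),
      arm = arm[i], country = country,
      latent_baseline_intensity = b7,
      response_lograte = g,
      autoimmune_class = auto,
      true_bhra_release = min(max(hr, 0), 100),
      true_reactivity_baseline = rr,
      total_ige = ige,
      dropout_day = if (dropped)
        sample(seq_len(TREATMENT_END_DAY), 1) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$arm <- factor(out$arm, levels = names(cfg$arms))
  rownames(out) <- NULL
  out
}

# expected week-end change in UAS7 for profile rows, given the realized
# response log-rate (used to couple biomarker trajectories to response)
profile_expected_change <- function(profiles, cfg, day = TREATMENT_END_DAY) {
  f <- 1 - exp(-day / cfg$onset_days)
  profiles$latent_baseline_intensity *
    (exp(profiles$response_lograte * f) - 1)
}

#' Simulate the diary trajectory of one patient
#'
#' Produces twice-daily itch and hive severities (ordinal 0-3) plus
#' rescue-medication use for the given study days, following the latent
#' exponential-onset model with AR(1) day-level noise described in the
#' package vignette. All entries are generated as observed; missingness
#' is layered on by [apply_missingness_and_dropout()].
#'
#' @param profile one-row data.frame from [generate_profiles()]
#' @param cfg a [trial_config()]
#' @param days integer study days (day 1 = first dose; no day 0)
#' @param calibrator optional precomputed latent calibrator (internal)
#' @return data.frame of diary entries (one row per patient-day-session)
#' @export
simulate_diary_trajectory <- function(profile, cfg, days = DIARY_DAYS,
                                      calibrator = NULL) {
  stopifnot(as.character(profile$arm) %in% names(cfg$arms))
  sigma_tot <- sqrt(cfg$day_noise_sd^2 + cfg$session_noise_sd^2)
  if (is.null(calibrator)) calibrator <- make_latent_calibrator(sigma_tot)

  f <- ifelse(days >= 1, 1 - exp(-pmax(days, 0) / cfg$onset_days), 0)
  mu_day <- pmin(profile$latent_baseline_intensity / 7 *
                   exp(profile$response_lograte * f), daily_mean_cap(cfg))

  nd <- length(days)
  # shared day-level AR(1) noise, stationary s.d. = day_noise_sd
  if (cfg$day_noise_sd > 0) {
    rho <- cfg$ar1_rho
    innov <- stats::rnorm(nd, 0, cfg$day_noise_sd * sqrt(1 - rho^2))
    u <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                  init = stats::rnorm(1, 0, cfg$day_noise_sd)))
  } else {
    u <- numeric(nd)
  }

  w <- c(itch = cfg$itch_fraction, hive = 1 - cfg$itch_fraction)
  score_component <- function(comp) {
    m <- calibrator(w[[comp]] * mu_day)
    sapply(c("AM", "PM"), function(s) {
      z <- m + u + stats::rnorm(nd, 0, cfg$session_noise_sd)
      (z > 0.5) + (z > 1.5) + (z > 2.5)
    })
  }
  itch <- score_component("itch")
  hive <- score_component("hive")
  p_rescue <- pmin(pmax(0.15 + 0.11 * mu_day, 0), 0.95)
  rescue <- matrix(stats::runif(2 * nd) < rep(p_rescue, 2), ncol = 2)

  data.frame(
    patient_id = profile$patient_id,
    study_day = rep(days, 2L),
    session = rep(c("AM", "PM"), each = nd),
    itch_score = as.integer(c(itch[, "AM"], itch[, "PM"])),
    hive_score = as.integer(c(hive[, "AM"], hive[, "PM"])),
    rescue_used = as.logical(rescue),
    missing = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Apply session missingness and treatment discontinuation to a cohort
#'
#' Flags every diary session after a patient's dropout day as missing and
#' independently drops post-baseline sessions at the configured rate.
#' Baseline-week sessions (the 7 days before day 1) are never removed,
#' mirroring the eDiary-completion eligibility requirement. Scores of
#' missing sessions are set to NA. Deterministic given the cohort seed.
#'
#' @param cohort a \code{csu_cohort} from [generate_cohort()]
#' @param cfg a [trial_config()] (defaults to the cohort's config)
#' @return the cohort with its diary's missing flags set
#' @export
apply_missingness_and_dropout <- function(cohort, cfg = cohort$config) {
  diary <- cohort$diary
  prof <- cohort$profiles
  dropout <- prof$dropout_day[match(diary$patient_id, prof$patient_id)]
  miss <- !is.na(dropout) & diary$study_day > dropout

  if (cfg$session_missing_rate > 0) {
    idx <- match(diary$patient_id, prof$patient_id)
    for (i in seq_len(nrow(prof))) {
      rows <- which(idx == i & diary$study_day >= 1)
      if (!length(rows)) next
      set.seed(derive_seed(cohort$seed, i, offset = 2L))
      miss[rows] <- miss[rows] |
        stats::runif(length(rows)) < cfg$session_missing_rate
    }
  }
  diary$missing <- miss
  diary$itch_score[miss] <- NA_integer_
  diary$hive_score[miss] <- NA_integer_
  diary$rescue_used[miss] <- NA
  cohort$diary <- diary
  cohort
}

#' Generate a complete synthetic trial cohort
#'
#' Runs profile generation, per-patient diary simulation, missingness /
#' dropout application and raw assay simulation under one master seed
#' with fixed per-patient substreams (adding patients never perturbs
#' existing ones). Output is byte-identical for identical (config, seed).
#'
#' @param cfg a [trial_config()]
#' @param seed master seed (defaults to the config seed)
#' @param apply_missingness set FALSE to keep the fully observed diary
#' @param simulate_assays set FALSE to skip raw assay simulation
#' @return object of class \code{csu_cohort}: list with
#'   \code{profiles}, \code{diary}, \code{assays} (\code{$elisa} well
#'   readings, \code{$bhra} raw histamine amounts), \code{config},
#'   \code{seed}
#' @examples
#' cfg <- trial_config(arms = c(placebo = 4L, active = 4L),
#'                     arm_effects = c(-11, -20),
#'                     autoimmune_effect_shift = c(0, 0),
#'                     rr_arm_pct_change = c(20, -45))
#' coh <- generate_cohort(cfg, seed = 1)
#' nrow(coh$profiles)
#' @export
generate_cohort <- function(cfg, seed = cfg$seed, apply_missingness = TRUE,
                            simulate_assays = TRUE) {
  validate_trial_config(cfg)
  profiles <- generate_profiles(cfg, seed)
  sigma_tot <- sqrt(cfg$day_noise_sd^2 + cfg$session_noise_sd^2)
  calib <- make_latent_calibrator(sigma_tot)

  diary <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    set.seed(derive_seed(seed, i, offset = 3L))
    simulate_diary_trajectory(profiles[i, ], cfg, calibrator = calib)
  }))
  rownames(diary) <- NULL

  cohort <- structure(
    list(profiles = profiles, diary = diary, assays = NULL,
         config = cfg, seed = seed),
    class = "csu_cohort"
  )
  if (simulate_assays)
    cohort$assays <- simulate_assay_measurements(profiles, cfg, seed)
  if (apply_missingness)
    cohort <- apply_missingness_and_dropout(cohort, cfg)
  cohort
}

#' @export
print.csu_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CSU trial cohort: %d patients, %d arms, seed %s\n",
              nrow(x$profiles), nlevels(x$profiles$arm),
              format(x$seed)))
  print(table(arm = x$profiles$arm))
  invisible(x)
}

#' Write cohort files
#'
#' Serializes a cohort to \code{profiles.csv}, \code{diary.csv},
#' \code{assays_elisa.csv} and \code{assays_bhra.csv} under \code{dir}.
#'
#' @param cohort a \code{csu_cohort}
#' @param dir output directory (created if needed)
#' @return character vector of file paths, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profiles = file.path(dir, "profiles.csv"),
             diary = file.path(dir, "diary.csv"),
             elisa = file.path(dir, "assays_elisa.csv"),
             bhra = file.path(dir, "assays_bhra.csv"))
  utils::write.csv(cohort$profiles, paths["profiles"], row.names = FALSE)
  utils::write.csv(cohort$diary, paths["diary"], row.names = FALSE)
  if (!is.null(cohort$assays)) {
    utils::write.csv(cohort$assays$elisa, paths["elisa"], row.names = FALSE)
    utils::write.csv(cohort$assays$bhra, paths["bhra"], row.names = FALSE)
  }
  invisible(paths)
}
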
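#' Trial configuration
#'
#' Builds and validates the full specification of a simulated dose-ranging
#' CSU trial: arm labels and sizes, the visit schedule, baseline UAS7
#' distribution, per-arm week-8 effects with an exponential onset
#' time-constant, the latent type IIb autoimmunity class structure,
#' dropout and diary missingness rates, countries, assay forward-model
#' parameters and the master seed.
#'
#' The defaults emulate the dose-ranging cohort of a phase 2
#' antihistamine-refractory CSU trial: four arms of 23/23/24/23 patients
#' (93 total), baseline UAS7 mean 27.5 (s.d. 7.3), week-8 mean UAS7
#' changes of -11.2 (placebo) to -20.7 (highest dose), ~41% BHRA-positive
#' prevalence tied to a latent autoimmunity class with low total IgE, and
#' ~14% early discontinuation.
#'
#' @param arms named integer vector: target number of patients per arm;
#'   the first arm is the placebo/reference arm.
#' @param visit_weeks integer vector of scheduled visit weeks
#'   (negative = screening, 0 = baseline/day 1, 1..8 treatment,
#'   9..12 follow-up). Must be strictly increasing.
#' @param baseline_uas7_mean,baseline_uas7_sd baseline UAS7 distribution
#'   across patients (score points, weekly scale 0-42).
#' @param arm_effects numeric vector, one per arm: mean week-8 change from
#'   baseline in UAS7 (score points; negative = improvement). The first
#'   element is the placebo effect.
#' @param onset_days time constant (days) of the exponential effect onset
#'   \eqn{1 - e^{-t/\tau}}.
#' @param autoimmune_effect_shift numeric vector, one per arm: additional
#'   week-8 UAS7 change (score points) in latent-class patients relative
#'   to non-class patients in the same arm. Parameterized so the arm-level
#'   mean change stays equal to \code{arm_effects}.
#' @param bhra_pos_prevalence target marginal prevalence of BHRA
#'   positivity in the cohort.
#' @param dropout_rate probability of early treatment discontinuation
#'   over the 8-week treatment period.
#' @param session_missing_rate probability that any given post-baseline
#'   diary session is missing (baseline-week sessions are always present,
#'   mirroring the eDiary-completion eligibility requirement).
#' @param countries named numeric vector of country sampling weights.
#' @param response_heterogeneity s.d. (log scale) of the patient-level
#'   multiplicative response factor. 0 makes every patient in an
#'   arm/class group respond with exactly the group mean effect; the
#'   default spread reproduces the realistic mix of complete remitters
#'   (including under placebo) and nonresponders while leaving arm-level
#'   mean changes at the configured values.
#' @param itch_fraction fraction of the daily UAS attributable to the
#'   itch component (the remainder is hives).
#' @param ar1_rho lag-1 autocorrelation of the shared day-level latent
#'   noise. The within-patient diary correlation is not identified by
#'   published summaries; this is a free parameter.
#' @param day_noise_sd stationary s.d. of the shared day-level AR(1)
#'   latent noise (component-score scale).
#' @param session_noise_sd s.d. of independent session-by-component
#'   latent noise (component-score scale).
#' @param rr_arm_pct_change numeric vector, one per arm: median percent
#'   change in IgG-anti-FcERI relative reactivity from baseline to week 8.
#' @param elisa_noise_sd s.d. of additive absorbance noise in the ELISA
#'   forward model (OD units); 0 gives exact round trips.
#' @param bhra_noise_sd s.d. of multiplicative log-scale noise on raw
#'   histamine amounts; 0 gives exact round trips.
#' @param healthy_rr_mean,healthy_rr_sd ELISA healthy-panel relative
#'   reactivity distribution (ng/ml); the per-batch upper normal range
#'   (UNR) is mean + 3 s.d. of the 16 sampled healthy sera.
#' @param healthy_hr_mean,healthy_hr_sd BHRA healthy-panel percentage
#'   histamine release distribution; the positivity threshold is
#'   mean + 2 s.d. of the 5 sampled healthy sera.
#' @param seed master seed; per-patient substreams are derived from it.
#' @return object of class \code{trial_config} (a validated list).
#' @examples
#' cfg <- trial_config()
#' cfg$arms
#' @export
trial_config <- function(arms = c("placebo" = 23L, "feneb 50 mg qd" = 23L,
                                  "feneb 150 mg qd" = 24L,
                                  "feneb 200 mg bid" = 23L),
                         visit_weeks = -2:12,
                         baseline_uas7_mean = 27.5,
                         baseline_uas7_sd = 7.3,
                         arm_effects = c(-11.2, -11.7, -17.6, -20.7),
                         onset_days = 10,
                         autoimmune_effect_shift = c(0, -5, -4, 0),
                         bhra_pos_prevalence = 0.41,
                         dropout_rate = 0.14,
                         session_missing_rate = 0.03,
                         countries = c(DEU = 0.30, POL = 0.25,
                                       USA = 0.25, CAN = 0.20),
                         response_heterogeneity = 0.9,
                         itch_fraction = 12.5 / 27.5,
                         ar1_rho = 0.6,
                         day_noise_sd = 0.30,
                         session_noise_sd = 0.35,
                         rr_arm_pct_change = c(20, -45, -55, -45),
                         elisa_noise_sd = 0.01,
                         bhra_noise_sd = 0.05,
                         healthy_rr_mean = 0.12,
                         healthy_rr_sd = 0.06,
                         healthy_hr_mean = 15,
                         healthy_hr_sd = 2.5,
                         seed = 20180528L) {
  cfg <- list(
    arms = arms, visit_weeks = as.integer(visit_weeks),
    baseline_uas7_mean = baseline_uas7_mean,
    baseline_uas7_sd = baseline_uas7_sd,
    arm_effects = arm_effects, onset_days = onset_days,
    autoimmune_effect_shift = autoimmune_effect_shift,
    bhra_pos_prevalence = bhra_pos_prevalence,
    dropout_rate = dropout_rate,
    session_missing_rate = session_missing_rate,
    countries = countries,
    response_heterogeneity = response_heterogeneity,
    itch_fraction = itch_fraction,
    ar1_rho = ar1_rho, day_noise_sd = day_noise_sd,
    session_noise_sd = session_noise_sd,
    rr_arm_pct_change = rr_arm_pct_change,
    elisa_noise_sd = elisa_noise_sd, bhra_noise_sd = bhra_noise_sd,
    healthy_rr_mean = healthy_rr_mean, healthy_rr_sd = healthy_rr_sd,
    healthy_hr_mean = healthy_hr_mean, healthy_hr_sd = healthy_hr_sd,
    seed = seed
  )
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

#' Validate a trial configuration
#'
#' Checks every structural invariant of a [trial_config()] and stops with
#' an error naming the offending field.
#'
#' @param cfg a \code{trial_config} object (or compatible list)
#' @return the config, invisibly, if valid
#' @export
validate_trial_config <- function(cfg) {
  if (length(cfg$arms) < 1 || any(cfg$arms < 1) ||
      any(cfg$arms != as.integer(cfg$arms)))
    stop_field("arms", "each arm needs a target n >= 1")
  if (is.null(names(cfg$arms)) || anyDuplicated(names(cfg$arms)))
    stop_field("arms", "arms must have unique labels")
  if (any(diff(cfg$visit_weeks) <= 0))
    stop_field("visit_weeks", "must be strictly increasing")
  if (cfg$baseline_uas7_mean < 0 || cfg$baseline_uas7_mean > 42)
    stop_field("baseline_uas7_mean", "must lie in [0, 42]")
  if (cfg$baseline_uas7_sd <= 0)
    stop_field("baseline_uas7_sd", "must be > 0")
  if (length(cfg$arm_effects) != length(cfg$arms))
    stop_field("arm_effects", "must be defined for every arm")
  if (length(cfg$autoimmune_effect_shift) != length(cfg$arms))
    stop_field("autoimmune_effect_shift", "must be defined for every arm")
  if (length(cfg$rr_arm_pct_change) != length(cfg$arms))
    stop_field("rr_arm_pct_change", "must be defined for every arm")
  for (f in c("bhra_pos_prevalence", "dropout_rate", "session_missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop_field(f, "must lie in [0, 1]")
  }
  if (cfg$dropout_rate >= 1) stop_field("dropout_rate", "must be < 1")
  if (length(cfg$countries) < 1 || any(cfg$countries < 0) ||
      sum(cfg$countries) <= 0)
    stop_field("countries", "needs nonnegative weights with positive sum")
  if (cfg$itch_fraction <= 0 || cfg$itch_fraction >= 1)
    stop_field("itch_fraction", "must lie in (0, 1)")
  if (abs(cfg$ar1_rho) >= 1) stop_field("ar1_rho", "must lie in (-1, 1)")
  if (cfg$onset_days <= 0) stop_field("onset_days", "must be > 0")
  if (cfg$response_heterogeneity < 0)
    stop_field("response_heterogeneity", "must be >= 0")
  for (f in c("day_noise_sd", "session_noise_sd", "elisa_noise_sd",
              "bhra_noise_sd", "healthy_rr_sd", "healthy_hr_sd"))
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  invisible(cfg)
}

#' Read / write a trial configuration as YAML
#'
#' @param path file path
#' @return \code{read_trial_config}: a validated [trial_config()].
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$arms <- unlist(raw$arms)
  raw$countries <- unlist(raw$countries)
  do.call(trial_config, raw)
}

#' @rdname read_trial_config
#' @param cfg a \code{trial_config}
#' @export
write_trial_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$arms <- as.list(x$arms)
  x$countries <- as.list(x$countries)
  yaml::write_yaml(x, path)
  invisible(path)
}
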
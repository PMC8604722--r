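# Forward simulation of raw assay data: competition-ELISA plate wells
# (absorbance at 450/630 nm) and BHRA raw histamine amounts. The forward
# model is the exact inverse of the quantification module, so noise-free
# simulation followed by quantification recovers the true biomarker
# values to numerical precision.

ELISA_VISITS <- c("screening", "day 1", "day 57", "day 85")
ELISA_A630 <- 0.04          # constant plate background read at 630 nm
ELISA_N_HEALTHY <- 16L      # healthy sera per batch defining the UNR
BHRA_N_HEALTHY <- 5L        # healthy sera defining the BHRA threshold
BHRA_HR_TOTAL <- 50         # total histamine in lysed donor basophils (ng)

#' Four-parameter-logistic forward model parameters of the simulated ELISA
#'
#' The generator's ground-truth calibration curve; standard-curve fitting
#' on noise-free simulated standards must recover these parameters.
#'
#' @return named list: \code{lower}, \code{upper} (OD asymptotes),
#'   \code{ec50} (inflection, ng/ml), \code{slope}
#' @export
elisa_forward_params <- function() {
  list(lower = 0.05, upper = 2.40, ec50 = 0.80, slope = 1.10)
}

# 7-point threefold dilution series spanning the printed 0.014-10 ng/ml
# calibration range (a strict 6-point threefold series cannot reach it)
elisa_standard_concs <- function() 10 / 3^(0:6)

fourpl_forward <- function(conc, p = elisa_forward_params()) {
  p$lower + (p$upper - p$lower) / (1 + (p$ec50 / pmax(conc, 1e-6))^p$slope)
}

elisa_wells <- function(batch, patient_id, role, spike, conc, replicate,
                        noise_sd) {
  a450 <- fourpl_forward(conc) + ELISA_A630 +
    if (noise_sd > 0) stats::rnorm(length(conc), 0, noise_sd) else 0
  role <- rep_len(role, length(conc))
  data.frame(batch = batch, patient_id = patient_id, role = role,
             spike = spike, replicate = replicate,
             nominal_conc = ifelse(role == "standard", conc, NA_real_),
             absorbance_450 = pmax(a450, 0), absorbance_630 = ELISA_A630,
             stringsAsFactors = FALSE)
}

#' Simulate raw assay measurements for a cohort
#'
#' Produces, per ELISA batch (one batch per serum visit), duplicate
#' standard wells following the 4PL forward model, a 16-serum healthy
#' panel and duplicate control-spiked / antigen-spiked sample wells per
#' patient; and the BHRA raw histamine-release amounts (screening serum)
#' with its 5-serum healthy panel. Patients' true relative reactivity
#' follows an arm-dependent percent change from baseline to day 57 that
#' is correlated with the patient's expected UAS7 response, with partial
#' rebound at day 85.
#'
#' @param profiles data.frame from [generate_profiles()]
#' @param cfg a [trial_config()]
#' @param seed master seed
#' @return list with \code{elisa} (long well-level data.frame),
#'   \code{bhra} (raw histamine amounts) and \code{truth} (per
#'   patient-visit true reactivity, for validation)
#' @export
simulate_assay_measurements <- function(profiles, cfg, seed = cfg$seed) {
  arm_idx <- match(as.character(profiles$arm), names(cfg$arms))
  exp_change <- profile_expected_change(profiles, cfg)
  arm_mean_change <- stats::ave(exp_change, arm_idx)

  # per-patient percent change in relative reactivity, tied to response
  pct <- numeric(nrow(profiles))
  bg <- numeric(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    set.seed(derive_seed(seed, i, offset = 5L))
    pct[i] <- max(cfg$rr_arm_pct_change[arm_idx[i]] +
                    1.0 * (exp_change[i] - arm_mean_change[i]) +
                    stats::rnorm(1, 0, 15), -95)
    bg[i] <- stats::rlnorm(1, log(0.3), 0.3)
  }
  rr_visit <- cbind(
    "screening" = profiles$true_reactivity_baseline,
    "day 1" = profiles$true_reactivity_baseline,
    "day 57" = pmax(profiles$true_reactivity_baseline * (1 + pct / 100), 0),
    "day 85" = pmax(profiles$true_reactivity_baseline * (1 + pct / 200), 0)
  )

  elisa <- list()
  for (v in seq_along(ELISA_VISITS)) {
    batch <- ELISA_VISITS[v]
    set.seed(derive_seed(seed, 0L, offset = 10L + v))
    concs <- elisa_standard_concs()
    elisa[[length(elisa) + 1L]] <- elisa_wells(
      batch, NA_character_, "standard", "none",
      rep(concs, 2), rep(1:2, each = length(concs)), cfg$elisa_noise_sd)
    # healthy panel: paired control/antigen-spiked duplicates
    h_rr <- pmax(stats::rnorm(ELISA_N_HEALTHY, cfg$healthy_rr_mean,
                              cfg$healthy_rr_sd), 0)
    h_bg <- stats::rlnorm(ELISA_N_HEALTHY, log(0.3), 0.3)
    h_id <- sprintf("H%02d", seq_len(ELISA_N_HEALTHY))
    elisa[[length(elisa) + 1L]] <- elisa_wells(
      batch, rep(h_id, 4), "healthy_control",
      rep(rep(c("control_protein", "antigen"), each = ELISA_N_HEALTHY), 2),
      rep(c(h_bg + h_rr, h_bg), 2),
      rep(1:2, each = 2 * ELISA_N_HEALTHY), cfg$elisa_noise_sd)
    # patient samples
    for (i in seq_len(nrow(profiles))) {
      set.seed(derive_seed(seed, i, offset = 20L + v))
      elisa[[length(elisa) + 1L]] <- elisa_wells(
        batch, profiles$patient_id[i], "sample",
        rep(c("control_protein", "antigen"), 2),
        rep(c(bg[i] + rr_visit[i, v], bg[i]), 2),
        rep(1:2, each = 2), cfg$elisa_noise_sd)
    }
  }
  elisa <- do.call(rbind, elisa)
  rownames(elisa) <- NULL

  # BHRA: screening serum per patient + one healthy panel
  set.seed(derive_seed(seed, 0L, offset = 30L))
  h_pct <- pmin(pmax(stats::rnorm(BHRA_N_HEALTHY, cfg$healthy_hr_mean,
                                  cfg$healthy_hr_sd), 0), 100)
  noise <- function(n) if (cfg$bhra_noise_sd > 0)
    exp(stats::rnorm(n, 0, cfg$bhra_noise_sd)) else rep(1, n)
  bhra_rows <- list(data.frame(
    patient_id = sprintf("HB%02d", seq_len(BHRA_N_HEALTHY)),
    role = "healthy", visit = "screening",
    hr_released = h_pct / 100 * BHRA_HR_TOTAL,
    hr_total = BHRA_HR_TOTAL, stringsAsFactors = FALSE))
  for (i in seq_len(nrow(profiles))) {
    set.seed(derive_seed(seed, i, offset = 31L))
    tot <- BHRA_HR_TOTAL * noise(1)
    bhra_rows[[i + 1L]] <- data.frame(
      patient_id = profiles$patient_id[i], role = "patient",
      visit = "screening",
      hr_released = profiles$true_bhra_release[i] / 100 * tot * noise(1),
      hr_total = tot, stringsAsFactors = FALSE)
  }
  bhra <- do.call(rbind, bhra_rows)
  rownames(bhra) <- NULL

  truth <- data.frame(
    patient_id = rep(profiles$patient_id, length(ELISA_VISITS)),
    visit = rep(ELISA_VISITS, each = nrow(profiles)),
    true_rr = as.vector(rr_visit), stringsAsFactors = FALSE)

  list(elisa = elisa, bhra = bhra, truth = truth)
}
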